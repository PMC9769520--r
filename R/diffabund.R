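#' Build a per-gene count matrix from per-sample site tables
#'
#' Applies the same insertion pre-filters as the essentiality stage
#' ([filter_policy()]) to every sample's intragenic insertions, sums the
#' surviving read counts per gene, and drops genes previously called
#' putatively essential (their mutants are absent or dying for reasons
#' unrelated to the tested condition).
#'
#' @param site_tables named list of `tn_sites` tables, one per sample.
#' @param annotation gene table.
#' @param essential_gene_ids character vector of gene ids to exclude (e.g.
#'   `calls$gene_id[calls$essential]`), or a `tn_calls` object.
#' @param policy a [filter_policy()].
#' @return integer matrix genes x samples (rownames gene ids, colnames
#'   sample names), excluding essential genes.
#' @export
build_count_matrix <- function(site_tables, annotation,
                               essential_gene_ids = character(0),
                               policy = filter_policy()) {
  if (inherits(essential_gene_ids, "tn_calls")) {
    essential_gene_ids <-
      essential_gene_ids$gene_id[essential_gene_ids$essential]
  }
  .assert(length(names(site_tables)) == length(site_tables),
          "site_tables must be a named list")
  keep_genes <- setdiff(annotation$gene_id, essential_gene_ids)
  counts <- vapply(site_tables, function(sites) {
    g <- .filtered_gene_counts(sites, annotation, policy)
    g[keep_genes]
  }, numeric(length(keep_genes)))
  counts <- matrix(counts, nrow = length(keep_genes),
                   dimnames = list(keep_genes, names(site_tables)))
  counts[is.na(counts)] <- 0
  storage.mode(counts) <- "integer"
  zero <- colSums(counts) == 0L
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(names(site_tables)[zero], collapse = ", "), call. = FALSE)
  }
  counts
}

.gene_ids <- function(counts) {
  ids <- rownames(counts)
  if (is.null(ids)) sprintf("gene%d", seq_len(nrow(counts))) else ids
}

# vectorised: assign sites to genes, apply the filter policy, sum counts
.filtered_gene_counts <- function(sites, annotation, policy) {
  asg <- assign_to_genes(sites, annotation)$assignments
  out <- stats::setNames(rep(0, nrow(annotation)), annotation$gene_id)
  if (nrow(asg) == 0L) return(out)
  i <- match(asg$gene_id, annotation$gene_id)
  len <- annotation$end[i] - annotation$start[i] + 1L
  protein <- annotation$gene_type[i] == "protein"
  off <- asg$offset
  sns <- asg$sense
  w <- policy$edge_window
  keep <- rep(TRUE, nrow(asg))
  if (policy$drop_plus1_frame_sense) {
    keep <- keep & !(protein & sns &
                       off %% 3L == policy$plus1_frame_offset_mod3)
  }
  if (policy$drop_stop_codon) keep <- keep & !(protein & off >= len - 3L)
  if (policy$edge_both_orientations) {
    keep <- keep & off < len - w & off >= w
  } else {
    keep <- keep & !(sns & off >= len - w) & !(!sns & off < w)
  }
  if (!any(keep)) return(out)
  sums <- tapply(asg$read_count[keep], asg$gene_id[keep], sum)
  out[names(sums)] <- sums
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation scalars: each sample's counts are divided by
#' the per-gene geometric means across samples, and the sample's size
#' factor is the median of those ratios over genes whose geometric mean is
#' positive. Factors are rescaled to geometric mean 1.
#'
#' @param counts integer matrix genes x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  .assert(is.matrix(counts) && ncol(counts) >= 1, "counts must be a matrix")
  loggeo <- rowMeans(log(counts))
  usable <- is.finite(loggeo)
  .assert(any(usable),
          "no gene has nonzero counts in every sample")
  sf <- apply(counts, 2, function(col) {
    exp(stats::median((log(col) - loggeo)[usable & col > 0]))
  })
  sf / .geomean(sf)
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Simplified empirical dispersion estimation for count matrices:
#' gene-wise method-of-moments estimates
#' `alpha = max(0, (var - mu) / mu^2)` with variances pooled within
#' conditions, a mean-dispersion trend `alpha(mu) = a1 / mu + a0` fitted by
#' robust regression over genes, and a final estimate that combines
#' gene-wise and trend values on the log scale with weight
#' `shrink_weight` on the trend.
#'
#' @param counts integer matrix genes x samples.
#' @param sf size factors from [size_factors()].
#' @param condition factor/character of sample conditions (columns).
#' @param shrink_weight weight on the trend in the log-scale combination.
#' @param min_alpha floor applied before taking logs.
#' @return data.frame `gene_id`, `mu` (mean normalised count),
#'   `alpha_genewise`, `alpha_trend`, `alpha` (final); all-zero genes have
#'   NA dispersions.
#' @export
estimate_dispersions <- function(counts, sf, condition,
                                 shrink_weight = 0.5, min_alpha = 1e-8) {
  condition <- as.factor(condition)
  .assert(length(condition) == ncol(counts),
          "condition must have one entry per sample")
  .assert(all(table(condition) >= 2), "need >= 2 samples per condition")
  k <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(k)

  groups <- levels(condition)
  ssq <- matrix(0, nrow(k), length(groups))
  dfs <- numeric(length(groups))
  for (j in seq_along(groups)) {
    cols <- condition == groups[j]
    ssq[, j] <- apply(k[, cols, drop = FALSE], 1, stats::var)
    dfs[j] <- sum(cols) - 1
  }
  v <- as.numeric(ssq %*% dfs) / sum(dfs)
  alpha_gw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)

  fit_ok <- which(!is.na(alpha_gw) & alpha_gw > 0 & mu > 0)
  if (length(fit_ok) >= 10) {
    rfit <- MASS::rlm(alpha_gw[fit_ok] ~ I(1 / mu[fit_ok]), maxit = 50)
    a0 <- max(stats::coef(rfit)[1], min_alpha)
    a1 <- max(stats::coef(rfit)[2], 0)
  } else {
    a0 <- max(stats::median(alpha_gw[fit_ok]), min_alpha)
    if (is.na(a0)) a0 <- min_alpha
    a1 <- 0
  }
  alpha_tr <- ifelse(mu > 0, a1 / mu + a0, NA_real_)

  # gene-wise estimates below the trend are dominated by sampling noise at
  # few replicates and are raised to the trend before combining; only
  # above-trend (outlier-like) dispersion survives partially
  gw_floored <- pmax(alpha_gw, alpha_tr, min_alpha)
  alpha <- exp(shrink_weight * log(pmax(alpha_tr, min_alpha)) +
                 (1 - shrink_weight) * log(gw_floored))
  alpha[is.na(alpha_gw)] <- NA_real_
  data.frame(gene_id = .gene_ids(counts), mu = mu,
             alpha_genewise = alpha_gw, alpha_trend = alpha_tr,
             alpha = alpha, stringsAsFactors = FALSE)
}

# one-gene NB GLM (log link, offset log sf) by IRLS; returns coef, SE and
# convergence flag for the two-group design matrix X
.nb_irls <- function(y, X, offset, alpha, max_iter = 50, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- stats::lm.fit(X, eta - offset)$coefficients
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta) + offset
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z)[, 1],
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      ok <- TRUE
      break
    }
    beta <- beta_new
  }
  mu <- exp(as.numeric(X %*% beta) + offset)
  W <- mu / (1 + alpha * mu)
  info <- t(X * W) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
    rep(NA_real_, ncol(X)))
  list(beta = beta, se = se, converged = ok)
}

#' Per-gene negative-binomial Wald test
#'
#' Fits, for every gene, a negative-binomial GLM with log link,
#' size-factor offsets and a two-group design (reference condition vs
#' selected condition) by iteratively reweighted least squares, and tests
#' the group log2 fold change with a two-sided Wald test. Genes with zero
#' counts throughout one group get a 0.5-count continuity correction and
#' are flagged `pseudo`.
#'
#' @param counts integer matrix genes x samples.
#' @param sf size factors.
#' @param dispersions data.frame from [estimate_dispersions()] (its
#'   `alpha` column is used), or a numeric vector of per-gene dispersions.
#' @param condition factor of sample conditions; its first level is the
#'   reference.
#' @return data.frame `gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`,
#'   `stat`, `pvalue`, `converged`, `pseudo`.
#' @export
wald_test <- function(counts, sf, dispersions, condition) {
  condition <- as.factor(condition)
  .assert(nlevels(condition) == 2,
          "wald_test expects a two-group design")
  alpha <- if (is.data.frame(dispersions)) dispersions$alpha else dispersions
  .assert(length(alpha) == nrow(counts),
          "one dispersion per gene required")
  X <- cbind(1, as.numeric(condition == levels(condition)[2]))
  offset <- log(sf)
  k <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[1]

  n <- nrow(counts)
  out <- data.frame(gene_id = .gene_ids(counts),
                    baseMean = rowMeans(k),
                    log2FoldChange = NA_real_, lfcSE = NA_real_,
                    stat = NA_real_, pvalue = NA_real_,
                    converged = FALSE, pseudo = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(alpha[i])) next
    y <- counts[i, ]
    pseudo <- all(y[g1] == 0L) || all(y[!g1] == 0L)
    if (pseudo) y <- y + 0.5
    fit <- .nb_irls(y, X, offset, alpha[i])
    out$log2FoldChange[i] <- fit$beta[2] / log(2)
    out$lfcSE[i] <- fit$se[2] / log(2)
    out$stat[i] <- fit$beta[2] / fit$se[2]
    out$pvalue[i] <- if (fit$converged && is.finite(out$stat[i]))
      2 * stats::pnorm(-abs(out$stat[i])) else NA_real_
    out$converged[i] <- fit$converged
    out$pseudo[i] <- pseudo
  }
  out
}

#' Benjamini-Hochberg adjustment and enrichment/depletion calls
#'
#' @param results data.frame from [wald_test()].
#' @param alpha false-discovery level.
#' @return the results with `padj` and `call` columns
#'   (`enriched`/`depleted`/`ns`): significant genes with positive log2
#'   fold change are enriched mutants, negative depleted.
#' @export
bh_adjust <- function(results, alpha = 0.1) {
  results$padj <- stats::p.adjust(results$pvalue, method = "BH")
  sig <- !is.na(results$padj) & results$padj <= alpha
  results$call <- ifelse(!sig, "ns",
                         ifelse(results$log2FoldChange > 0,
                                "enriched", "depleted"))
  attr(results, "alpha") <- alpha
  results
}

#' Conditional enrichment/depletion analysis of a count matrix
#'
#' Full differential-abundance stage: median-of-ratios size factors,
#' simplified dispersion estimation, per-gene NB Wald test and BH
#' correction.
#'
#' @inheritParams wald_test
#' @param alpha_fdr false-discovery level for [bh_adjust()].
#' @param shrink_weight passed to [estimate_dispersions()].
#' @return object of class `tn_diff` (a data.frame) with the standard
#'   columns `gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`, `stat`,
#'   `pvalue`, `padj`, `call`.
#' @export
diff_abundance <- function(counts, condition, alpha_fdr = 0.1,
                           shrink_weight = 0.5) {
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf, condition,
                               shrink_weight = shrink_weight)
  res <- wald_test(counts, sf, disp, condition)
  res <- bh_adjust(res, alpha = alpha_fdr)
  attr(res, "size_factors") <- sf
  class(res) <- c("tn_diff", "data.frame")
  res
}

#' @export
print.tn_diff <- function(x, ...) {
  cat(sprintf("NB Wald enrichment/depletion: %d genes, %d enriched, %d depleted (BH alpha = %g)\n",
              nrow(x), sum(x$call == "enriched", na.rm = TRUE),
              sum(x$call == "depleted", na.rm = TRUE), attr(x, "alpha")))
  invisible(x)
}

#' @method summary tn_diff
#' @export
summary.tn_diff <- function(object, ...) {
  cat(sprintf("out of %d genes tested:\n", nrow(object)))
  cat(sprintf("  enriched: %d\n", sum(object$call == "enriched", na.rm = TRUE)))
  cat(sprintf("  depleted: %d\n", sum(object$call == "depleted", na.rm = TRUE)))
  cat(sprintf("  non-converged fits: %d\n", sum(!object$converged)))
  invisible(object)
}
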