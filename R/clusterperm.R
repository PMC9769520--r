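#' Maximal runs of essential genes in genomic order
#'
#' @param labels logical/0-1 vector of essential flags in genomic gene
#'   order.
#' @param circular if `TRUE`, a run wrapping from the last to the first
#'   gene is merged.
#' @return data.frame `start_index`, `length`, one row per maximal run of
#'   essential genes.
#' @examples
#' find_clusters(c(0, 1, 1, 0, 1, 1, 1))
#' @export
find_clusters <- function(labels, circular = FALSE) {
  lab <- as.integer(as.logical(labels))
  n <- length(lab)
  if (n == 0L || !any(lab == 1L)) {
    return(data.frame(start_index = integer(0), length = integer(0)))
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  out <- data.frame(start_index = starts[keep], length = r$lengths[keep])
  if (circular && nrow(out) > 1L &&
      out$start_index[1] == 1L &&
      out$start_index[nrow(out)] + out$length[nrow(out)] - 1L == n) {
    # wrap-around: merge last run into first
    out$start_index[1] <- out$start_index[nrow(out)]
    out$length[1] <- out$length[1] + out$length[nrow(out)]
    out <- out[-nrow(out), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# longest run of TRUE in a sampled label arrangement, via the positions of
# the essential labels (equivalent to shuffling the full label vector)
.max_run_from_positions <- function(pos) {
  if (length(pos) == 0L) return(0L)
  r <- rle(diff(pos) == 1L)
  m <- r$lengths[r$values]
  if (length(m)) max(m) + 1L else 1L
}

#' Monte-Carlo p-values for runs of essential genes
#'
#' Estimates, for each queried run length n, the probability that a random
#' arrangement of the observed label multiset (uniform shuffle of
#' `n_essential` essential flags among `n_genes` genes) contains at least
#' one run of >= n consecutive essential genes. The add-one estimator
#' p = (#{permutations with max run >= n} + 1) / (n_perm + 1) counts the
#' observed arrangement itself and never returns 0.
#'
#' @param n_genes total number of (protein-coding) genes, or the full
#'   label vector in genomic order (in which case `n_essential` is
#'   derived from it).
#' @param n_essential number of essential labels among them.
#' @param lengths integer vector of run lengths to test.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `tn_perm_test`: list with `p_values` (named
#'   numeric, one per length), `lengths`, `n_perm`, `n_genes`,
#'   `n_essential`, `max_run_counts` (tabulated null max-run lengths).
#' @export
permutation_pvalues <- function(n_genes, n_essential = NULL, lengths,
                                n_perm = 100000L, seed = 1L) {
  if (length(n_genes) > 1L) {
    labels <- as.logical(n_genes)
    n_genes <- length(labels)
    n_essential <- sum(labels)
  }
  .assert(n_perm >= 1, "n_perm must be >= 1")
  .assert(all(lengths >= 1 & lengths <= n_genes),
          "lengths must lie in 1..n_genes")
  .assert(n_essential >= 0 && n_essential <= n_genes,
          "n_essential must lie in 0..n_genes")
  set.seed(seed)
  maxrun <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    maxrun[i] <- .max_run_from_positions(sort.int(sample.int(n_genes,
                                                             n_essential)))
  }
  p <- vapply(lengths, function(n) (sum(maxrun >= n) + 1) / (n_perm + 1),
              numeric(1))
  names(p) <- as.character(lengths)
  structure(list(p_values = p, lengths = as.integer(lengths),
                 n_perm = as.integer(n_perm),
                 n_genes = as.integer(n_genes),
                 n_essential = as.integer(n_essential),
                 max_run_counts = table(maxrun)),
            class = "tn_perm_test")
}

#' @export
print.tn_perm_test <- function(x, ...) {
  cat(sprintf("run-length permutation test: %s genes, %s essential, %s permutations\n",
              format(x$n_genes, big.mark = ","),
              format(x$n_essential, big.mark = ","),
              format(x$n_perm, big.mark = ",")))
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Exact run-length p-values by exhaustive enumeration
#'
#' Enumerates all arrangements of the label multiset (feasible for small
#' gene counts) and returns the exact probability of at least one run of
#' >= n essential genes. Serves as the independent oracle for
#' [permutation_pvalues()].
#'
#' @inheritParams permutation_pvalues
#' @return named numeric vector of exact probabilities.
#' @export
exact_run_pvalues <- function(n_genes, n_essential, lengths) {
  .assert(choose(n_genes, n_essential) <= 2e6,
          "too many arrangements to enumerate")
  combos <- utils::combn(n_genes, n_essential)
  maxrun <- apply(combos, 2, .max_run_from_positions)
  p <- vapply(lengths, function(n) mean(maxrun >= n), numeric(1))
  names(p) <- as.character(lengths)
  p
}

#' Holm step-down decisions at family-wise level alpha
#'
#' One hypothesis per tested run length; decisions via
#' `stats::p.adjust(method = "holm")`.
#'
#' @param pvals named numeric vector of p-values.
#' @param alpha family-wise error level.
#' @return named logical vector, `TRUE` where rejected (significant).
#' @export
holm_adjust <- function(pvals, alpha = 0.05) {
  stats::p.adjust(pvals, method = "holm") <= alpha
}

#' Flag observed clusters by the significance of their lengths
#'
#' @param clusters data.frame from [find_clusters()].
#' @param perm a `tn_perm_test` whose tested lengths cover the distinct
#'   observed cluster lengths.
#' @param alpha family-wise error level for the Holm step-down.
#' @return object of class `tn_cluster_test`: the cluster table with
#'   `p_value` and `holm_significant` columns, plus attributes
#'   `min_significant_length` and `alpha`.
#' @export
call_significant_clusters <- function(clusters, perm, alpha = 0.05) {
  obs_lengths <- sort(unique(clusters$length))
  .assert(all(obs_lengths %in% perm$lengths),
          "permutation test does not cover all observed cluster lengths")
  p_by_len <- perm$p_values[as.character(obs_lengths)]
  sig_by_len <- holm_adjust(p_by_len, alpha)
  out <- clusters
  out$p_value <- unname(p_by_len[as.character(clusters$length)])
  out$holm_significant <- unname(sig_by_len[as.character(clusters$length)])
  min_sig <- if (any(out$holm_significant))
    min(out$length[out$holm_significant]) else NA_integer_
  structure(out, min_significant_length = min_sig, alpha = alpha,
            class = c("tn_cluster_test", "data.frame"))
}

#' @export
print.tn_cluster_test <- function(x, ...) {
  cat(sprintf("%d essential-gene clusters, %d significant (Holm alpha = %g)\n",
              nrow(x), sum(x$holm_significant), attr(x, "alpha")))
  ms <- attr(x, "min_significant_length")
  if (!is.na(ms)) cat(sprintf("minimum significant cluster length: %d genes\n", ms))
  NextMethod()
}

#' Smallest run length with chance probability below a threshold
#'
#' Convenience wrapper: estimates run-length p-values for a range of
#' lengths and reports the smallest length whose Monte-Carlo probability of
#' occurring by chance falls below `threshold`.
#'
#' @inheritParams permutation_pvalues
#' @param threshold probability cutoff.
#' @return list with `min_length` and the underlying `tn_perm_test`.
#' @export
min_significant_run_length <- function(n_genes, n_essential,
                                       lengths = 3:10, n_perm = 100000L,
                                       threshold = 0.05, seed = 1L) {
  perm <- permutation_pvalues(n_genes, n_essential, lengths, n_perm, seed)
  below <- perm$p_values < threshold
  list(min_length = if (any(below)) min(perm$lengths[below]) else NA_integer_,
       perm = perm)
}
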