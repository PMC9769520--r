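nb_counts <- function(n, mu, alpha) {
  if (alpha <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

test_that("count matrices recount the site tables with filters applied", {
  ann <- data.frame(gene_id = c("g1", "g2"),
                    start = c(101L, 601L), end = c(400L, 900L),
                    strand = "+", gene_type = "protein",
                    essential = c(FALSE, TRUE), stringsAsFactors = FALSE)
  # two antisense mid-gene insertions in g1 (survive every filter) with
  # read counts 3 and 5; one insertion in the essential g2
  sites <- data.frame(position = c(201L, 251L, 700L),
                      orientation = c("-", "-", "-"),
                      read_count = c(3L, 5L, 7L))
  class(sites) <- c("tn_sites", "data.frame")
  m <- build_count_matrix(list(s1 = sites), ann,
                          essential_gene_ids = "g2")
  expect_equal(rownames(m), "g1")
  expect_equal(unname(m["g1", "s1"]), 8L)

  # a sample with zero surviving counts is an error
  empty <- sites[0, ]
  class(empty) <- c("tn_sites", "data.frame")
  expect_error(build_count_matrix(list(s1 = sites, s2 = empty), ann,
                                  essential_gene_ids = "g2"),
               "zero total counts")

  # synthetic many-gene matrix equals a brute-force recount
  cfg <- small_config(genome_length = 80000L, n_genes = 50L,
                      n_insertions = 4000L)
  gen <- generate_genome(cfg)
  lib <- simulate_insertion_library(gen$genome, gen$annotation, cfg)
  st <- unique_sites(cbind(lib$pool[, c("position", "orientation")],
                           read_count = 1L +
                             rpois(nrow(lib$pool), 20)))
  pol <- filter_policy()
  m2 <- build_count_matrix(list(a = st), gen$annotation, character(0), pol)
  ann2 <- gen$annotation
  brute <- sapply(ann2$gene_id, function(g) {
    row <- ann2[ann2$gene_id == g, ]
    len <- row$end - row$start + 1L
    inside <- st[st$position >= row$start & st$position <= row$end, ]
    if (nrow(inside) == 0) return(0L)
    off <- if (row$strand == "+") inside$position - row$start
           else row$end - inside$position
    sns <- inside$orientation == row$strand
    keep <- rep(TRUE, nrow(inside))
    if (row$gene_type == "protein") {
      keep <- keep & !(sns & off %% 3 == 0) & !(off >= len - 3)
    }
    keep <- keep & !(sns & off >= len - 9) & !(!sns & off < 9)
    sum(inside$read_count[keep])
  })
  expect_equal(unname(m2[, "a"]), unname(brute[rownames(m2)]))
})

test_that("median-of-ratios size factors have the documented closed forms", {
  a <- c(10, 30, 100)
  m <- cbind(s1 = a, s2 = a)
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = a, s2 = 2 * a)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(prod(sf), 1, tolerance = 1e-12)

  m3 <- matrix(c(10, 30, 100, 20, 60, 200), ncol = 2)
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), 2)

  # independent cross-check against the reference implementation
  set.seed(8)
  m4 <- matrix(rnbinom(300, mu = 50, size = 5), ncol = 6)
  ours <- size_factors(m4)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m4)
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]),
               tolerance = 1e-10)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("dispersion estimation recovers simulated values", {
  set.seed(10)
  cond <- rep(c("a", "b"), each = 25)
  pois <- t(replicate(300, nb_counts(50, 100, 0)))
  colnames(pois) <- paste0("s", 1:50)
  d <- estimate_dispersions(pois, rep(1, 50), cond)
  expect_lte(median(d$alpha), 0.01)

  nb <- t(replicate(300, nb_counts(200, 100, 0.5)))
  d2 <- estimate_dispersions(nb, rep(1, 200), rep(c("a", "b"), each = 100))
  expect_lt(abs(median(d2$alpha) - 0.5), 0.1)

  const <- matrix(7, nrow = 4, ncol = 6)
  rownames(const) <- paste0("g", 1:4)
  d3 <- estimate_dispersions(const, rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(all(d3$alpha_genewise == 0))
})

test_that("the NB Wald fit matches closed forms and a reference GLM", {
  # single gene, two groups, equal size factors: LFC is the log2 ratio of
  # group means
  y <- matrix(c(12L, 18L, 15L, 45L, 60L, 75L), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  cond <- factor(rep(c("ref", "sel"), each = 3), levels = c("ref", "sel"))
  res <- wald_test(y, rep(1, 6), 0.1, cond)
  expect_equal(res$log2FoldChange, log2(mean(y[1, 4:6]) / mean(y[1, 1:3])),
               tolerance = 1e-6)

  # coefficients and standard errors against glm with a fixed-theta NB
  # family (an independent IRLS implementation)
  set.seed(12)
  sf <- c(0.8, 1, 1.25, 0.9, 1.1, 1)
  counts <- rbind(g1 = rnbinom(6, mu = 80 * sf, size = 10),
                  g2 = as.integer(round(c(40, 50, 60, 15, 12, 18) * sf)))
  res2 <- wald_test(counts, sf, c(0.1, 0.1), cond)
  for (i in 1:2) {
    fit <- suppressWarnings(
      glm(counts[i, ] ~ cond + offset(log(sf)),
          family = MASS::negative.binomial(theta = 10)))
    sm <- summary(fit, dispersion = 1)$coefficients
    expect_equal(res2$log2FoldChange[i], sm[2, 1] / log(2), tolerance = 1e-4)
    expect_equal(res2$lfcSE[i], sm[2, 2] / log(2), tolerance = 1e-3)
  }

  # null behaviour: LFC centred at 0, p-values roughly uniform
  set.seed(13)
  null <- t(replicate(400, nb_counts(6, 100, 0.05)))
  rownames(null) <- paste0("g", 1:400)
  resn <- diff_abundance(null, cond)
  expect_lt(abs(median(resn$log2FoldChange, na.rm = TRUE)), 0.1)
  expect_gt(mean(resn$pvalue, na.rm = TRUE), 0.35)
  expect_lt(mean(resn$pvalue, na.rm = TRUE), 0.65)

  # recovery of a simulated 4-fold depletion
  set.seed(14)
  dep <- t(sapply(1:200, function(i)
    c(nb_counts(3, 200, 0.1), nb_counts(3, 50, 0.1))))
  rownames(dep) <- paste0("g", 1:200)
  resd <- wald_test(dep, rep(1, 6), rep(0.1, 200), cond)
  expect_lt(abs(median(resd$log2FoldChange) + 2), 0.3)
})

test_that("BH adjustment and calls follow the step-up definition", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2FoldChange = c(1, -1, 2),
                    pvalue = c(0.01, 0.02, 0.9))
  adj <- bh_adjust(res, alpha = 0.1)
  expect_equal(adj$padj, c(0.03, 0.03, 0.9))
  expect_equal(adj$call, c("enriched", "depleted", "ns"))

  res$pvalue <- rep(1, 3)
  expect_true(all(bh_adjust(res)$call == "ns"))
})

test_that("rescaling one sample moves its size factor, not the LFCs", {
  set.seed(15)
  cond <- factor(rep(c("ref", "sel"), each = 3), levels = c("ref", "sel"))
  counts <- matrix(rnbinom(600, mu = 100, size = 10), ncol = 6,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 4L
  sf1 <- size_factors(counts)
  sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[3] / sf1[3] / (sf2[1] / sf1[1])), 4,
               tolerance = 1e-10)
  # with fixed dispersions the fitted LFCs are essentially unchanged
  w1 <- wald_test(counts, sf1, rep(0.1, 100), cond)
  w2 <- wald_test(scaled, sf2, rep(0.1, 100), cond)
  expect_lt(max(abs(w2$log2FoldChange - w1$log2FoldChange)), 0.05)
  # re-estimating dispersions perturbs them only marginally
  r1 <- diff_abundance(counts, cond)
  r2 <- diff_abundance(scaled, cond)
  expect_lt(max(abs(r2$log2FoldChange - r1$log2FoldChange)), 0.1)
})
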