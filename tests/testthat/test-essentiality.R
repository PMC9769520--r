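test_that("site-to-gene assignment uses 5' offsets on the gene strand", {
  ann <- toy_annotation()
  sites <- unique_sites(data.frame(
    position = c(101L, 199L, 199L, 350L),
    orientation = c("+", "-", "+", "+")))
  asg <- assign_to_genes(sites, ann)
  expect_equal(asg$intragenic_count, 3L)  # 101+, 199-, 199+ all inside gA
  expect_equal(asg$intergenic_count, 1L)  # 350 between genes

  a <- asg$assignments
  # plus-strand gene gA starts at 101: offset 0, sense when orientation +
  row <- a[a$gene_id == "gA" & a$offset == 0L & a$sense, , drop = FALSE]
  expect_equal(nrow(row), 1)
  # gB is [401,700] on minus strand; none of these sites are inside it
  expect_false("gB" %in% a$gene_id)

  # minus-strand gene [100,199]: site at 199 with orientation "-" is the 5'
  # end, offset 0, sense
  annm <- data.frame(gene_id = "gM", start = 100L, end = 199L, strand = "-",
                     gene_type = "protein", essential = FALSE,
                     stringsAsFactors = FALSE)
  am <- assign_to_genes(sites, annm)$assignments
  m <- am[am$offset == 0L, , drop = FALSE]
  expect_equal(nrow(m), 2)        # both orientations sit at the 5' base
  expect_equal(sum(m$sense), 1L)  # only orientation "-" is sense

})

test_that("insertion pre-filters match a brute-force per-rule check", {
  pol <- filter_policy()
  gene <- data.frame(gene_id = "g", start = 1L, end = 999L, strand = "+",
                     gene_type = "protein", stringsAsFactors = FALSE)

  # forced single-rule cases
  g300 <- transform(gene, end = 300L)
  stopcase <- data.frame(offset = 297L, sense = TRUE, read_count = 1L)
  expect_equal(nrow(apply_filters(stopcase, pol, g300)), 0)
  anti_first <- data.frame(offset = 4L, sense = FALSE, read_count = 1L)
  expect_equal(nrow(apply_filters(anti_first, pol, g300)), 0)

  # random profiles vs an independent re-statement of every rule
  set.seed(21)
  for (rep in 1:5) {
    prof <- data.frame(offset = sample(0:998, 200, replace = TRUE),
                       sense = sample(c(TRUE, FALSE), 200, replace = TRUE),
                       read_count = 1L)
    got <- apply_filters(prof, pol, gene)
    len <- 999L
    keep <- !(prof$sense & prof$offset %% 3 == 0) &      # +1 frame, sense
      !(prof$offset >= len - 3) &                        # stop codon
      !(prof$sense & prof$offset >= len - 9) &           # sense, last 9 bp
      !(!prof$sense & prof$offset < 9)                   # antisense, first 9
    expect_equal(got, prof[keep, ], ignore_attr = TRUE)
  }

  # RNA genes: frame and stop-codon filters do not apply
  rna <- transform(gene, gene_type = "RNA")
  prof <- data.frame(offset = c(0L, 996L, 500L), sense = TRUE,
                     read_count = 1L)
  out <- apply_filters(prof, pol, rna)
  expect_equal(sort(out$offset), c(0L, 500L))  # only the last-9 filter bites

  # idempotence
  prof2 <- data.frame(offset = sample(0:998, 100), sense = TRUE,
                      read_count = 1L)
  once <- apply_filters(prof2, pol, gene)
  expect_identical(apply_filters(once, pol, gene), once)
})

test_that("gene classification implements the three essentiality rules", {
  pol <- filter_policy()
  gene <- data.frame(gene_id = "g", start = 1L, end = 1000L, strand = "+",
                     gene_type = "protein", stringsAsFactors = FALSE)
  none <- data.frame(offset = integer(0), sense = logical(0),
                     read_count = integer(0))
  expect_equal(classify_gene(none, gene, pol)$verdict, "essential_non_hit")

  one95 <- data.frame(offset = 950L, sense = FALSE, read_count = 1L)
  expect_equal(classify_gene(one95, gene, pol)$verdict, "essential_last10")

  two <- data.frame(offset = c(10L, 900L), sense = FALSE, read_count = 1L)
  cl <- classify_gene(two, gene, pol)
  expect_equal(cl$verdict, "essential_gap80")
  expect_equal(cl$largest_gap_fraction, 889 / 1000)

  dense <- data.frame(offset = seq(50L, 950L, by = 100L), sense = FALSE,
                      read_count = 1L)
  expect_equal(classify_gene(dense, gene, pol)$verdict, "nonessential")
})

test_that("adding insertions never turns a nonessential gene essential", {
  pol <- filter_policy()
  gene <- data.frame(gene_id = "g", start = 1L, end = 900L, strand = "+",
                     gene_type = "protein", stringsAsFactors = FALSE)
  set.seed(33)
  for (rep in 1:20) {
    prof <- data.frame(offset = sample(0:899, sample(3:12, 1)),
                       sense = FALSE, read_count = 1L)
    v1 <- classify_gene(apply_filters(prof, pol, gene), gene, pol)$verdict
    extra <- rbind(prof, data.frame(offset = sample(0:899, 1),
                                    sense = FALSE, read_count = 1L))
    v2 <- classify_gene(apply_filters(extra, pol, gene), gene, pol)$verdict
    if (v1 == "nonessential") expect_equal(v2, "nonessential")
  }
})

test_that("call summaries count verdicts and sequence features", {
  cfg <- small_config(genome_length = 60000L, n_genes = 40L,
                      n_insertions = 6000L)
  gen <- generate_genome(cfg)
  lib <- simulate_insertion_library(gen$genome, gen$annotation, cfg)
  sites <- unique_sites(lib$pool[, c("position", "orientation")])
  calls <- call_essentiality(sites, gen$annotation)
  s <- summarize_calls(calls, gen$annotation, gen$genome)
  expect_equal(s$n_essential, s$n_essential_protein + s$n_essential_rna)
  expect_equal(s$percent_essential,
               round_half_up(100 * s$n_essential / s$n_genes))
  if (s$n_essential_protein > 0) {
    expect_true(s$essential_protein_gc_percent > 0 &&
                  s$essential_protein_gc_percent < 100)
  }

  # all-nonessential degenerate case
  calls0 <- calls
  calls0$essential <- FALSE
  calls0$verdict <- "nonessential"
  s0 <- summarize_calls(calls0, gen$annotation, gen$genome)
  expect_equal(s0$n_essential, 0)
  expect_true(is.na(s0$essential_protein_gc_percent))
})
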