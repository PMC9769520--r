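test_that("marker filtering keeps exactly the transposon-derived reads", {
  marker <- "ACTTGTGTATAAGAGTCAG"
  out <- filter_and_trim(paste0(marker, "ACGTACGTACGTACGTACGT"), marker)
  expect_equal(out$fragments$sequence, "ACGTACGTACGTACGTACGT")

  out <- filter_and_trim("TTTTTTTTTTTTTTTTTTTTTTTT", marker)
  expect_equal(nrow(out$fragments), 0)
  expect_equal(unname(out$attrition["n_no_marker"]), 1L)

  # 1000 simulated reads, 100 spiked marker-free decoys -> exactly 900 kept
  cfg <- small_config(library_size = 900L)
  gen <- generate_genome(cfg)
  lib <- simulate_insertion_library(gen$genome, gen$annotation, cfg)
  rd <- simulate_reads(lib$pool, gen$genome, cfg)
  set.seed(5)
  decoys <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), cfg$read_length, replace = TRUE),
          collapse = ""), character(1))
  stopifnot(!any(grepl(cfg$oend_marker, decoys, fixed = TRUE)))
  reads <- data.frame(id = sprintf("r%04d", 1:1000),
                      sequence = c(rd$reads$sequence, decoys))
  out <- filter_and_trim(reads, cfg$oend_marker)
  expect_equal(nrow(out$fragments), 900)
  expect_equal(unname(out$attrition["n_no_marker"]), 100L)

  # trailing primer sequence is cut off
  out <- filter_and_trim(paste0(marker, "ACGTACGTACGTACGTAAAA", "GGGCCCGGG"),
                         marker, primer_set = "GGGCCCGGG")
  expect_equal(out$fragments$sequence, "ACGTACGTACGTACGTAAAA")
})

test_that("seed-and-extend alignment agrees with a brute-force scan", {
  genome <- random_genome(50000, seed = 3)
  idx <- genome_index(genome)

  # a unique substring maps to its own position with identity 1
  frag <- substr(genome, 12345, 12345 + 99)
  hit <- align_fragment(frag, idx)
  expect_true(hit$mapped && !hit$ambiguous)
  expect_equal(hit$contig_position, 12345L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$identity, 1)

  # a duplicated locus with identical full-length identity is ambiguous
  dup <- paste0(substr(genome, 1, 3000),
                substr(genome, 10001, 10150),   # copy of a 150 bp block
                substr(genome, 3001, 50000))
  hitd <- align_fragment(substr(genome, 10001, 10150), genome_index(dup))
  expect_true(hitd$ambiguous)

  # 500 error-free fragments vs exhaustive string search on both strands
  set.seed(9)
  starts <- sample(49000, 400)
  strands <- sample(c("+", "-"), 400, replace = TRUE)
  rc <- reverse_complement(genome)
  frags <- ifelse(strands == "+",
                  substring(genome, starts, starts + 119),
                  substring(rc, 50000 - (starts + 119) + 1, 50000 - starts + 1))
  hits <- align_fragments(frags, idx)
  for (i in seq_len(50)) {  # spot-check a subset against the full scan
    fwd <- gregexpr(frags[i], genome, fixed = TRUE)[[1]]
    rev <- gregexpr(frags[i], rc, fixed = TRUE)[[1]]
    n_occ <- sum(fwd > 0) + sum(rev > 0)
    expect_equal(n_occ, 1L)
    if (strands[i] == "+") {
      expect_equal(hits$contig_position[i], starts[i])
      expect_equal(hits$strand[i], "+")
    } else {
      # fragment came from the minus strand ending at starts[i] + 119
      expect_equal(hits$contig_position[i], starts[i] + 119L)
      expect_equal(hits$strand[i], "-")
    }
  }
  expect_true(all(hits$mapped))
  expect_true(all(hits$identity == 1))
  expect_false(any(hits$ambiguous))
})

test_that("duplication correction follows the documented convention", {
  hit <- data.frame(contig_position = 100L, strand = "+", coverage = 1,
                    identity = 1, ambiguous = FALSE, mapped = TRUE)
  site <- to_insertion_site(hit, dup_len = 9)
  expect_equal(site$position, 108L)
  expect_equal(site$orientation, "-")

  # no-duplication limit: position unchanged, orientation flipped
  site0 <- to_insertion_site(hit, dup_len = 0)
  expect_equal(site0$position, 100L)
  expect_equal(site0$orientation, "-")

  hitm <- transform(hit, strand = "-")
  sitem <- to_insertion_site(hitm, dup_len = 9)
  expect_equal(sitem$position, 92L)
  expect_equal(sitem$orientation, "+")

  # circular wrap
  wrap <- to_insertion_site(data.frame(contig_position = 998L, strand = "+",
                                       coverage = 1, identity = 1,
                                       ambiguous = FALSE, mapped = TRUE),
                            dup_len = 9, genome_length = 1000L)
  expect_equal(wrap$position, 6L)
})

test_that("error-free simulator round trip recovers truth sites exactly", {
  cfg <- small_config(genome_length = 40000L, n_genes = 25L,
                      n_insertions = 1200L, library_size = 20000L)
  gen <- generate_genome(cfg)
  lib <- simulate_insertion_library(gen$genome, gen$annotation, cfg)
  rd <- simulate_reads(lib$pool, gen$genome, cfg)
  rs <- reads_to_sites(rd$reads, gen$genome, cfg$oend_marker,
                       dup_len = cfg$duplication_length)
  got <- paste(rs$sites$position, rs$sites$orientation)
  truth <- paste(rd$truth$position, rd$truth$orientation)
  expect_setequal(got, unique(truth))
  # read counts per site match the truth sidecar
  tt <- table(truth)
  expect_equal(rs$sites$read_count,
               as.integer(tt[paste(rs$sites$position, rs$sites$orientation)]))
})

test_that("unique site collapsing matches brute-force grouping", {
  obs <- data.frame(position = c(10L, 10L, 10L), orientation = "+")
  u <- unique_sites(obs)
  expect_equal(nrow(u), 1)
  expect_equal(u$read_count, 3L)

  obs2 <- data.frame(position = c(10L, 10L), orientation = c("+", "-"))
  expect_equal(nrow(unique_sites(obs2)), 2)

  set.seed(4)
  obs3 <- data.frame(position = sample(1000L, 10000L, replace = TRUE),
                     orientation = sample(c("+", "-"), 10000L, replace = TRUE))
  u3 <- unique_sites(obs3)
  b3 <- brute_unique(obs3)
  expect_equal(u3$position, b3$position)
  expect_equal(u3$orientation, b3$orientation)
  expect_equal(u3$read_count, b3$read_count)
})

test_that("reverse-complementing genome and reads mirrors the site table", {
  cfg <- small_config(genome_length = 20000L, n_genes = 10L,
                      n_insertions = 300L, library_size = 3000L)
  gen <- generate_genome(cfg)
  lib <- simulate_insertion_library(gen$genome, gen$annotation, cfg)
  rd <- simulate_reads(lib$pool, gen$genome, cfg)
  rs <- reads_to_sites(rd$reads, gen$genome, cfg$oend_marker)

  rc_genome <- reverse_complement(gen$genome)
  rs_rc <- reads_to_sites(rd$reads, rc_genome, cfg$oend_marker)
  L <- nchar(gen$genome)
  mirrored <- data.frame(position = L - rs$sites$position + 1L,
                         orientation = ifelse(rs$sites$orientation == "+",
                                              "-", "+"))
  expect_setequal(paste(rs_rc$sites$position, rs_rc$sites$orientation),
                  paste(mirrored$position, mirrored$orientation))
})
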