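# shared fixture builders; everything is generated in code, no data files

# small but alignable study configuration for fast end-to-end runs
small_config <- function(...) {
  args <- list(genome_length = 30000L, n_genes = 30L, n_insertions = 800L,
               library_size = 5000L, per_base_error = 0,
               generations = 5L, bottleneck = Inf, seed = 7L,
               mean_gene_length = 500L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# deterministic toy genome with one gene on each strand
toy_annotation <- function() {
  data.frame(gene_id = c("gA", "gB"),
             start = c(101L, 401L), end = c(250L, 700L),
             strand = c("+", "-"),
             gene_type = c("protein", "protein"),
             essential = c(FALSE, FALSE),
             operon_id = c(1L, 2L),
             stringsAsFactors = FALSE)
}

random_genome <- function(len, seed = 1, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force site-collapsing oracle used against unique_sites()
brute_unique <- function(obs) {
  key <- paste(obs$position, obs$orientation, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                    orientation = vapply(parts, `[`, "", 2),
                    read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$orientation), ]
}
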