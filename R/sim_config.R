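#' Configuration for the synthetic Tn-Seq study generator
#'
#' Bundles every tunable of the simulator: genome composition, gene/operon
#' layout, the essential-gene fraction, transposon geometry (9-bp target
#' duplication, O-end marker), sequencing parameters and the selection
#' design. The defaults emulate a high-GC betaproteobacterial chromosome
#' mutagenised with a promoter-carrying Tn5: GC 0.68, ~15% essential genes,
#' 9-bp duplication, 150-bp reads, triplicate libraries.
#'
#' @param genome_length genome size in bp.
#' @param gc_content target GC fraction in `[0,1]`.
#' @param n_genes number of genes to place.
#' @param operon_size_weights unnormalised weights for operon sizes 1..6.
#' @param essential_fraction fraction of genes labelled essential.
#' @param n_insertions number of candidate transposon insertions drawn.
#' @param duplication_length length of the target-site duplication in bp
#'   (Tn5 duplicates 9 bp).
#' @param read_length junction read length in bp.
#' @param oend_marker nucleotide string at the transposon O end that every
#'   junction read starts with; the true marker is instrument/construct
#'   specific, so it is a parameter with a documented default.
#' @param per_base_error per-base sequencing error probability.
#' @param library_size reads per sequencing library.
#' @param n_replicates replicate libraries per condition.
#' @param generations generations of selective growth.
#' @param bottleneck population size of the Wright-Fisher resampling step;
#'   `Inf` gives the deterministic (infinite-population) limit.
#' @param abundance_sdlog log-normal sigma of initial mutant abundances.
#' @param sense_rescue if `TRUE`, a sense insertion in an essential gene is
#'   viable when its 5' offset falls in the +1 codon register (read-through
#'   rescue); off by default, so any disruption of an essential gene is
#'   lethal and only intergenic insertions in essential regions survive.
#' @param mean_gene_length mean gene length in bp (protein-coding).
#' @param rna_gene_fraction fraction of genes tagged as RNA genes.
#' @param seed integer seed fixing all downstream randomness.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 50000, n_genes = 40, seed = 1)
#' @export
sim_config <- function(genome_length = 500000,
                       gc_content = 0.68,
                       n_genes = 400,
                       operon_size_weights = c(0.35, 0.25, 0.16, 0.12, 0.07, 0.05),
                       essential_fraction = 0.15,
                       n_insertions = 20000,
                       duplication_length = 9,
                       read_length = 150,
                       oend_marker = "ACTTGTGTATAAGAGTCAG",
                       per_base_error = 0.001,
                       library_size = 200000,
                       n_replicates = 3,
                       generations = 10,
                       bottleneck = 1e5,
                       abundance_sdlog = 1,
                       sense_rescue = FALSE,
                       mean_gene_length = 900,
                       rna_gene_fraction = 0.03,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    n_genes = as.integer(n_genes),
    operon_size_weights = operon_size_weights,
    essential_fraction = essential_fraction,
    n_insertions = as.integer(n_insertions),
    duplication_length = as.integer(duplication_length),
    read_length = as.integer(read_length),
    oend_marker = toupper(oend_marker),
    per_base_error = per_base_error,
    library_size = as.integer(library_size),
    n_replicates = as.integer(n_replicates),
    generations = as.integer(generations),
    bottleneck = bottleneck,
    abundance_sdlog = abundance_sdlog,
    sense_rescue = isTRUE(sense_rescue),
    mean_gene_length = as.integer(mean_gene_length),
    rna_gene_fraction = rna_gene_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param x a `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  .assert(inherits(x, "sim_config"), "not a sim_config")
  frac <- c(gc = x$gc_content, essential = x$essential_fraction,
            error = x$per_base_error, rna = x$rna_gene_fraction)
  .assert(all(frac >= 0 & frac <= 1), "all fractions must lie in [0, 1]")
  .assert(x$genome_length >= 1L, "genome_length must be positive")
  .assert(x$duplication_length >= 0L, "duplication_length must be >= 0")
  .assert(x$read_length >= 1L, "read_length must be positive")
  .assert(nchar(x$oend_marker) >= 1L, "oend_marker must be non-empty")
  .assert(all(x$operon_size_weights >= 0) && sum(x$operon_size_weights) > 0,
          "operon_size_weights must be non-negative and not all zero")
  .assert(x$n_replicates >= 1L, "n_replicates must be >= 1")
  .assert(is.infinite(x$bottleneck) || x$bottleneck >= 1,
          "bottleneck must be >= 1 or Inf")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Tn-Seq simulation config\n")
  cat(sprintf("  genome: %s bp, GC %.2f, %d genes (%.0f%% essential)\n",
              format(x$genome_length, big.mark = ","), x$gc_content,
              x$n_genes, 100 * x$essential_fraction))
  cat(sprintf("  transposon: %d-bp duplication, O-end marker %s\n",
              x$duplication_length, x$oend_marker))
  cat(sprintf("  reads: %d bp, error %.2g, %s per library\n",
              x$read_length, x$per_base_error,
              format(x$library_size, big.mark = ",")))
  cat(sprintf("  selection: %d generations, bottleneck %s, %d replicates\n",
              x$generations, format(x$bottleneck), x$n_replicates))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
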