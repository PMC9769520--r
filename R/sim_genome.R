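#' Generate a synthetic bacterial genome with operon-structured annotation
#'
#' Draws an i.i.d. nucleotide sequence at the configured GC content and
#' places non-overlapping genes along it, grouped into operons of 1--6 genes
#' that share one strand and are separated by short intragenic-operon
#' spacers and longer inter-operon spacers. A configurable fraction of genes
#' is tagged essential; whole operons are marked essential first (so that
#' essential genes occur in contiguous genomic runs, as functionally related
#' bacterial genes do) and the remainder as isolated essential genes.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a list with elements
#'   \describe{
#'     \item{genome}{single character string of length `genome_length`.}
#'     \item{annotation}{data.frame with columns `gene_id`, `start`, `end`,
#'       `strand`, `gene_type` ("protein" or "RNA"), `essential` (logical),
#'       `operon_id`. Coordinates are 1-based inclusive.}
#'   }
#' @examples
#' gen <- generate_genome(sim_config(genome_length = 30000, n_genes = 20,
#'                                   n_insertions = 100, seed = 1))
#' nrow(gen$annotation)
#' @export
generate_genome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)

  genome <- .random_sequence(config$genome_length, config$gc_content)

  if (config$n_genes == 0L) {
    ann <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_type = character(0), essential = logical(0),
                      operon_id = integer(0), stringsAsFactors = FALSE)
    return(list(genome = genome, annotation = ann))
  }

  # operon sizes drawn until n_genes genes are assigned
  sizes <- integer(0)
  while (sum(sizes) < config$n_genes) {
    sizes <- c(sizes, sample.int(length(config$operon_size_weights), 1L,
                                 prob = config$operon_size_weights))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - config$n_genes)
  sizes <- sizes[sizes > 0L]

  n_rna <- round(config$rna_gene_fraction * config$n_genes)
  is_rna <- rep(FALSE, config$n_genes)
  if (n_rna > 0) is_rna[sample.int(config$n_genes, n_rna)] <- TRUE

  # protein gene lengths: multiples of 3 around the configured mean;
  # RNA genes are short (tRNA/small RNA scale)
  glen <- integer(config$n_genes)
  npro <- sum(!is_rna)
  glen[!is_rna] <- 3L * pmax(50L, as.integer(round(
    rgamma(npro, shape = 4, scale = config$mean_gene_length / 3 / 4))))
  if (n_rna > 0) {
    glen[is_rna] <- as.integer(round(exp(rnorm(n_rna, log(120), 0.4))))
  }

  operon_of <- rep(seq_along(sizes), sizes)
  intra_sp <- as.integer(sample(10:60, config$n_genes, replace = TRUE))
  inter_sp <- as.integer(sample(80:300, length(sizes), replace = TRUE))

  needed <- sum(glen) + sum(inter_sp) + sum(intra_sp)
  if (needed > config$genome_length) {
    stop(sprintf(paste0("genome too short: %d genes plus spacers need ",
                        "~%d bp but genome_length is %d"),
                 config$n_genes, needed, config$genome_length),
         call. = FALSE)
  }

  strand_op <- sample(c("+", "-"), length(sizes), replace = TRUE)
  start <- integer(config$n_genes)
  end <- integer(config$n_genes)
  pos <- inter_sp[1]
  for (i in seq_len(config$n_genes)) {
    if (i > 1L && operon_of[i] != operon_of[i - 1L]) {
      pos <- pos + inter_sp[operon_of[i]]
    } else if (i > 1L) {
      pos <- pos + intra_sp[i]
    }
    start[i] <- pos + 1L
    end[i] <- pos + glen[i]
    pos <- end[i]
  }

  # essential labels: whole operons first (contiguous runs), then singles
  target <- round(config$essential_fraction * config$n_genes)
  essential <- rep(FALSE, config$n_genes)
  if (target > 0) {
    for (op in sample(seq_along(sizes))) {
      idx <- which(operon_of == op)
      if (sum(essential) + length(idx) <= ceiling(0.7 * target)) {
        essential[idx] <- TRUE
      }
    }
    pool <- which(!essential)
    need <- target - sum(essential)
    if (need > 0 && length(pool) > 0) {
      essential[sample(pool, min(need, length(pool)))] <- TRUE
    }
  }

  ann <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    start = start, end = end,
    strand = strand_op[operon_of],
    gene_type = ifelse(is_rna, "RNA", "protein"),
    essential = essential,
    operon_id = operon_of,
    stringsAsFactors = FALSE
  )
  list(genome = genome, annotation = ann)
}

.random_sequence <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' GC content of a nucleotide string
#'
#' @param seq character string of nucleotides.
#' @return fraction of G+C among A/C/G/T bases.
#' @export
gc_content <- function(seq) {
  x <- Biostrings::DNAString(seq)
  gc <- Biostrings::letterFrequency(x, "GC")
  acgt <- Biostrings::letterFrequency(x, "ACGT")
  unname(gc / acgt)
}
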