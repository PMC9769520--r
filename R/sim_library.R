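#' Simulate a pooled transposon insertion library
#'
#' Draws candidate Tn5 insertion positions uniformly along the genome with
#' random promoter orientation, applies the viability rule, collapses
#' duplicates, and assigns log-normal initial abundances. The viability rule
#' encodes the transposon's biology: any insertion disrupting an essential
#' gene is lethal, with an optional rescue switch under which a sense
#' insertion (internal promoter pointing along the gene) survives when its
#' 5' offset falls in the +1 codon register, so downstream operon members
#' stay transcribed. Insertions in nonessential genes and intergenic
#' insertions are always viable.
#'
#' Candidate positions are kept away from the genome ends by one read span
#' so that simulated junction reads never run off a linear sequence.
#'
#' @param genome character string (the chromosome).
#' @param annotation gene table as returned by [generate_genome()].
#' @param config a [sim_config()]; `config$sense_rescue` toggles the rescue
#'   rule.
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @return a list with
#'   \describe{
#'     \item{pool}{data.frame `position`, `orientation`, `gene_id` (NA when
#'       intergenic), `sense`, `abundance` (sums to 1).}
#'     \item{truth}{list with `true_sites` (position/orientation of the
#'       surviving pool), `essential_gene_ids`, `initial_abundances`,
#'       `n_candidates`, `n_lethal`.}
#'   }
#' @export
simulate_insertion_library <- function(genome, annotation, config,
                                       seed = config$seed + 1L) {
  set.seed(seed)
  L <- nchar(genome)
  frag_len <- config$read_length - nchar(config$oend_marker)
  margin <- frag_len + config$duplication_length
  .assert(L > 2L * margin + 2L, "genome too short for configured read length")

  position <- sample((margin + 1L):(L - margin), config$n_insertions,
                     replace = TRUE)
  orientation <- sample(c("+", "-"), config$n_insertions, replace = TRUE)

  hit <- .locate_gene(position, annotation)
  gene_id <- hit$gene_id
  sense <- !is.na(gene_id) & orientation == hit$strand

  viable <- insertion_viable(position, orientation, annotation, config)

  pos <- position[viable]
  ori <- orientation[viable]
  gid <- gene_id[viable]
  sns <- sense[viable]

  key <- paste(pos, ori)
  keep <- !duplicated(key)
  pool <- data.frame(position = pos[keep], orientation = ori[keep],
                     gene_id = gid[keep], sense = sns[keep],
                     stringsAsFactors = FALSE)
  o <- order(pool$position, pool$orientation)
  pool <- pool[o, , drop = FALSE]
  rownames(pool) <- NULL

  ab <- exp(rnorm(nrow(pool), 0, config$abundance_sdlog))
  pool$abundance <- ab / sum(ab)

  truth <- list(
    true_sites = pool[, c("position", "orientation")],
    essential_gene_ids = annotation$gene_id[annotation$essential],
    initial_abundances = pool$abundance,
    n_candidates = config$n_insertions,
    n_lethal = sum(!viable)
  )
  list(pool = pool, truth = truth)
}

#' Viability of candidate insertions
#'
#' Vectorised lethal/viable rule used by the simulator (and by brute-force
#' oracles in the tests): an insertion inside an essential gene is lethal,
#' except, when `config$sense_rescue` is on, sense insertions whose 5'
#' offset is in the +1 codon register (`offset %% 3 == 0`).
#'
#' @inheritParams simulate_insertion_library
#' @param position,orientation candidate site vectors.
#' @return logical vector, `TRUE` where the mutant survives.
#' @export
insertion_viable <- function(position, orientation, annotation, config) {
  hit <- .locate_gene(position, annotation)
  in_ess <- !is.na(hit$gene_id) & hit$essential
  sense <- orientation == hit$strand
  offset <- ifelse(hit$strand == "+", position - hit$start,
                   hit$end - position)
  rescued <- config$sense_rescue & sense & (offset %% 3L == 0L)
  !(in_ess & !(rescued %in% TRUE))
}

# map positions to containing gene (first by start order on overlap)
.locate_gene <- function(position, annotation) {
  n <- length(position)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    strand = rep(NA_character_, n),
                    start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    essential = rep(FALSE, n), stringsAsFactors = FALSE)
  if (nrow(annotation) == 0L) return(out)
  q <- IRanges::IRanges(start = position, width = 1L)
  s <- IRanges::IRanges(start = annotation$start, end = annotation$end)
  ov <- IRanges::findOverlaps(q, s, select = "first")
  has <- !is.na(ov)
  out$gene_id[has] <- annotation$gene_id[ov[has]]
  out$strand[has] <- annotation$strand[ov[has]]
  out$start[has] <- annotation$start[ov[has]]
  out$end[has] <- annotation$end[ov[has]]
  out$essential[has] <- annotation$essential[ov[has]]
  out
}

#' Wright-Fisher selection of the mutant pool
#'
#' Updates mutant relative abundances over discrete generations with
#' multiplicative fitness `exp(s)` per generation, followed each generation
#' by multinomial resampling at the configured bottleneck population size.
#' With `bottleneck = Inf` the update is deterministic. Intergenic mutants
#' (NA `gene_id`) and genes absent from `fitness` are neutral (`s = 0`);
#' `s = -Inf` is lethal.
#'
#' @param pool pool data.frame from [simulate_insertion_library()].
#' @param fitness named numeric vector of per-generation selection
#'   coefficients, names are gene ids.
#' @param generations number of generations.
#' @param config a [sim_config()] supplying the bottleneck size.
#' @param seed integer seed; defaults to `config$seed + 2`.
#' @return the pool with updated `abundance` (sums to 1; extinct mutants
#'   keep their row with abundance 0).
#' @export
simulate_selection <- function(pool, fitness, generations, config,
                               seed = config$seed + 2L) {
  set.seed(seed)
  if (nrow(pool) == 0L) return(pool)
  s <- rep(0, nrow(pool))
  known <- !is.na(pool$gene_id) & pool$gene_id %in% names(fitness)
  s[known] <- fitness[pool$gene_id[known]]
  w <- exp(s)

  freq <- pool$abundance
  for (g in seq_len(generations)) {
    f <- freq * w
    f[freq == 0] <- 0  # extinct stays extinct even for w = Inf guards
    .assert(sum(f) > 0, "entire pool is lethal under the given fitness")
    f <- f / sum(f)
    if (is.finite(config$bottleneck)) {
      n <- stats::rmultinom(1L, size = as.integer(config$bottleneck), prob = f)
      freq <- as.numeric(n) / config$bottleneck
    } else {
      freq <- f
    }
  }
  pool$abundance <- freq
  pool
}

#' Draw per-gene fitness effects for selection conditions
#'
#' Assigns a selection coefficient to a random subset of nonessential genes
#' for each condition; all other genes are neutral. Used to give the
#' simulated selection experiment a known set of conditionally enriched
#' (s > 0, mutant advantage) and depleted (s < 0) mutants.
#'
#' @param annotation gene table.
#' @param conditions character vector of condition names.
#' @param frac_affected fraction of nonessential genes with an effect.
#' @param s_magnitude absolute per-generation selection coefficient given to
#'   affected genes (sign drawn at random).
#' @param seed integer seed.
#' @return matrix genes x conditions of selection coefficients, with gene
#'   ids as rownames.
#' @export
simulate_fitness_effects <- function(annotation, conditions,
                                     frac_affected = 0.1,
                                     s_magnitude = 0.2, seed = 1L) {
  set.seed(seed)
  s <- matrix(0, nrow(annotation), length(conditions),
              dimnames = list(annotation$gene_id, conditions))
  cand <- which(!annotation$essential)
  for (j in seq_along(conditions)) {
    k <- round(frac_affected * length(cand))
    if (k > 0) {
      idx <- sample(cand, k)
      s[idx, j] <- sample(c(-1, 1), k, replace = TRUE) * s_magnitude
    }
  }
  s
}

#' Simulate Tn5 junction reads from a mutant pool
#'
#' Read counts per mutant are multinomial in the pool abundances. Each read
#' is the O-end marker followed by the genomic sequence starting at the base
#' adjacent to the transposon O end and reading away from the transposon
#' body, with i.i.d. per-base substitution errors. For a site at position p
#' (the I-end-adjacent base) with duplication d >= 1 and genomic fragment
#' length f: orientation "-" reads the plus strand over `[p-d+1, p-d+f]`;
#' orientation "+" reads the minus strand over `[p+d-f, p+d-1]` (reverse
#' complement). This is the inverse of the coordinate correction applied by
#' [to_insertion_site()], which the round-trip tests pin down.
#'
#' @param pool pool data.frame (positive `abundance` rows are sampled).
#' @param genome character string.
#' @param config a [sim_config()].
#' @param n_reads number of reads; defaults to `config$library_size`.
#' @param seed integer seed; defaults to `config$seed + 3`.
#' @return list with `reads` (data.frame `id`, `sequence`) and `truth`
#'   (data.frame `id`, `position`, `orientation`).
#' @export
simulate_reads <- function(pool, genome, config,
                           n_reads = config$library_size,
                           seed = config$seed + 3L) {
  set.seed(seed)
  live <- pool[pool$abundance > 0, , drop = FALSE]
  if (nrow(live) == 0L) {
    return(list(reads = data.frame(id = character(0), sequence = character(0),
                                   stringsAsFactors = FALSE),
                truth = data.frame(id = character(0), position = integer(0),
                                   orientation = character(0),
                                   stringsAsFactors = FALSE)))
  }
  frag_len <- config$read_length - nchar(config$oend_marker)
  .assert(frag_len >= 15L, "read_length leaves fewer than 15 genomic bases")
  .assert(config$read_length <= nchar(genome),
          "read_length longer than genome")

  counts <- as.integer(stats::rmultinom(1L, n_reads,
                                        live$abundance / sum(live$abundance)))
  idx <- rep.int(seq_len(nrow(live)), counts)
  if (length(idx) == 0L) {
    return(list(reads = data.frame(id = character(0), sequence = character(0),
                                   stringsAsFactors = FALSE),
                truth = data.frame(id = character(0), position = integer(0),
                                   orientation = character(0),
                                   stringsAsFactors = FALSE)))
  }
  pos <- live$position[idx]
  ori <- live$orientation[idx]
  d <- max(config$duplication_length - 1L, 0L)  # coordinate span of the
                                                # duplicated target site
  frag <- character(length(idx))
  minus <- ori == "-"
  frag[minus] <- substring(genome, pos[minus] - d,
                           pos[minus] - d + frag_len - 1L)
  if (any(!minus)) {
    ends <- pos[!minus] + d
    frag[!minus] <- reverse_complement(substring(genome, ends - frag_len + 1L,
                                                 ends))
  }
  frag <- .add_read_errors(frag, config$per_base_error)

  ids <- sprintf("read%07d", seq_along(idx))
  reads <- data.frame(id = ids,
                      sequence = paste0(config$oend_marker, frag),
                      stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, position = pos, orientation = ori,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

.add_read_errors <- function(frag, rate) {
  if (rate <= 0 || length(frag) == 0L) return(frag)
  len <- nchar(frag[1])
  n_err <- stats::rbinom(length(frag), len, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    at <- sample.int(len, n_err[i])
    for (p in at) {
      cur <- substr(frag[i], p, p)
      substr(frag[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  frag
}
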