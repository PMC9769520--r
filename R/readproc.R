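#' Filter junction reads for the transposon marker and trim to genomic DNA
#'
#' Keeps only reads that contain the Tn5 O-end marker, removes the marker
#' and everything before it, and cuts any trailing (semi)arbitrary-primer
#' sequence. A minimal quality screen then drops fragments shorter than
#' `min_length` or with too many ambiguous bases; simulated or pre-trimmed
#' reads need nothing more.
#'
#' @param reads data.frame with columns `id` and `sequence`, or a character
#'   vector of sequences.
#' @param oend_marker O-end marker string each transposon-derived read must
#'   contain.
#' @param primer_set optional character vector of primer sequences; a
#'   fragment is cut at the first occurrence of any of them.
#' @param min_length minimum genomic fragment length kept.
#' @param max_n_frac maximum tolerated fraction of N bases.
#' @return list with `fragments` (data.frame `id`, `sequence`) and a named
#'   integer vector `attrition` (`n_input`, `n_no_marker`, `n_qc_fail`,
#'   `n_kept`).
#' @export
filter_and_trim <- function(reads, oend_marker, primer_set = NULL,
                            min_length = 15L, max_n_frac = 0.1) {
  .assert(nchar(oend_marker) > 0, "oend_marker must be non-empty")
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("read%07d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  n_input <- nrow(reads)
  at <- regexpr(oend_marker, reads$sequence, fixed = TRUE)
  has <- at > 0L
  frag <- substring(reads$sequence[has], at[has] + nchar(oend_marker))
  ids <- reads$id[has]

  for (p in primer_set) {
    cut <- regexpr(p, frag, fixed = TRUE)
    hit <- cut > 0L
    frag[hit] <- substring(frag[hit], 1L, cut[hit] - 1L)
  }

  n_count <- nchar(gsub("[^Nn]", "", frag))
  len <- nchar(frag)
  ok <- len >= min_length & ifelse(len > 0, n_count / len, 1) <= max_n_frac
  out <- data.frame(id = ids[ok], sequence = frag[ok],
                    stringsAsFactors = FALSE)
  list(fragments = out,
       attrition = c(n_input = n_input,
                     n_no_marker = sum(!has),
                     n_qc_fail = sum(!ok),
                     n_kept = nrow(out)))
}

#' Exact-seed index of a genome
#'
#' Hashes every `seed_len`-mer of the genome and of its reverse complement
#' so that fragment alignment can list all perfect seed occurrences on both
#' strands in O(1). Build once per genome and reuse across fragments.
#'
#' @param genome character string.
#' @param seed_len seed length in bp; the first `seed_len` bases of every
#'   fragment must match the genome perfectly.
#' @return an object of class `tn_genome_index`.
#' @export
genome_index <- function(genome, seed_len = 15L) {
  genome <- toupper(genome)
  L <- nchar(genome)
  .assert(L >= seed_len, "genome shorter than seed length")
  rc <- reverse_complement(genome)
  starts <- seq_len(L - seed_len + 1L)
  fwd <- list2env(split(starts, substring(genome, starts, starts + seed_len - 1L)),
                  envir = new.env(hash = TRUE, size = length(starts)))
  rev <- list2env(split(starts, substring(rc, starts, starts + seed_len - 1L)),
                  envir = new.env(hash = TRUE, size = length(starts)))
  structure(list(genome = genome, rc = rc, length = L,
                 seed_len = as.integer(seed_len), fwd = fwd, rev = rev),
            class = "tn_genome_index")
}

#' @export
print.tn_genome_index <- function(x, ...) {
  cat(sprintf("genome index: %s bp, %d-bp exact seeds, both strands\n",
              format(x$length, big.mark = ","), x$seed_len))
  invisible(x)
}

#' Align a genomic fragment by exact seed and ungapped extension
#'
#' Finds every position (both strands) where the fragment's first
#' `seed_len` bases match the genome exactly, extends each seed ungapped to
#' the fragment end, and keeps the hit with the highest coverage and, among
#' those, the highest identity. Exact ties for best are reported ambiguous
#' and discarded downstream.
#'
#' @param fragment character string (genomic part of a junction read).
#' @param index a [genome_index()]; its `seed_len` is used.
#' @return data.frame with one row: `contig_position` (1-based genome
#'   coordinate of the fragment's first base), `strand`, `coverage`,
#'   `identity`, `ambiguous`, `mapped`. Unmapped fragments (no perfect
#'   seed, or shorter than the seed) have `mapped = FALSE`.
#' @seealso [align_fragments()] for the vectorised version.
#' @export
align_fragment <- function(fragment, index) {
  align_fragments(fragment, index)
}

#' @rdname align_fragment
#' @param fragments character vector of fragments.
#' @export
align_fragments <- function(fragments, index) {
  n <- length(fragments)
  out <- data.frame(contig_position = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    coverage = rep(NA_real_, n),
                    identity = rep(NA_real_, n),
                    ambiguous = rep(FALSE, n),
                    mapped = rep(FALSE, n))
  k <- index$seed_len
  L <- index$length
  for (i in seq_len(n)) {
    frag <- fragments[i]
    flen <- nchar(frag)
    if (flen < k) next
    seed <- substr(frag, 1L, k)
    fpos <- index$fwd[[seed]]
    rpos <- index$rev[[seed]]
    if (is.null(fpos) && is.null(rpos)) next

    best <- NULL
    for (strand in c("+", "-")) {
      pos <- if (strand == "+") fpos else rpos
      for (p in pos) {
        alen <- min(flen, L - p + 1L)
        ref <- if (strand == "+") substr(index$genome, p, p + alen - 1L)
               else substr(index$rc, p, p + alen - 1L)
        mism <- sum(charToRaw(substr(frag, 1L, alen)) != charToRaw(ref))
        cand <- c(cov = alen / flen, ident = (alen - mism) / alen,
                  p = p, minus = as.numeric(strand == "-"))
        if (is.null(best)) {
          best <- cand; tied <- FALSE
        } else if (cand["cov"] > best["cov"] ||
                   (cand["cov"] == best["cov"] && cand["ident"] > best["ident"])) {
          best <- cand; tied <- FALSE
        } else if (cand["cov"] == best["cov"] && cand["ident"] == best["ident"]) {
          tied <- TRUE
        }
      }
    }
    # rc-index coordinates map back to genome coordinates for minus hits
    contig <- if (best["minus"] == 1) L - as.integer(best["p"]) + 1L
              else as.integer(best["p"])
    out$contig_position[i] <- contig
    out$strand[i] <- if (best["minus"] == 1) "-" else "+"
    out$coverage[i] <- best[["cov"]]
    out$identity[i] <- best[["ident"]]
    out$ambiguous[i] <- tied
    out$mapped[i] <- TRUE
  }
  out
}

#' Convert an alignment hit to the corrected Tn5 insertion site
#'
#' Reads are sequenced out of the Tn5 O end while the internal promoter
#' sits at the I end, so the reported site is the base adjacent to the I
#' end, on the other side of the 9-bp target-site duplication, and the
#' orientation is flipped to the promoter's direction of transcription:
#' a hit on strand "+" at contig position c becomes position `c + dup_len
#' - 1` with orientation "-", and a hit on strand "-" becomes `c - dup_len
#' + 1` with orientation "+". In the no-duplication limit (`dup_len = 0`)
#' the position is unchanged and only the orientation flips.
#'
#' @param hit data.frame from [align_fragments()] (ambiguous or unmapped
#'   rows are rejected).
#' @param dup_len target-site duplication length in bp (Tn5: 9).
#' @param genome_length genome length; needed when `circular = TRUE` to
#'   wrap corrected positions, otherwise used for bounds checking.
#' @param circular treat the genome as circular.
#' @return data.frame `position`, `orientation`.
#' @export
to_insertion_site <- function(hit, dup_len = 9L, genome_length = NULL,
                              circular = TRUE) {
  .assert(all(hit$mapped) && !any(hit$ambiguous),
          "hits must be mapped and unambiguous")
  # the two duplication copies span dup_len - 1 bases; without duplication
  # the coordinate is unchanged
  off <- max(dup_len - 1L, 0L)
  pos <- ifelse(hit$strand == "+",
                hit$contig_position + off,
                hit$contig_position - off)
  ori <- ifelse(hit$strand == "+", "-", "+")
  if (!is.null(genome_length)) {
    if (circular) {
      pos <- .wrap_pos(pos, genome_length)
    } else {
      .assert(all(pos >= 1L & pos <= genome_length),
              "corrected position outside linear genome")
    }
  }
  data.frame(position = as.integer(pos), orientation = ori,
             stringsAsFactors = FALSE)
}

#' Collapse site observations to unique insertion sites
#'
#' Unique sites are defined by (position, orientation); the read count of a
#' site is the number of observations collapsing onto it (or the sum of a
#' supplied count column).
#'
#' @param observations data.frame with `position` and `orientation`
#'   columns; an optional `read_count` column is summed.
#' @return a `tn_sites` data.frame `position`, `orientation`, `read_count`,
#'   sorted by position then orientation.
#' @export
unique_sites <- function(observations) {
  counts <- if ("read_count" %in% names(observations))
    observations$read_count else rep(1L, nrow(observations))
  if (nrow(observations) == 0L) {
    out <- data.frame(position = integer(0), orientation = character(0),
                      read_count = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("tn_sites", "data.frame")
    return(out)
  }
  agg <- stats::aggregate(counts,
                          by = list(position = observations$position,
                                    orientation = observations$orientation),
                          FUN = sum)
  names(agg)[3] <- "read_count"
  agg <- agg[order(agg$position, agg$orientation), , drop = FALSE]
  rownames(agg) <- NULL
  agg$position <- as.integer(agg$position)
  agg$read_count <- as.integer(agg$read_count)
  class(agg) <- c("tn_sites", "data.frame")
  agg
}

#' @export
print.tn_sites <- function(x, ...) {
  cat(sprintf("%d unique insertion sites (%s reads)\n", nrow(x),
              format(sum(x$read_count), big.mark = ",")))
  NextMethod()
}

#' Run the full read-to-site stage
#'
#' Convenience wrapper chaining [filter_and_trim()], [align_fragments()],
#' [to_insertion_site()] and [unique_sites()], with per-stage attrition
#' accounting.
#'
#' @inheritParams filter_and_trim
#' @param genome character string or a prebuilt [genome_index()].
#' @param dup_len target-site duplication length in bp.
#' @param seed_len exact-match seed length in bp.
#' @param circular treat the genome as circular when correcting positions.
#' @return list with `sites` (a `tn_sites` table) and `attrition` (named
#'   integer vector incl. `n_mapped`, `n_ambiguous`, `n_unique_sites`).
#' @export
reads_to_sites <- function(reads, genome, oend_marker, primer_set = NULL,
                           dup_len = 9L, seed_len = 15L, circular = TRUE) {
  idx <- if (inherits(genome, "tn_genome_index")) genome
         else genome_index(genome, seed_len)
  ft <- filter_and_trim(reads, oend_marker, primer_set)
  # identical fragments (frequent at high read depth) are aligned once
  frag <- ft$fragments$sequence
  uniq <- unique(frag)
  hits <- align_fragments(uniq, idx)[match(frag, uniq), , drop = FALSE]
  usable <- hits$mapped & !hits$ambiguous
  obs <- to_insertion_site(hits[usable, , drop = FALSE], dup_len = dup_len,
                           genome_length = idx$length, circular = circular)
  sites <- unique_sites(obs)
  list(sites = sites,
       attrition = c(ft$attrition,
                     n_mapped = sum(hits$mapped),
                     n_ambiguous = sum(hits$ambiguous, na.rm = TRUE),
                     n_unique_sites = nrow(sites)))
}
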