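#' Library summary statistics
#'
#' Computes the per-library summary printed in Tn-Seq sequencing tables:
#' insertion density (bp per unique insertion, genome length divided by the
#' number of unique sites, rounded half away from zero), the intragenic
#' site fraction (percent of unique sites falling within any annotated gene
#' span, rounded to integer percent), and — when raw read counts are given —
#' the percent of reads passing filtering and mapping.
#'
#' @param sites a `tn_sites` table (or any data.frame with `position`,
#'   `orientation`), or `NULL` when only read attrition is of interest.
#' @param genome_length genome length in bp.
#' @param annotation optional gene table (`start`, `end`) for the
#'   intragenic fraction.
#' @param n_raw,n_filtered,n_mapped optional read counts per stage.
#' @param n_unique_sites override for the unique-site count (used when
#'   summarising published tables without the site list itself).
#' @return an object of class `tn_library_stats`: list with `n_raw`,
#'   `n_filtered`, `n_mapped`, `pct_filtered`, `pct_mapped`,
#'   `n_unique_sites`, `density_bp_per_insertion`, `intragenic_fraction`
#'   (integer percent or NA).
#' @examples
#' library_stats(genome_length = 4376040, n_unique_sites = 183437)
#' @export
library_stats <- function(sites = NULL, genome_length, annotation = NULL,
                          n_raw = NA_real_, n_filtered = NA_real_,
                          n_mapped = NA_real_, n_unique_sites = NULL) {
  .assert(genome_length > 0, "genome_length must be positive")
  if (is.null(n_unique_sites)) {
    n_unique_sites <- if (is.null(sites)) NA_integer_ else nrow(sites)
  }
  density <- if (!is.na(n_unique_sites) && n_unique_sites > 0)
    round_half_up(genome_length / n_unique_sites) else NA_real_

  intragenic <- NA_real_
  n_intragenic <- NA_integer_
  if (!is.null(sites) && !is.null(annotation) && nrow(sites) > 0) {
    hit <- .locate_gene(sites$position, annotation)
    n_intragenic <- sum(!is.na(hit$gene_id))
    intragenic <- round_half_up(100 * n_intragenic / nrow(sites))
  }

  out <- list(
    n_raw = n_raw, n_filtered = n_filtered, n_mapped = n_mapped,
    pct_filtered = if (!is.na(n_raw) && !is.na(n_filtered))
      round_half_up(100 * n_filtered / n_raw) else NA_real_,
    pct_mapped = if (!is.na(n_raw) && !is.na(n_mapped))
      round_half_up(100 * n_mapped / n_raw) else NA_real_,
    n_unique_sites = n_unique_sites,
    n_intragenic = n_intragenic,
    density_bp_per_insertion = density,
    intragenic_fraction = intragenic,
    genome_length = genome_length
  )
  class(out) <- "tn_library_stats"
  out
}

#' @export
print.tn_library_stats <- function(x, ...) {
  cat("Tn-Seq library statistics\n")
  if (!is.na(x$n_raw)) {
    cat(sprintf("  reads: %s raw, %s filtered (%g%%), %s mapped (%g%%)\n",
                format(x$n_raw, big.mark = ","),
                format(x$n_filtered, big.mark = ","), x$pct_filtered,
                format(x$n_mapped, big.mark = ","), x$pct_mapped))
  }
  cat(sprintf("  unique sites: %s  (one insertion every %g bp)\n",
              format(x$n_unique_sites, big.mark = ","),
              x$density_bp_per_insertion))
  if (!is.na(x$intragenic_fraction)) {
    cat(sprintf("  intragenic: %s sites (%g%%)\n",
                format(x$n_intragenic, big.mark = ","),
                x$intragenic_fraction))
  }
  invisible(x)
}

#' Percent loss of unique insertion sites between libraries
#'
#' Expresses pool contraction (freezer passage, selective growth) as the
#' integer percent of unique sites lost relative to the earlier library.
#'
#' @param n_before,n_after unique-site counts.
#' @return integer percent lost, rounded half away from zero.
#' @examples
#' site_loss_percent(183437, 105421)  # passage loss
#' @export
site_loss_percent <- function(n_before, n_after) {
  .assert(all(n_before > 0), "n_before must be positive")
  round_half_up(100 * (1 - n_after / n_before))
}

#' Gap statistics between consecutive insertion sites
#'
#' Sites are collapsed by position (two orientations at one position count
#' once); gaps are the numbers of insertion-free bases between consecutive
#' collapsed sites, with circular wrap-around by default. With n sites the
#' gaps sum to `genome_length - n`.
#'
#' @param sites site table with a `position` column.
#' @param genome_length genome length in bp.
#' @param circular treat the genome as circular (default); linear mode
#'   returns n-1 internal gaps only.
#' @return object of class `tn_gap_stats`: list with `gap_sizes`,
#'   `fraction_le_25bp` (percent), `largest_gap`, `n_collapsed_sites`.
#' @export
gap_stats <- function(sites, genome_length, circular = TRUE) {
  pos <- sort(unique(sites$position))
  .assert(length(pos) >= 1L, "gap statistics need at least one site")
  .assert(all(pos >= 1L & pos <= genome_length), "site outside genome")
  if (circular) {
    gaps <- if (length(pos) == 1L) genome_length - 1L
            else c(diff(pos) - 1L, pos[1] + genome_length - pos[length(pos)] - 1L)
  } else {
    gaps <- if (length(pos) == 1L) integer(0) else diff(pos) - 1L
  }
  out <- list(gap_sizes = as.integer(gaps),
              fraction_le_25bp = if (length(gaps))
                round_half_up(100 * mean(gaps <= 25), 1) else NA_real_,
              largest_gap = if (length(gaps)) max(gaps) else NA_integer_,
              n_collapsed_sites = length(pos))
  class(out) <- "tn_gap_stats"
  out
}

#' @export
print.tn_gap_stats <- function(x, ...) {
  cat(sprintf("gaps between %d collapsed sites: %g%% <= 25 bp, largest %s bp\n",
              x$n_collapsed_sites, x$fraction_le_25bp,
              format(x$largest_gap, big.mark = ",")))
  invisible(x)
}
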