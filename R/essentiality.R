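#' Insertion filter policy for essentiality calling
#'
#' The stringent pre-filters applied to intragenic insertions before a gene
#' is classified. For protein-coding genes: sense insertions in the +1
#' reading frame are discarded (the transposon's internal promoter, SD and
#' ATG can express the downstream ORF portion in frame, so such mutants do
#' not prove dispensability), insertions in the stop codon (last 3 bp) are
#' discarded, sense insertions in the last `edge_window` bp and antisense
#' insertions in the first `edge_window` bp are discarded. RNA genes have
#' no reading frame, so only the edge filters apply to them.
#'
#' @param drop_plus1_frame_sense drop sense insertions in the +1 register.
#' @param plus1_frame_offset_mod3 which offset residue mod 3 counts as the
#'   +1 register (the arithmetic convention is configurable; 0 means the
#'   transposon-borne ATG lands in the codon register).
#' @param drop_stop_codon drop insertions in the last 3 bp (both
#'   orientations).
#' @param edge_window terminal window in bp for the sense-last /
#'   antisense-first edge filters.
#' @param edge_both_orientations if `TRUE`, remove both orientations in
#'   both terminal windows instead of the respective pairing.
#' @param last_fraction_rule a gene whose surviving insertions all lie in
#'   the last this-fraction of the ORF is called essential (`last10`).
#' @param gap_fraction_rule a gene with an insertion-free gap of at least
#'   this fraction of the ORF length is called essential (`gap80`).
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(drop_plus1_frame_sense = TRUE,
                          plus1_frame_offset_mod3 = 0L,
                          drop_stop_codon = TRUE,
                          edge_window = 9L,
                          edge_both_orientations = FALSE,
                          last_fraction_rule = 0.10,
                          gap_fraction_rule = 0.80) {
  .assert(plus1_frame_offset_mod3 %in% 0:2, "offset register must be 0, 1 or 2")
  .assert(edge_window >= 0, "edge_window must be >= 0")
  .assert(last_fraction_rule > 0 && last_fraction_rule < 1 &&
            gap_fraction_rule > 0 && gap_fraction_rule < 1,
          "rule fractions must lie in (0, 1)")
  structure(list(drop_plus1_frame_sense = isTRUE(drop_plus1_frame_sense),
                 plus1_frame_offset_mod3 = as.integer(plus1_frame_offset_mod3),
                 drop_stop_codon = isTRUE(drop_stop_codon),
                 edge_window = as.integer(edge_window),
                 edge_both_orientations = isTRUE(edge_both_orientations),
                 last_fraction_rule = last_fraction_rule,
                 gap_fraction_rule = gap_fraction_rule),
            class = "filter_policy")
}

#' Assign insertion sites to genes
#'
#' Every site whose position lies within a gene span contributes an
#' insertion to that gene (sites in overlapping genes count for each of
#' them). The insertion offset is measured from the gene's 5' end on its
#' own strand (0-based), and an insertion is sense when the site's promoter
#' orientation equals the gene strand.
#'
#' @param sites `tn_sites` table (`position`, `orientation`, optional
#'   `read_count`).
#' @param annotation gene table (`gene_id`, `start`, `end`, `strand`,
#'   `gene_type`).
#' @return list with
#'   \describe{
#'     \item{assignments}{data.frame `gene_id`, `offset`, `sense`,
#'       `read_count` (one row per site-gene pair).}
#'     \item{intragenic_count}{number of sites inside at least one gene.}
#'     \item{intergenic_count}{number of sites in no gene.}
#'   }
#' @export
assign_to_genes <- function(sites, annotation) {
  rc <- if ("read_count" %in% names(sites)) sites$read_count
        else rep(1L, nrow(sites))
  if (nrow(sites) == 0L || nrow(annotation) == 0L) {
    return(list(assignments = data.frame(gene_id = character(0),
                                         offset = integer(0),
                                         sense = logical(0),
                                         read_count = integer(0),
                                         stringsAsFactors = FALSE),
                intragenic_count = 0L,
                intergenic_count = nrow(sites)))
  }
  q <- IRanges::IRanges(start = sites$position, width = 1L)
  s <- IRanges::IRanges(start = annotation$start, end = annotation$end)
  ov <- IRanges::findOverlaps(q, s)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  offset <- ifelse(annotation$strand[gi] == "+",
                   sites$position[si] - annotation$start[gi],
                   annotation$end[gi] - sites$position[si])
  asg <- data.frame(gene_id = annotation$gene_id[gi],
                    offset = as.integer(offset),
                    sense = sites$orientation[si] == annotation$strand[gi],
                    read_count = as.integer(rc[si]),
                    stringsAsFactors = FALSE)
  list(assignments = asg,
       intragenic_count = length(unique(si)),
       intergenic_count = nrow(sites) - length(unique(si)))
}

#' Apply the insertion pre-filters to one gene profile
#'
#' @param profile data.frame `offset`, `sense` (and optionally
#'   `read_count`) for one gene.
#' @param policy a [filter_policy()].
#' @param gene one-row slice of the annotation (`start`, `end`,
#'   `gene_type`).
#' @return the profile restricted to insertions that survive the filters.
#' @export
apply_filters <- function(profile, policy, gene) {
  len <- gene$end - gene$start + 1L
  .assert(all(profile$offset >= 0 & profile$offset < len),
          "offsets must lie within the gene")
  keep <- rep(TRUE, nrow(profile))
  off <- profile$offset
  sns <- profile$sense
  w <- policy$edge_window
  if (identical(gene$gene_type, "protein")) {
    if (policy$drop_plus1_frame_sense) {
      keep <- keep & !(sns & (off %% 3L == policy$plus1_frame_offset_mod3))
    }
    if (policy$drop_stop_codon) keep <- keep & !(off >= len - 3L)
  }
  if (policy$edge_both_orientations) {
    keep <- keep & !(off >= len - w) & !(off < w)
  } else {
    keep <- keep & !(sns & off >= len - w)    # sense in last window
    keep <- keep & !(!sns & off < w)          # antisense in first window
  }
  profile[keep, , drop = FALSE]
}

#' Classify one gene from its filtered insertion profile
#'
#' Verdicts, in precedence order: `essential_non_hit` (no surviving
#' insertion), `essential_last10` (every surviving insertion in the last
#' 10% of the ORF), `essential_gap80` (largest insertion-free stretch,
#' boundary flanks included, covers at least 80% of the ORF), else
#' `nonessential`.
#'
#' @inheritParams apply_filters
#' @param filtered_profile output of [apply_filters()].
#' @return one-row data.frame `gene_id`, `verdict`,
#'   `n_insertions_after_filter`, `largest_gap_fraction`.
#' @export
classify_gene <- function(filtered_profile, gene, policy = filter_policy()) {
  len <- gene$end - gene$start + 1L
  off <- sort(unique(filtered_profile$offset))
  n <- length(off)
  if (n == 0L) {
    verdict <- "essential_non_hit"
    gapfrac <- 1
  } else {
    gaps <- c(off[1],                       # 5' flank up to first insertion
              if (n > 1L) diff(off) - 1L,
              len - off[n] - 1L)            # last insertion to gene end
    gapfrac <- max(gaps) / len
    if (all(off >= (1 - policy$last_fraction_rule) * len)) {
      verdict <- "essential_last10"
    } else if (gapfrac >= policy$gap_fraction_rule) {
      verdict <- "essential_gap80"
    } else {
      verdict <- "nonessential"
    }
  }
  data.frame(gene_id = gene$gene_id, verdict = verdict,
             n_insertions_after_filter = n,
             largest_gap_fraction = gapfrac, stringsAsFactors = FALSE)
}

#' Call putative essentiality for every annotated gene
#'
#' Orchestrates [assign_to_genes()], [apply_filters()] and
#' [classify_gene()] across the annotation.
#'
#' @inheritParams assign_to_genes
#' @param policy a [filter_policy()].
#' @return a `tn_calls` data.frame with one row per gene: `gene_id`,
#'   `verdict`, `n_insertions_after_filter`, `largest_gap_fraction`,
#'   `gene_type`, `essential` (any essential verdict).
#' @export
call_essentiality <- function(sites, annotation, policy = filter_policy()) {
  asg <- assign_to_genes(sites, annotation)$assignments
  by_gene <- split(asg[, c("offset", "sense", "read_count")], asg$gene_id)
  empty <- data.frame(offset = integer(0), sense = logical(0),
                      read_count = integer(0))
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    gene <- annotation[i, , drop = FALSE]
    prof <- by_gene[[gene$gene_id]]
    if (is.null(prof)) prof <- empty
    classify_gene(apply_filters(prof, policy, gene), gene, policy)
  })
  calls <- do.call(rbind, rows)
  calls$gene_type <- annotation$gene_type
  calls$essential <- calls$verdict != "nonessential"
  class(calls) <- c("tn_calls", "data.frame")
  calls
}

#' @export
print.tn_calls <- function(x, ...) {
  tab <- table(factor(x$verdict, levels = c("essential_non_hit",
                                            "essential_last10",
                                            "essential_gap80",
                                            "nonessential")))
  cat(sprintf("essentiality calls for %d genes: %d putatively essential\n",
              nrow(x), sum(x$essential)))
  print(tab)
  invisible(x)
}

#' Summarise essentiality calls
#'
#' Counts by verdict and gene type, plus sequence-level descriptors of the
#' essential protein-coding set (mean per-gene GC percent and mean length)
#' when the genome sequence is supplied.
#'
#' @param calls a `tn_calls` table.
#' @param annotation gene table matching the calls.
#' @param genome optional genome string for GC/length summaries.
#' @return object of class `tn_ess_summary`.
#' @export
summarize_calls <- function(calls, annotation, genome = NULL) {
  stopifnot(nrow(calls) == nrow(annotation))
  ess <- calls$essential
  pro <- calls$gene_type == "protein"
  n_ess_pro <- sum(ess & pro)
  n_ess_rna <- sum(ess & !pro)

  gc_pct <- NA_real_
  mean_len <- NA_real_
  idx <- which(ess & pro)
  if (length(idx)) {
    ann <- annotation[match(calls$gene_id[idx], annotation$gene_id), ]
    mean_len <- mean(ann$end - ann$start + 1)
    if (!is.null(genome)) {
      gc_pct <- 100 * mean(vapply(seq_len(nrow(ann)), function(i) {
        gc_content(substr(genome, ann$start[i], ann$end[i]))
      }, numeric(1)))
    }
  }
  out <- list(n_genes = nrow(calls),
              n_essential = sum(ess),
              n_essential_protein = n_ess_pro,
              n_essential_rna = n_ess_rna,
              percent_essential = round_half_up(100 * sum(ess) / nrow(calls)),
              by_verdict = table(calls$verdict),
              essential_protein_gc_percent = gc_pct,
              essential_protein_mean_length = mean_len)
  class(out) <- "tn_ess_summary"
  out
}

#' @export
print.tn_ess_summary <- function(x, ...) {
  cat(sprintf("%d of %d genes putatively essential (%g%%): %d protein + %d RNA\n",
              x$n_essential, x$n_genes, x$percent_essential,
              x$n_essential_protein, x$n_essential_rna))
  if (!is.na(x$essential_protein_gc_percent)) {
    cat(sprintf("essential protein-coding set: mean GC %.2f%%, mean length %.0f bp\n",
                x$essential_protein_gc_percent, x$essential_protein_mean_length))
  }
  invisible(x)
}
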