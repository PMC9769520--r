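#' File readers and writers
#'
#' All coordinates in files written by this package are 1-based inclusive;
#' every table carries a `#` comment header stating that, plus provenance
#' (package version and seed where applicable). Formats are plain text:
#' FASTA and FASTQ via Biostrings, GFF3 via rtracklayer, TSV for tables,
#' YAML for configs.
#'
#' @name tnseq5-io
NULL

#' @rdname tnseq5-io
#' @param genome character string.
#' @param path output file.
#' @param name sequence name.
#' @export
write_genome_fasta <- function(genome, path, name = "chromosome") {
  dna <- Biostrings::DNAStringSet(genome)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname tnseq5-io
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  as.character(dna[[1]])
}

#' @rdname tnseq5-io
#' @param annotation gene table.
#' @export
write_annotation_gff3 <- function(annotation, path, name = "chromosome") {
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$gene_type <- annotation$gene_type
  S4Vectors::mcols(gr)$essential <- tolower(as.character(annotation$essential))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname tnseq5-io
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  data.frame(gene_id = as.character(mc$ID),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_type = as.character(mc$gene_type),
             essential = as.character(mc$essential) == "true",
             stringsAsFactors = FALSE)
}

#' @rdname tnseq5-io
#' @param reads data.frame `id`, `sequence`.
#' @param quality_char constant quality character written for every base.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  qual <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n)
    strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname tnseq5-io
#' @export
read_reads_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(dna), sequence = as.character(dna),
             stringsAsFactors = FALSE)
}

# provenance header for TSVs
.tsv_header <- function(extra = character(0)) {
  c("# coordinates: 1-based inclusive",
    sprintf("# tool: tnseq5 %s",
            as.character(utils::packageVersion("tnseq5"))),
    extra)
}

#' @rdname tnseq5-io
#' @param sites `tn_sites` table.
#' @param comment extra `#` header lines (e.g. seed, config hash).
#' @export
write_sites_tsv <- function(sites, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(comment), con)
  utils::write.table(sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tnseq5-io
#' @export
read_sites_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c("integer", "character", "integer"))
  class(tab) <- c("tn_sites", "data.frame")
  tab
}

#' @rdname tnseq5-io
#' @param x any data.frame.
#' @export
write_table_tsv <- function(x, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tnseq5-io
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @rdname tnseq5-io
#' @param config a [sim_config()].
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname tnseq5-io
#' @export
read_config_yaml <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
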