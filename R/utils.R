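#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed library summaries use
#' commercial rounding (0.5 always moves away from zero), so densities and
#' percentages are rounded with this helper throughout.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# stopifnot with a readable message
.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# 1-based circular wrap of positions onto 1..len
.wrap_pos <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

# geometric mean of strictly positive values
.geomean <- function(x) exp(mean(log(x)))
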