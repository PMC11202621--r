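#' Canonical 96-channel SBS labels
#'
#' Returns the 96 trinucleotide substitution channel labels in the canonical
#' plotting order used by COSMIC-style signature catalogs: substitution class
#' major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank,
#' both alphabetical. Labels look like \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (cl in classes) {
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", cl, "]", three))
      }
    }
  }
  out
}

#' Parse a channel label into its components
#'
#' @param label Channel label such as \code{"A[C>T]G"}.
#' @return List with \code{five}, \code{ref}, \code{alt}, \code{three}.
#' @keywords internal
parse_channel <- function(label) {
  m <- regmatches(label, regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", label))[[1]]
  if (length(m) != 5) {
    stop("malformed channel label: ", label)
  }
  list(five = m[2], ref = m[3], alt = m[4], three = m[5])
}

# reverse complement for plain uppercase ACGTN strings
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)
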