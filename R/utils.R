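`%||%` <- function(x, y) if (is.null(x)) y else x

.BASES <- c("A", "C", "G", "T")

#' Percentage with half-up rounding
#'
#' Computes `100 * a / b` rounded half-up (0.005 rounds to 0.01, unlike the
#' banker's rounding of [round()]), the convention used throughout survey
#' summary tables.
#'
#' @param a Numerator(s).
#' @param b Denominator(s); must be non-zero.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' pct_half_up(1383575, 2812813) # 49.19
#' @export
pct_half_up <- function(a, b, digits = 2) {
  if (any(b == 0)) stop("denominator is zero")
  # the 1e-9 nudge keeps exact decimal boundaries (e.g. 1.005) rounding up
  # despite their binary representation falling a hair below .5
  floor(100 * a / b * 10^digits + 0.5 + 1e-9) / 10^digits
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce reads input (sim_reads, character vector, DNAStringSet, or FASTQ
# path) to a list with elements `seq` and (possibly NULL) `qual`.
.as_reads <- function(x) {
  if (inherits(x, "sim_reads")) {
    return(list(seq = x$sequence, qual = x$quality))
  }
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    qual <- S4Vectors::mcols(x)[["qualities"]]
    return(list(seq = as.character(x),
                qual = if (is.null(qual)) NULL else as.character(qual)))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x, format = "fastq",
                                        with.qualities = TRUE)
    return(.as_reads(set))
  }
  if (is.character(x)) {
    return(list(seq = x, qual = NULL))
  }
  stop("cannot interpret reads input of class ", paste(class(x), collapse = "/"))
}

# Coerce sequence input (character vector, DNAStringSet or FASTA path) to a
# named character vector.
.as_seqs <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    out <- as.character(x)
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(.as_seqs(Biostrings::readDNAStringSet(x)))
  }
  if (is.character(x)) {
    if (length(x) && is.null(names(x)))
      names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret sequence input of class ",
       paste(class(x), collapse = "/"))
}
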