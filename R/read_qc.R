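#' Read-level quality and composition statistics
#'
#' Computes the standard sequencing QC layer from Phred+33 qualities:
#' Q20/Q30 percentages (strictly greater than 20/30), overall GC over
#' unambiguous bases, the expected error percentage from the Phred scores
#' (`mean(10^(-Q/10))`), and the per-position base content table.
#'
#' @param reads Reads as a `sim_reads` object, FASTQ path, `DNAStringSet`
#'   with qualities, or a character vector (then `quals` must be given).
#' @param quals Optional character vector of Phred+33 quality strings
#'   matching `reads` when `reads` is a plain character vector.
#' @return An object of class `read_qc_stats` with fields `n_reads`,
#'   `n_bases`, `q20_pct`, `q30_pct`, `gc_pct`, `expected_error_pct` and
#'   `per_position_content` (data frame: `pos`, `A`, `C`, `G`, `T`, `N`
#'   fractions summing to 1 at each covered position).
#' @export
read_stats <- function(reads, quals = NULL) {
  rd <- .as_reads(reads)
  if (!is.null(quals)) rd$qual <- quals
  if (is.null(rd$qual)) stop("no quality strings available for these reads")
  if (length(rd$seq) == 0L) stop("no reads supplied")
  st <- .fastq_stats_cpp(rd$seq, rd$qual)
  pc <- st$pos_counts
  covered <- colSums(pc)
  frac <- t(pc) / ifelse(covered > 0, covered, 1)
  per_pos <- data.frame(pos = seq_len(ncol(pc)),
                        A = frac[, 1L], C = frac[, 2L], G = frac[, 3L],
                        T = frac[, 4L], N = frac[, 5L])
  structure(
    list(n_reads = st$n_reads,
         n_bases = st$n_bases,
         q20_pct = 100 * st$q20 / st$n_bases,
         q30_pct = 100 * st$q30 / st$n_bases,
         gc_pct = 100 * st$gc / st$acgt,
         expected_error_pct = 100 * st$err_sum / st$n_bases,
         per_position_content = per_pos),
    class = "read_qc_stats")
}

#' @export
print.read_qc_stats <- function(x, ...) {
  cat("read_qc_stats\n")
  cat(sprintf("  reads / bases  : %.0f / %.0f\n", x$n_reads, x$n_bases))
  cat(sprintf("  Q20 / Q30      : %.3f%% / %.3f%%\n", x$q20_pct, x$q30_pct))
  cat(sprintf("  GC             : %.2f%%\n", x$gc_pct))
  cat(sprintf("  expected error : %.4f%%\n", x$expected_error_pct))
  invisible(x)
}

#' Assembly contig statistics (N50/N90)
#'
#' N50 is the length of the contig at which the cumulative length of contigs
#' sorted in decreasing order first reaches 50% of the total assembly
#' length; N90 analogously at 90%.
#'
#' @param contigs Character vector, `DNAStringSet`, or FASTA path.
#' @return An object of class `assembly_stats` with `total_length`,
#'   `n_contigs`, `n50`, `n90` and `max_contig`.
#' @export
assembly_stats <- function(contigs) {
  seqs <- .as_seqs(contigs)
  if (length(seqs) == 0L) stop("empty contig set")
  lens <- sort(unname(nchar(seqs)), decreasing = TRUE)
  total <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(lens))
  structure(
    list(total_length = total,
         n_contigs = length(lens),
         n50 = lens[which(cum >= 0.5 * total)[1L]],
         n90 = lens[which(cum >= 0.9 * total)[1L]],
         max_contig = lens[1L]),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly_stats: %d contigs, %.0f bp total, N50 %d, N90 %d, max %d\n",
              x$n_contigs, x$total_length, x$n50, x$n90, x$max_contig))
  invisible(x)
}

#' Write the per-position base content table as TSV
#'
#' @param stats A [read_stats()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_position_content <- function(stats, path) {
  stopifnot(inherits(stats, "read_qc_stats"))
  utils::write.table(stats$per_position_content, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
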