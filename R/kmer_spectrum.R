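#' Construct a k-mer depth histogram object
#'
#' A `kmer_histogram` maps depth (occurrence count of a distinct canonical
#' k-mer across all reads) to the number of distinct canonical k-mers seen
#' at that depth. It is the object every spectrum estimator consumes.
#'
#' @param depth Integer vector of depths (all >= 1).
#' @param count Number of distinct canonical k-mers at each depth.
#' @param k Odd k-mer size (odd so no k-mer is its own reverse complement).
#' @return An object of class `kmer_histogram` with fields `k`, `depth`,
#'   `count` and `total_occurrences` (`sum(depth * count)`).
#' @export
kmer_histogram <- function(depth, count, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  depth <- as.integer(depth)
  count <- as.numeric(count)
  if (length(depth) != length(count)) stop("depth and count lengths differ")
  if (any(depth < 1L)) stop("depths must be >= 1")
  if (anyDuplicated(depth)) stop("duplicated depth values")
  ord <- order(depth)
  depth <- depth[ord]
  count <- count[ord]
  structure(list(k = k, depth = depth, count = count,
                 total_occurrences = sum(as.numeric(depth) * count)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("kmer_histogram (k = %d): %d depth bins, %.6g distinct k-mers, %.6g occurrences\n",
              x$k, length(x$depth), sum(x$count), x$total_occurrences))
  invisible(x)
}

#' @export
as.data.frame.kmer_histogram <- function(x, ...) {
  data.frame(depth = x$depth, count = x$count)
}

#' Count canonical k-mers from reads
#'
#' Every length-`k` window free of ambiguous bases contributes one
#' occurrence to its canonical form, the lexicographic minimum of the window
#' and its reverse complement. Windows containing `N` are skipped entirely.
#'
#' @param reads Reads as a character vector, `sim_reads` object,
#'   `DNAStringSet`, or a FASTQ file path.
#' @param k Odd k-mer size between 3 and 31 (default 17).
#' @return A [kmer_histogram()].
#' @export
count_canonical_kmers <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (even k makes the canonical form ambiguous)")
  if (k < 3L || k > 31L) stop("k must be between 3 and 31")
  seqs <- .as_reads(reads)$seq
  if (length(seqs) == 0L) stop("no reads supplied")
  h <- .kmer_histogram_cpp(seqs, k)
  if (length(h$depth) == 0L) stop("no k-mers counted (reads shorter than k?)")
  kmer_histogram(h$depth, h$count, k)
}

#' Locate the main peak of a k-mer spectrum
#'
#' Scanning the populated depth bins upward from depth 1, the first local
#' minimum separates the low-depth error component from genuine genomic
#' k-mers; the main peak is the most populated depth beyond that cutoff and
#' estimates the average k-mer depth of the homozygous genome.
#'
#' @param hist A [kmer_histogram()].
#' @param smooth Apply a window-3 moving average to the counts before
#'   scanning (useful for noisy spectra; default off).
#' @return List with integer `peak_depth` and `low_depth_cutoff` (depths
#'   `<= low_depth_cutoff` are treated as anomalous and excluded from
#'   downstream totals).
#' @export
find_main_peak <- function(hist, smooth = FALSE) {
  stopifnot(inherits(hist, "kmer_histogram"))
  d <- hist$depth
  cnt <- hist$count
  if (smooth && length(cnt) >= 3L) {
    sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
    cnt <- ifelse(is.na(sm), cnt, as.numeric(sm))
  }
  n <- length(d)
  cutoff_i <- NA_integer_
  if (n >= 2L) {
    rising <- which(cnt[-n] <= cnt[-1L])
    if (length(rising)) cutoff_i <- rising[1L]
  }
  if (is.na(cutoff_i))
    stop("monotonically decreasing k-mer spectrum: no genomic peak ",
         "(insufficient coverage)")
  cutoff <- d[cutoff_i]
  beyond <- which(d > cutoff)
  peak <- d[beyond][which.max(cnt[beyond])]
  list(peak_depth = as.integer(peak), low_depth_cutoff = as.integer(cutoff))
}

#' Total retained k-mer occurrences
#'
#' Sum of `depth * count` over depths above the low-depth cutoff, i.e. the
#' "k-mer number" after removing depth anomalies.
#'
#' @param hist A [kmer_histogram()].
#' @param low_depth_cutoff Depths `<=` this value are excluded (default 0,
#'   i.e. keep everything).
#' @return Numeric scalar.
#' @export
kmer_number <- function(hist, low_depth_cutoff = 0L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  keep <- hist$depth > low_depth_cutoff
  sum(as.numeric(hist$depth[keep]) * hist$count[keep])
}

#' Genome size from k-mer number and peak depth
#'
#' The classic spectrum estimator: genome size = k-mer number / average
#' k-mer depth, where the average depth is read off the main peak of the
#' spectrum.
#'
#' @param kmer_number Total retained k-mer occurrences.
#' @param peak_depth Main-peak depth (>= 1).
#' @return Estimated haploid genome size in bp, rounded to whole bp.
#' @examples
#' estimate_genome_size(47338914261, 24) # 1972454761, i.e. ~1.97 Gb
#' @export
estimate_genome_size <- function(kmer_number, peak_depth) {
  if (peak_depth < 1) stop("peak_depth must be >= 1")
  round(kmer_number / peak_depth)
}

#' Error-corrected genome size
#'
#' Revised genome size = genome size x (1 - error rate), removing the
#' inflation contributed by erroneous k-mers.
#'
#' @param genome_size Genome size in bp.
#' @param error_rate Sequencing error rate as a fraction in `[0, 1)`.
#' @return Revised genome size in bp, rounded to whole bp.
#' @export
revise_genome_size <- function(genome_size, error_rate) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  round(genome_size * (1 - error_rate))
}

#' Repeat ratio from the high-depth tail of the spectrum
#'
#' Repetitive sequence shows up as k-mer mass well beyond the main peak.
#' The ratio is the occurrence-weighted fraction of retained k-mers at
#' depths greater than `multiplier` times the peak depth.
#'
#' @param hist A [kmer_histogram()].
#' @param peak_depth Main-peak depth from [find_main_peak()].
#' @param multiplier Depth threshold as a multiple of the peak (default 1.8).
#' @param low_depth_cutoff Error-depth exclusion bound (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
estimate_repeat_ratio <- function(hist, peak_depth, multiplier = 1.8,
                                  low_depth_cutoff = 0L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  d <- as.numeric(hist$depth)
  w <- d * hist$count
  denom <- sum(w[d > low_depth_cutoff])
  if (denom == 0) return(0)
  sum(w[d > multiplier * peak_depth]) / denom
}

#' Heterozygosity from the half-depth component of the spectrum
#'
#' In a diploid, k-mers overlapping a heterozygous site occur on only one
#' haplotype and pile up at half the main-peak depth, while homozygous
#' k-mers pile up at the full peak. The spectrum between the low-depth
#' cutoff and 1.5x the peak is decomposed into two Poisson components with
#' means `lambda / 2` and `lambda` (`lambda` re-estimated from the bins
#' around the peak) by non-negative least squares. The occurrence-weighted
#' share `f` of the half-depth component is converted to a per-base rate via
#' `h = 1 - (1 - f)^(1/k)`, since a k-mer is affected when any of its k
#' bases is heterozygous.
#'
#' @param hist A [kmer_histogram()].
#' @param peak_depth Main-peak depth from [find_main_peak()].
#' @param k K-mer size used to build the histogram.
#' @param low_depth_cutoff Error-depth exclusion bound (default 0).
#' @return Per-base heterozygosity as a fraction; 0 when no half-depth
#'   component is detectable.
#' @export
estimate_heterozygosity <- function(hist, peak_depth, k = hist$k,
                                    low_depth_cutoff = 0L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  d <- as.numeric(hist$depth)
  cnt <- hist$count
  win <- d > low_depth_cutoff & d <= 1.5 * peak_depth
  if (sum(win) < 3L) return(0)
  pw <- d >= 0.8 * peak_depth & d <= 1.2 * peak_depth
  lambda <- if (any(pw)) sum(d[pw] * cnt[pw]) / sum(cnt[pw]) else peak_depth
  if (!is.finite(lambda) || lambda <= 0) lambda <- peak_depth
  X <- cbind(het = stats::dpois(hist$depth[win], lambda / 2),
             hom = stats::dpois(hist$depth[win], lambda))
  cf <- .nnls2(X, cnt[win])
  A <- cf[1L]
  B <- cf[2L]
  if (A <= 0) return(0)
  f <- A * (lambda / 2) / (A * lambda / 2 + B * lambda)
  1 - (1 - f)^(1 / k)
}

# Two-column non-negative least squares: unconstrained fit, then clamp a
# negative coefficient to zero and refit the other column.
.nnls2 <- function(X, y) {
  cf <- tryCatch(stats::lsfit(X, y, intercept = FALSE)$coefficients,
                 error = function(e) c(0, 0))
  if (any(cf < 0)) {
    i <- which.min(cf)
    j <- setdiff(1:2, i)
    cf[i] <- 0
    cf[j] <- max(0, sum(X[, j] * y) / sum(X[, j]^2))
  }
  unname(cf)
}

#' Survey estimates from a k-mer spectrum
#'
#' Bundles the full estimation chain: main peak and low-depth cutoff,
#' retained k-mer number, genome size, error-revised genome size,
#' heterozygosity, and repeat ratio.
#'
#' @param hist A [kmer_histogram()].
#' @param error_rate Sequencing error rate used for the size revision
#'   (fraction; default 0).
#' @param multiplier Repeat-tail threshold multiplier (default 1.8).
#' @param smooth Passed to [find_main_peak()].
#' @return An object of class `survey_estimates` with fields `peak_depth`,
#'   `low_depth_cutoff`, `kmer_number`, `genome_size`,
#'   `revised_genome_size`, `error_rate`, `heterozygosity`, `repeat_ratio`.
#' @export
survey_estimates <- function(hist, error_rate = 0, multiplier = 1.8,
                             smooth = FALSE) {
  stopifnot(inherits(hist, "kmer_histogram"))
  pk <- find_main_peak(hist, smooth = smooth)
  kn <- kmer_number(hist, pk$low_depth_cutoff)
  gs <- estimate_genome_size(kn, pk$peak_depth)
  structure(
    list(peak_depth = pk$peak_depth,
         low_depth_cutoff = pk$low_depth_cutoff,
         kmer_number = kn,
         genome_size = gs,
         revised_genome_size = revise_genome_size(gs, error_rate),
         error_rate = error_rate,
         heterozygosity = estimate_heterozygosity(hist, pk$peak_depth,
                                                  hist$k, pk$low_depth_cutoff),
         repeat_ratio = estimate_repeat_ratio(hist, pk$peak_depth, multiplier,
                                              pk$low_depth_cutoff)),
    class = "survey_estimates")
}

#' @export
print.survey_estimates <- function(x, ...) {
  cat("survey_estimates\n")
  cat(sprintf("  peak depth          : %d (low-depth cutoff %d)\n",
              x$peak_depth, x$low_depth_cutoff))
  cat(sprintf("  k-mer number        : %.6g\n", x$kmer_number))
  cat(sprintf("  genome size         : %.0f bp\n", x$genome_size))
  cat(sprintf("  revised genome size : %.0f bp (error rate %.4g)\n",
              x$revised_genome_size, x$error_rate))
  cat(sprintf("  heterozygosity      : %.4f%%\n", 100 * x$heterozygosity))
  cat(sprintf("  repeat ratio        : %.2f%%\n", 100 * x$repeat_ratio))
  invisible(x)
}

#' GC content in non-overlapping windows
#'
#' Splits each contig into fixed-width non-overlapping windows (trailing
#' partial windows keep their actual length) and reports per-window GC as
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from the
#' denominator, and an all-N window yields `NA`.
#'
#' @param contigs Character vector, `DNAStringSet`, or FASTA path.
#' @param window Window width in bp (default 10000).
#' @return Data frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive) and `gc`.
#' @export
windowed_gc <- function(contigs, window = 10000L) {
  window <- as.integer(window)
  if (window <= 0L) stop("window must be positive")
  seqs <- .as_seqs(contigs)
  if (length(seqs) == 0L) stop("no contigs supplied")
  out <- lapply(seq_along(seqs), function(i) {
    s <- Biostrings::DNAString(seqs[[i]])
    len <- length(s)
    starts <- seq.int(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    freq <- Biostrings::letterFrequency(
      Biostrings::Views(s, start = starts, end = ends),
      letters = c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
    data.frame(seq_id = names(seqs)[i], start = starts, end = ends, gc = gc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a k-mer histogram as two-column TSV
#'
#' The depth/count layout is the one common k-mer counters dump, so the file
#' can be compared with or read by external tooling.
#'
#' @param hist A [kmer_histogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  utils::write.table(as.data.frame(hist), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column depth/count histogram dump
#'
#' @param path TSV file with depth and distinct-count columns (no header).
#' @param k K-mer size the dump was computed with.
#' @return A [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  tab <- utils::read.table(path, header = FALSE)
  kmer_histogram(tab[[1L]], tab[[2L]], k)
}
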