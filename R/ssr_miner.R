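#' Microsatellite detection thresholds
#'
#' Minimum repeat counts per unit size 1..6 and the maximum gap for compound
#' SSR formation. Defaults are the common MISA settings: mono >= 10 units,
#' di >= 6, tri/tetra/penta/hexa >= 5, compound gap 100 bp.
#'
#' @param min_repeats Named numeric vector with names "1".."6".
#' @param max_compound_gap Maximum inter-locus gap (bp) for two SSRs to be
#'   considered one compound microsatellite.
#' @return An object of class `ssr_thresholds`.
#' @export
ssr_thresholds <- function(min_repeats = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                           `4` = 5L, `5` = 5L, `6` = 5L),
                           max_compound_gap = 100L) {
  if (!identical(sort(names(min_repeats)), as.character(1:6)))
    stop("min_repeats must be named with unit sizes '1'..'6'")
  min_repeats <- as.integer(min_repeats[as.character(1:6)])
  if (any(min_repeats < 2L)) stop("all minimum repeat counts must be >= 2")
  structure(list(min_repeats = stats::setNames(min_repeats, 1:6),
                 max_compound_gap = as.integer(max_compound_gap)),
            class = "ssr_thresholds")
}

.is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  divs <- which(u %% seq_len(u - 1L) == 0L)
  !any(vapply(divs, function(d)
    strrep(substr(motif, 1L, d), u %/% d) == motif, logical(1)))
}

#' Find perfect microsatellites in one sequence
#'
#' Detects all maximal perfect tandem repeats of primitive 1-6 bp motifs
#' meeting the thresholds. Runs are broken at ambiguous bases; a repeat
#' whose motif is itself a repetition of a shorter motif is reported only at
#' the smallest unit size; a locus strictly contained in a longer reported
#' locus is suppressed (longest-span precedence, ties to the smaller unit
#' size). Coordinates are 1-based inclusive and satisfy
#' `end - start + 1 == unit_size * n_repeats`.
#'
#' @param sequence DNA sequence as a single character string (A/C/G/T/N).
#' @param seq_id Identifier recorded in the output.
#' @param thresholds An [ssr_thresholds()].
#' @return Data frame with columns `seq_id`, `start`, `end`, `motif` (as
#'   read at the locus start on the forward strand), `motif_class`
#'   (standardized rotation/reverse-complement class), `unit_size`,
#'   `n_repeats`, `compound_id` (`NA` until [merge_compound()]).
#' @export
find_ssrs <- function(sequence, seq_id = "seq",
                      thresholds = ssr_thresholds()) {
  stopifnot(inherits(thresholds, "ssr_thresholds"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_class = character(), unit_size = integer(),
                      n_repeats = integer(), compound_id = integer())
  if (n == 0L) return(empty)
  chars <- charToRaw(sequence)
  valid <- chars %in% charToRaw("ACGT")
  minrep <- thresholds$min_repeats
  rows <- list()
  for (u in 1:6) {
    need <- u * minrep[[u]]
    if (n < need) next
    head_i <- seq_len(n - u)
    eq <- (chars[head_i] == chars[head_i + u]) & valid[head_i] & valid[head_i + u]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    sel <- which(r$values & (r$lengths + u) >= need)
    for (j in sel) {
      i <- run_start[j]
      span <- r$lengths[j] + u
      nrep <- span %/% u
      motif <- substr(sequence, i, i + u - 1L)
      if (!.is_primitive(motif)) next
      rows[[length(rows) + 1L]] <-
        data.frame(seq_id = seq_id, start = i, end = i + u * nrep - 1L,
                   motif = motif, unit_size = u, n_repeats = nrep)
    }
  }
  if (length(rows) == 0L) return(empty)
  loci <- do.call(rbind, rows)
  loci <- .suppress_contained(loci)
  loci$motif_class <- vapply(loci$motif, standardize_motif, character(1),
                             USE.NAMES = FALSE)
  loci$compound_id <- NA_integer_
  loci <- loci[order(loci$start, loci$unit_size),
               c("seq_id", "start", "end", "motif", "motif_class",
                 "unit_size", "n_repeats", "compound_id")]
  rownames(loci) <- NULL
  loci
}

# Drop loci strictly contained in a longer locus (longest-span precedence;
# identical spans keep the smaller unit size).
.suppress_contained <- function(loci) {
  m <- nrow(loci)
  if (m <= 1L) return(loci)
  span <- loci$end - loci$start + 1L
  ord <- order(-span, loci$unit_size)
  loci <- loci[ord, , drop = FALSE]
  span <- span[ord]
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (!keep[i]) next
    contained <- loci$start >= loci$start[i] & loci$end <= loci$end[i] &
      (span < span[i] | (span == span[i] & loci$unit_size > loci$unit_size[i]))
    keep[contained] <- FALSE
  }
  loci[keep, , drop = FALSE]
}

#' Mine microsatellites across a sequence set
#'
#' Runs [find_ssrs()] on every sequence, assigns compound membership with
#' [merge_compound()], and attaches an [summarize_ssrs()] summary.
#'
#' @param sequences Character vector, `DNAStringSet`, or FASTA path.
#' @param thresholds An [ssr_thresholds()].
#' @return List with `loci` (data frame) and `summary` (`ssr_summary`).
#' @export
mine_ssrs <- function(sequences, thresholds = ssr_thresholds()) {
  seqs <- .as_seqs(sequences)
  loci <- do.call(rbind, lapply(seq_along(seqs), function(i)
    find_ssrs(seqs[[i]], names(seqs)[i], thresholds)))
  loci <- merge_compound(loci, thresholds$max_compound_gap)
  list(loci = loci,
       summary = summarize_ssrs(loci, n_sequences = length(seqs),
                                total_bp = sum(as.numeric(nchar(seqs)))))
}

.rotations <- function(motif) {
  u <- nchar(motif)
  vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1L, i - 1L)), character(1))
}

#' Standardize a motif into its rotation/reverse-complement class
#'
#' The class representative is the lexicographically smallest string among
#' all rotations of the motif and all rotations of its reverse complement,
#' rendered as `"X/Y"` where `Y` is the smallest rotation of `X`'s reverse
#' complement (`Y` equals `X` for self-complementary classes such as
#' `"AT/AT"`).
#'
#' @param motif Primitive motif of length 1-6 over A/C/G/T.
#' @return Single string, e.g. `"AC/GT"` for any of CA, AC, TG, GT.
#' @export
standardize_motif <- function(motif) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif) || nchar(motif) < 1L || nchar(motif) > 6L)
    stop("motif must be a 1-6 bp string over A/C/G/T")
  if (!.is_primitive(motif))
    stop("motif '", motif, "' is not primitive")
  x <- min(c(.rotations(motif), .rotations(.revcomp(motif))))
  y <- min(.rotations(.revcomp(x)))
  paste0(x, "/", y)
}

#' Group nearby microsatellites into compound loci
#'
#' Two SSRs on the same sequence whose inter-locus gap is at most `max_gap`
#' belong to the same compound; membership is transitive. Loci in a
#' component of size one keep `compound_id = NA`.
#'
#' @param loci SSR loci sorted by (`seq_id`, `start`), as from
#'   [find_ssrs()].
#' @param max_gap Maximum gap in bp (default 100).
#' @return The loci with `compound_id` filled in (sequential integers).
#' @export
merge_compound <- function(loci, max_gap = 100L) {
  if (is.null(loci) || nrow(loci) == 0L) return(loci)
  if (!identical(order(loci$seq_id, loci$start), seq_len(nrow(loci))))
    stop("loci must be sorted by (seq_id, start)")
  comp <- integer(nrow(loci))
  cid <- 0L
  prev_seq <- ""
  max_end <- -Inf
  for (i in seq_len(nrow(loci))) {
    if (loci$seq_id[i] != prev_seq ||
        loci$start[i] - max_end - 1L > max_gap) {
      cid <- cid + 1L
      max_end <- loci$end[i]
    } else {
      max_end <- max(max_end, loci$end[i])
    }
    comp[i] <- cid
    prev_seq <- loci$seq_id[i]
  }
  sizes <- table(comp)
  multi <- as.integer(names(sizes)[sizes > 1L])
  loci$compound_id <- ifelse(comp %in% multi,
                             match(comp, multi), NA_integer_)
  loci
}

#' Summarize a microsatellite census
#'
#' @param loci SSR loci (after [merge_compound()] if compound counts are
#'   wanted).
#' @param n_sequences Number of sequences examined.
#' @param total_bp Total length examined in bp.
#' @return An object of class `ssr_summary` with the examined totals,
#'   SSR-containing sequence counts, compound count, counts by unit size,
#'   by repeat number and by motif class, and the dominant raw motif per
#'   unit size. Percentages are computed with [pct_half_up()] by the print
#'   method and are reported as `NA` when there are no loci.
#' @export
summarize_ssrs <- function(loci, n_sequences, total_bp) {
  n_ssr <- if (is.null(loci)) 0L else nrow(loci)
  with_ssr <- if (n_ssr) length(unique(loci$seq_id)) else 0L
  per_seq <- if (n_ssr) table(loci$seq_id) else integer()
  by_unit <- stats::setNames(integer(6L), 1:6)
  if (n_ssr) {
    tab <- table(factor(loci$unit_size, levels = 1:6))
    by_unit[] <- as.integer(tab)
  }
  dominant <- rep(NA_character_, 6L)
  names(dominant) <- 1:6
  if (n_ssr) {
    for (u in 1:6) {
      sub <- loci$motif[loci$unit_size == u]
      if (length(sub)) dominant[[as.character(u)]] <-
          names(sort(table(sub), decreasing = TRUE))[1L]
    }
  }
  structure(
    list(n_sequences_examined = n_sequences,
         total_examined_bp = total_bp,
         n_ssr = n_ssr,
         n_sequences_with_ssr = with_ssr,
         n_sequences_with_more_than_one = sum(per_seq > 1L),
         n_compound = if (n_ssr) sum(!is.na(loci$compound_id)) else 0L,
         counts_by_unit_size = by_unit,
         counts_by_repeat_number = if (n_ssr) table(loci$n_repeats) else table(integer()),
         counts_by_motif_class = if (n_ssr) table(loci$motif_class) else table(character()),
         dominant_motif_per_unit_size = dominant),
    class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("ssr_summary\n")
  cat(sprintf("  sequences examined : %d (%.0f bp)\n",
              x$n_sequences_examined, x$total_examined_bp))
  occ <- if (x$n_sequences_examined > 0 && x$n_ssr > 0)
    sprintf(" (%.2f%% of sequences)",
            pct_half_up(x$n_sequences_with_ssr, x$n_sequences_examined))
  else ""
  cat(sprintf("  SSRs identified    : %d in %d sequences%s\n",
              x$n_ssr, x$n_sequences_with_ssr, occ))
  cat(sprintf("  compound SSRs      : %d\n", x$n_compound))
  if (x$n_ssr > 0) {
    cat("  by unit size       :",
        paste(sprintf("%s:%d (%.2f%%)", names(x$counts_by_unit_size),
                      x$counts_by_unit_size,
                      pct_half_up(x$counts_by_unit_size, x$n_ssr)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write SSR loci as a MISA-style per-locus TSV
#'
#' Columns: sequence id, SSR number on that sequence, type (`p1`..`p6`, or
#' `c` when part of a compound), motif in `"(AC)6"` notation, size, start,
#' end.
#'
#' @param loci SSR loci data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(loci, path) {
  nr <- if (is.null(loci)) 0L else nrow(loci)
  tab <- data.frame(
    ID = if (nr) loci$seq_id else character(),
    SSR_nr = if (nr) stats::ave(seq_len(nr), loci$seq_id,
                                FUN = seq_along) else integer(),
    SSR_type = if (nr) ifelse(is.na(loci$compound_id),
                              paste0("p", loci$unit_size), "c") else character(),
    SSR = if (nr) sprintf("(%s)%d", loci$motif, loci$n_repeats) else character(),
    size = if (nr) loci$end - loci$start + 1L else integer(),
    start = if (nr) loci$start else integer(),
    end = if (nr) loci$end else integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
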