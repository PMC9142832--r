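# Controlled vocabulary for vertebrate mitogenome features. Canonical names
# use full tRNA spellings with isotype suffixes for the duplicated serine
# and leucine tRNAs (S1 = Ser(UCN), S2 = Ser(AGY), L1 = Leu(CUN),
# L2 = Leu(UUR)).
.MITO_CANON <- c(
  "tRNA-Phe", "12S-rRNA", "tRNA-Val", "16S-rRNA", "tRNA-Leu(UUR)", "ND1",
  "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2", "tRNA-Trp", "tRNA-Ala",
  "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr", "COX1", "tRNA-Ser(UCN)", "tRNA-Asp",
  "COX2", "tRNA-Lys", "ATP8", "ATP6", "COX3", "tRNA-Gly", "ND3",
  "tRNA-Arg", "ND4L", "ND4", "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)",
  "ND5", "ND6", "tRNA-Glu", "CYTB", "tRNA-Thr", "tRNA-Pro", "D-loop")

.MITO_L_STRAND <- c("tRNA-Gln", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys",
                    "tRNA-Tyr", "tRNA-Ser(UCN)", "ND6", "tRNA-Glu",
                    "tRNA-Pro")

.mito_alias_table <- function() {
  aa <- c(F = "tRNA-Phe", V = "tRNA-Val", I = "tRNA-Ile", Q = "tRNA-Gln",
          M = "tRNA-Met", W = "tRNA-Trp", A = "tRNA-Ala", N = "tRNA-Asn",
          C = "tRNA-Cys", Y = "tRNA-Tyr", D = "tRNA-Asp", K = "tRNA-Lys",
          G = "tRNA-Gly", R = "tRNA-Arg", H = "tRNA-His", E = "tRNA-Glu",
          T = "tRNA-Thr", P = "tRNA-Pro",
          S1 = "tRNA-Ser(UCN)", S2 = "tRNA-Ser(AGY)",
          L1 = "tRNA-Leu(CUN)", L2 = "tRNA-Leu(UUR)")
  extra <- c("trnF" = "tRNA-Phe", "trnV" = "tRNA-Val", "trnI" = "tRNA-Ile",
             "trnQ" = "tRNA-Gln", "trnM" = "tRNA-Met", "trnW" = "tRNA-Trp",
             "trnA" = "tRNA-Ala", "trnN" = "tRNA-Asn", "trnC" = "tRNA-Cys",
             "trnY" = "tRNA-Tyr", "trnD" = "tRNA-Asp", "trnK" = "tRNA-Lys",
             "trnG" = "tRNA-Gly", "trnR" = "tRNA-Arg", "trnH" = "tRNA-His",
             "trnE" = "tRNA-Glu", "trnT" = "tRNA-Thr", "trnP" = "tRNA-Pro",
             "trnS1" = "tRNA-Ser(UCN)", "trnS2" = "tRNA-Ser(AGY)",
             "trnL1" = "tRNA-Leu(CUN)", "trnL2" = "tRNA-Leu(UUR)",
             "tRNA-Ser(UCA)" = "tRNA-Ser(UCN)",
             "tRNA-Ser(AGC)" = "tRNA-Ser(AGY)",
             "12S" = "12S-rRNA", "rrnS" = "12S-rRNA", "12S rRNA" = "12S-rRNA",
             "16S" = "16S-rRNA", "rrnL" = "16S-rRNA", "16S rRNA" = "16S-rRNA",
             "COI" = "COX1", "COII" = "COX2", "COIII" = "COX3",
             "CO1" = "COX1", "CO2" = "COX2", "CO3" = "COX3",
             "COB" = "CYTB", "CytB" = "CYTB", "cytb" = "CYTB",
             "ATPase6" = "ATP6", "ATPase8" = "ATP8",
             "CR" = "D-loop", "OH" = "D-loop", "control region" = "D-loop",
             "control_region" = "D-loop", "D loop" = "D-loop")
  c(stats::setNames(.MITO_CANON, .MITO_CANON), aa, extra)
}

#' Normalize mitochondrial feature names
#'
#' Maps the common aliases (single-letter tRNA codes as used in mitogenome
#' papers, `trnX` styles, `COI`/`COX1`, `CR`/`D-loop`, ...) onto the
#' package's controlled vocabulary.
#'
#' @param x Character vector of feature names.
#' @return Character vector of canonical names.
#' @export
normalize_feature <- function(x) {
  tab <- .mito_alias_table()
  hit <- tab[as.character(x)]
  if (anyNA(hit))
    stop("unknown mitochondrial feature name(s): ",
         paste(unique(x[is.na(hit)]), collapse = ", "))
  unname(hit)
}

#' Mitogenome base composition
#'
#' Percentages of A, C, G and T over unambiguous bases, plus the A+T and
#' G+C contents. All values are rounded half-up to 2 decimals; the combined
#' contents are summed before rounding.
#'
#' @param sequence DNA sequence as a single character string.
#' @return Named numeric vector with elements `A`, `C`, `G`, `T`, `AT`,
#'   `GC` (percentages).
#' @export
base_composition <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(sequence))
  n <- sum(f[c("A", "C", "G", "T")])
  if (n == 0) stop("sequence contains no unambiguous bases")
  raw_pct <- 100 * f[c("A", "C", "G", "T")] / n
  half_up <- function(v) floor(v * 100 + 0.5 + 1e-9) / 100
  c(half_up(raw_pct),
    AT = half_up(raw_pct[["A"]] + raw_pct[["T"]]),
    GC = half_up(raw_pct[["C"]] + raw_pct[["G"]]))
}

#' The canonical vertebrate mitochondrial gene order
#'
#' The standard 37-gene vertebrate arrangement (13 protein-coding genes, 22
#' tRNAs, 2 rRNAs) plus the control region, with heavy/light strand
#' assignment: ND6 and eight tRNAs (Gln, Ala, Asn, Cys, Tyr, Ser(UCN), Glu,
#' Pro) are on the L-strand, everything else on the H-strand. The order is
#' linearized at tRNA-Phe.
#'
#' @return An object of class `gene_order`: a data frame with columns
#'   `feature` and `strand`.
#' @export
canonical_vertebrate_order <- function() {
  structure(
    data.frame(feature = .MITO_CANON,
               strand = ifelse(.MITO_CANON %in% .MITO_L_STRAND, "L", "H")),
    class = c("gene_order", "data.frame"))
}

#' Read a mitogenome annotation table
#'
#' Accepts either a BED-like TSV with columns `feature`, `strand`, `start`,
#' `end` (any order, header required; strand as `H`/`L` or `+`/`-`) or a
#' minimal GFF3 whose attributes carry `Name=` (requires the rtracklayer
#' package).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gff3"`.
#' @return Data frame with `feature` (canonical names), `strand` (`H`/`L`),
#'   `start`, `end`.
#' @export
read_mito_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("feature", "strand", "start", "end")
    if (!all(need %in% names(tab)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    tab <- tab[, need]
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    tab <- data.frame(feature = as.character(gr$Name),
                      strand = as.character(BiocGenerics::strand(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr))
  }
  tab$feature <- normalize_feature(tab$feature)
  tab$strand <- c(`+` = "H", `-` = "L", H = "H", L = "L")[tab$strand]
  tab
}

#' Compare an observed mitogenome gene order against a reference
#'
#' The observed annotation is ordered by start coordinate (if provided),
#' treated as circular, and linearized at tRNA-Phe. Features occurring more
#' than once are reported as duplicated; for each duplicated feature the
#' copy that best aligns with the reference is retained for the order
#' comparison. The translocated set is the minimum set of features whose
#' removal makes the remaining observed order equal to the reference as a
#' circular sequence, computed exactly via longest common circular
#' subsequence over all rotation pairs. Strand changes are listed
#' separately and do not count as translocations.
#'
#' @param observed Data frame with column `feature` (any recognized alias)
#'   and optional `strand` and `start` columns, or a character vector of
#'   feature names in order.
#' @param reference A `gene_order` (default [canonical_vertebrate_order()]).
#' @return An object of class `rearrangement_report` with fields
#'   `translocated`, `duplicated`, `strand_changes` (data frame `feature`,
#'   `from`, `to`) and `is_canonical` (true iff all three are empty).
#' @export
compare_gene_order <- function(observed,
                               reference = canonical_vertebrate_order()) {
  if (is.character(observed)) observed <- data.frame(feature = observed)
  if (!is.null(observed$start))
    observed <- observed[order(observed$start), , drop = FALSE]
  feats <- normalize_feature(observed$feature)
  strands <- observed$strand
  if (!is.null(strands))
    strands <- c(`+` = "H", `-` = "L", H = "H", L = "L")[as.character(strands)]

  # linearize at tRNA-Phe if present
  anchor <- match("tRNA-Phe", feats)
  if (!is.na(anchor) && anchor > 1L) {
    idx <- c(anchor:length(feats), seq_len(anchor - 1L))
    feats <- feats[idx]
    strands <- strands[idx]
  }

  dup <- unique(feats[duplicated(feats)])
  ref_feats <- reference$feature

  # for duplicated features, try every choice of which copy to keep and
  # retain the choice that maximizes the common circular subsequence
  dup_pos <- lapply(dup, function(f) which(feats == f))
  combos <- if (length(dup)) do.call(expand.grid, dup_pos) else NULL
  n_combo <- if (is.null(combos)) 1L else nrow(combos)
  best_kept <- character(0)
  best_feats <- NULL
  for (ci in seq_len(n_combo)) {
    drop_idx <- integer(0)
    if (!is.null(combos)) {
      for (di in seq_along(dup))
        drop_idx <- c(drop_idx, setdiff(dup_pos[[di]], combos[ci, di]))
    }
    fs <- if (length(drop_idx)) feats[-drop_idx] else feats
    common <- intersect(fs, ref_feats)
    a <- match(fs[fs %in% common], .MITO_CANON)
    b <- match(ref_feats[ref_feats %in% common], .MITO_CANON)
    kept <- .MITO_CANON[.lccs_cpp(a, b)]
    if (length(kept) > length(best_kept)) {
      best_kept <- kept
      best_feats <- fs
    }
  }
  if (is.null(best_feats)) best_feats <- unique(feats)
  translocated <- setdiff(intersect(best_feats, ref_feats), best_kept)

  strand_changes <- data.frame(feature = character(), from = character(),
                               to = character())
  if (!is.null(strands)) {
    first <- !duplicated(feats)
    obs_strand <- stats::setNames(strands[first], feats[first])
    shared <- intersect(names(obs_strand), ref_feats)
    ref_strand <- stats::setNames(reference$strand, reference$feature)
    changed <- shared[!is.na(obs_strand[shared]) &
                        obs_strand[shared] != ref_strand[shared]]
    strand_changes <- data.frame(feature = changed,
                                 from = unname(ref_strand[changed]),
                                 to = unname(obs_strand[changed]))
  }
  structure(
    list(translocated = translocated,
         duplicated = dup,
         strand_changes = strand_changes,
         is_canonical = length(translocated) == 0L && length(dup) == 0L &&
           nrow(strand_changes) == 0L),
    class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat("rearrangement_report\n")
  if (x$is_canonical) {
    cat("  canonical vertebrate gene order\n")
  } else {
    cat(sprintf("  translocated  : %s\n",
                if (length(x$translocated)) paste(x$translocated, collapse = ", ") else "-"))
    cat(sprintf("  duplicated    : %s\n",
                if (length(x$duplicated)) paste(x$duplicated, collapse = ", ") else "-"))
    cat(sprintf("  strand changes: %s\n",
                if (nrow(x$strand_changes))
                  paste(sprintf("%s (%s->%s)", x$strand_changes$feature,
                                x$strand_changes$from, x$strand_changes$to),
                        collapse = ", ")
                else "-"))
  }
  invisible(x)
}
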