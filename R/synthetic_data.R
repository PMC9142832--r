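#' Simulation configuration for a diploid genome survey
#'
#' Bundles every knob of the simulator: a random background genome with a
#' target GC content, segmental duplications (the mechanism that inflates
#' k-mer depth beyond the main peak), a planted microsatellite catalog,
#' heterozygous SNPs between the two haplotypes, and uniform-coverage
#' fixed-length reads with per-base substitution errors and Phred qualities.
#'
#' @param genome_length Haploid background length in bp (before SSR
#'   insertions, which extend the sequence slightly).
#' @param gc_content Target GC fraction in `[0, 1]`.
#' @param het_rate Per-base probability that the second haplotype carries a
#'   substitution (heterozygous SNP rate).
#' @param repeat_fraction Fraction of the genome overwritten with copies of
#'   segments taken from elsewhere, in `[0, 1)`. Both source and copy then
#'   carry k-mers at twice the background depth.
#' @param repeat_unit_length Length in bp of each duplicated segment.
#' @param ssr_spec Planted microsatellite catalog: a `data.frame` with
#'   columns `motif` (primitive, A/C/G/T only), `n_repeats` and `n_insert`
#'   (how many copies of that tract to insert). May be empty.
#' @param coverage Overall fold coverage (summed over both haplotypes).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error probability in `[0, 1)`.
#' @param quality_model Either `list(type = "constant", q = 30)` or
#'   `list(type = "two_state", q_high = 38, q_low = 12, p_low = 0.1)` for
#'   per-base high/low qualities.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_config`.
#' @seealso [simulate_genome()], [diploidize()], [simulate_reads()],
#'   [simulate_survey()]
#' @export
sim_config <- function(genome_length,
                       gc_content = 0.5,
                       het_rate = 0,
                       repeat_fraction = 0,
                       repeat_unit_length = 500L,
                       ssr_spec = NULL,
                       coverage = 40,
                       read_length = 150L,
                       error_rate = 0,
                       quality_model = list(type = "constant", q = 30L),
                       seed = 1L) {
  genome_length <- as.integer(genome_length)
  read_length <- as.integer(read_length)
  if (genome_length <= read_length)
    stop("genome_length must exceed read_length")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  if (het_rate < 0 || het_rate > 1) stop("het_rate must be in [0, 1]")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)")
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  ssr_spec <- .normalize_ssr_spec(ssr_spec)
  if (!quality_model$type %in% c("constant", "two_state"))
    stop("quality_model$type must be 'constant' or 'two_state'")
  structure(
    list(genome_length = genome_length, gc_content = gc_content,
         het_rate = het_rate, repeat_fraction = repeat_fraction,
         repeat_unit_length = as.integer(repeat_unit_length),
         ssr_spec = ssr_spec, coverage = coverage,
         read_length = read_length, error_rate = error_rate,
         quality_model = quality_model, seed = as.integer(seed)),
    class = "sim_config")
}

.normalize_ssr_spec <- function(spec) {
  if (is.null(spec) || (is.data.frame(spec) && nrow(spec) == 0L)) {
    return(data.frame(motif = character(), n_repeats = integer(),
                      n_insert = integer()))
  }
  if (!is.data.frame(spec)) {
    spec <- do.call(rbind, lapply(spec, function(s) {
      data.frame(motif = as.character(s[[1]]),
                 n_repeats = as.integer(s[[2]]),
                 n_insert = as.integer(s[[3]]))
    }))
  }
  spec$motif <- toupper(as.character(spec$motif))
  spec$n_repeats <- as.integer(spec$n_repeats)
  spec$n_insert <- as.integer(spec$n_insert)
  bad <- grepl("[^ACGT]", spec$motif)
  if (any(bad))
    stop("ssr_spec motif contains non-ACGT symbol: ",
         paste(spec$motif[bad], collapse = ", "))
  if (any(!vapply(spec$motif, .is_primitive, logical(1))))
    stop("ssr_spec motifs must be primitive (not a repetition of a shorter motif)")
  if (any(spec$n_repeats < 2L) || any(spec$n_insert < 1L))
    stop("ssr_spec requires n_repeats >= 2 and n_insert >= 1")
  spec
}

#' Simulate a reference haplotype with repeats and planted microsatellites
#'
#' Draws a random background sequence at the configured GC content, realizes
#' the repeat fraction by overwriting randomly chosen target blocks with
#' copies of other blocks (segmental duplication), then inserts the planted
#' SSR tracts at uniformly chosen positions kept at least two motif lengths
#' apart. Each tract is flanked by guard bases chosen so it cannot be
#' extended by another unit, which keeps the truth catalog maximal. Finally
#' any spontaneous tandem repeat that meets the default detection thresholds
#' but is not part of the catalog is broken by a single-base change, so the
#' planted catalog is the complete set of detectable loci.
#'
#' @param config A [sim_config()].
#' @return A list with `sequence` (single character string) and `truth`, a
#'   `truth_record` holding the realized haploid length, GC, repeat fraction,
#'   het rate, and the planted SSR catalog with exact 1-based coordinates.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  x <- sample(.BASES, L, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  rho <- config$repeat_fraction
  if (rho > 0) {
    unit <- config$repeat_unit_length
    nblock <- L %/% unit
    n_dup <- max(1L, as.integer(floor(rho * L / unit)))
    if (n_dup >= nblock)
      stop("repeat_fraction too high for this repeat_unit_length")
    tgt <- sample.int(nblock, n_dup)
    src <- sample(setdiff(seq_len(nblock), tgt), n_dup, replace = TRUE)
    for (j in seq_len(n_dup)) {
      ti <- (tgt[j] - 1L) * unit
      si <- (src[j] - 1L) * unit
      x[(ti + 1L):(ti + unit)] <- x[(si + 1L):(si + unit)]
    }
  }

  spec <- config$ssr_spec
  planted <- data.frame(motif = character(), unit_size = integer(),
                        n_repeats = integer(), start = integer(),
                        end = integer())
  if (nrow(spec) > 0L) {
    ins <- spec[rep(seq_len(nrow(spec)), spec$n_insert),
                c("motif", "n_repeats"), drop = FALSE]
    n_ins <- nrow(ins)
    ins <- ins[sample.int(n_ins), , drop = FALSE]
    min_gap <- 2L * max(nchar(ins$motif))
    anchors <- .spaced_positions(length(x), n_ins, min_gap)
    pieces <- vector("list", 2L * n_ins + 1L)
    starts <- ends <- integer(n_ins)
    prev <- 0L
    offset <- 0L
    for (j in seq_len(n_ins)) {
      u <- nchar(ins$motif[j])
      tract <- strsplit(strrep(ins$motif[j], ins$n_repeats[j]), "")[[1]]
      first <- tract[1L]
      last <- tract[length(tract)]
      guard_l <- setdiff(.BASES, c(last, first))[1L]
      guard_r <- setdiff(.BASES, c(first, last))[1L]
      pieces[[2L * j - 1L]] <- x[(prev + 1L):anchors[j]]
      pieces[[2L * j]] <- c(guard_l, tract, guard_r)
      starts[j] <- anchors[j] + offset + 2L # skip the left guard base
      ends[j] <- starts[j] + length(tract) - 1L
      offset <- offset + length(tract) + 2L
      prev <- anchors[j]
    }
    pieces[[2L * n_ins + 1L]] <- x[(prev + 1L):length(x)]
    x <- unlist(pieces, use.names = FALSE)
    planted <- data.frame(motif = ins$motif,
                          unit_size = nchar(ins$motif),
                          n_repeats = ins$n_repeats,
                          start = starts, end = ends)
    planted <- planted[order(planted$start), , drop = FALSE]
    rownames(planted) <- NULL
    x <- .scrub_background(x, planted)
  }

  truth <- structure(
    list(haploid_genome_length = length(x),
         true_het_rate = config$het_rate,
         true_repeat_fraction = rho,
         planted_ssrs = planted,
         realized_gc = sum(x == "G" | x == "C") / length(x),
         realized_error_rate = NA_real_),
    class = "truth_record")
  list(sequence = paste(x, collapse = ""), truth = truth)
}

# n positions in [min_gap+1, L-min_gap-1] pairwise at least min_gap apart.
.spaced_positions <- function(L, n, min_gap) {
  lo <- min_gap + 1L
  hi <- L - min_gap - 1L
  if (hi - lo < n * (min_gap + 1L))
    stop("genome too short to place ", n, " spaced SSR insertions")
  for (i in 1:1000) {
    pos <- sort(sample(lo:hi, n))
    if (n == 1L || all(diff(pos) >= min_gap)) return(pos)
  }
  stop("could not place spaced SSR insertions") # nocov
}

# Break any detectable tandem repeat that is not a planted locus by mutating
# a single base of its span (outside planted intervals), iterating until the
# planted catalog is the complete set of detectable loci.
.scrub_background <- function(x, planted) {
  key <- paste(planted$start, planted$end)
  in_planted <- logical(length(x))
  for (j in seq_len(nrow(planted)))
    in_planted[planted$start[j]:planted$end[j]] <- TRUE
  for (iter in 1:25) {
    det <- find_ssrs(paste(x, collapse = ""), "ref", ssr_thresholds())
    bad <- det[!paste(det$start, det$end) %in% key, , drop = FALSE]
    if (nrow(bad) == 0L) return(x)
    for (j in seq_len(nrow(bad))) {
      span <- bad$start[j]:bad$end[j]
      cand <- span[!in_planted[span]]
      if (length(cand) == 0L) next # nocov
      p <- cand[(length(cand) + 1L) %/% 2L]
      neigh <- c(x[max(1L, p - 1L)], x[p], x[min(length(x), p + 1L)])
      x[p] <- setdiff(.BASES, neigh)[1L]
    }
  }
  stop("failed to scrub spontaneous tandem repeats from the background") # nocov
}

#' Derive the second haplotype by planting heterozygous SNPs
#'
#' Each position of the reference is substituted independently with
#' probability `het_rate`; the alternative base is drawn uniformly from the
#' three non-reference bases, so every planted SNP is a real difference.
#'
#' @param reference Reference haplotype as a single character string.
#' @param het_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `haplotype` (character string) and `snp_positions`
#'   (integer vector, 1-based).
#' @export
diploidize <- function(reference, het_rate, seed = 1L) {
  if (het_rate < 0 || het_rate > 1) stop("het_rate must be in [0, 1]")
  set.seed(seed)
  x <- strsplit(reference, "", fixed = TRUE)[[1]]
  code <- match(x, .BASES)
  pos <- which(stats::runif(length(x)) < het_rate & !is.na(code))
  if (length(pos)) {
    step <- sample.int(3L, length(pos), replace = TRUE)
    x[pos] <- .BASES[((code[pos] - 1L + step) %% 4L) + 1L]
  }
  list(haplotype = paste(x, collapse = ""), snp_positions = pos)
}

#' Simulate uniform-coverage shotgun reads from one or two haplotypes
#'
#' Reads of fixed length are drawn uniformly from both haplotypes and both
#' strands of a linear genome (no origin-spanning reads). Total read bases
#' approximate `coverage * haploid_length`, split evenly between the
#' haplotypes. Each base is substituted independently with probability
#' `error_rate`; qualities follow the configured quality model.
#'
#' @param haplotypes Character vector or list of 1 or 2 haplotype sequences.
#' @param config A [sim_config()] supplying coverage, read length, error
#'   rate and quality model.
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return An object of class `sim_reads`: a list with `sequence` and
#'   `quality` character vectors, a `meta` data frame retaining each read's
#'   source haplotype, start coordinate, strand and substitution count, and
#'   `realized_error_rate`.
#' @export
simulate_reads <- function(haplotypes, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  haps <- unlist(haplotypes, use.names = FALSE)
  stopifnot(length(haps) %in% 1:2)
  rl <- config$read_length
  lens <- nchar(haps)
  if (any(rl > lens)) stop("read_length exceeds haplotype length")
  set.seed(seed)
  n <- as.integer(round(config$coverage * lens[1L] / rl))
  hap <- sample.int(length(haps), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- floor(stats::runif(n) * (lens[hap] - rl + 1)) + 1L
  seqs <- substring(haps[hap], start, start + rl - 1L)
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- .revcomp(seqs[minus])

  n_err <- integer(n)
  if (config$error_rate > 0) {
    n_err <- stats::rbinom(n, rl, config$error_rate)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      at <- sample.int(rl, n_err[i])
      code <- match(chars[at], .BASES)
      step <- sample.int(3L, n_err[i], replace = TRUE)
      chars[at] <- .BASES[((code - 1L + step) %% 4L) + 1L]
      seqs[i] <- paste(chars, collapse = "")
    }
  }

  qm <- config$quality_model
  if (qm$type == "constant") {
    quals <- rep(strrep(rawToChar(as.raw(33L + qm$q)), rl), n)
  } else {
    qmat <- matrix(sample(c(qm$q_high, qm$q_low), n * rl, replace = TRUE,
                          prob = c(1 - qm$p_low, qm$p_low)), nrow = n)
    quals <- apply(qmat + 33L, 1L, function(r) rawToChar(as.raw(r)))
  }

  structure(
    list(sequence = seqs, quality = quals,
         meta = data.frame(read_id = sprintf("read_%06d", seq_len(n)),
                           haplotype = hap, start = start, strand = strand,
                           n_errors = n_err),
         read_length = rl,
         realized_error_rate = sum(n_err) / (as.numeric(n) * rl)),
    class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d reads x %d bp (realized error rate %.4g)\n",
              length(x$sequence), x$read_length, x$realized_error_rate))
  invisible(x)
}

#' Run the full simulation: genome, second haplotype, reads
#'
#' Convenience wrapper chaining [simulate_genome()], [diploidize()] (seed
#' `config$seed + 1`) and [simulate_reads()] (seed `config$seed + 2`), and
#' completing the truth record with the realized heterozygosity and error
#' rate.
#'
#' @param config A [sim_config()].
#' @return List with `reference`, `haplotype2`, `snp_positions`, `reads`
#'   (a `sim_reads`) and `truth` (a `truth_record`).
#' @export
simulate_survey <- function(config) {
  gen <- simulate_genome(config)
  dip <- diploidize(gen$sequence, config$het_rate, seed = config$seed + 1L)
  reads <- simulate_reads(c(gen$sequence, dip$haplotype), config,
                          seed = config$seed + 2L)
  truth <- gen$truth
  truth$realized_het_rate <-
    length(dip$snp_positions) / truth$haploid_genome_length
  truth$realized_error_rate <- reads$realized_error_rate
  list(reference = gen$sequence, haplotype2 = dip$haplotype,
       snp_positions = dip$snp_positions, reads = reads, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record\n")
  cat(sprintf("  haploid genome length : %d bp\n", x$haploid_genome_length))
  cat(sprintf("  GC (realized)         : %.4f\n", x$realized_gc))
  cat(sprintf("  het rate (target)     : %.4g\n", x$true_het_rate))
  cat(sprintf("  repeat fraction       : %.3g\n", x$true_repeat_fraction))
  cat(sprintf("  planted SSR loci      : %d\n", nrow(x$planted_ssrs)))
  invisible(x)
}

#' Write simulated reads as Phred+33 FASTQ
#'
#' @param reads A `sim_reads` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "sim_reads"))
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$meta$read_id
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write a sequence set as 60-column wrapped FASTA
#'
#' @param sequences Named character vector (or single unnamed sequence).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqs <- .as_seqs(sequences)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Write the simulation truth to TSV + JSON
#'
#' Emits `<prefix>_ssrs.tsv` (planted loci, 1-based inclusive coordinates)
#' and `<prefix>_truth.json` (scalar truth fields).
#'
#' @param truth A `truth_record`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "truth_record"))
  tsv <- paste0(prefix, "_ssrs.tsv")
  json <- paste0(prefix, "_truth.json")
  utils::write.table(truth$planted_ssrs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  scalars <- truth[setdiff(names(truth), "planted_ssrs")]
  jsonlite::write_json(scalars, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, json))
}
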