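#' Run a full genome survey and assemble the report
#'
#' Orchestrates the analysis stages over one input set: k-mer spectrum and
#' survey estimates from the reads, read QC, and optionally assembly
#' statistics, windowed GC and microsatellite mining on contigs, and
#' composition plus gene-order comparison on a mitogenome. Any stage
#' failure is re-raised with the stage name so pipeline errors are easy to
#' locate.
#'
#' @param reads Reads input (FASTQ path, `sim_reads`, character vector or
#'   `DNAStringSet` with qualities).
#' @param contigs Optional contig input (FASTA path, character vector or
#'   `DNAStringSet`).
#' @param mito_sequence Optional mitogenome sequence (single string or
#'   FASTA path).
#' @param mito_annotation Optional annotation data frame (see
#'   [read_mito_annotation()]) or path to a TSV.
#' @param k K-mer size (default 17).
#' @param thresholds An [ssr_thresholds()].
#' @param error_rate Sequencing error rate used to revise the genome size;
#'   when `NULL` the Phred-expected error from read QC is used.
#' @param gc_window Window width for contig GC (default 10000).
#' @param out_dir Optional directory; when given, `report.json` and
#'   `report.txt` are written there.
#' @return An object of class `survey_report`: a list with elements
#'   `parameters`, `read_qc`, `kmer` (histogram summary + survey
#'   estimates), and optionally `assembly`, `ssr`, `mito`.
#' @export
run_survey <- function(reads, contigs = NULL, mito_sequence = NULL,
                       mito_annotation = NULL, k = 17L,
                       thresholds = ssr_thresholds(), error_rate = NULL,
                       gc_window = 10000L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " stage failed: ", conditionMessage(e), call. = FALSE))
  }

  hist <- stage("kmer", count_canonical_kmers(reads, k))
  qc <- stage("qc", read_stats(reads))
  er <- error_rate %||% (qc$expected_error_pct / 100)
  est <- stage("kmer", survey_estimates(hist, error_rate = er))

  report <- list(
    parameters = list(k = k,
                      min_repeats = as.list(thresholds$min_repeats),
                      max_compound_gap = thresholds$max_compound_gap,
                      gc_window = gc_window,
                      error_rate = er),
    read_qc = list(n_reads = qc$n_reads, n_bases = qc$n_bases,
                   q20_pct = qc$q20_pct, q30_pct = qc$q30_pct,
                   gc_pct = qc$gc_pct,
                   expected_error_pct = qc$expected_error_pct),
    kmer = list(peak_depth = est$peak_depth,
                low_depth_cutoff = est$low_depth_cutoff,
                kmer_number = est$kmer_number,
                genome_size = est$genome_size,
                revised_genome_size = est$revised_genome_size,
                heterozygosity = est$heterozygosity,
                repeat_ratio = est$repeat_ratio))

  if (!is.null(contigs)) {
    seqs <- stage("assembly", .as_seqs(contigs))
    asm <- stage("assembly", assembly_stats(seqs))
    gcw <- stage("assembly", windowed_gc(seqs, gc_window))
    report$assembly <- list(total_length = asm$total_length,
                            n_contigs = asm$n_contigs, n50 = asm$n50,
                            n90 = asm$n90, max_contig = asm$max_contig,
                            mean_window_gc = mean(gcw$gc, na.rm = TRUE))
    ssr <- stage("ssr", mine_ssrs(seqs, thresholds))
    s <- ssr$summary
    report$ssr <- list(
      n_sequences_examined = s$n_sequences_examined,
      total_examined_bp = s$total_examined_bp,
      n_ssr = s$n_ssr,
      n_sequences_with_ssr = s$n_sequences_with_ssr,
      n_sequences_with_more_than_one = s$n_sequences_with_more_than_one,
      n_compound = s$n_compound,
      counts_by_unit_size = as.list(s$counts_by_unit_size))
  }

  if (!is.null(mito_sequence)) {
    mseq <- stage("mito", .as_seqs(mito_sequence))[[1L]]
    comp <- stage("mito", base_composition(mseq))
    report$mito <- list(length = nchar(mseq),
                        composition = as.list(comp))
    if (!is.null(mito_annotation)) {
      ann <- if (is.character(mito_annotation))
        stage("mito", read_mito_annotation(mito_annotation))
      else mito_annotation
      rr <- stage("mito", compare_gene_order(ann))
      report$mito$gene_order <- list(
        is_canonical = rr$is_canonical,
        translocated = as.list(rr$translocated),
        duplicated = as.list(rr$duplicated),
        strand_changes = if (nrow(rr$strand_changes)) rr$strand_changes
        else list())
    }
  }

  class(report) <- "survey_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a survey report as JSON and readable text
#'
#' The JSON is deterministic for identical inputs (no timestamps), so two
#' runs with the same configuration produce byte-identical files.
#'
#' @param report A `survey_report`.
#' @param out_dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "survey_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- file.path(out_dir, "report.json")
  txt <- file.path(out_dir, "report.txt")
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(c(json, txt))
}

#' @export
print.survey_report <- function(x, ...) {
  cat("genome survey report\n")
  cat(sprintf("  reads: %.0f (%.0f bases), Q20 %.3f%%, Q30 %.3f%%, GC %.2f%%\n",
              x$read_qc$n_reads, x$read_qc$n_bases, x$read_qc$q20_pct,
              x$read_qc$q30_pct, x$read_qc$gc_pct))
  cat(sprintf("  k-mer (k=%d): peak %d, k-mer number %.6g\n",
              x$parameters$k, x$kmer$peak_depth, x$kmer$kmer_number))
  cat(sprintf("  genome size %.0f bp (revised %.0f bp), het %.4f%%, repeats %.2f%%\n",
              x$kmer$genome_size, x$kmer$revised_genome_size,
              100 * x$kmer$heterozygosity, 100 * x$kmer$repeat_ratio))
  if (!is.null(x$assembly))
    cat(sprintf("  assembly: %d contigs, %.0f bp, N50 %d, N90 %d, max %d\n",
                x$assembly$n_contigs, x$assembly$total_length,
                x$assembly$n50, x$assembly$n90, x$assembly$max_contig))
  if (!is.null(x$ssr))
    cat(sprintf("  SSRs: %d loci in %d/%d sequences (%d compound)\n",
                x$ssr$n_ssr, x$ssr$n_sequences_with_ssr,
                x$ssr$n_sequences_examined, x$ssr$n_compound))
  if (!is.null(x$mito)) {
    cat(sprintf("  mitogenome: %d bp, A+T %.2f%%\n",
                x$mito$length, x$mito$composition$AT))
    if (!is.null(x$mito$gene_order))
      cat(sprintf("  gene order canonical: %s\n",
                  x$mito$gene_order$is_canonical))
  }
  invisible(x)
}

#' Validate a survey report against the bundled JSON schema
#'
#' Performs a structural check of the required properties and their
#' primitive types as declared in the schema shipped at
#' `inst/schema/survey-report.schema.json`.
#'
#' @param report A `survey_report` or a path to a written `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  obj <- if (is.character(report)) jsonlite::read_json(report)
  else unclass(report)
  schema <- jsonlite::read_json(
    system.file("schema", "survey-report.schema.json",
                package = "genomesurvey"))
  .check_schema(obj, schema, "report")
  invisible(TRUE)
}

.check_schema <- function(obj, schema, where) {
  type <- schema$type
  if (identical(type, "object")) {
    if (!is.list(obj)) stop(where, ": expected object")
    for (req in unlist(schema$required))
      if (is.null(obj[[req]])) stop(where, ": missing required field '", req, "'")
    for (nm in names(schema$properties))
      if (!is.null(obj[[nm]]))
        .check_schema(obj[[nm]], schema$properties[[nm]],
                      paste0(where, ".", nm))
  } else if (identical(type, "number") || identical(type, "integer")) {
    if (!is.numeric(obj)) stop(where, ": expected a number")
  } else if (identical(type, "string")) {
    if (!is.character(obj)) stop(where, ": expected a string")
  } else if (identical(type, "boolean")) {
    if (!is.logical(obj)) stop(where, ": expected a boolean")
  }
  invisible(TRUE)
}
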