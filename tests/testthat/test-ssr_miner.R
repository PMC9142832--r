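test_that("detection thresholds act as exact lower bounds per unit size", {
  expect_equal(nrow(find_ssrs(strrep("A", 10))), 1L)
  expect_equal(nrow(find_ssrs(strrep("A", 9))), 0L)
  di6 <- find_ssrs(strrep("AC", 6))
  expect_equal(nrow(di6), 1L)
  expect_equal(di6$motif, "AC")
  expect_equal(di6$n_repeats, 6L)
  expect_equal(di6$end - di6$start + 1L, 12L)
  expect_equal(nrow(find_ssrs(strrep("AC", 5))), 0L)
  expect_equal(nrow(find_ssrs(strrep("AAG", 5))), 1L)
  expect_equal(nrow(find_ssrs(strrep("AAG", 4))), 0L)
})

test_that("non-primitive motifs are reported once at the smallest unit size", {
  loci <- find_ssrs(strrep("AT", 6)) # never also (ATAT)3 or (ATATAT)2
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$unit_size, 2L)
  mono <- find_ssrs(strrep("A", 20))
  expect_equal(mono$unit_size, 1L)
  expect_equal(mono$n_repeats, 20L)
})

test_that("runs are broken at ambiguous bases", {
  expect_equal(nrow(find_ssrs(paste0(strrep("A", 6), "N", strrep("A", 6)))), 0L)
  one <- find_ssrs(paste0(strrep("A", 11), "N", strrep("A", 4)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_repeats, 11L)
})

test_that("shorter loci inside a longer locus span are suppressed", {
  th <- ssr_thresholds(min_repeats = c(`1` = 2L, `2` = 2L, `3` = 3L,
                                       `4` = 3L, `5` = 3L, `6` = 3L))
  loci <- find_ssrs(strrep("AAC", 5), thresholds = th)
  # the (A)2 runs inside (AAC)5 are contained in its span and dropped
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$unit_size, 3L)
  expect_equal(loci$motif, "AAC")
})

test_that("the scan matches the exhaustive (start, unit, count) oracle", {
  set.seed(15)
  for (rep in 1:20) {
    s <- random_ssr_instance(n = 300, n_tandem = 3)
    got <- find_ssrs(s, "x")
    ora <- oracle_find_ssrs(s)
    expect_identical(got[, c("start", "end", "motif", "unit_size", "n_repeats")],
                     ora, info = paste("instance", rep))
  }
})

test_that("planted loci are recovered perfectly with no extras", {
  spec <- data.frame(motif = c("AC", "A", "AAT", "AAAT"),
                     n_repeats = c(8L, 12L, 6L, 5L),
                     n_insert = c(4L, 3L, 3L, 2L))
  g <- simulate_genome(sim_config(10000, ssr_spec = spec, seed = 16))
  det <- find_ssrs(g$sequence, "ref")
  tr <- g$truth$planted_ssrs
  expect_identical(det[, c("start", "end", "motif")],
                   tr[, c("start", "end", "motif")])
})

test_that("motif standardization collapses rotation/revcomp orbits", {
  expect_identical(standardize_motif("CA"), "AC/GT")
  expect_identical(standardize_motif("AC"), "AC/GT")
  expect_identical(standardize_motif("TG"), "AC/GT")
  expect_identical(standardize_motif("GT"), "AC/GT")
  expect_identical(standardize_motif("AT"), "AT/AT")
  expect_error(standardize_motif("ATAT"), "primitive")
  expect_error(standardize_motif("AXT"), "A/C/G/T")
})

test_that("the class representative is a fixed point of standardization", {
  set.seed(17)
  motifs <- unique(replicate(50, random_dna(sample(1:6, 1))))
  motifs <- motifs[vapply(motifs, function(m)
    !is.null(tryCatch(standardize_motif(m), error = function(e) NULL)),
    logical(1))]
  for (m in motifs) {
    cls <- standardize_motif(m)
    rep_x <- sub("/.*$", "", cls)
    expect_identical(standardize_motif(rep_x), cls)
  }
})

test_that("trinucleotides form exactly 10 classes, dinucleotides exactly 4", {
  rots <- function(m) {
    u <- nchar(m)
    vapply(seq_len(u), function(i)
      paste0(substr(m, i, u), substr(m, 1, i - 1)), character(1))
  }
  orbit <- function(m) sort(unique(c(rots(m), rots(oracle_revcomp(m)))))
  tri <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                           c("A","C","G","T")), 1, paste, collapse = "")
  tri <- tri[!tri %in% c("AAA", "CCC", "GGG", "TTT")] # non-primitive
  classes <- unique(vapply(tri, standardize_motif, character(1)))
  expect_length(classes, 10L)
  # oracle: number of distinct rotation/revcomp orbits
  orbits <- unique(vapply(tri, function(m) paste(orbit(m), collapse = ","),
                          character(1)))
  expect_length(orbits, 10L)
  # every motif's class representative belongs to its own orbit
  for (m in tri) {
    expect_true(sub("/.*$", "", standardize_motif(m)) %in% orbit(m))
  }

  di <- c("AC", "CA", "GT", "TG", "AG", "GA", "CT", "TC",
          "AT", "TA", "CG", "GC")
  expect_setequal(unique(vapply(di, standardize_motif, character(1))),
                  c("AC/GT", "AG/CT", "AT/AT", "CG/CG"))
})

test_that("mining the reverse complement mirrors the loci", {
  spec <- data.frame(motif = c("AC", "AAG", "AAAT"),
                     n_repeats = c(7L, 5L, 5L), n_insert = c(3L, 2L, 2L))
  g <- simulate_genome(sim_config(8000, ssr_spec = spec, seed = 18))
  n <- nchar(g$sequence)
  fwd <- find_ssrs(g$sequence, "x")
  rev <- find_ssrs(oracle_revcomp(g$sequence), "x")
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(rev$motif_class, rev$n_repeats),
                  paste(fwd$motif_class, fwd$n_repeats))
  # planted loci are exact unit multiples: coordinates mirror exactly
  mirrored <- data.frame(start = n - fwd$end + 1L, end = n - fwd$start + 1L)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(rev$start, mirrored$start)
  expect_equal(rev$end, mirrored$end)
})

test_that("compound grouping respects the gap threshold exactly", {
  loci <- data.frame(seq_id = "s", start = c(1L, 14L), end = c(12L, 25L),
                     motif = c("AC", "AG"), motif_class = c("AC/GT", "AG/CT"),
                     unit_size = 2L, n_repeats = 6L, compound_id = NA_integer_)
  out <- merge_compound(loci, max_gap = 100)
  expect_equal(out$compound_id, c(1L, 1L))

  far <- loci
  far$start[2] <- far$end[1] + 102L # gap of 101
  far$end[2] <- far$start[2] + 11L
  out2 <- merge_compound(far, max_gap = 100)
  expect_true(all(is.na(out2$compound_id)))
  out3 <- merge_compound(far, max_gap = 101)
  expect_equal(out3$compound_id, c(1L, 1L))

  expect_error(merge_compound(loci[2:1, ], 100), "sorted")
})

test_that("compound components equal the interval-graph oracle", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    starts <- sort(sample(1:2000, n))
    widths <- sample(10:60, n, replace = TRUE)
    ends <- starts + widths
    # drop overlapping-into-next intervals to keep (seq_id, start) sorted loci sane
    loci <- data.frame(seq_id = "s", start = starts, end = ends,
                       motif = "AC", motif_class = "AC/GT", unit_size = 2L,
                       n_repeats = 6L, compound_id = NA_integer_)
    gap <- sample(5:100, 1)
    out <- merge_compound(loci, gap)
    # oracle: connected components of the pairwise-gap graph
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      i != j && max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1 <= gap
    }))
    comp <- seq_len(n)
    repeat {
      new <- comp
      for (i in seq_len(n)) new[i] <- min(comp[adj[i, ] | seq_len(n) == i])
      if (identical(new, comp)) break
      comp <- new
    }
    sizes <- table(comp)
    oracle_multi <- comp %in% as.integer(names(sizes)[sizes > 1])
    expect_identical(!is.na(out$compound_id), oracle_multi)
    # same partition among multi-member components
    if (any(oracle_multi)) {
      expect_identical(
        as.integer(factor(out$compound_id[oracle_multi])),
        as.integer(factor(comp[oracle_multi])))
    }
  }
})

test_that("summary counts are conserved and handle edge cases", {
  spec <- data.frame(motif = c("AC", "AAG"), n_repeats = c(7L, 5L),
                     n_insert = c(3L, 2L))
  g <- simulate_genome(sim_config(8000, ssr_spec = spec, seed = 20))
  res <- mine_ssrs(c(ref = g$sequence))
  s <- res$summary
  expect_equal(sum(s$counts_by_unit_size), s$n_ssr)
  expect_equal(sum(s$counts_by_repeat_number), s$n_ssr)
  expect_equal(sum(s$counts_by_motif_class), s$n_ssr)
  expect_lte(s$n_sequences_with_more_than_one, s$n_sequences_with_ssr)
  expect_lte(s$n_sequences_with_ssr, s$n_sequences_examined)

  one <- summarize_ssrs(find_ssrs(strrep("AC", 8), "z"), 1, 16)
  expect_equal(pct_half_up(one$counts_by_unit_size[["2"]], one$n_ssr), 100)

  none <- summarize_ssrs(find_ssrs("ACGTACGT", "w"), 1, 8)
  expect_equal(none$n_ssr, 0L)
  expect_true(all(is.na(none$dominant_motif_per_unit_size)))
})

test_that("census percentages use half-up rounding to two decimals", {
  expect_equal(pct_half_up(1383575, 2812813), 49.19)
  expect_equal(pct_half_up(2187607, 9382261), 23.32)
  expect_equal(pct_half_up(1, 8), 12.5)
  expect_equal(pct_half_up(1005, 100000), 1.01) # 1.005 rounds up, not to even
})

test_that("the MISA-style locus table is written with compound flags", {
  s <- paste0(strrep("AC", 7), "TTGTT", strrep("AG", 6), strrep("G", 30),
              collapse = "")
  loci <- merge_compound(find_ssrs(s, "c1"), 100)
  f <- tempfile(fileext = ".tsv")
  write_ssr_table(loci, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(loci))
  expect_true(all(tab$SSR_type[!is.na(loci$compound_id)] == "c"))
})
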