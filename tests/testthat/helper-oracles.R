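# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

oracle_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# depth -> number of distinct canonical k-mers, as a named integer vector,
# by materializing every window in a plain table
oracle_kmer_hist <- function(reads, k) {
  wins <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (length(wins) == 0) return(integer())
  rc <- oracle_revcomp(wins)
  canon <- ifelse(wins <= rc, wins, rc)
  depth_per_kmer <- table(canon)
  tab <- table(as.integer(depth_per_kmer))
  stats::setNames(as.integer(tab), names(tab))
}

hist_as_named <- function(h) stats::setNames(as.integer(h$count), h$depth)

# Tests every (start, unit, count) triple; reports the leftmost whole-unit
# placement of each maximal perfect tandem meeting the thresholds, with
# primitive motifs only and strictly-contained shorter loci suppressed.
oracle_find_ssrs <- function(s, minrep = c(10, 6, 5, 5, 5, 5)) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  prim <- function(m) {
    u <- nchar(m)
    if (u == 1) return(TRUE)
    for (d in seq_len(u - 1)) {
      if (u %% d == 0 && strrep(substr(m, 1, d), u / d) == m) return(FALSE)
    }
    TRUE
  }
  res <- list()
  for (u in 1:6) {
    for (i in seq_len(n)) {
      if (i + u * minrep[u] - 1 > n) break
      unit <- ch[i:(i + u - 1)]
      if (!all(ok[i:(i + u - 1)])) next
      # leftmost phase: position i-1 must not continue the period-u chain
      if (i > 1 && ok[i - 1] && i - 1 + u <= n && ch[i - 1] == ch[i - 1 + u])
        next
      r <- 1L
      while (i + (r + 1L) * u - 1L <= n &&
             all(ok[(i + r * u):(i + (r + 1L) * u - 1L)]) &&
             all(ch[(i + r * u):(i + (r + 1L) * u - 1L)] == unit)) {
        r <- r + 1L
      }
      if (r < minrep[u]) next
      m <- paste(unit, collapse = "")
      if (!prim(m)) next
      res[[length(res) + 1]] <-
        data.frame(start = as.integer(i), end = as.integer(i + u * r - 1L),
                   motif = m, unit_size = as.integer(u), n_repeats = r)
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_size = integer(), n_repeats = integer()))
  }
  loci <- do.call(rbind, res)
  span <- loci$end - loci$start + 1
  keep <- rep(TRUE, nrow(loci))
  for (a in seq_len(nrow(loci))) {
    for (b in seq_len(nrow(loci))) {
      if (a == b) next
      if (loci$start[a] >= loci$start[b] && loci$end[a] <= loci$end[b] &&
          (span[a] < span[b] ||
           (span[a] == span[b] && loci$unit_size[a] > loci$unit_size[b])))
        keep[a] <- FALSE
    }
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$start, loci$unit_size), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# plants a few random perfect tandems into a random background so SSR
# instances actually contain something to find
random_ssr_instance <- function(n = 300, n_tandem = 3) {
  s <- strsplit(random_dna(n), "", fixed = TRUE)[[1]]
  for (j in seq_len(n_tandem)) {
    u <- sample(1:6, 1)
    motif <- random_dna(u)
    r <- sample(3:14, 1)
    tract <- strsplit(strrep(motif, r), "", fixed = TRUE)[[1]]
    at <- sample(seq_len(length(s) - length(tract)), 1)
    s[at:(at + length(tract) - 1)] <- tract
  }
  paste(s, collapse = "")
}

oracle_nx <- function(lens, frac) {
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= frac * total) return(l)
  }
}

oracle_pos_content <- function(reads) {
  maxlen <- max(nchar(reads))
  mat <- matrix(0, nrow = maxlen, ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (s in reads) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_along(ch)) {
      col <- if (ch[i] %in% c("A", "C", "G", "T")) ch[i] else "N"
      mat[i, col] <- mat[i, col] + 1
    }
  }
  mat / rowSums(mat)
}

# --- circular gene-order helpers -----------------------------------------

rotate_vec <- function(x, i) if (i == 0) x else c(x[(i + 1):length(x)], x[seq_len(i)])

circ_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0) return(TRUE)
  any(vapply(seq_along(a) - 1, function(i) identical(rotate_vec(a, i), b),
             logical(1)))
}

# move feature at index `from` to sit after index `after` (0 = front)
move_feature <- function(x, from, after) {
  f <- x[from]
  rest <- x[-from]
  append(rest, f, after = after)
}

# all single features whose removal makes obs and ref circularly equal
oracle_single_removals <- function(obs, ref) {
  Filter(function(f) circ_equal(setdiff(obs, f), setdiff(ref, f)), ref)
}
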