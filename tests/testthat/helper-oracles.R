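# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (per-base loops, full enumeration) so they share no
# code path with the implementation they check.

# maximal uncovered gaps between consecutive exons, by per-base scanning
naiveIntronCount <- function(exons) {
  if (nrow(exons) < 2L) return(0L)
  lo <- min(exons$start); hi <- max(exons$end)
  covered <- rep(FALSE, hi - lo)
  for (i in seq_len(nrow(exons)))
    covered[(exons$start[i] - lo + 1L):(exons$end[i] - lo)] <- TRUE
  r <- rle(covered)
  sum(!r$values & seq_along(r$values) > 1L &
        seq_along(r$values) < length(r$values))
}

# per-base accumulation of bedGraph-style intervals over [start, end)
naiveCoverage <- function(intervals, start, end) {
  d <- numeric(end - start)
  for (i in seq_len(nrow(intervals))) {
    s <- max(intervals$start[i], start); e <- min(intervals$end[i], end)
    if (e > s) d[(s - start + 1L):(e - start)] <-
        d[(s - start + 1L):(e - start)] + intervals$score[i]
  }
  d
}

# O(n*m) motif scan with invariant GT at motif positions 4-5
naiveScan <- function(s, consensus = "CAGGTAAGT", maxMismatch = 1L) {
  chars <- strsplit(toupper(s), "")[[1]]
  cons <- strsplit(toupper(consensus), "")[[1]]
  m <- length(cons)
  hits <- integer(0); mm <- integer(0)
  if (length(chars) < m) return(data.frame(position = hits,
                                           mismatches = mm))
  for (i in seq_len(length(chars) - m + 1L)) {
    w <- chars[i:(i + m - 1L)]
    if (w[4L] != cons[4L] || w[5L] != cons[5L]) next
    d <- sum(w[-c(4L, 5L)] != cons[-c(4L, 5L)])
    if (d <= maxMismatch) { hits <- c(hits, i - 1L); mm <- c(mm, d) }
  }
  data.frame(position = hits, mismatches = mm)
}

# exhaustive residual-sum-of-squares change-point fit
rssOracle <- function(d) {
  n <- length(d)
  best <- NULL; bestRss <- Inf
  for (b in 1:(n - 1L)) {
    m1 <- mean(d[1:b]); m2 <- mean(d[(b + 1L):n])
    rss <- sum((d[1:b] - m1)^2) + sum((d[(b + 1L):n] - m2)^2)
    if (rss < bestRss - 1e-9) { bestRss <- rss; best <- c(b, m1, m2) }
  }
  list(breakpoint = best[1L], mean_before = best[2L],
       mean_after = best[3L])
}

# two-sided Fisher p by enumeration of the hypergeometric support
fisherOracle <- function(a, b, c, d) {
  # margins: row1 = a + b (DEG), col1 = a + c (in bin), total n
  n <- a + b + c + d
  K <- a + c; nd <- a + b
  ks <- max(0L, nd - (n - K)):min(nd, K)
  probs <- dhyper(ks, K, n - K, nd)
  pObs <- dhyper(a, K, n - K, nd)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exhaustive membership tabulation for set overlap
membershipOracle <- function(sets) {
  un <- sort(unique(unlist(sets)))
  k <- vapply(un, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  list(common = un[k == length(sets)],
       unique = lapply(sets, function(s)
       sort(un[k == 1L & un %in% s])),
       k = setNames(k, un))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

tinyModels <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(0, 1000), end = c(300, 1400), strand = c("+", "-"),
    utr3_start = c(200, 1000), utr3_end = c(300, 1150),
    polya_proximal = c(240, 1120), polya_distal = c(290, 1010),
    gc_fraction = NA_real_, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gA", "gB"),
                      start = c(0, 200, 1000), end = c(100, 300, 1400))
  GeneModels(genes, exons)
}
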