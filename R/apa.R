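#' Estimate PDUI from one 3'-UTR coverage track
#'
#' Two-segment change-point estimator of the percentage of distal
#' polyA-site usage. The transcript-oriented depth vector is fit by a
#' piecewise-constant model with one breakpoint; the breakpoint
#' minimizing the residual sum of squares over all interior positions is
#' chosen (ties broken toward the most proximal position). PDUI is the
#' ratio mean_after / mean_before clamped to [0,1]; a best fit whose
#' downstream mean is not below the upstream mean is flagged degenerate
#' with PDUI 1 (flat coverage, all-distal usage).
#'
#' @param track a \linkS4class{CoverageTrack} over a 3'-UTR
#' @param minDepth minimum mean depth for eligibility (default 5)
#' @param minLength minimum UTR length in nt (default 100)
#' @return one-row data.frame gene_id, sample, strain, breakpoint
#'   (0-based transcript-relative offset of the first base after the
#'   break), pdui, mean_before, mean_after, degenerate; or NULL when the
#'   track is skipped (all-zero, shallow, or short; with a warning)
#' @export
estimatePdui <- function(track, minDepth = 5, minLength = 100) {
  d <- track@depth
  if (track@strand == "-") d <- rev(d)   # transcript orientation
  n <- length(d)
  if (n < minLength) {
    warning("UTR of ", track@gene_id, " shorter than ", minLength,
            " nt; skipped")
    return(NULL)
  }
  if (all(d == 0)) {
    warning("all-zero coverage for ", track@gene_id, " in ",
            track@sample, "; skipped")
    return(NULL)
  }
  if (mean(d) < minDepth) {
    warning("mean depth below ", minDepth, " for ", track@gene_id,
            " in ", track@sample, "; skipped")
    return(NULL)
  }
  cs <- cumsum(d)
  tot <- cs[n]
  b <- seq_len(n - 1L)                  # first segment = positions 1..b
  s1 <- cs[b]
  s2 <- tot - s1
  # RSS = sum d^2 - s1^2/b - s2^2/(n-b); sum d^2 constant across b
  fit <- -(s1^2 / b + s2^2 / (n - b))
  best <- which.min(fit)                # which.min takes the first tie
  mb <- s1[best] / best
  ma <- s2[best] / (n - best)
  degenerate <- ma >= mb
  pdui <- if (degenerate) 1 else min(1, max(0, ma / mb))
  data.frame(gene_id = track@gene_id, sample = track@sample,
             strain = track@strain, breakpoint = best,
             pdui = pdui, mean_before = mb, mean_after = ma,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Estimate PDUI for every track of every sample
#'
#' @param tracks per-sample list of CoverageTrack lists, as produced by
#'   \code{simulateUtrCoverage} or repeated \code{loadCoverage} calls
#' @param ... passed to \code{estimatePdui}
#' @return data.frame of per-gene, per-sample PDUI estimates
#' @export
estimatePduiSet <- function(tracks, ...) {
  rows <- list()
  for (s in names(tracks))
    for (tr in tracks[[s]]) {
      r <- estimatePdui(tr, ...)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  do.call(rbind, rows)
}

#' Call APA events between a knockout strain and the reference
#'
#' Delta-PDUI is the difference of replicate-mean PDUIs (knockout minus
#' reference); significance comes from a two-sided Welch t-test on the
#' replicate PDUIs, BH-adjusted across genes. Direction follows the
#' published screen: distal if delta > \code{deltaThreshold} and FDR <
#' \code{fdrThreshold}, proximal if delta < -\code{deltaThreshold} and
#' FDR < \code{fdrThreshold}, otherwise ns.
#'
#' @param estimates data.frame from \code{estimatePduiSet}
#' @param strain knockout strain label
#' @param reference reference strain label (default "WT")
#' @param deltaThreshold |delta PDUI| screen threshold (default 0.25)
#' @param fdrThreshold FDR screen threshold (default 0.05)
#' @return data.frame gene_id, pdui_wt, pdui_ko, delta_pdui, p, fdr,
#'   direction
#' @export
callApaEvents <- function(estimates, strain, reference = "WT",
                          deltaThreshold = 0.25, fdrThreshold = 0.05) {
  est <- estimates[estimates$strain %in% c(strain, reference), ,
                   drop = FALSE]
  rows <- list()
  for (gid in unique(est$gene_id)) {
    e <- est[est$gene_id == gid, , drop = FALSE]
    pw <- e$pdui[e$strain == reference]
    pk <- e$pdui[e$strain == strain]
    if (length(pw) < 2L || length(pk) < 2L) {
      message("gene ", gid, " skipped: < 2 replicate PDUI estimates")
      next
    }
    delta <- mean(pk) - mean(pw)
    p <- .welchP(pk, pw)
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = gid, pdui_wt = mean(pw), pdui_ko = mean(pk),
                 delta_pdui = delta, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(
    out$delta_pdui > deltaThreshold & out$fdr < fdrThreshold, "distal",
    ifelse(out$delta_pdui < -deltaThreshold & out$fdr < fdrThreshold,
           "proximal", "ns"))
  out
}

# Welch t p-value robust to zero-variance groups.
.welchP <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Classify an APA event's genomic region
#'
#' An event is a 3'-UTR event when both polyA sites lie inside the
#' annotated 3'-UTR; otherwise (or when the 3'-UTR is missing) it is a
#' terminal exon/intron event.
#'
#' @param gene_id gene of the event
#' @param models GeneModels
#' @return list(region_class, flagged) where flagged marks a missing UTR
#' @export
classifyEventRegion <- function(gene_id, models) {
  g <- models@genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("gene not in models: ", gene_id)
  if (is.na(g$utr3_start[i]))
    return(list(region_class = "terminal_exon_intron", flagged = TRUE))
  inutr <- function(p) !is.na(p) && p >= g$utr3_start[i] &&
    p < g$utr3_end[i]
  cls <- if (inutr(g$polya_proximal[i]) && inutr(g$polya_distal[i]))
    "three_prime_utr" else "terminal_exon_intron"
  list(region_class = cls, flagged = FALSE)
}

#' Scan a sense-strand sequence for U1-binding (5'SS-like) sites
#'
#' Default mode slides the 9-mer 5'-splice-site consensus (3 exonic
#' positions, then GT and four more intronic positions) along the
#' sequence; a position is a hit when the GT dinucleotide is present and
#' the remaining 7 positions carry at most \code{maxMismatch}
#' mismatches. An optional PWM mode scores with
#' \code{Biostrings::matchPWM} at \code{pwmMinScore}.
#'
#' @param sequence character or DNAString, sense strand
#' @param consensus motif string (default "CAGGTAAGT"); GT must sit at
#'   positions 4-5
#' @param maxMismatch maximum mismatches outside the GT (default 1)
#' @param pwm optional 4 x width PWM (rows ACGT); switches to PWM mode
#' @param pwmMinScore minimum score for PWM mode (default "80%")
#' @return data.frame position (0-based start), mismatches, score;
#'   empty when the sequence is shorter than the motif
#' @export
scanU1Sites <- function(sequence, consensus = "CAGGTAAGT",
                        maxMismatch = 1L, pwm = NULL,
                        pwmMinScore = "80%") {
  s <- toupper(as.character(sequence))
  if (!is.null(pwm)) {
    hits <- Biostrings::matchPWM(pwm, Biostrings::DNAString(s),
                                 min.score = pwmMinScore, with.score = TRUE)
    return(data.frame(position = BiocGenerics::start(hits) - 1L,
                      mismatches = NA_integer_,
                      score = as.numeric(S4Vectors::mcols(hits)$score)))
  }
  cons <- strsplit(toupper(consensus), "")[[1]]
  m <- length(cons)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < m)
    return(data.frame(position = integer(), mismatches = integer(),
                      score = numeric()))
  nPos <- n - m + 1L
  mism <- integer(nPos)
  gtOK <- rep(TRUE, nPos)
  for (j in seq_len(m)) {
    cj <- chars[j:(j + nPos - 1L)]
    if (j %in% c(4L, 5L)) {
      gtOK <- gtOK & cj == cons[j]
    } else {
      mism <- mism + (cj != cons[j])
    }
  }
  hit <- gtOK & mism <= maxMismatch
  data.frame(position = which(hit) - 1L, mismatches = mism[hit],
             score = (m - 2L - mism[hit]) / (m - 2L))
}

#' Count U1-binding-site hits in windows around both polyA sites
#'
#' Scans the sense-strand sequence around the proximal and the distal
#' polyA site and counts hits whose sense-strand start position falls
#' within +/- \code{window} nt of the site (genomic windows, truncated
#' at chromosome ends). When the two windows overlap, a hit inside both
#' is counted in both.
#'
#' @param gene_id gene of the event
#' @param genome DNAStringSet
#' @param models GeneModels
#' @param window half-window size in nt (default 200)
#' @param ... passed to \code{scanU1Sites}
#' @return one-row data.frame gene_id, n_proximal_window, n_distal_window
#' @export
windowSiteCounts <- function(gene_id, genome, models, window = 200L, ...) {
  g <- models@genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("gene not in models: ", gene_id)
  if (is.na(g$polya_proximal[i]))
    stop("gene ", gene_id, " has no polyA sites")
  chromSeq <- genome[[g$chrom[i]]]
  clen <- length(chromSeq)
  m <- 9L   # default consensus width; recomputed below if overridden
  dots <- list(...)
  if (!is.null(dots$consensus)) m <- nchar(dots$consensus)
  countAt <- function(site) {
    lo <- max(0L, site - window)
    hi <- min(clen, site + window + 1L)
    if (g$strand[i] == "+") {
      a <- lo
      b <- min(clen, hi + m - 1L)       # let motifs starting late fit
      sub <- as.character(Biostrings::subseq(chromSeq, a + 1L, b))
      hits <- scanU1Sites(sub, ...)
      sum(a + hits$position >= lo & a + hits$position < hi)
    } else {
      a <- max(0L, lo - m + 1L)
      b <- hi
      sub <- Biostrings::reverseComplement(
        Biostrings::subseq(chromSeq, a + 1L, b))
      hits <- scanU1Sites(as.character(sub), ...)
      senseStart <- b - 1L - hits$position   # genomic pos of sense start
      sum(senseStart >= lo & senseStart < hi)
    }
  }
  data.frame(gene_id = gene_id,
             n_proximal_window = countAt(g$polya_proximal[i]),
             n_distal_window = countAt(g$polya_distal[i]))
}

#' Compare U1-site counts between proximal and distal windows per
#' direction group
#'
#' Events are grouped by their called direction (proximal-activated vs
#' distal-activated). Per group the aggregate ratio
#' sum(proximal-window hits) / sum(distal-window hits) is reported with
#' a Wilcoxon signed-rank test on the per-event (proximal - distal)
#' differences. Groups with fewer than 5 events are flagged low-n and
#' get no p-value.
#'
#' @param events data.frame from \code{callApaEvents} (gene_id,
#'   direction)
#' @param windowCounts data.frame from repeated \code{windowSiteCounts}
#' @return data.frame group, n_events, sum_proximal, sum_distal, ratio,
#'   p, low_n
#' @export
compareSiteRatios <- function(events, windowCounts) {
  merged <- merge(events[, c("gene_id", "direction")], windowCounts,
                  by = "gene_id")
  rows <- lapply(c("proximal", "distal"), function(grp) {
    e <- merged[merged$direction == grp, , drop = FALSE]
    nEv <- nrow(e)
    sp <- sum(e$n_proximal_window)
    sd <- sum(e$n_distal_window)
    ratio <- if (nEv == 0L) NA_real_ else sp / sd
    lowN <- nEv < 5L
    p <- NA_real_
    if (!lowN) {
      diffs <- e$n_proximal_window - e$n_distal_window
      if (any(diffs != 0))
        p <- suppressWarnings(
          stats::wilcox.test(e$n_proximal_window, e$n_distal_window,
                             paired = TRUE)$p.value)
      else p <- 1
    }
    data.frame(group = paste0(grp, "-activated"), n_events = nEv,
               sum_proximal = sp, sum_distal = sd, ratio = ratio,
               p = p, low_n = lowN, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative distal-site selection from qPCR-style quantities
#'
#' The ratio of distal-specific to common 3'-UTR signal in a strain,
#' normalized by the same ratio in the wild type:
#' (expr_distal / expr_common) / (wt_distal / wt_common).
#'
#' @param exprDistal,exprCommon strain measurements (> 0)
#' @param wtDistal,wtCommon wild-type measurements (> 0)
#' @return numeric relative distal selection (NA with a warning when a
#'   denominator is zero)
#' @export
distalCommonRatio <- function(exprDistal, exprCommon, wtDistal, wtCommon) {
  bad <- exprCommon == 0 | wtCommon == 0 | wtDistal == 0
  if (any(bad)) {
    warning("zero denominator in distal/common ratio; returning NA")
  }
  out <- (exprDistal / exprCommon) / (wtDistal / wtCommon)
  out[bad] <- NA_real_
  out
}
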