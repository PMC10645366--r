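#' Quantify trans-spliced isoform usage from junction reads
#'
#' Usage of isoform i is its specific junction count divided by the
#' gene's common-exon reads; because both are drawn from the same
#' library, the per-million depth normalization cancels in the ratio.
#' The depth-normalized specific count (CPM) is reported alongside for
#' cross-sample context.
#'
#' @param junctions data.frame with columns sample, gene_id, count,
#'   label (\code{common} or \code{isoform-specific:<id>})
#' @param librarySizes named numeric vector of library sizes per sample
#'   (reads); names must cover the samples present
#' @return data.frame gene_id, sample, isoform, junction_count,
#'   common_reads, usage, cpm, flagged (TRUE when common reads are 0 and
#'   usage is undefined)
#' @export
quantifyIsoformUsage <- function(junctions, librarySizes) {
  need <- c("sample", "gene_id", "count", "label")
  stopifnot(all(need %in% names(junctions)))
  rows <- list()
  for (s in unique(junctions$sample)) {
    if (!s %in% names(librarySizes))
      stop("library size missing for sample ", s)
    ls <- librarySizes[[s]]
    js <- junctions[junctions$sample == s, , drop = FALSE]
    for (gid in unique(js$gene_id)) {
      jg <- js[js$gene_id == gid, , drop = FALSE]
      common <- sum(jg$count[jg$label == "common"])
      spec <- jg[grepl("^isoform-specific:", jg$label), , drop = FALSE]
      iso <- sub("^isoform-specific:", "", spec$label)
      flagged <- common == 0
      if (flagged)
        warning("common reads are 0 for ", gid, " in ", s,
                "; usage undefined")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, sample = s, isoform = iso,
        junction_count = spec$count, common_reads = common,
        usage = if (flagged) NA_real_ else spec$count / common,
        cpm = spec$count / ls * 1e6,
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare isoform usage between a knockout strain and the reference
#'
#' Per isoform: ratio of replicate-mean usage (knockout over reference)
#' and a two-sided Welch t-test on the replicate usage values,
#' BH-adjusted across the gene's isoforms.
#'
#' @param usage data.frame from \code{quantifyIsoformUsage}, with a
#'   strain column attached (e.g. via merge with the sample sheet)
#' @param strain knockout strain label
#' @param reference reference strain label (default "WT")
#' @return data.frame gene_id, isoform, usage_wt, usage_ko, ratio, p,
#'   fdr, flagged
#' @export
compareUsage <- function(usage, strain, reference = "WT") {
  stopifnot("strain" %in% names(usage))
  u <- usage[usage$strain %in% c(strain, reference) & !usage$flagged, ,
             drop = FALSE]
  rows <- list()
  for (gid in unique(u$gene_id)) {
    ug <- u[u$gene_id == gid, , drop = FALSE]
    for (iso in unique(ug$isoform)) {
      uw <- ug$usage[ug$isoform == iso & ug$strain == reference]
      uk <- ug$usage[ug$isoform == iso & ug$strain == strain]
      flagged <- length(uw) < 2L || length(uk) < 2L
      ratio <- if (length(uw) && length(uk) && mean(uw) > 0)
        mean(uk) / mean(uw) else NA_real_
      p <- if (flagged) NA_real_ else .welchP(uk, uw)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, isoform = iso,
        usage_wt = if (length(uw)) mean(uw) else NA_real_,
        usage_ko = if (length(uk)) mean(uk) else NA_real_,
        ratio = ratio, p = p, flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- NA_real_
  for (gid in unique(out$gene_id)) {
    sel <- out$gene_id == gid & !is.na(out$p)
    out$fdr[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out
}
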