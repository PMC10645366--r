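#' Stratify genes by structural features
#'
#' Bins every gene by intron count (0 / 1-2 / >=3), gene span length
#' (< 2 kb / >= 2 kb), mean intron length (< 0.5 kb / >= 0.5 kb /
#' no-intron) and GC-content quantile.
#'
#' @param models GeneModels (gc_fraction must be filled for GC bins;
#'   genes with NA GC get bin NA)
#' @param gcQuantiles number of GC quantile bins (default 4, quartiles)
#' @return data.frame gene_id, n_introns, intron_bin, gene_length,
#'   length_bin, mean_intron_length, intron_length_bin, gc_bin
#' @export
stratifyGenes <- function(models, gcQuantiles = 4L) {
  g <- models@genes
  ints <- introns(models)
  nInt <- table(factor(ints$gene_id, levels = g$gene_id))
  nInt <- as.integer(nInt)
  meanIntLen <- rep(NA_real_, nrow(g))
  if (nrow(ints)) {
    ml <- tapply(ints$end - ints$start, factor(ints$gene_id,
                                               levels = g$gene_id), mean)
    meanIntLen <- as.numeric(ml)
  }
  intronBin <- ifelse(nInt == 0L, "0", ifelse(nInt <= 2L, "1-2", ">=3"))
  geneLen <- g$end - g$start
  lengthBin <- ifelse(geneLen < 2000, "<2kb", ">=2kb")
  intLenBin <- ifelse(nInt == 0L, "no-intron",
                      ifelse(meanIntLen < 500, "<0.5kb", ">=0.5kb"))
  gcBin <- rep(NA_character_, nrow(g))
  okGc <- !is.na(g$gc_fraction)
  if (sum(okGc) >= gcQuantiles) {
    br <- stats::quantile(g$gc_fraction[okGc],
                          probs = seq(0, 1, length.out = gcQuantiles + 1L))
    br[1L] <- -Inf; br[length(br)] <- Inf
    gcBin[okGc] <- paste0("Q", as.integer(cut(g$gc_fraction[okGc], br,
                                              labels = FALSE)))
  }
  data.frame(gene_id = g$gene_id, n_introns = nInt,
             intron_bin = intronBin, gene_length = geneLen,
             length_bin = lengthBin, mean_intron_length = meanIntLen,
             intron_length_bin = intLenBin, gc_bin = gcBin,
             stringsAsFactors = FALSE)
}

#' Feature-bin enrichment of a DEG set against a background
#'
#' For each bin of the chosen feature, builds the 2x2 table (in-bin vs
#' out-of-bin, DEG vs non-DEG background), runs a two-sided Fisher exact
#' test, reports the cross-product odds ratio (Haldane 0.5 correction
#' when any cell is zero) and BH-adjusts p across the feature's bins.
#'
#' @param degSet character vector of gene ids (must be a subset of
#'   \code{background})
#' @param background character vector of gene ids (the transcribed set)
#' @param strata data.frame from \code{stratifyGenes}
#' @param feature one of "intron_bin", "length_bin", "intron_length_bin",
#'   "gc_bin"
#' @return data.frame feature, bin, n_deg_in_bin, n_deg, n_bg_in_bin,
#'   n_bg, odds_ratio, p, fdr
#' @export
enrichmentTest <- function(degSet, background, strata,
                           feature = c("intron_bin", "length_bin",
                                       "intron_length_bin", "gc_bin")) {
  feature <- match.arg(feature)
  if (!all(degSet %in% background))
    stop("degSet must be a subset of background")
  st <- strata[match(background, strata$gene_id), , drop = FALSE]
  if (anyNA(st$gene_id)) stop("background gene(s) missing from strata")
  bins <- sort(unique(st[[feature]][!is.na(st[[feature]])]))
  isDeg <- background %in% degSet
  nDeg <- sum(isDeg)
  nBg <- length(background)
  rows <- lapply(bins, function(b) {
    inBin <- !is.na(st[[feature]]) & st[[feature]] == b
    a <- sum(inBin & isDeg)          # DEG in bin
    bq <- sum(!inBin & isDeg)        # DEG out of bin
    cc <- sum(inBin & !isDeg)        # non-DEG in bin
    dd <- sum(!inBin & !isDeg)
    if (nDeg == 0L) {
      p <- 1; orr <- NA_real_
    } else {
      p <- stats::fisher.test(matrix(c(a, bq, cc, dd), 2L,
                                     byrow = TRUE))$p.value
      if (cc + dd == 0L || a + bq == 0L) {
        orr <- 1   # one group empty: no contrast, by convention
      } else {
        h <- if (any(c(a, bq, cc, dd) == 0L)) 0.5 else 0
        orr <- ((a + h) * (dd + h)) / ((bq + h) * (cc + h))
      }
    }
    data.frame(feature = feature, bin = b, n_deg_in_bin = a,
               n_deg = nDeg, n_bg_in_bin = a + cc, n_bg = nBg,
               odds_ratio = orr, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-bin membership fractions for density-style plots
#'
#' Fraction of a gene set falling in each bin of a feature, for the DEG
#' set and the background side by side.
#'
#' @inheritParams enrichmentTest
#' @return data.frame feature, bin, frac_deg, frac_background
#' @export
featureDensity <- function(degSet, background, strata,
                           feature = c("intron_bin", "length_bin",
                                       "intron_length_bin", "gc_bin")) {
  feature <- match.arg(feature)
  st <- strata[match(background, strata$gene_id), , drop = FALSE]
  bins <- sort(unique(st[[feature]][!is.na(st[[feature]])]))
  isDeg <- background %in% degSet
  data.frame(
    feature = feature, bin = bins,
    frac_deg = vapply(bins, function(b)
      if (sum(isDeg)) mean(st[[feature]][isDeg] == b, na.rm = TRUE)
      else NA_real_, numeric(1)),
    frac_background = vapply(bins, function(b)
      mean(st[[feature]] == b, na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
}
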