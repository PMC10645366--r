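#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median across reference genes of
#' the ratio count / geometric mean, where reference genes are those with
#' nonzero counts in every sample.
#'
#' @param object a U1CountSet or a count matrix
#' @return named positive numeric vector, one factor per sample
#' @export
computeSizeFactors <- function(object) {
  m <- if (is(object, "U1CountSet")) counts(object) else as.matrix(object)
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) stop("no reference genes without zeros for normalization")
  lg <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(sweep(lg, 1, geo)), 2, stats::median)
  stats::setNames(sf, colnames(m))
}

#' Two-group negative-binomial differential expression test
#'
#' Per-gene knockout-vs-reference comparison on median-of-ratios
#' normalized counts. Dispersion is estimated by method of moments from
#' each gene's pooled within-group variance (alpha = (s^2 - m)/m^2, with
#' a Poisson fallback alpha = 0 when the sample variance does not exceed
#' the mean) and then pooled across tested genes as the median, since a
#' per-gene estimate from a handful of replicates is too noisy to test
#' against. A Wald statistic on the difference of group means with model
#' variance mu + alpha mu^2 is referred to the standard normal (the
#' pooled dispersion makes the denominator nearly non-random). log2
#' fold-changes use a 0.5 pseudocount on normalized group means. Genes
#' below \code{meanFloor} normalized base mean are excluded from testing
#' (fdr reported as 1, p as NA); BH adjustment runs across tested genes
#' only.
#'
#' @param object a U1CountSet
#' @param strain knockout strain label to test
#' @param reference reference strain label (default "WT")
#' @param meanFloor normalized base-mean floor defining "transcribed"
#' @return data.frame gene_id, base_mean, log2fc, p, fdr, tested
#' @export
testDE <- function(object, strain, reference = "WT", meanFloor = 1) {
  st <- strains(object)
  if (!strain %in% st) stop("strain not in sample sheet: ", strain)
  if (!reference %in% st) stop("reference not in sample sheet: ", reference)
  i1 <- which(st == reference)
  i2 <- which(st == strain)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need >= 2 replicates per group")
  m <- counts(object)
  sf <- computeSizeFactors(m)
  nc <- sweep(m, 2, sf, "/")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(nc[, i1, drop = FALSE])
  m2 <- rowMeans(nc[, i2, drop = FALSE])
  v1 <- apply(nc[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(nc[, i2, drop = FALSE], 1, stats::var)
  baseMean <- rowMeans(nc[, c(i1, i2), drop = FALSE])
  tested <- baseMean >= meanFloor

  mp <- (n1 * m1 + n2 * m2) / (n1 + n2)
  s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  alphaGene <- pmax(0, (s2p - mp) / mp^2)   # Poisson fallback at 0
  alpha <- stats::median(alphaGene[tested & mp > 0])
  if (!is.finite(alpha)) alpha <- 0
  V1 <- m1 + alpha * m1^2
  V2 <- m2 + alpha * m2^2
  se2 <- V1 / n1 + V2 / n2
  z <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), 0)
  p <- ifelse(m1 == m2, 1, 2 * stats::pnorm(-abs(z)))
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))

  res <- data.frame(gene_id = rownames(m), base_mean = baseMean,
                    log2fc = lfc, p = NA_real_, fdr = 1,
                    tested = tested, stringsAsFactors = FALSE)
  res$p[tested] <- p[tested]
  res$fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  rownames(res) <- NULL
  res
}

#' Screen DE results into down/up DEG sets
#'
#' The published screen: fold-change > \code{fcThreshold} (in either
#' direction) and FDR < \code{fdrThreshold}.
#'
#' @param results data.frame from \code{testDE}
#' @param fcThreshold linear fold-change threshold (default 2)
#' @param fdrThreshold FDR threshold (default 0.05)
#' @return list(down = gene ids, up = gene ids); disjoint by construction
#' @export
screenDEGs <- function(results, fcThreshold = 2, fdrThreshold = 0.05) {
  l2 <- log2(fcThreshold)
  sig <- !is.na(results$p) & results$fdr < fdrThreshold
  list(down = results$gene_id[sig & results$log2fc < -l2],
       up = results$gene_id[sig & results$log2fc > l2])
}

#' Partition DEG sets into common / shared-by-k / unique classes
#'
#' @param sets named list of gene-id character vectors (e.g. the down
#'   sets of the five knockout strains)
#' @return list(common, unique = named list per input set,
#'   membership = data.frame(gene_id, k, sets))
#' @export
overlapSets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  un <- unique(unlist(sets, use.names = FALSE))
  if (length(un) == 0L)
    return(list(common = character(),
                unique = lapply(sets, function(s) character()),
                membership = data.frame(gene_id = character(),
                                        k = integer(), sets = character())))
  memb <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) memb <- matrix(memb, nrow = 1L,
                                       dimnames = list(NULL, names(sets)))
  k <- rowSums(memb)
  inSets <- apply(memb, 1L, function(r)
    paste(names(sets)[r], collapse = ","))
  membership <- data.frame(gene_id = un, k = k, sets = inSets,
                           stringsAsFactors = FALSE)
  common <- un[k == length(sets)]
  uniq <- lapply(stats::setNames(names(sets), names(sets)), function(nm)
    un[k == 1L & memb[, nm]])
  list(common = common, unique = uniq, membership = membership)
}
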