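#' Gene identifiers of an object
#' @param x an object holding genes
#' @return character vector of gene ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Derived introns (inter-exon gaps)
#' @param x a GeneModels object
#' @return data.frame gene_id, start, end (0-based half-open), one row per
#'   intron
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' Raw counts accessor
#' @param object a U1CountSet
#' @return integer matrix of counts
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @describeIn GeneModels gene ids
#' @param x a GeneModels
#' @export
setMethod("geneIds", "GeneModels", function(x) x@genes$gene_id)

#' @describeIn U1CountSet gene ids (rownames of the count assay)
#' @export
setMethod("geneIds", "U1CountSet", function(x) rownames(x))

#' @describeIn GeneModels derived introns as inter-exon gaps
#' @export
setMethod("introns", "GeneModels", function(x) {
  e <- x@exons
  out <- lapply(split(e, factor(e$gene_id, levels = unique(e$gene_id))),
                function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    s <- ex$end[-nrow(ex)]
    t <- ex$start[-1L]
    keep <- t > s
    if (!any(keep)) return(NULL)
    data.frame(gene_id = ex$gene_id[1L], start = s[keep], end = t[keep])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(gene_id = character(),
                                      start = numeric(), end = numeric())
  rownames(out) <- NULL
  out
})

#' @describeIn U1CountSet counts assay
#' @export
setMethod("counts", "U1CountSet",
          function(object) SummarizedExperiment::assay(object, "counts"))

#' Strain labels of the samples
#' @param x a U1CountSet or a sample sheet data.frame
#' @return character vector of strain labels
#' @export
strains <- function(x) {
  if (is(x, "U1CountSet"))
    as.character(SummarizedExperiment::colData(x)$strain)
  else as.character(x$strain)
}

setMethod("show", "GeneModels", function(object) {
  g <- object@genes
  napa <- sum(!is.na(g$polya_proximal) & !is.na(g$polya_distal))
  cat("GeneModels with", nrow(g), "genes on",
      length(unique(g$chrom)), "chromosome(s);",
      nrow(object@exons), "exons;", napa, "genes with two polyA sites\n")
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack %s %s:%d-%d(%s) sample=%s mean depth %.2f\n",
              object@gene_id, object@chrom, object@start, object@end,
              object@strand, object@sample, mean(object@depth)))
})
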