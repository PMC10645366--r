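#' @title Core data containers
#'
#' @description S4 containers for the U1-knockout RNA-seq pipeline. All
#' genomic coordinates inside these objects are 0-based half-open;
#' conversion to/from the 1-based GTF dialect happens only in the readers
#' and writers.
#'
#' @name u1apa-classes
NULL

.GENE_COLS <- c("gene_id", "chrom", "start", "end", "strand",
                "utr3_start", "utr3_end", "polya_proximal", "polya_distal",
                "gc_fraction")

#' Gene model collection
#'
#' Per-gene span, exon structure, 3'-UTR and proximal/distal polyA sites
#' for a set of genes. Introns are derived, not stored: they are exactly
#' the gaps between consecutive exons. Genes without annotated polyA
#' sites carry \code{NA} in the polyA columns and are excluded from APA
#' analysis downstream.
#'
#' @slot genes data.frame with columns gene_id, chrom, start, end, strand,
#'   utr3_start, utr3_end, polya_proximal, polya_distal, gc_fraction.
#' @slot exons data.frame with columns gene_id, start, end, sorted by
#'   genomic start within gene.
#' @export
setClass("GeneModels",
         representation(genes = "data.frame", exons = "data.frame"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  e <- object@exons
  if (!all(.GENE_COLS %in% names(g)))
    return(paste("genes slot must have columns:",
                 paste(.GENE_COLS, collapse = ", ")))
  if (!all(c("gene_id", "start", "end") %in% names(e)))
    return("exons slot must have columns gene_id, start, end")
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("duplicated gene_id")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (any(g$start < 0) || any(g$start >= g$end))
    return("gene spans must satisfy 0 <= start < end")
  # exons within span, non-overlapping, covering the span ends
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- e[e$gene_id == gid, , drop = FALSE]
    if (nrow(ex) == 0L) return(paste0("gene ", gid, " has no exons"))
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < g$start[i]) || any(ex$end > g$end[i]))
      return(paste0("exons of ", gid, " outside gene span"))
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      return(paste0("overlapping exons in ", gid))
    u0 <- g$utr3_start[i]; u1 <- g$utr3_end[i]
    pp <- g$polya_proximal[i]; pd <- g$polya_distal[i]
    if (!is.na(pp) && !is.na(pd)) {
      if (is.na(u0) || is.na(u1))
        return(paste0(gid, ": polyA sites without a 3'-UTR"))
      inutr <- function(p) p >= u0 && p < u1
      if (!inutr(pp) || !inutr(pd))
        return(paste0(gid, ": polyA site outside the 3'-UTR"))
      ok <- if (g$strand[i] == "+") pp < pd else pp > pd
      if (!ok)
        return(paste0(gid, ": proximal/distal ordering violates strand"))
    }
    if (!is.na(g$gc_fraction[i]) &&
        (g$gc_fraction[i] < 0 || g$gc_fraction[i] > 1))
      return(paste0(gid, ": gc_fraction outside [0,1]"))
  }
  TRUE
})

#' Construct a GeneModels object
#'
#' @param genes per-gene data.frame (see class docs)
#' @param exons per-exon data.frame (gene_id, start, end)
#' @return a validated \linkS4class{GeneModels}
#' @export
GeneModels <- function(genes, exons) {
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  new("GeneModels", genes = genes, exons = exons)
}

#' Count matrix with strain/replicate metadata
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{counts}
#' holds nonnegative integer gene-level counts and whose colData carries
#' \code{strain} and \code{replicate} for every sample.
#' @export
setClass("U1CountSet", contains = "SummarizedExperiment")

setValidity("U1CountSet", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) return("negative counts")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("strain", "replicate") %in% names(cd)))
    return("colData must have strain and replicate")
  if (any(is.na(cd$strain))) return("every sample needs a strain label")
  TRUE
})

#' Construct a U1CountSet
#'
#' @param counts gene x sample matrix of nonnegative integers with
#'   rownames (gene ids) and colnames (sample ids)
#' @param sampleSheet data.frame with columns sample, strain, replicate
#'   (and optionally library_size); rows are matched to the count columns
#'   by the sample column
#' @return a \linkS4class{U1CountSet}
#' @export
U1CountSet <- function(counts, sampleSheet) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("count matrix needs sample column names")
  idx <- match(colnames(counts), sampleSheet$sample)
  if (anyNA(idx))
    stop("sample sheet is missing samples: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(sampleSheet[idx, , drop = FALSE],
                             row.names = colnames(counts))
  new("U1CountSet",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd))
}

#' Per-base coverage over one 3'-UTR for one sample
#'
#' Depth is stored in genomic orientation; consumers reverse the vector
#' for a transcript-oriented view of minus-strand genes.
#' @export
setClass("CoverageTrack",
         representation(gene_id = "character", chrom = "character",
                        start = "numeric", end = "numeric",
                        strand = "character", sample = "character",
                        strain = "character", depth = "numeric"))

setValidity("CoverageTrack", function(object) {
  if (length(object@depth) != object@end - object@start)
    return("depth length must equal region width")
  if (any(object@depth < 0)) return("negative depth")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  TRUE
})

#' Construct a CoverageTrack
#' @param gene_id,chrom,start,end,strand region identity (0-based half-open)
#' @param sample,strain sample identity
#' @param depth per-base nonnegative depth, genomic orientation
#' @export
CoverageTrack <- function(gene_id, chrom, start, end, strand,
                          sample, strain = NA_character_, depth) {
  new("CoverageTrack", gene_id = gene_id, chrom = chrom,
      start = as.numeric(start), end = as.numeric(end), strand = strand,
      sample = sample, strain = as.character(strain),
      depth = as.numeric(depth))
}
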