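#' The Drosophila U1 snRNA gene registry
#'
#' The five U1 snRNA gene copies of \emph{D. melanogaster}. U1:21D sits on
#' chromosome arm 2L; 82Eb, 95Ca, 95Cb and 95Cc sit on 3R. Transcripts of
#' 21D, 95Ca and 95Cb are identical to the canonical U1; 95Cc carries a
#' U-to-C variation at position 123 and 82Eb a G-to-U variation at
#' position 134 of the 164-nt snRNA, both in or near the Sm binding site.
#'
#' @return data.frame with columns name, chrom, variant_position,
#'   ref_base, alt_base (variant columns NA for canonical copies)
#' @examples
#' u1Registry()
#' @export
u1Registry <- function() {
  reg <- data.frame(
    name = c("21D", "82Eb", "95Ca", "95Cb", "95Cc"),
    chrom = c("2L", "3R", "3R", "3R", "3R"),
    variant_position = c(NA, 134L, NA, NA, 123L),
    ref_base = c(NA, "G", NA, NA, "U"),
    alt_base = c(NA, "U", NA, NA, "C"),
    stringsAsFactors = FALSE)
  stopifnot(nrow(reg) == 5L,
            all(is.na(reg$variant_position) | reg$variant_position <= 164L))
  reg
}

# ---- annotation ----

#' Load gene models from GTF plus a polyA-site BED
#'
#' The GTF (1-based inclusive) must provide gene and exon features and may
#' provide three_prime_utr features; the BED6 (0-based half-open) names
#' each single-base polyA site \code{<gene_id>|proximal} or
#' \code{<gene_id>|distal}. Coordinates are converted to the package's
#' 0-based half-open convention. Genes with overlapping exons are dropped
#' with a warning; a polyA site falling outside the gene's 3'-UTR is a
#' validation error. Genes lacking an annotated 3'-UTR but having polyA
#' sites get the transcript-final exon as inferred 3'-UTR.
#'
#' @param gtfPath path to the GTF file
#' @param polyaBedPath optional path to the polyA BED6 file
#' @param genome optional DNAStringSet; when given, gc_fraction is filled
#' @return a \linkS4class{GeneModels}
#' @export
loadAnnotation <- function(gtfPath, polyaBedPath = NULL, genome = NULL) {
  gr <- rtracklayer::import(gtfPath, format = "gtf")
  typ <- as.character(gr$type)
  gid <- as.character(gr$gene_id)
  chr <- as.character(GenomicRanges::seqnames(gr))
  std <- as.character(BiocGenerics::strand(gr))
  s0 <- BiocGenerics::start(gr) - 1L   # to 0-based half-open
  e0 <- BiocGenerics::end(gr)

  gi <- which(typ == "gene")
  genes <- data.frame(gene_id = gid[gi], chrom = chr[gi],
                      start = s0[gi], end = e0[gi], strand = std[gi],
                      utr3_start = NA_real_, utr3_end = NA_real_,
                      polya_proximal = NA_real_, polya_distal = NA_real_,
                      gc_fraction = NA_real_, stringsAsFactors = FALSE)

  ei <- which(typ == "exon")
  exons <- data.frame(gene_id = gid[ei], start = s0[ei], end = e0[ei],
                      stringsAsFactors = FALSE)
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]

  # reject genes whose exons overlap
  bad <- vapply(split(exons, factor(exons$gene_id, genes$gene_id)),
                function(ex) nrow(ex) > 1L &&
                  any(ex$start[-1L] < ex$end[-nrow(ex)]), logical(1))
  if (any(bad)) {
    warning("dropping genes with overlapping exons: ",
            paste(genes$gene_id[bad], collapse = ", "))
    genes <- genes[!bad, , drop = FALSE]
    exons <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]
  }

  ui <- which(typ == "three_prime_utr")
  if (length(ui)) {
    m <- match(gid[ui], genes$gene_id)
    ok <- !is.na(m)
    genes$utr3_start[m[ok]] <- s0[ui][ok]
    genes$utr3_end[m[ok]] <- e0[ui][ok]
  }

  if (!is.null(polyaBedPath)) {
    bed <- rtracklayer::import(polyaBedPath, format = "BED")
    nm <- strsplit(as.character(bed$name), "|", fixed = TRUE)
    pgene <- vapply(nm, `[`, character(1), 1L)
    ptag <- vapply(nm, `[`, character(1), 2L)
    pos0 <- BiocGenerics::start(bed) - 1L
    for (k in seq_along(pgene)) {
      i <- match(pgene[k], genes$gene_id)
      if (is.na(i)) next
      if (ptag[k] == "proximal") genes$polya_proximal[i] <- pos0[k]
      else if (ptag[k] == "distal") genes$polya_distal[i] <- pos0[k]
    }
    # infer missing utr3 from the transcript-final exon
    need <- !is.na(genes$polya_proximal) & !is.na(genes$polya_distal) &
      is.na(genes$utr3_start)
    for (i in which(need)) {
      ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
      last <- if (genes$strand[i] == "+") which.max(ex$start)
              else which.min(ex$start)
      genes$utr3_start[i] <- ex$start[last]
      genes$utr3_end[i] <- ex$end[last]
    }
    chk <- !is.na(genes$polya_proximal) & !is.na(genes$polya_distal)
    out <- chk & (is.na(genes$utr3_start) |
                  genes$polya_proximal < genes$utr3_start |
                  genes$polya_proximal >= genes$utr3_end |
                  genes$polya_distal < genes$utr3_start |
                  genes$polya_distal >= genes$utr3_end)
    if (any(out))
      stop("polyA site outside the 3'-UTR for gene(s): ",
           paste(genes$gene_id[out], collapse = ", "))
  }

  models <- GeneModels(genes, exons)
  if (!is.null(genome)) models <- fillGcFraction(models, genome)
  models
}

#' Write gene models as GTF + polyA BED
#'
#' Inverse of \code{loadAnnotation}: emits gene, exon and three_prime_utr
#' GTF features (1-based inclusive) and one BED6 row per polyA site.
#'
#' @param models a GeneModels object
#' @param gtfPath,polyaBedPath output paths
#' @export
writeAnnotation <- function(models, gtfPath, polyaBedPath = NULL) {
  g <- models@genes
  e <- models@exons
  rows <- list()
  mk <- function(gene_id, chrom, start0, end0, strand, type)
    data.frame(chrom = chrom, start = start0 + 1L, end = end0,
               strand = strand, type = type, gene_id = gene_id,
               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    rows[[length(rows) + 1L]] <-
      mk(gid, g$chrom[i], g$start[i], g$end[i], g$strand[i], "gene")
    ex <- e[e$gene_id == gid, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      mk(gid, g$chrom[i], ex$start, ex$end, g$strand[i], "exon")
    if (!is.na(g$utr3_start[i]))
      rows[[length(rows) + 1L]] <-
        mk(gid, g$chrom[i], g$utr3_start[i], g$utr3_end[i], g$strand[i],
           "three_prime_utr")
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  S4Vectors::mcols(gr)$source <- "u1apa"
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$gene_id
  rtracklayer::export(gr, gtfPath, format = "gtf")

  if (!is.null(polyaBedPath)) {
    keep <- !is.na(g$polya_proximal) & !is.na(g$polya_distal)
    gk <- g[keep, , drop = FALSE]
    pos <- c(gk$polya_proximal, gk$polya_distal)
    nm <- c(paste0(gk$gene_id, "|proximal"), paste0(gk$gene_id, "|distal"))
    ord <- order(rep(gk$chrom, 2L), pos)
    bed <- GenomicRanges::GRanges(rep(gk$chrom, 2L)[ord],
                                  IRanges::IRanges(pos[ord] + 1L,
                                                   pos[ord] + 1L),
                                  strand = rep(gk$strand, 2L)[ord])
    S4Vectors::mcols(bed)$name <- nm[ord]
    S4Vectors::mcols(bed)$score <- 0L
    rtracklayer::export(bed, polyaBedPath, format = "BED")
  }
  invisible(NULL)
}

# ---- coverage ----

#' Load per-base 3'-UTR coverage from a bedGraph
#'
#' Expands a bedGraph (0-based half-open) to per-base depth over each
#' gene's 3'-UTR. Bases absent from the bedGraph have depth 0, including
#' whole chromosomes absent from an empty file; overlapping bedGraph
#' intervals are an error. When \code{knownChroms} is supplied, a region
#' on a chromosome outside that universe is an error.
#'
#' @param bedgraphPath path to the bedGraph file
#' @param models GeneModels; coverage is extracted over each 3'-UTR
#' @param sample,strain sample identity attached to the tracks
#' @param knownChroms optional character vector of valid chromosomes
#' @return named list of \linkS4class{CoverageTrack}, one per gene with a
#'   3'-UTR
#' @export
loadCoverage <- function(bedgraphPath, models, sample = "sample",
                         strain = NA_character_, knownChroms = NULL) {
  gr <- rtracklayer::import(bedgraphPath, format = "bedGraph")
  if (length(gr)) {
    red <- GenomicRanges::reduce(gr)
    if (sum(BiocGenerics::width(red)) < sum(BiocGenerics::width(gr)))
      stop("overlapping intervals in bedGraph: ", bedgraphPath)
  }
  w <- if (length(gr) && !is.null(gr$score)) gr$score else 1
  cov <- GenomicRanges::coverage(gr, weight = w)
  g <- models@genes
  g <- g[!is.na(g$utr3_start), , drop = FALSE]
  out <- vector("list", nrow(g))
  names(out) <- g$gene_id
  for (i in seq_len(nrow(g))) {
    chrom <- g$chrom[i]
    if (!is.null(knownChroms) && !chrom %in% knownChroms)
      stop("region on unknown chromosome: ", chrom)
    s <- g$utr3_start[i]; e <- g$utr3_end[i]
    d <- numeric(e - s)
    if (chrom %in% names(cov)) {
      v <- cov[[chrom]]
      hi <- min(e, length(v))
      if (hi > s) d[seq_len(hi - s)] <- as.numeric(v[(s + 1L):hi])
    }
    out[[i]] <- CoverageTrack(g$gene_id[i], chrom, s, e, g$strand[i],
                              sample, strain, d)
  }
  out
}

#' Write coverage tracks as a bedGraph
#'
#' Per-base depth is run-length compressed; zero-depth runs are omitted,
#' matching the sparse bedGraph convention.
#'
#' @param tracks list of CoverageTrack (one sample)
#' @param path output path
#' @export
writeCoverage <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    r <- rle(tr@depth)
    e <- cumsum(r$lengths)
    s <- c(0, e[-length(e)])
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = tr@chrom, start = tr@start + s[keep],
               end = tr@start + e[keep], score = r$values[keep])
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab))
    tab <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric())
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1, tab$end))
  S4Vectors::mcols(gr)$score <- tab$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(NULL)
}

# ---- sequence ----

#' GC fraction over gene spans
#'
#' Fraction of G/C bases over the full gene span (TSS to TES).
#'
#' @param genome DNAStringSet keyed by chromosome
#' @param models GeneModels
#' @return named numeric vector of fractions in [0,1]
#' @export
gcFraction <- function(genome, models) {
  g <- models@genes
  out <- numeric(nrow(g))
  names(out) <- g$gene_id
  for (i in seq_len(nrow(g))) {
    if (!g$chrom[i] %in% names(genome))
      stop("chromosome ", g$chrom[i], " not in genome")
    chromSeq <- genome[[g$chrom[i]]]
    if (length(chromSeq) < g$end[i])
      stop("sequence of ", g$chrom[i], " shorter than span of ",
           g$gene_id[i])
    s <- Biostrings::subseq(chromSeq, g$start[i] + 1L, g$end[i])
    out[i] <- as.numeric(Biostrings::letterFrequency(s, "CG")) / length(s)
  }
  out
}

#' Fill the gc_fraction column of a GeneModels from a genome
#' @param models GeneModels
#' @param genome DNAStringSet
#' @return GeneModels with gc_fraction populated
#' @export
fillGcFraction <- function(models, genome) {
  models@genes$gc_fraction <- unname(gcFraction(genome, models))
  validObject(models)
  models
}

# ---- tabular I/O ----

#' Read a count matrix plus its sample sheet
#' @param countsPath TSV with header gene_id then sample ids
#' @param samplesPath TSV with columns sample, strain, replicate
#' @return a \linkS4class{U1CountSet}
#' @export
readCounts <- function(countsPath, samplesPath) {
  tab <- utils::read.delim(countsPath, check.names = FALSE)
  ss <- utils::read.delim(samplesPath, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  U1CountSet(m, ss)
}

#' Write a count matrix plus its sample sheet
#' @param cs a U1CountSet
#' @param countsPath,samplesPath output TSV paths
#' @export
writeCounts <- function(cs, countsPath, samplesPath) {
  m <- counts(cs)
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(cs))
  utils::write.table(cd, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a splice-junction table
#'
#' Columns: sample, gene_id, chrom, donor, acceptor, strand, count, label
#' (label is \code{common} or \code{isoform-specific:<isoform_id>}).
#' @param path TSV path
#' @return data.frame
#' @export
readJunctions <- function(path) {
  j <- utils::read.delim(path, check.names = FALSE)
  if (any(j$donor == j$acceptor)) stop("junction with donor == acceptor")
  if (any(j$count < 0)) stop("negative junction count")
  j
}

#' @rdname readJunctions
#' @param junctions junction data.frame
#' @export
writeJunctions <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a qPCR Ct table (sample, target, ct)
#'
#' Records with Ct >= 40 cycles are rejected with a diagnostic, matching
#' the assay's validity rule.
#' @param path TSV path
#' @return data.frame with columns sample, target, ct
#' @export
readCtTable <- function(path) {
  ct <- utils::read.delim(path, check.names = FALSE)
  bad <- ct$ct >= 40
  if (any(bad)) {
    warning(sum(bad), " Ct record(s) >= 40 cycles rejected")
    ct <- ct[!bad, , drop = FALSE]
  }
  ct
}

#' @rdname readCtTable
#' @param ct Ct data.frame
#' @export
writeCtTable <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
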