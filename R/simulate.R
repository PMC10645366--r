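#' Simulation configuration
#'
#' Parameters of the synthetic six-strain larval RNA-seq design: a wild
#' type plus five single-U1-gene deletion strains, replicated bulk
#' RNA-seq. Defaults define the canonical fixture (300 genes, 3
#' replicates per strain, seed 20231102).
#'
#' Knockout effects are defined per strain so that one dataset carries
#' both a strongly affected regime (del82Eb, the largest affected
#' fraction) and mildly affected regimes. Down-regulated genes are
#' oversampled from the 1-2-intron stratum by \code{enrichMultiplier}.
#' APA genes carry two polyA sites in a 1-kb 3'-UTR with the proximal
#' site at 35-45% of the UTR, keeping the two +/-200-nt motif windows
#' disjoint; motif planting follows the telescripting logic: genes whose
#' knockout response is a distal shift carry a U1 motif in the proximal
#' window only, genes with a proximal shift carry one motif in each
#' window, and APA-stable genes carry none.
#'
#' @param seed master seed (mandatory); four independent sub-streams
#'   (genome, expression, coverage, junctions) are derived from it
#' @param nGenes number of genes
#' @param nReplicates replicates per strain (>= 2)
#' @param strains strain labels, reference first
#' @param intronCountProbs probabilities for the intron-count strata
#'   0 / 1-2 (uniform on 1..2) / >=3 (uniform on 3..8); must sum to 1
#' @param geneLengthRange,intronLengthRange nt ranges used for geometry
#'   validation and sampling
#' @param gcTarget genome GC fraction
#' @param libSizeMean mean library size (reads)
#' @param nbDispersion NB dispersion (variance = mu + disp * mu^2); 0
#'   gives the Poisson limit
#' @param deConfig list: fractionAffected (named per KO strain),
#'   downFraction, lfcRange (|log2FC| uniform range), enrichMultiplier
#' @param apaConfig list: fraction (genes with two polyA sites),
#'   utrLength, proximalFracRange, basePdui ranges per class, shift,
#'   depth, classProbs (null/proximal/distal), minUtr
#' @param motifConfig list: consensus, maxMismatch, plantOffset
#' @param transConfig list: nGenes, nIsoforms, commonDepth, specificRate,
#'   usageMultiplier, affectedStrains
#' @return a validated object of class \code{u1SimConfig}
#' @export
simConfig <- function(seed,
                      nGenes = 300L,
                      nReplicates = 3L,
                      strains = c("WT", "del21D", "del82Eb", "del95Ca",
                                  "del95Cb", "del95Cc"),
                      intronCountProbs = c("0" = 0.20, "1-2" = 0.45,
                                           ">=3" = 0.35),
                      geneLengthRange = c(600L, 15000L),
                      intronLengthRange = c(60L, 1800L),
                      gcTarget = 0.43,
                      libSizeMean = 2e6,
                      nbDispersion = 0.05,
                      deConfig = list(
                        fractionAffected = c(del21D = 0.02, del82Eb = 0.12,
                                             del95Ca = 0.05, del95Cb = 0.04,
                                             del95Cc = 0.06),
                        downFraction = 0.8,
                        lfcRange = c(1, 3),
                        enrichMultiplier = 2),
                      apaConfig = list(
                        fraction = 0.4, utrLength = 1000L,
                        proximalFracRange = c(0.35, 0.45),
                        basePduiProximal = c(0.60, 0.85),
                        basePduiDistal = c(0.15, 0.40),
                        basePduiNull = c(0.30, 0.70),
                        shift = 0.5, depth = 30,
                        classProbs = c(null = 0.40, proximal = 0.35,
                                       distal = 0.25),
                        minUtr = 100L),
                      motifConfig = list(consensus = "CAGGTAAGT",
                                         maxMismatch = 1L,
                                         plantOffset = 150L),
                      transConfig = list(
                        nGenes = 2L, nIsoforms = c(4L, 3L),
                        commonDepth = 1000L, specificRate = 0.8,
                        usageMultiplier = 1.5,
                        affectedStrains = c("del21D", "del95Ca",
                                            "del95Cb"))) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(intronCountProbs) - 1) < 1e-8,
            abs(sum(apaConfig$classProbs) - 1) < 1e-8,
            all(deConfig$fractionAffected >= 0 &
                deConfig$fractionAffected <= 1),
            deConfig$downFraction >= 0, deConfig$downFraction <= 1,
            apaConfig$fraction >= 0, apaConfig$fraction <= 1,
            gcTarget > 0, gcTarget < 1,
            nbDispersion >= 0, nReplicates >= 1)
  # infeasible geometry: one intron plus two minimal exons must fit
  if (intronLengthRange[1] + 2L * 150L > geneLengthRange[2])
    stop("infeasible geometry: intron lengths exceed gene length range")
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              nReplicates = as.integer(nReplicates), strains = strains,
              intronCountProbs = intronCountProbs,
              geneLengthRange = geneLengthRange,
              intronLengthRange = intronLengthRange,
              gcTarget = gcTarget, libSizeMean = libSizeMean,
              nbDispersion = nbDispersion, deConfig = deConfig,
              apaConfig = apaConfig, motifConfig = motifConfig,
              transConfig = transConfig)
  # independent sub-streams so regenerating one output leaves the others
  set.seed(cfg$seed)
  cfg$subSeeds <- sample.int(.Machine$integer.max - 1L, 5L)
  class(cfg) <- "u1SimConfig"
  cfg
}

#' Sample sheet for a config
#' @param config a u1SimConfig
#' @return data.frame sample, strain, replicate, library_size
#' @export
sampleSheet <- function(config) {
  set.seed(config$subSeeds[5L])
  ss <- expand.grid(replicate = seq_len(config$nReplicates),
                    strain = config$strains, stringsAsFactors = FALSE)
  ss <- ss[, c("strain", "replicate")]
  ss$sample <- paste0(ss$strain, "_", ss$replicate)
  ss$library_size <- round(config$libSizeMean *
                             stats::runif(nrow(ss), 0.7, 1.3))
  ss[, c("sample", "strain", "replicate", "library_size")]
}

#' Build a synthetic genome and gene models
#'
#' Generates one random chromosome at the target GC content, places
#' non-overlapping genes on alternating strands with the configured
#' intron-count distribution, assigns two polyA sites to APA genes, and
#' plants 5'-splice-site-like U1 motifs around polyA sites according to
#' each gene's APA response class. Planted motifs and class labels are
#' recorded in the returned truth tables.
#'
#' @param config a u1SimConfig
#' @return list(genome = DNAStringSet, models = GeneModels,
#'   truth = list(genes, motifs))
#' @export
simulateGenome <- function(config) {
  set.seed(config$subSeeds[1L])
  n <- config$nGenes
  ic <- config$intronCountProbs
  ac <- config$apaConfig
  mo <- config$motifConfig
  gap <- 400L

  bin <- sample(names(ic), n, replace = TRUE, prob = ic)
  nIntrons <- integer(n)
  nIntrons[bin == "1-2"] <- sample(1:2, sum(bin == "1-2"), replace = TRUE)
  nIntrons[bin == ">=3"] <- sample(3:8, sum(bin == ">=3"), replace = TRUE)
  isApa <- stats::runif(n) < ac$fraction
  apaClass <- rep("none", n)
  apaClass[isApa] <- sample(names(ac$classProbs), sum(isApa),
                            replace = TRUE, prob = ac$classProbs)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                      chrom = "chrS", start = NA_real_, end = NA_real_,
                      strand = strand, utr3_start = NA_real_,
                      utr3_end = NA_real_, polya_proximal = NA_real_,
                      polya_distal = NA_real_, gc_fraction = NA_real_,
                      stringsAsFactors = FALSE)
  exonRows <- vector("list", n)
  truthGenes <- data.frame(gene_id = genes$gene_id, n_introns = nIntrons,
                           intron_bin = bin, apa_class = apaClass,
                           gene_length = NA_integer_,
                           mean_intron_length = NA_real_,
                           utr_length = NA_integer_,
                           prox_offset = NA_integer_,
                           stringsAsFactors = FALSE)
  motifRows <- list()

  pos <- 500L   # leading pad keeps planted motif windows on-chromosome
  for (i in seq_len(n)) {
    k <- nIntrons[i]
    utrLen <- if (isApa[i]) as.integer(ac$utrLength) else 300L
    exLens <- round(stats::runif(k + 1L, 150, 450))
    exLens[k + 1L] <- round(stats::runif(1, 150, 300)) + utrLen
    inLens <- if (k > 0L) {
      short <- stats::runif(k) < 0.6
      ifelse(short,
             round(stats::runif(k, config$intronLengthRange[1], 400)),
             round(stats::runif(k, 500, config$intronLengthRange[2])))
    } else integer(0)
    L <- sum(exLens) + sum(inLens)
    # transcript-space exon starts
    tpos <- 0L
    exT <- matrix(0, nrow = k + 1L, ncol = 2L)
    for (j in seq_len(k + 1L)) {
      exT[j, 1L] <- tpos
      exT[j, 2L] <- tpos + exLens[j]
      tpos <- exT[j, 2L] + if (j <= k) inLens[j] else 0L
    }
    gstart <- pos
    toGenomic <- function(t) if (strand[i] == "+") gstart + t
                             else gstart + L - t    # half-open flip
    if (strand[i] == "+") {
      exG <- cbind(gstart + exT[, 1L], gstart + exT[, 2L])
    } else {
      exG <- cbind(gstart + L - exT[, 2L], gstart + L - exT[, 1L])
    }
    exG <- exG[order(exG[, 1L]), , drop = FALSE]
    exonRows[[i]] <- data.frame(gene_id = genes$gene_id[i],
                                start = exG[, 1L], end = exG[, 2L])
    genes$start[i] <- gstart
    genes$end[i] <- gstart + L
    # 3'-UTR = transcript-final utrLen nt
    if (strand[i] == "+") {
      genes$utr3_start[i] <- gstart + L - utrLen
      genes$utr3_end[i] <- gstart + L
    } else {
      genes$utr3_start[i] <- gstart
      genes$utr3_end[i] <- gstart + utrLen
    }
    truthGenes$gene_length[i] <- L
    truthGenes$mean_intron_length[i] <- if (k > 0L) mean(inLens) else NA
    truthGenes$utr_length[i] <- utrLen
    if (isApa[i]) {
      proxOff <- round(stats::runif(1, ac$proximalFracRange[1],
                                    ac$proximalFracRange[2]) * utrLen)
      truthGenes$prox_offset[i] <- proxOff
      # transcript positions within UTR -> genomic
      tProx <- L - utrLen + proxOff
      tDist <- L - 1L
      if (strand[i] == "+") {
        genes$polya_proximal[i] <- gstart + tProx
        genes$polya_distal[i] <- gstart + tDist
      } else {
        genes$polya_proximal[i] <- gstart + L - 1L - tProx
        genes$polya_distal[i] <- gstart + L - 1L - tDist
      }
    }
    pos <- gstart + L + gap
  }

  totalLen <- pos
  p <- c(A = (1 - config$gcTarget) / 2, C = config$gcTarget / 2,
         G = config$gcTarget / 2, T = (1 - config$gcTarget) / 2)
  seqChars <- sample(names(p), totalLen, replace = TRUE, prob = p)

  # plant U1 motifs; sense-strand start position recorded
  consensus <- strsplit(mo$consensus, "")[[1]]
  m <- length(consensus)
  plant <- function(gi, site, siteType) {
    off <- sample(seq(-mo$plantOffset, mo$plantOffset - m), 1L)
    senseStart <- site + off
    if (genes$strand[gi] == "+") {
      seqChars[(senseStart + 1L):(senseStart + m)] <<- consensus
    } else {
      rc <- rev(chartr("ACGT", "TGCA", consensus))
      seqChars[(senseStart - m + 2L):(senseStart + 1L)] <<- rc
    }
    motifRows[[length(motifRows) + 1L]] <<-
      data.frame(gene_id = genes$gene_id[gi], site = siteType,
                 sense_start = senseStart, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (apaClass[i] == "distal") {
      plant(i, genes$polya_proximal[i], "proximal")
    } else if (apaClass[i] == "proximal") {
      plant(i, genes$polya_proximal[i], "proximal")
      plant(i, genes$polya_distal[i], "distal")
    }
  }

  genome <- Biostrings::DNAStringSet(paste(seqChars, collapse = ""))
  names(genome) <- "chrS"
  models <- GeneModels(genes, do.call(rbind, exonRows))
  models <- fillGcFraction(models, genome)
  motifs <- if (length(motifRows)) do.call(rbind, motifRows)
            else data.frame(gene_id = character(), site = character(),
                            sense_start = numeric())
  list(genome = genome, models = models,
       truth = list(genes = truthGenes, motifs = motifs))
}

#' Simulate gene-level counts
#'
#' Counts are NB(mean = baseline x 2^log2FC x library factor,
#' variance = mu + dispersion x mu^2); dispersion 0 gives Poisson draws.
#' Affected genes per knockout strain are drawn with the 1-2-intron
#' stratum oversampled among the down-regulated by the configured
#' multiplier.
#'
#' @param config a u1SimConfig
#' @param models GeneModels from \code{simulateGenome}
#' @param truth truth list from \code{simulateGenome}
#' @param sheet optional sample sheet (defaults to \code{sampleSheet(config)})
#' @return list(counts = U1CountSet, truth = truth with $de appended)
#' @export
simulateExpression <- function(config, models, truth,
                               sheet = sampleSheet(config)) {
  set.seed(config$subSeeds[2L])
  if (config$nReplicates < 2L)
    stop("at least 2 replicates per strain are required")
  n <- config$nGenes
  de <- config$deConfig
  gid <- geneIds(models)
  baseMean <- stats::rlnorm(n, log(150), 1)
  bin12 <- truth$genes$intron_bin == "1-2"
  koStrains <- setdiff(config$strains, config$strains[1L])
  lfc <- matrix(0, nrow = n, ncol = length(koStrains),
                dimnames = list(gid, koStrains))
  for (s in koStrains) {
    frac <- de$fractionAffected[[s]]
    if (is.null(frac) || is.na(frac)) frac <- 0
    nAff <- round(frac * n)
    if (nAff == 0L) next
    nDown <- round(de$downFraction * nAff)
    w <- ifelse(bin12, de$enrichMultiplier, 1)
    down <- sample(seq_len(n), nDown, prob = w)
    up <- sample(setdiff(seq_len(n), down), nAff - nDown)
    lfc[down, s] <- -stats::runif(nDown, de$lfcRange[1], de$lfcRange[2])
    lfc[up, s] <- stats::runif(nAff - nDown, de$lfcRange[1],
                               de$lfcRange[2])
  }
  libFactor <- sheet$library_size / mean(sheet$library_size)
  cnt <- matrix(0L, nrow = n, ncol = nrow(sheet),
                dimnames = list(gid, sheet$sample))
  for (j in seq_len(nrow(sheet))) {
    s <- sheet$strain[j]
    l2 <- if (s %in% koStrains) lfc[, s] else 0
    mu <- baseMean * 2^l2 * libFactor[j]
    cnt[, j] <- as.integer(if (config$nbDispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$nbDispersion)
    else stats::rpois(n, mu))
  }
  deTruth <- data.frame(gene_id = rep(gid, length(koStrains)),
                        strain = rep(koStrains, each = n),
                        true_log2fc = as.vector(lfc),
                        stringsAsFactors = FALSE)
  truth$de <- deTruth
  truth$baseMean <- stats::setNames(baseMean, gid)
  list(counts = U1CountSet(cnt, sheet), truth = truth)
}

#' Simulate per-base 3'-UTR coverage
#'
#' Each APA gene expresses a short isoform ending at the proximal site
#' and a long isoform spanning the full UTR; the long fraction is the
#' gene's true PDUI. Per-base depth is Poisson around
#' depth x (1 - PDUI) + depth x PDUI before the proximal site and
#' depth x PDUI after it. Knockout strains shift the PDUI of
#' motif-coupled genes by the configured amount: proximal-window-only
#' planting yields a distal shift on knockout, dual planting a proximal
#' shift.
#'
#' @inheritParams simulateExpression
#' @return list(tracks = per-sample list of CoverageTrack lists,
#'   truth = truth with $apa appended)
#' @export
simulateUtrCoverage <- function(config, models, truth,
                                sheet = sampleSheet(config)) {
  set.seed(config$subSeeds[3L])
  ac <- config$apaConfig
  g <- models@genes
  tg <- truth$genes
  apaIdx <- which(tg$apa_class != "none")
  ref <- config$strains[1L]
  koStrains <- setdiff(config$strains, ref)

  skip <- apaIdx[tg$utr_length[apaIdx] < ac$minUtr]
  if (length(skip)) {
    warning("skipping APA genes with UTR < ", ac$minUtr, " nt: ",
            paste(tg$gene_id[skip], collapse = ", "))
    apaIdx <- setdiff(apaIdx, skip)
  }

  apaRows <- list()
  pduiTab <- list()
  for (i in apaIdx) {
    cls <- tg$apa_class[i]
    p0 <- switch(cls,
                 proximal = stats::runif(1, ac$basePduiProximal[1],
                                         ac$basePduiProximal[2]),
                 distal = stats::runif(1, ac$basePduiDistal[1],
                                       ac$basePduiDistal[2]),
                 null = stats::runif(1, ac$basePduiNull[1],
                                     ac$basePduiNull[2]))
    pKO <- switch(cls,
                  proximal = max(0, p0 - ac$shift),
                  distal = min(1, p0 + ac$shift),
                  null = p0)
    pduiTab[[tg$gene_id[i]]] <- c(stats::setNames(p0, ref),
                                  stats::setNames(rep(pKO,
                                                      length(koStrains)),
                                                  koStrains))
    apaRows[[length(apaRows) + 1L]] <-
      data.frame(gene_id = tg$gene_id[i], apa_class = cls,
                 pdui_wt = p0, pdui_ko = pKO,
                 true_delta = pKO - p0, stringsAsFactors = FALSE)
  }

  tracks <- vector("list", nrow(sheet))
  names(tracks) <- sheet$sample
  for (j in seq_len(nrow(sheet))) {
    s <- sheet$strain[j]
    trs <- vector("list", length(apaIdx))
    names(trs) <- tg$gene_id[apaIdx]
    for (kk in seq_along(apaIdx)) {
      i <- apaIdx[kk]
      utrLen <- tg$utr_length[i]
      proxOff <- tg$prox_offset[i]
      p <- pduiTab[[tg$gene_id[i]]][[s]]
      muT <- c(rep(ac$depth, proxOff),
               rep(ac$depth * p, utrLen - proxOff))
      d <- stats::rpois(utrLen, muT)
      if (g$strand[i] == "-") d <- rev(d)   # genomic orientation
      trs[[kk]] <- CoverageTrack(tg$gene_id[i], g$chrom[i],
                                 g$utr3_start[i], g$utr3_end[i],
                                 g$strand[i], sheet$sample[j], s, d)
    }
    tracks[[j]] <- trs
  }
  truth$apa <- if (length(apaRows)) do.call(rbind, apaRows)
               else data.frame(gene_id = character())
  list(tracks = tracks, truth = truth)
}

#' Simulate trans-splicing junction tables
#'
#' The last \code{transConfig$nGenes} genes act as trans-spliced loci
#' (mod(mdg4)/lola analogs). Per sample, common-exon reads are Poisson
#' around the configured depth and isoform-specific junction reads are
#' multinomial around true usage x common depth. Affected knockout
#' strains get the first isoform's usage multiplied by
#' \code{usageMultiplier}.
#'
#' @inheritParams simulateExpression
#' @return list(junctions = data.frame, truth = truth with $trans)
#' @export
simulateJunctions <- function(config, models, truth,
                              sheet = sampleSheet(config)) {
  set.seed(config$subSeeds[4L])
  tc <- config$transConfig
  g <- models@genes
  stopifnot(tc$nGenes >= 1L, all(tc$nIsoforms >= 2L))
  idx <- seq(nrow(g) - tc$nGenes + 1L, nrow(g))
  rows <- list()
  transRows <- list()
  for (t in seq_along(idx)) {
    i <- idx[t]
    nIso <- tc$nIsoforms[min(t, length(tc$nIsoforms))]
    props <- rev(seq_len(nIso)) / sum(seq_len(nIso))
    baseUsage <- tc$specificRate * props
    donors <- g$start[i] + 100 * seq_len(nIso)
    acceptors <- donors + 50 + 10 * seq_len(nIso)
    for (s in config$strains) {
      u <- baseUsage
      if (s %in% tc$affectedStrains) u[1L] <- u[1L] * tc$usageMultiplier
      transRows[[length(transRows) + 1L]] <-
        data.frame(gene_id = g$gene_id[i], strain = s,
                   isoform = paste0("iso", seq_len(nIso)),
                   true_usage = u, true_prop = u / sum(u),
                   stringsAsFactors = FALSE)
      for (j in which(sheet$strain == s)) {
        common <- stats::rpois(1L, tc$commonDepth)
        total <- stats::rpois(1L, sum(u) * common)
        J <- as.vector(stats::rmultinom(1L, total, u / sum(u)))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sheet$sample[j], gene_id = g$gene_id[i],
          chrom = g$chrom[i],
          donor = c(donors, g$start[i] + 10),
          acceptor = c(acceptors, g$start[i] + 70),
          strand = g$strand[i],
          count = c(J, common),
          label = c(paste0("isoform-specific:iso", seq_len(nIso)),
                    "common"),
          stringsAsFactors = FALSE)
      }
    }
  }
  truth$trans <- do.call(rbind, transRows)
  list(junctions = do.call(rbind, rows), truth = truth)
}

#' Run all four generators under one config
#'
#' @param config a u1SimConfig
#' @return list(genome, models, sheet, counts, tracks, junctions, truth)
#' @export
simulateAll <- function(config) {
  sheet <- sampleSheet(config)
  gen <- simulateGenome(config)
  expr <- simulateExpression(config, gen$models, gen$truth, sheet)
  cov <- simulateUtrCoverage(config, gen$models, expr$truth, sheet)
  jun <- simulateJunctions(config, gen$models, cov$truth, sheet)
  list(genome = gen$genome, models = gen$models, sheet = sheet,
       counts = expr$counts, tracks = cov$tracks,
       junctions = jun$junctions, truth = jun$truth)
}

#' Write a full simulation to disk in standard formats
#'
#' Emits genome.fa, annotation.gtf, polya.bed, counts.tsv, samples.tsv,
#' one bedGraph per sample under coverage/, junctions.tsv, and truth
#' tables under truth/. Output is byte-deterministic given the config
#' seed.
#'
#' @param sim result of \code{simulateAll}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeAnnotation(sim$models, file.path(dir, "annotation.gtf"),
                  file.path(dir, "polya.bed"))
  writeCounts(sim$counts, file.path(dir, "counts.tsv"),
              file.path(dir, "samples.tsv"))
  covDir <- file.path(dir, "coverage")
  dir.create(covDir, showWarnings = FALSE)
  for (s in names(sim$tracks))
    writeCoverage(sim$tracks[[s]], file.path(covDir, paste0(s, ".bedGraph")))
  writeJunctions(sim$junctions, file.path(dir, "junctions.tsv"))
  truthDir <- file.path(dir, "truth")
  dir.create(truthDir, showWarnings = FALSE)
  for (nm in c("genes", "motifs", "de", "apa", "trans")) {
    if (!is.null(sim$truth[[nm]]))
      utils::write.table(sim$truth[[nm]],
                         file.path(truthDir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
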