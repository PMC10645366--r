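#' Per-sample delta-Ct
#'
#' Delta-Ct of a target amplicon against a reference gene:
#' Ct_target - Ct_reference per sample. Records with Ct >= 40 cycles are
#' rejected with a diagnostic.
#'
#' @param ctTable data.frame sample, target, ct
#' @param target target amplicon identifier
#' @param reference reference amplicon (default "gapdh")
#' @return data.frame sample, delta_ct
#' @export
deltaCt <- function(ctTable, target, reference = "gapdh") {
  bad <- ctTable$ct >= 40
  if (any(bad)) {
    warning(sum(bad), " Ct record(s) >= 40 cycles rejected")
    ctTable <- ctTable[!bad, , drop = FALSE]
  }
  tt <- ctTable[ctTable$target == target, , drop = FALSE]
  rr <- ctTable[ctTable$target == reference, , drop = FALSE]
  common <- intersect(tt$sample, rr$sample)
  if (!length(common))
    stop("no sample has both target and reference Ct values")
  data.frame(sample = common,
             delta_ct = tt$ct[match(common, tt$sample)] -
               rr$ct[match(common, rr$sample)],
             stringsAsFactors = FALSE)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Delta-delta-Ct is the per-sample delta-Ct minus the mean wild-type
#' delta-Ct; fold change is 2^(-delta-delta-Ct). A two-sided Welch
#' t-test compares each non-reference strain's delta-Ct replicates with
#' the wild type's.
#'
#' @param deltaCts data.frame sample, delta_ct, strain
#' @param wtStrain wild-type strain label (default "WT")
#' @return list(perSample = data.frame sample, strain, delta_ct,
#'   delta_delta_ct, fold; tests = data.frame strain, mean_fold, p)
#' @export
relativeExpression <- function(deltaCts, wtStrain = "WT") {
  stopifnot(all(c("sample", "delta_ct", "strain") %in% names(deltaCts)))
  wt <- deltaCts$delta_ct[deltaCts$strain == wtStrain]
  if (length(wt) < 1L) stop("no wild-type delta-Ct values")
  ddct <- deltaCts$delta_ct - mean(wt)
  perSample <- data.frame(sample = deltaCts$sample,
                          strain = deltaCts$strain,
                          delta_ct = deltaCts$delta_ct,
                          delta_delta_ct = ddct,
                          fold = 2^(-ddct), stringsAsFactors = FALSE)
  others <- setdiff(unique(deltaCts$strain), wtStrain)
  tests <- do.call(rbind, lapply(others, function(s) {
    x <- deltaCts$delta_ct[deltaCts$strain == s]
    p <- if (length(x) >= 2L && length(wt) >= 2L) .welchP(x, wt)
         else NA_real_
    data.frame(strain = s,
               mean_fold = mean(2^(-(x - mean(wt)))),
               p = p, stringsAsFactors = FALSE)
  }))
  list(perSample = perSample, tests = tests)
}

#' Pipeline configuration
#'
#' Bundles a simulation config (simulate mode) or input paths with the
#' published screen thresholds.
#'
#' @param sim a u1SimConfig for simulate mode (NULL to run from paths)
#' @param paths named list of input paths (gtf, polyaBed, genome,
#'   counts, samples, coverageDir, junctions) for non-simulate mode
#' @param fcThreshold,fdrDE DEG screen thresholds
#' @param deltaPdui,fdrApa APA screen thresholds
#' @param window U1-site half-window (nt)
#' @param motif list(consensus, maxMismatch)
#' @return object of class u1PipelineConfig
#' @export
pipelineConfig <- function(sim = NULL, paths = NULL, fcThreshold = 2,
                           fdrDE = 0.05, deltaPdui = 0.25,
                           fdrApa = 0.05, window = 200L,
                           motif = list(consensus = "CAGGTAAGT",
                                        maxMismatch = 1L)) {
  stopifnot(fcThreshold > 0, fdrDE > 0, deltaPdui > 0, fdrApa > 0,
            window > 0)
  if (is.null(sim)) {
    if (is.null(paths)) stop("either sim or paths must be given")
    missing <- !vapply(paths, file.exists, logical(1))
    if (any(missing))
      stop("missing inputs: ", paste(names(paths)[missing],
                                     collapse = ", "))
  }
  structure(list(sim = sim, paths = paths, fcThreshold = fcThreshold,
                 fdrDE = fdrDE, deltaPdui = deltaPdui, fdrApa = fdrApa,
                 window = as.integer(window), motif = motif),
            class = "u1PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) inputs, then run differential expression and the
#' DEG screen per strain, the overlap partition, feature enrichment of
#' the down- and up-regulated sets, PDUI estimation and the APA screen,
#' U1-site window counts with the proximal/distal ratio comparison,
#' trans-splicing usage comparisons, and, in simulate mode, truth
#' recovery metrics. Deterministic given the simulation seed.
#'
#' @param config a u1PipelineConfig
#' @param outDir optional directory; when given, TSV tables and a
#'   report.json are written
#' @return the report (a list of data.frames and count summaries),
#'   invisibly when outDir is given
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "u1PipelineConfig"))
  if (!is.null(config$sim)) {
    sim <- simulateAll(config$sim)
    genome <- sim$genome; models <- sim$models; cs <- sim$counts
    sheet <- sim$sheet; tracks <- sim$tracks
    junctions <- sim$junctions; truth <- sim$truth
  } else {
    p <- config$paths
    genome <- Biostrings::readDNAStringSet(p$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    models <- loadAnnotation(p$gtf, p$polyaBed, genome)
    cs <- readCounts(p$counts, p$samples)
    sheet <- as.data.frame(SummarizedExperiment::colData(cs))
    tracks <- lapply(stats::setNames(sheet$sample, sheet$sample),
                     function(s) loadCoverage(
                       file.path(p$coverageDir, paste0(s, ".bedGraph")),
                       models, sample = s,
                       strain = sheet$strain[sheet$sample == s]))
    junctions <- readJunctions(p$junctions)
    truth <- NULL
  }
  ref <- unique(sheet$strain)[1L]
  koStrains <- setdiff(unique(sheet$strain), ref)

  # --- differential expression ---
  deRes <- lapply(stats::setNames(koStrains, koStrains),
                  function(s) testDE(cs, s, reference = ref))
  degSets <- lapply(deRes, screenDEGs, fcThreshold = config$fcThreshold,
                    fdrThreshold = config$fdrDE)
  degCounts <- data.frame(
    strain = koStrains,
    n_down = vapply(degSets, function(x) length(x$down), integer(1)),
    n_up = vapply(degSets, function(x) length(x$up), integer(1)),
    n_tested = vapply(deRes, function(x) sum(x$tested), integer(1)),
    row.names = NULL)
  overlapDown <- overlapSets(lapply(degSets, `[[`, "down"))
  overlapUp <- overlapSets(lapply(degSets, `[[`, "up"))

  # --- feature enrichment (background: transcribed genes) ---
  strata <- stratifyGenes(models)
  background <- deRes[[1L]]$gene_id[deRes[[1L]]$tested]
  enrich <- list()
  for (s in koStrains) {
    for (dirn in c("down", "up")) {
      set <- intersect(degSets[[s]][[dirn]], background)
      for (f in c("intron_bin", "length_bin", "intron_length_bin",
                  "gc_bin")) {
        et <- enrichmentTest(set, background, strata, f)
        et$strain <- s; et$direction <- dirn
        enrich[[length(enrich) + 1L]] <- et
      }
    }
  }
  enrich <- do.call(rbind, enrich)

  # --- APA ---
  estimates <- estimatePduiSet(tracks)
  apaEvents <- lapply(stats::setNames(koStrains, koStrains), function(s)
    callApaEvents(estimates, s, reference = ref,
                  deltaThreshold = config$deltaPdui,
                  fdrThreshold = config$fdrApa))
  apaCounts <- data.frame(
    strain = koStrains,
    n_distal = vapply(apaEvents, function(x)
      if (is.null(x)) 0L else sum(x$direction == "distal"), integer(1)),
    n_proximal = vapply(apaEvents, function(x)
      if (is.null(x)) 0L else sum(x$direction == "proximal"), integer(1)),
    n_ns = vapply(apaEvents, function(x)
      if (is.null(x)) 0L else sum(x$direction == "ns"), integer(1)),
    row.names = NULL)

  # U1 windows + ratio comparison on the union of significant events
  allEv <- do.call(rbind, lapply(koStrains, function(s) {
    ev <- apaEvents[[s]]
    if (is.null(ev)) return(NULL)
    ev <- ev[ev$direction != "ns", , drop = FALSE]
    if (nrow(ev)) ev$strain <- s
    ev
  }))
  siteRatios <- NULL; windowCounts <- NULL
  if (!is.null(allEv) && nrow(allEv)) {
    # one direction per gene: keep the largest |delta|
    allEv <- allEv[order(-abs(allEv$delta_pdui)), , drop = FALSE]
    allEv <- allEv[!duplicated(allEv$gene_id), , drop = FALSE]
    windowCounts <- do.call(rbind, lapply(allEv$gene_id, function(g)
      windowSiteCounts(g, genome, models, window = config$window,
                       consensus = config$motif$consensus,
                       maxMismatch = config$motif$maxMismatch)))
    regions <- vapply(allEv$gene_id, function(g)
      classifyEventRegion(g, models)$region_class, character(1))
    allEv$region_class <- regions
    siteRatios <- compareSiteRatios(allEv, windowCounts)
  }

  # --- trans-splicing ---
  libSizes <- stats::setNames(sheet$library_size, sheet$sample)
  usage <- quantifyIsoformUsage(junctions, libSizes)
  usage <- merge(usage, sheet[, c("sample", "strain")], by = "sample")
  transCmp <- do.call(rbind, lapply(koStrains, function(s) {
    cmp <- compareUsage(usage, s, reference = ref)
    if (!is.null(cmp)) cmp$strain <- s
    cmp
  }))

  report <- list(degCounts = degCounts, overlapDown = overlapDown,
                 overlapUp = overlapUp, enrichment = enrich,
                 apaCounts = apaCounts, apaEvents = allEv,
                 windowCounts = windowCounts, siteRatios = siteRatios,
                 transComparison = transCmp)

  if (!is.null(config$sim)) {
    report$recovery <- .recoveryMetrics(config, deRes, degSets,
                                        estimates, apaEvents, truth,
                                        koStrains)
  }
  if (!is.null(outDir)) .writeReport(report, outDir)
  if (is.null(outDir)) report else invisible(report)
}

# Truth-vs-estimate recovery metrics for simulate mode.
.recoveryMetrics <- function(config, deRes, degSets, estimates,
                             apaEvents, truth, koStrains) {
  out <- list()
  # DE: fraction of truly affected genes passing the screen (strongest
  # strain) among genes with detectable effects
  de <- truth$de
  sens <- vapply(koStrains, function(s) {
    tl <- de[de$strain == s & de$true_log2fc != 0, ]
    if (!nrow(tl)) return(NA_real_)
    called <- c(degSets[[s]]$down, degSets[[s]]$up)
    mean(tl$gene_id %in% called)
  }, numeric(1))
  out$deSensitivity <- data.frame(strain = koStrains,
                                  sensitivity = unname(sens))
  # APA: per-gene-and-sample PDUI error and direction accuracy
  ta <- truth$apa
  if (!is.null(ta) && nrow(ta)) {
    wt <- estimates[estimates$strain == "WT", ]
    errWt <- abs(wt$pdui - ta$pdui_wt[match(wt$gene_id, ta$gene_id)])
    ko <- estimates[estimates$strain != "WT", ]
    errKo <- abs(ko$pdui - ta$pdui_ko[match(ko$gene_id, ta$gene_id)])
    out$pduiRecovery <- mean(c(errWt, errKo) <= 0.05)
    s <- koStrains[1L]
    ev <- apaEvents[[s]]
    if (!is.null(ev)) {
      m <- merge(ev, ta, by = "gene_id")
      shifted <- m[m$apa_class %in% c("proximal", "distal"), ]
      nullg <- m[m$apa_class == "null", ]
      out$directionAccuracy <-
        if (nrow(shifted)) mean(shifted$direction == shifted$apa_class)
        else NA_real_
      out$nullSpecificity <-
        if (nrow(nullg)) mean(nullg$direction == "ns") else NA_real_
    }
  }
  out
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, nm) if (!is.null(x) && is.data.frame(x))
    utils::write.table(x, file.path(outDir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$degCounts, "deg_counts")
  wt(report$overlapDown$membership, "overlap_down")
  wt(report$overlapUp$membership, "overlap_up")
  wt(report$enrichment, "enrichment")
  wt(report$apaCounts, "apa_counts")
  wt(report$apaEvents, "apa_events")
  wt(report$windowCounts, "u1_window_counts")
  wt(report$siteRatios, "site_ratios")
  wt(report$transComparison, "trans_splicing")
  json <- list(degCounts = report$degCounts,
               apaCounts = report$apaCounts,
               siteRatios = report$siteRatios,
               recovery = report$recovery)
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(NULL)
}
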