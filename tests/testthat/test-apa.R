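mkTrack <- function(depth, strand = "+", gene = "g1", sample = "WT_1",
                    strain = "WT")
  CoverageTrack(gene, "chr1", 0, length(depth), strand, sample, strain,
                depth)

test_that("change-point PDUI handles flat, truncated and two-level tracks", {
  flat <- estimatePdui(mkTrack(rep(8, 200)))
  expect_equal(flat$pdui, 1)
  expect_true(flat$degenerate)

  cut0 <- estimatePdui(mkTrack(c(rep(10, 100), rep(0, 100))))
  expect_equal(cut0$pdui, 0)
  expect_equal(cut0$breakpoint, 100)

  two <- estimatePdui(mkTrack(c(rep(10, 100), rep(4, 100))))
  expect_equal(two$breakpoint, 100)
  expect_equal(two$pdui, 0.4)

  # minus-strand track is reversed into transcript orientation
  neg <- estimatePdui(mkTrack(rev(c(rep(10, 100), rep(4, 100))),
                              strand = "-"))
  expect_equal(neg$breakpoint, 100)
  expect_equal(neg$pdui, 0.4)

  expect_warning(expect_null(estimatePdui(mkTrack(rep(0, 200)))),
                 "all-zero")
  expect_warning(expect_null(estimatePdui(mkTrack(rep(5, 50)))),
                 "shorter")
  expect_warning(expect_null(estimatePdui(mkTrack(rep(1, 200)))),
                 "mean depth")
})

test_that("the fit matches an exhaustive RSS oracle and scales invariantly", {
  set.seed(41)
  for (k in 1:20) {
    b <- sample(30:170, 1)
    hi <- runif(1, 10, 40)
    lo <- hi * runif(1, 0, 0.9)
    d <- c(rpois(b, hi), rpois(200 - b, lo))
    if (mean(d) < 5 || all(d == 0)) next
    est <- estimatePdui(mkTrack(d))
    want <- rssOracle(d)
    expect_equal(est$breakpoint, want$breakpoint)
    expect_equal(est$mean_before, want$mean_before)
    expect_equal(est$mean_after, want$mean_after)
    # uniform depth scaling leaves pdui and breakpoint unchanged
    sc <- estimatePdui(mkTrack(3.7 * d))
    expect_equal(sc$breakpoint, est$breakpoint)
    expect_equal(sc$pdui, est$pdui)
  }
})

test_that("APA event calls obey the delta and FDR screen", {
  mkEst <- function(gene, pw, pk) rbind(
    data.frame(gene_id = gene, sample = paste0("WT_", seq_along(pw)),
               strain = "WT", breakpoint = 100, pdui = pw,
               mean_before = 30, mean_after = 15, degenerate = FALSE),
    data.frame(gene_id = gene, sample = paste0("KO_", seq_along(pk)),
               strain = "KO", breakpoint = 100, pdui = pk,
               mean_before = 30, mean_after = 15, degenerate = FALSE))

  flat <- callApaEvents(mkEst("g1", c(0.8, 0.8), c(0.8, 0.8)), "KO")
  expect_equal(flat$delta_pdui, 0)
  expect_equal(flat$direction, "ns")

  big <- callApaEvents(mkEst("g2", c(0.90, 0.88), c(0.30, 0.32)), "KO")
  expect_equal(big$delta_pdui, mean(c(0.30, 0.32)) - mean(c(0.90, 0.88)))
  want <- t.test(c(0.30, 0.32), c(0.90, 0.88))$p.value
  expect_equal(big$p, want)
  expect_equal(big$direction,
               if (big$fdr < 0.05) "proximal" else "ns")

  # |delta| below 0.25 is never significant, whatever the p-value
  sub <- callApaEvents(mkEst("g3", c(0.600, 0.602), c(0.400, 0.402)),
                       "KO")
  expect_lt(sub$p, 0.001)
  expect_equal(sub$direction, "ns")

  # fewer than 2 replicates per group: gene skipped
  one <- rbind(mkEst("g4", c(0.8, 0.8), c(0.4, 0.4)),
               data.frame(gene_id = "g5", sample = "WT_1", strain = "WT",
                          breakpoint = 100, pdui = 0.5, mean_before = 30,
                          mean_after = 15, degenerate = FALSE))
  expect_message(got <- callApaEvents(one, "KO"), "skipped")
  expect_false("g5" %in% got$gene_id)
})

test_that("event regions classify by polyA containment in the 3'-UTR", {
  gm <- tinyModels()
  expect_equal(classifyEventRegion("gA", gm)$region_class,
               "three_prime_utr")
  # move gA's proximal site into the intron [100,200): slot mutation
  # bypasses construction-time validation, as a caller with a stale
  # annotation would
  gm3 <- gm
  gm3@genes$polya_proximal[1] <- 150
  expect_equal(classifyEventRegion("gA", gm3)$region_class,
               "terminal_exon_intron")
  # missing UTR: flagged terminal
  g3 <- tinyModels()@genes
  g3$utr3_start[2] <- NA; g3$utr3_end[2] <- NA
  g3$polya_proximal[2] <- NA; g3$polya_distal[2] <- NA
  gm4 <- GeneModels(g3, tinyModels()@exons)
  cls <- classifyEventRegion("gB", gm4)
  expect_equal(cls$region_class, "terminal_exon_intron")
  expect_true(cls$flagged)

  # randomized placements against a direct containment oracle
  set.seed(43)
  base <- tinyModels()
  for (k in 1:20) {
    pp <- sample(0:298, 1); pd <- pp + 1
    gmk <- base
    gmk@genes$polya_proximal[1] <- pp
    gmk@genes$polya_distal[1] <- pd
    want <- if (pp >= 200 && pp < 300 && pd >= 200 && pd < 300)
      "three_prime_utr" else "terminal_exon_intron"
    expect_equal(classifyEventRegion("gA", gmk)$region_class, want)
  }
})

test_that("motif scanning matches a naive scan and respects the GT core", {
  hit1 <- scanU1Sites(paste0(strrep("T", 20), "CAGGTAAGT",
                             strrep("T", 20)))
  expect_equal(nrow(hit1), 1L)
  expect_equal(hit1$position, 20L)
  expect_equal(hit1$mismatches, 0L)

  expect_equal(nrow(scanU1Sites(strrep("A", 500))), 0L)
  expect_equal(nrow(scanU1Sites("CAGG")), 0L)   # shorter than motif

  # GT is invariant: a GT mutation kills the hit even with 0 other
  # mismatches, while 1 non-GT mismatch survives
  expect_equal(nrow(scanU1Sites("CACGTAAGT")), 1L)
  expect_equal(nrow(scanU1Sites("CAGCTAAGT")), 0L)

  set.seed(44)
  for (k in 1:10) {
    s <- randomSeq(1000)
    got <- scanU1Sites(s)
    want <- naiveScan(s)
    expect_equal(got$position, want$position)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("window counts localize hits to the +/-200 nt site windows", {
  # plus strand: motif 50 nt upstream of the proximal site only
  pad <- strrep("A", 2000)
  g <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 2000,
                  strand = "+", utr3_start = 500, utr3_end = 1900,
                  polya_proximal = 1000, polya_distal = 1850,
                  gc_fraction = NA_real_)
  ex <- data.frame(gene_id = "g1", start = 0, end = 2000)
  gm <- GeneModels(g, ex)
  seqc <- strsplit(pad, "")[[1]]
  seqc[951:959] <- strsplit("CAGGTAAGT", "")[[1]]   # starts at 950
  genome <- Biostrings::DNAStringSet(c(c = paste(seqc, collapse = "")))
  wc <- windowSiteCounts("g1", genome, gm)
  expect_equal(wc$n_proximal_window, 1L)
  expect_equal(wc$n_distal_window, 0L)

  # 250 nt away from both sites: counted in neither window
  seqc <- strsplit(pad, "")[[1]]
  seqc[1251:1259] <- strsplit("CAGGTAAGT", "")[[1]]  # 1000+250, 1850-600
  genome2 <- Biostrings::DNAStringSet(c(c = paste(seqc, collapse = "")))
  wc2 <- windowSiteCounts("g1", genome2, gm)
  expect_equal(wc2$n_proximal_window, 0L)
  expect_equal(wc2$n_distal_window, 0L)

  # sites closer than 2 windows: one hit counted in both (documented)
  g3 <- g; g3$polya_proximal <- 1000; g3$polya_distal <- 1300
  gm3 <- GeneModels(g3, ex)
  seqc <- strsplit(pad, "")[[1]]
  seqc[1151:1159] <- strsplit("CAGGTAAGT", "")[[1]]  # 1150: in both
  genome3 <- Biostrings::DNAStringSet(c(c = paste(seqc, collapse = "")))
  wc3 <- windowSiteCounts("g1", genome3, gm3)
  expect_equal(wc3$n_proximal_window, 1L)
  expect_equal(wc3$n_distal_window, 1L)

  # random plantings vs a brute-force whole-chromosome scan + interval
  # membership, both strands
  set.seed(45)
  for (strand in c("+", "-")) {
    for (k in 1:8) {
      s <- randomSeq(3000)
      gr <- data.frame(gene_id = "gR", chrom = "c", start = 0, end = 3000,
                       strand = strand, utr3_start = 800, utr3_end = 2600,
                       polya_proximal = if (strand == "+") 1500 else 2300,
                       polya_distal = if (strand == "+") 2500 else 900,
                       gc_fraction = NA_real_)
      gmr <- GeneModels(gr, data.frame(gene_id = "gR", start = 0,
                                       end = 3000))
      genomeR <- Biostrings::DNAStringSet(c(c = s))
      wcR <- windowSiteCounts("gR", genomeR, gmr)
      sense <- if (strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      hits <- naiveScan(sense)
      senseStart <- if (strand == "+") hits$position
                    else 3000 - 1 - hits$position
      inWin <- function(site) sum(senseStart >= site - 200 &
                                    senseStart <= site + 200)
      expect_equal(wcR$n_proximal_window, inWin(gr$polya_proximal))
      expect_equal(wcR$n_distal_window, inWin(gr$polya_distal))
    }
  }
})

test_that("site-ratio comparison reports balanced and skewed groups", {
  ev <- data.frame(gene_id = sprintf("g%02d", 1:24),
                   direction = rep(c("proximal", "distal"), each = 12))
  wc <- data.frame(gene_id = ev$gene_id,
                   n_proximal_window = c(rep(2, 12), rep(1, 12)),
                   n_distal_window = c(rep(2, 12), rep(0, 12)))
  sr <- compareSiteRatios(ev, wc)
  prox <- sr[sr$group == "proximal-activated", ]
  dist <- sr[sr$group == "distal-activated", ]
  expect_equal(prox$ratio, 1)
  expect_equal(prox$p, 1)        # all paired differences zero
  expect_gt(dist$ratio, 1)
  expect_lt(dist$p, 0.05)
  # small groups are flagged low-n without a p-value
  sr2 <- compareSiteRatios(ev[1:3, ], wc[1:3, ])
  expect_true(sr2$low_n[sr2$group == "proximal-activated"])
  expect_true(is.na(sr2$p[sr2$group == "proximal-activated"]))
})

test_that("distal/common ratio follows the WT-normalized formula", {
  expect_equal(distalCommonRatio(20, 100, 20, 100), 1)
  expect_equal(distalCommonRatio(10, 100, 20, 100), 0.5)
  set.seed(46)
  for (k in 1:20) {
    q <- runif(4, 1, 100)
    expect_equal(distalCommonRatio(q[1], q[2], q[3], q[4]),
                 (q[1] / q[2]) / (q[3] / q[4]))
  }
  expect_warning(r0 <- distalCommonRatio(10, 0, 20, 100), "zero")
  expect_true(is.na(r0))
})
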