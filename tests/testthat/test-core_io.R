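test_that("introns are exactly the inter-exon gaps", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0, end = 300,
                      strand = "+", utr3_start = NA_real_,
                      utr3_end = NA_real_, polya_proximal = NA_real_,
                      polya_distal = NA_real_, gc_fraction = NA_real_)
  exons <- data.frame(gene_id = "g1", start = c(0, 200), end = c(100, 300))
  gm <- GeneModels(genes, exons)
  expect_equal(introns(gm),
               data.frame(gene_id = "g1", start = 100, end = 200))
})

test_that("intron counts match a brute-force gap-scan oracle on random models", {
  set.seed(42)
  cfg <- simConfig(seed = 101, nGenes = 50)
  gen <- simulateGenome(cfg)
  ints <- introns(gen$models)
  got <- table(factor(ints$gene_id, levels = geneIds(gen$models)))
  for (gid in geneIds(gen$models)) {
    ex <- gen$models@exons[gen$models@exons$gene_id == gid, ]
    expect_equal(unname(got[[gid]]), naiveIntronCount(ex), info = gid)
  }
})

test_that("annotation writes and re-reads to identical models", {
  cfg <- simConfig(seed = 77, nGenes = 25)
  gen <- simulateGenome(cfg)
  gtf <- tempfile(fileext = ".gtf"); bed <- tempfile(fileext = ".bed")
  writeAnnotation(gen$models, gtf, bed)
  m2 <- loadAnnotation(gtf, bed, gen$genome)
  g1 <- gen$models@genes
  g2 <- m2@genes[match(g1$gene_id, m2@genes$gene_id), ]
  rownames(g2) <- NULL
  expect_equal(g1, g2)
  e1 <- gen$models@exons[order(gen$models@exons$gene_id,
                               gen$models@exons$start), ]
  e2 <- m2@exons[order(m2@exons$gene_id, m2@exons$start), ]
  expect_equal(e1$start, e2$start)
  expect_equal(e1$end, e2$end)
})

test_that("overlapping exons reject the gene; stray polyA is an error", {
  dir <- tempfile(); dir.create(dir)
  gtf <- file.path(dir, "a.gtf"); bed <- file.path(dir, "a.bed")
  att <- function(g) sprintf('gene_id "%s"; transcript_id "%s";', g, g)
  row <- function(type, s1, e1, g)   # 1-based inclusive GTF coordinates
    sprintf("chr1\ttest\t%s\t%d\t%d\t.\t+\t.\t%s", type, s1, e1, att(g))
  writeLines(c(row("gene", 1, 300, "ok"),
               row("exon", 1, 100, "ok"), row("exon", 201, 300, "ok"),
               row("three_prime_utr", 201, 300, "ok"),
               row("gene", 501, 900, "bad"),
               row("exon", 501, 650, "bad"), row("exon", 601, 900, "bad")),
             gtf)
  writeLines(c("chr1\t240\t241\tok|proximal\t0\t+",
               "chr1\t290\t291\tok|distal\t0\t+"), bed)
  expect_warning(m <- loadAnnotation(gtf, bed), "overlapping exons")
  expect_false("bad" %in% geneIds(m))
  expect_true("ok" %in% geneIds(m))
  expect_equal(m@genes$polya_proximal[m@genes$gene_id == "ok"], 240)

  # polyA outside the UTR is a validation error naming the gene
  bed2 <- file.path(dir, "b.bed")
  writeLines(c("chr1\t150\t151\tok|proximal\t0\t+",
               "chr1\t290\t291\tok|distal\t0\t+"), bed2)
  expect_error(suppressWarnings(loadAnnotation(gtf, bed2)), "ok")
})

test_that("bedGraph coverage expands per base, zero-fills, adds, and rejects overlap", {
  gm <- tinyModels()
  bg <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t200\t300\t5", bg)
  tr <- loadCoverage(bg, gm, sample = "s1")
  expect_equal(tr$gA@depth, rep(5, 100))
  expect_equal(tr$gB@depth, rep(0, 150))   # absent chromosome region

  writeLines(character(0), bg)
  tr0 <- loadCoverage(bg, gm)
  expect_true(all(tr0$gA@depth == 0) && all(tr0$gB@depth == 0))

  # random disjoint intervals vs per-base oracle; additivity
  set.seed(5)
  starts <- sort(sample(seq(200, 290, by = 10), 5))
  iv <- data.frame(start = starts, end = starts + sample(3:9, 5, TRUE),
                   score = sample(1:20, 5))
  b1 <- tempfile(); b2 <- tempfile(); b12 <- tempfile()
  wl <- function(df, f) writeLines(
    sprintf("chr1\t%d\t%d\t%d", df$start, df$end, df$score), f)
  wl(iv[1:2, ], b1); wl(iv[3:5, ], b2); wl(iv, b12)
  d1 <- loadCoverage(b1, gm)$gA@depth
  d2 <- loadCoverage(b2, gm)$gA@depth
  d12 <- loadCoverage(b12, gm)$gA@depth
  expect_equal(d12, naiveCoverage(iv, 200, 300))
  expect_equal(d1 + d2, d12)

  writeLines(c("chr1\t200\t250\t2", "chr1\t240\t260\t3"), bg)
  expect_error(loadCoverage(bg, gm), "overlapping")
  writeLines("chr1\t200\t210\t1", bg)
  expect_error(loadCoverage(bg, gm, knownChroms = "chr9"),
               "unknown chromosome")
})

test_that("gcFraction matches a direct base tally", {
  gm <- tinyModels()
  gc <- Biostrings::DNAStringSet(c(chr1 = paste(rep("GC", 800),
                                                collapse = "")))
  expect_equal(unname(gcFraction(gc, gm)), c(1, 1))
  at <- Biostrings::DNAStringSet(c(chr1 = paste(rep("AT", 800),
                                                collapse = "")))
  expect_equal(unname(gcFraction(at, gm)), c(0, 0))
  set.seed(9)
  s <- randomSeq(1600)
  rnd <- Biostrings::DNAStringSet(c(chr1 = s))
  chars <- strsplit(s, "")[[1]]
  want <- mean(chars[1:300] %in% c("G", "C"))
  expect_equal(unname(gcFraction(rnd, gm))[1], want)
  short <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_error(gcFraction(short, gm), "shorter")
})

test_that("the U1 locus registry matches the five fly copies", {
  reg <- u1Registry()
  expect_equal(nrow(reg), 5L)
  expect_setequal(reg$name, c("21D", "82Eb", "95Ca", "95Cb", "95Cc"))
  expect_true(is.na(reg$variant_position[reg$name == "21D"]))
  expect_true(is.na(reg$variant_position[reg$name == "95Ca"]))
  expect_true(is.na(reg$variant_position[reg$name == "95Cb"]))
  expect_equal(reg$variant_position[reg$name == "82Eb"], 134L)
  expect_equal(reg$ref_base[reg$name == "82Eb"], "G")
  expect_equal(reg$alt_base[reg$name == "82Eb"], "U")
  expect_equal(reg$variant_position[reg$name == "95Cc"], 123L)
  expect_equal(reg$ref_base[reg$name == "95Cc"], "U")
  expect_equal(reg$alt_base[reg$name == "95Cc"], "C")
  expect_true(all(is.na(reg$variant_position) |
                    reg$variant_position <= 164L))
})

test_that("count and Ct tables round-trip; hot Ct records are rejected", {
  cfg <- simConfig(seed = 3, nGenes = 20)
  sim <- simulateAll(cfg)
  d <- tempfile(); dir.create(d)
  writeCounts(sim$counts, file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  cs2 <- readCounts(file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  expect_identical(counts(sim$counts), counts(cs2))
  expect_equal(strains(sim$counts), strains(cs2))

  ct <- data.frame(sample = c("a", "a", "b"), target = "gfp",
                   ct = c(25, 41, 30))
  f <- file.path(d, "ct.tsv")
  writeCtTable(ct, f)
  expect_warning(got <- readCtTable(f), "rejected")
  expect_equal(nrow(got), 2L)
  expect_true(all(got$ct < 40))
})

test_that("GeneModels validity enforces strand-aware polyA ordering", {
  g <- tinyModels()@genes
  e <- tinyModels()@exons
  bad <- g
  bad$polya_proximal[1] <- 290; bad$polya_distal[1] <- 240  # + strand flip
  expect_error(GeneModels(bad, e), "ordering")
  bad2 <- g
  bad2$polya_proximal[2] <- 1005; bad2$polya_distal[2] <- 1120
  expect_error(GeneModels(bad2, e), "ordering")
})
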