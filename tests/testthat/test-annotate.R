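cl_tiny <- c(chrI = 12000, chrII = 8000)

mk_calls <- function(df) SVCallSet(df, cl_tiny)

test_that("annotateVariants applies category precedence", {
  db <- tiny_feature_db()
  df <- data.frame(
    svtype = "DEL",
    contig = "chrI",
    #        CDS-A    UTR-A    intron-A  pseudo   interg+enh  interg/other
    start = c(1150,   2850,    1700,     6100,    7050,       9000),
    end   = c(1250,   2950,    1800,     6200,    7100,       9100),
    length = 100, stringsAsFactors = FALSE)
  ann <- annotateVariants(mk_calls(df), db)
  expect_equal(ann$category,
               c("CDS", "UTR", "intron", "pseudogene", "intergenic",
                 "intergenic"))
  expect_equal(ann$subcategory[5:6], c("enhancer", "other"))
  expect_true(all(is.na(ann$subcategory[1:4])))
  expect_equal(ann$affected_genes[1], "geneA")
  expect_equal(ann$affected_genes[5], "")
})

test_that("a variant spanning two genes lists both, CDS wins precedence", {
  db <- tiny_feature_db()
  # spans the CDS of geneB and (constructed) the intron of geneA
  df <- data.frame(svtype = "DEL", contig = "chrI", start = 1700,
                   end = 4500, length = 2800)
  ann <- annotateVariants(mk_calls(df), db)
  expect_equal(ann$category, "CDS")
  expect_equal(ann$affected_genes, "geneA,geneB")
  # interval-overlap oracle: every gene whose span intersects is listed
  genes <- geneRanges(db)
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges("chrI", IRanges::IRanges(1701, 4500)), genes)
  expect_setequal(strsplit(ann$affected_genes, ",")[[1]],
                  unique(genes$gene_id[S4Vectors::subjectHits(ov)]))
})

test_that("precedence is total: every precise call gets exactly one category", {
  db <- tiny_feature_db()
  set.seed(5)
  start <- sample.int(11000, 40)
  df <- data.frame(svtype = "DEL", contig = "chrI", start = start,
                   end = start + 80, length = 80)
  ann <- annotateVariants(mk_calls(df), db)
  expect_equal(nrow(ann), 40L)
  expect_true(all(ann$category %in% c("CDS", "UTR", "exon", "intron",
                                      "pseudogene", "intergenic")))
  expect_equal(is.na(ann$subcategory), ann$category != "intergenic")
})

test_that("annotating a contig unknown to the db errors", {
  db <- tiny_feature_db()
  df <- data.frame(svtype = "DEL", contig = "chrII", start = 100, end = 200,
                   length = 100)
  # chrII is known (regulatory features live there), chrX is not
  ann <- suppressWarnings(annotateVariants(mk_calls(df), db))
  expect_equal(ann$category, "intergenic")
  cs <- SVCallSet(data.frame(svtype = "DEL", contig = "chrX", start = 100,
                             end = 200, length = 100), c(chrX = 1000))
  expect_error(annotateVariants(cs, db), "absent")
})

test_that("genesAffected counts distinct genes hit by deletions", {
  db <- tiny_feature_db()
  two_hits_same_gene <- mk_calls(data.frame(
    svtype = "DEL", contig = "chrI", start = c(1100, 2500),
    end = c(1300, 2700), length = 200))
  expect_equal(genesAffected(two_hits_same_gene, db), 1L)
  expect_equal(genesAffected(mk_calls(data.frame(
    svtype = "INS", contig = "chrI", start = 1100, end = 1100,
    length = 10, novel_seq = strrep("A", 10))), db), 0L)
  three <- mk_calls(data.frame(
    svtype = c("DEL", "DELINS", "DEL"), contig = "chrI",
    start = c(1100, 4100, 6100), end = c(1200, 4300, 6300),
    length = c(100, 200, 200), novel_seq = c("", "AC", "")))
  expect_equal(genesAffected(three, db), 3L)
  # never exceeds the direct interval-overlap count
  genes <- geneRanges(db)
  direct <- length(unique(genes$gene_id[S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(GenomicRanges::GRanges(
      "chrI", IRanges::IRanges(c(1101, 4101, 6101), c(1200, 4300, 6300))),
      genes))]))
  expect_lte(genesAffected(three, db), direct)
})

test_that("chromosomeStats counts large calls per chromosome", {
  df <- data.frame(
    svtype = "DEL", contig = c("chrI", "chrI", "chrI", "chrII", "chrI"),
    start = c(1000, 2000, 3000, 1000, 5000),
    end = c(1100, 2100, 3100, 1100, 5030),
    length = c(100, 100, 100, 100, 30))     # last one is small (<50)
  cs <- chromosomeStats(mk_calls(df))
  expect_equal(cs$n_chromosomes, 2L)
  expect_equal(cs$per_chromosome, c(chrI = 3L, chrII = 1L))
  empty <- chromosomeStats(SVCallSet(contigLengths = cl_tiny))
  expect_equal(empty$n_chromosomes, 0L)
  expect_equal(length(empty$per_chromosome), 0L)
})

test_that("sizeDistribution matches a quantile oracle", {
  df <- data.frame(svtype = "DEL", contig = "chrI",
                   start = seq(100, 700, by = 300),
                   end = seq(100, 700, by = 300) + c(100, 150, 200))
  df$length <- df$end - df$start
  sd_ <- sizeDistribution(mk_calls(df))
  expect_equal(sd_$median, 150)
  one <- sizeDistribution(mk_calls(data.frame(
    svtype = "DEL", contig = "chrI", start = 100, end = 400, length = 300)))
  expect_equal(one$median, 300)
  expect_equal(one$iqr, 0)
  expect_true(is.na(sizeDistribution(SVCallSet(contigLengths = cl_tiny))$median))
  set.seed(6)
  lens <- sample(60:5000, 31)
  rnd <- data.frame(svtype = "DEL", contig = "chrI",
                    start = seq_along(lens) * 10, end = 0)
  rnd$end <- rnd$start + lens
  rnd$length <- lens
  sr <- sizeDistribution(mk_calls(rnd))
  expect_equal(sr$median, unname(quantile(lens, 0.5)))
  expect_equal(sr$iqr, unname(diff(quantile(lens, c(0.25, 0.75)))))
  expect_equal(sort(sr$values), sort(lens))
})

test_that("variant density is uncorrelated with AT content under the null", {
  lens <- c(chrI = 300000)
  g <- simulateGenome(lens, at_fraction = 0.6, seed = 51)
  set.seed(52)
  start <- sort(sample.int(299000, 200))
  cs <- SVCallSet(data.frame(svtype = "DEL", contig = "chrI", start = start,
                             end = start + 100, length = 100), lens)
  r2 <- atContentCorrelation(cs, g, window = 3000)
  expect_lt(r2, 0.05)
})

test_that("variants planted in AT-rich windows give a high R-squared", {
  window <- 3000
  set.seed(53)
  # build a genome whose windows alternate in AT content
  at <- rep(c(0.35, 0.85), each = 1, times = 50)
  seqs <- vapply(at, function(a) {
    p <- c(A = a / 2, T = a / 2, C = (1 - a) / 2, G = (1 - a) / 2)
    paste(sample(names(p), window, TRUE, prob = p), collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(c(chrI = paste(seqs, collapse = "")))
  rich <- which(at > 0.5) - 1L
  start <- unlist(lapply(rich, function(w)
    w * window + sort(sample.int(window - 200, 4))))
  cs <- SVCallSet(data.frame(svtype = "DEL", contig = "chrI",
                             start = start, end = start + 100, length = 100),
                  genomeContigLengths(g))
  expect_gt(atContentCorrelation(cs, g, window = window), 0.5)
})

test_that("a constant-AT regressor yields zero by convention", {
  g <- Biostrings::DNAStringSet(c(chrI = strrep("AT", 30000)))
  start <- seq(1000, 50000, by = 5000)
  cs <- SVCallSet(data.frame(svtype = "DEL", contig = "chrI", start = start,
                             end = start + 100, length = 100),
                  genomeContigLengths(g))
  expect_equal(atContentCorrelation(cs, g, window = 5000), 0)
  expect_error(atContentCorrelation(cs, g, window = 500), "window")
  expect_error(atContentCorrelation(cs, g, window = 40000), "windows")
})
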