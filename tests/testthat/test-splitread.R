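test_that("extractClipped computes anchors from CIGAR arithmetic", {
  aln <- rbind(
    aln_row("a", "chrI", 99, "30M20S", paste0(strrep("A", 30), strrep("C", 20))),
    aln_row("b", "chrI", 50, "50M", strrep("G", 50)),
    aln_row("c", "chrI", 10, "10S40M", strrep("T", 50)),
    aln_row("d", "chrI", 200, "5H25S30M", paste0(strrep("A", 25), strrep("G", 30)))
  )
  seg <- extractClipped(aln, min_clip_len = 15)
  expect_equal(nrow(seg), 2L)  # b has no clip, c's clip is too short
  right <- seg[seg$read_id == "a", ]
  expect_equal(right$side, "right")
  expect_equal(right$anchor_pos, 129)
  expect_equal(right$clip_seq, strrep("C", 20))
  left <- seg[seg$read_id == "d", ]
  expect_equal(left$side, "left")
  expect_equal(left$anchor_pos, 200)   # hard clip consumes no sequence
  expect_equal(left$clip_seq, strrep("A", 25))
  expect_equal(nrow(extractClipped(aln[0, ], 15)), 0L)
})

test_that("realignClip finds unique exact and reverse-complement hits", {
  g <- tiny_genome()
  clip <- as.character(Biostrings::subseq(g[["chrI"]], 5001, 5030))
  ra <- realignClip(clip, g)
  expect_equal(nrow(ra$hit), 1L)
  expect_equal(ra$hit$contig, "chrI")
  expect_equal(ra$hit$start, 5000)     # 0-based
  expect_equal(ra$hit$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(g[["chrI"]], 5001, 5030)))
  rr <- realignClip(rc, g)
  expect_equal(rr$hit$start, 5000)
  expect_equal(rr$hit$strand, "-")
})

test_that("multi-best-hit clips are discarded as ambiguous", {
  unit <- paste(rep(c("ACGTTGCA", "GGATCCTT"), 2), collapse = "")
  rep_seq <- paste0(strrep("AC", 100), unit, strrep("GT", 500),
                    unit, strrep("TG", 100))
  g <- Biostrings::DNAStringSet(c(chrI = rep_seq))
  ra <- realignClip(unit, g)
  expect_equal(nrow(ra$hit), 0L)
  bf <- brute_force_realign(unit, g, 1)
  expect_gt(length(bf$hits), 1L)       # the oracle confirms two best loci
})

test_that("classifyPattern implements the break-site rules", {
  hit <- function(contig, start, end, strand)
    data.frame(contig = contig, start = start, end = end, strand = strand,
               mismatches = 0L, stringsAsFactors = FALSE)
  # right anchor 1000, hit downstream -> DEL with 200 bp gap
  r <- classifyPattern("chrI", 1000, "right", hit("chrI", 1200, 1250, "+"))
  expect_equal(r$pattern, "DEL"); expect_equal(c(r$start, r$end), c(1000, 1200))
  # hit back upstream -> DUP
  r <- classifyPattern("chrI", 1000, "right", hit("chrI", 800, 850, "+"))
  expect_equal(r$pattern, "DUP"); expect_equal(c(r$start, r$end), c(800, 1000))
  # other contig -> TRA
  r <- classifyPattern("chrI", 1000, "right", hit("chrII", 500, 550, "+"),
                       contig_order = c("chrI", "chrII"))
  expect_equal(r$pattern, "TRA")
  expect_equal(c(r$contig, r$contig2), c("chrI", "chrII"))
  expect_equal(r$pos2, 500)
  # positive gap with novel prefix -> DELINS
  r <- classifyPattern("chrI", 1000, "right", hit("chrI", 1300, 1350, "+"),
                       novel = "GATC")
  expect_equal(r$pattern, "DELINS"); expect_equal(r$novel, "GATC")
  expect_equal(c(r$start, r$end), c(1000, 1300))
  # zero gap with novel prefix -> INS
  r <- classifyPattern("chrI", 1000, "right", hit("chrI", 1000, 1040, "+"),
                       novel = "TTAA")
  expect_equal(r$pattern, "INS")
  # opposite strand -> INV breakend, canonical (min, max)
  r <- classifyPattern("chrI", 1000, "right", hit("chrI", 1960, 2000, "-"))
  expect_equal(r$pattern, "INV"); expect_equal(c(r$start, r$end), c(1000, 2000))
  # left-side mirror: hit end upstream of anchor -> DEL
  r <- classifyPattern("chrI", 1200, "left", hit("chrI", 960, 1000, "+"))
  expect_equal(r$pattern, "DEL"); expect_equal(c(r$start, r$end), c(1000, 1200))
})

test_that("clusterEvidence merges by tolerance, takes modal coordinates and filters", {
  raw1 <- do.call(rbind, lapply(1:5, function(i)
    data.frame(pattern = "DEL", contig = "chrI", start = 1000, end = 1200,
               contig2 = NA_character_, pos2 = NA_real_, novel = "",
               anchor_contig = "chrI", anchor_pos = 1000,
               read_id = paste0("r", i), read_strand = "+",
               stringsAsFactors = FALSE)))
  ev <- clusterEvidence(raw1, tolerance = 5, min_support = 3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$support, 5L)
  expect_equal(ev$fwd_support, 5L)
  # below min_support
  expect_equal(nrow(clusterEvidence(raw1[1:2, ], 5, 3)), 0L)
  # jittered starts merge; modal coordinate with smallest-tie rule
  raw2 <- raw1
  raw2$start <- c(1000, 1001, 1000, 1001, 1002)
  ev2 <- clusterEvidence(raw2, tolerance = 5, min_support = 3)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$start, 1000)
  # support counts distinct reads, never alignments
  raw3 <- rbind(raw1, raw1[1, ])
  ev3 <- clusterEvidence(raw3, tolerance = 5, min_support = 3)
  expect_equal(ev3$support, 5L)
  # distant breakpoints do not merge
  raw4 <- raw1
  raw4$start[4:5] <- 1900
  raw4$end[4:5] <- 2100
  expect_equal(nrow(clusterEvidence(raw4, 5, 1)), 2L)
})

test_that("exhaustive pairwise clustering oracle agrees on a toy set", {
  set.seed(11)
  centers <- data.frame(start = c(1000, 1300, 5000), end = c(1200, 1500, 5400))
  raw <- do.call(rbind, lapply(seq_len(nrow(centers)), function(ci) {
    n <- 4 + ci
    data.frame(pattern = "DEL", contig = "chrI",
               start = centers$start[ci] + sample(-2:2, n, TRUE),
               end = centers$end[ci] + sample(-2:2, n, TRUE),
               contig2 = NA_character_, pos2 = NA_real_, novel = "",
               anchor_contig = "chrI", anchor_pos = centers$start[ci],
               read_id = sprintf("c%d_r%d", ci, seq_len(n)),
               read_strand = "+", stringsAsFactors = FALSE)
  }))
  raw <- raw[sample(nrow(raw)), ]
  ev <- clusterEvidence(raw, tolerance = 5, min_support = 1)
  # oracle: single-linkage components under the same tolerance
  n <- nrow(raw)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    abs(raw$start[i] - raw$start[j]) <= 5 && abs(raw$end[i] - raw$end[j]) <= 5))
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  expect_equal(nrow(ev), length(unique(comp)))
  expect_equal(sort(ev$support), sort(as.integer(table(comp))))
})

test_that("no split-read evidence arises from a variant-free genome", {
  g <- tiny_genome()
  st <- simulateStrain(g, NULL, depth = 20, seed = 3)
  expect_equal(sum(grepl("S", st$alignments$cigar)), 0L)
  ev <- detectSplitReads(st$alignments, g)
  expect_equal(nrow(ev), 0L)
})

test_that("engineered deletions are recovered exactly from error-free reads", {
  lens <- c(chrI = 120000)
  g <- simulateGenome(lens, seed = 15)
  specs <- randomVariantSpecs(lens, n_del = 10, n_dup = 0, n_mult = 0,
                              n_ins = 0, n_delins = 0, n_inv = 0, n_tra = 0,
                              het_fraction = 0, seed = 16)
  st <- simulateStrain(g, specs, depth = 20, seed = 17)
  ev <- detectSplitReads(st$alignments, g)
  ev <- ev[ev$pattern == "DEL", ]
  found <- mapply(function(s, e)
    any(ev$start == s & ev$end == e), st$truth$start, st$truth$end)
  expect_gte(mean(found), 0.9)
  # every DEL evidence matches an engineered junction (no spurious calls)
  spurious <- mapply(function(s, e)
    !any(abs(st$truth$start - s) <= 2 & abs(st$truth$end - e) <= 2),
    ev$start, ev$end)
  expect_equal(sum(spurious), 0L)
})

test_that("noisy reads still recover deletions within 2 bp", {
  lens <- c(chrI = 200000)
  g <- simulateGenome(lens, seed = 25)
  specs <- randomVariantSpecs(lens, n_del = 15, n_dup = 0, n_mult = 0,
                              n_ins = 0, n_delins = 0, n_inv = 0, n_tra = 0,
                              het_fraction = 0, seed = 26)
  st <- simulateStrain(g, specs, depth = 20, error_rate = 0.01, seed = 27)
  ev <- detectSplitReads(st$alignments, g)
  ev <- ev[ev$pattern == "DEL", ]
  found <- mapply(function(s, e)
    any(abs(ev$start - s) <= 2 & abs(ev$end - e) <= 2),
    st$truth$start, st$truth$end)
  expect_gte(mean(found), 0.9)
})
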