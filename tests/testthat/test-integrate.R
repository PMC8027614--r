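mk_ev <- function(pattern, contig, start, end, support = 10L, novel = "",
                  contig2 = NA_character_, pos2 = NA_real_) {
  data.frame(pattern = pattern, contig = contig, start = start, end = end,
             contig2 = contig2, pos2 = pos2, novel_seq = novel,
             support = as.integer(support),
             fwd_support = as.integer(ceiling(support / 2)),
             rev_support = as.integer(floor(support / 2)),
             support_start = as.integer(ceiling(support / 2)),
             support_end = as.integer(floor(support / 2)),
             breakends = NA_integer_, stringsAsFactors = FALSE)
}

test_that("combineEvidence pairs split and CN support by reciprocal overlap", {
  cl <- c(chrI = 50000)
  ev <- rbind(mk_ev("DEL", "chrI", 1000, 1200),
              mk_ev("DEL", "chrI", 10000, 12000),
              mk_ev("DUP", "chrI", 20000, 23000))
  segs <- data.frame(
    contig = "chrI", start = c(10000, 20000), end = c(12000, 23000),
    class = c("DEL_CN", "MULT_CN"), mean_ratio = c(0.02, 3.1),
    n_bins = c(4L, 6L), stringsAsFactors = FALSE)
  cs <- combineEvidence(ev, segs, cl)
  df <- calls(cs)
  small <- df[df$start == 1000, ]
  expect_equal(small$source, "split_only")    # event smaller than a bin
  expect_true(is.na(small$cn_ratio_mean))
  big <- df[df$start == 10000, ]
  expect_equal(big$source, "split+cn")
  expect_equal(big$cn_ratio_mean, 0.02)
  dup <- df[df$start == 20000, ]
  expect_equal(dup$svtype, "MULT")            # promoted by MULT_CN match
  # provenance fields survive integration
  expect_true(all(c("support", "fwd_support", "rev_support",
                    "cn_ratio_mean") %in% names(df)))
  expect_equal(big$support, 10L)
})

test_that("CN-only segments are emitted as imprecise calls above 2 kb", {
  cl <- c(chrI = 50000)
  segs <- data.frame(
    contig = "chrI", start = c(5000, 30000), end = c(5500, 33000),
    class = "DEL_CN", mean_ratio = c(0.1, 0.05), n_bins = c(1L, 6L),
    stringsAsFactors = FALSE)
  cs <- combineEvidence(NULL, segs, cl)
  df <- calls(cs)
  expect_equal(nrow(df), 1L)                  # 500 bp segment suppressed
  expect_false(df$precise)
  expect_equal(df$source, "cn_only")
  expect_true(is.na(df$frequency))            # no breakpoint to interrogate
})

test_that("variantFrequency counts junction vs spanning reads", {
  cl <- c(chrI = 10000)
  call_df <- calls(SVCallSet(
    data.frame(svtype = "DEL", contig = "chrI", start = 5000, end = 5200,
               length = 200, support = 10L, support_start = 5L,
               support_end = 5L), cl))
  # no spanning reads -> frequency 1
  aln0 <- aln_row("x", "chrI", 100, "50M", strrep("A", 50))
  expect_equal(variantFrequency(call_df[1, ], aln0), 1.0)
  # 10 junction vs 10 spanning -> 0.5
  span <- do.call(rbind, lapply(1:10, function(i)
    aln_row(paste0("s", i), "chrI", 4940, "120M", strrep("A", 120))))
  expect_equal(variantFrequency(call_df[1, ], span), 0.5)
  # spanning requires min_clip_len aligned bases on both sides
  near <- aln_row("n", "chrI", 4990, "20M", strrep("A", 20))
  expect_equal(variantFrequency(call_df[1, ], near), 1.0)
})

test_that("callZygosity applies the frequency bands", {
  expect_equal(callZygosity(1.0), "hom")
  expect_equal(callZygosity(0.8), "hom")
  expect_equal(callZygosity(0.5), "het")
  expect_equal(callZygosity(0.1), "unknown")
  expect_equal(callZygosity(NA_real_), "unknown")
  expect_equal(callZygosity(c(0.9, 0.4, 0.05)), c("hom", "het", "unknown"))
})

test_that("subtractBackground removes shared calls and keeps private ones", {
  cl <- c(chrI = 100000)
  shared <- data.frame(svtype = "DEL", contig = "chrI", start = 10000,
                       end = 10500, length = 500)
  mk_strain <- function(extra_start = NULL, shift = 0) {
    df <- shared
    df$start <- df$start + shift
    df$end <- df$end + shift
    if (!is.null(extra_start))
      df <- rbind(df, data.frame(svtype = "DEL", contig = "chrI",
                                 start = extra_start, end = extra_start + 300,
                                 length = 300))
    SVCallSet(df, cl)
  }
  strains <- list(s1 = mk_strain(50000), s2 = mk_strain(), s3 = mk_strain(60000, shift = 3),
                  s4 = SVCallSet(data.frame(svtype = "DEL", contig = "chrI",
                                            start = 80000, end = 80400,
                                            length = 400), cl),
                  s5 = SVCallSet(contigLengths = cl))
  res <- subtractBackground(strains, tolerance = 5, min_strains = 2)
  # shared call (3 bp offset counts as shared) removed everywhere
  expect_equal(length(res$filtered$s1), 1L)
  expect_equal(calls(res$filtered$s1)$start, 50000)
  expect_equal(length(res$filtered$s2), 0L)
  expect_equal(calls(res$filtered$s3)$start, 60000)
  # private calls retained
  expect_equal(calls(res$filtered$s4)$start, 80000)
  # background reported once
  expect_equal(nrow(res$background), 1L)
  expect_equal(res$background$n_strains, 3L)
  # idempotent
  res2 <- subtractBackground(res$filtered, tolerance = 5, min_strains = 2)
  expect_equal(nrow(res2$background), 0L)
  expect_equal(vapply(res2$filtered, length, integer(1)),
               vapply(res$filtered, length, integer(1)))
  # symmetric in strain order
  res3 <- subtractBackground(rev(strains), tolerance = 5, min_strains = 2)
  expect_equal(sort(calls(res3$filtered$s1)$start),
               sort(calls(res$filtered$s1)$start))
  expect_equal(nrow(res3$background), 1L)
})

test_that("a multi-strain panel with planted background is cleaned", {
  set.seed(9)
  cl <- c(chrI = 1e6)
  n_strain <- 20
  bg <- data.frame(svtype = "DEL",
                   start = sort(sample.int(9.5e5, 15)))
  bg$end <- bg$start + 500
  strains <- lapply(seq_len(n_strain), function(i) {
    priv_start <- sample.int(9.5e5, 8)
    df <- data.frame(svtype = "DEL", contig = "chrI",
                     start = c(bg$start, priv_start),
                     end = c(bg$end, priv_start + 200),
                     length = c(rep(500, nrow(bg)), rep(200, 8)))
    SVCallSet(df, cl)
  })
  names(strains) <- paste0("st", seq_len(n_strain))
  res <- subtractBackground(strains, tolerance = 5, min_strains = 2)
  remaining <- do.call(rbind, lapply(res$filtered, calls))
  # no planted background call survives in any strain
  expect_false(any(remaining$start %in% bg$start))
  # nearly all private calls survive (collisions are the only legal loss)
  expect_gte(nrow(remaining) / (n_strain * 8), 0.95)
})
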