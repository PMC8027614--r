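# Desk-scale validation harness: simulate a genome with a known variant
# spectrum, run the full detection pipeline, and score recall, breakpoint
# exactness and zygosity against the engineered truth.

#' Match detected calls against an engineered truth table
#'
#' A truth variant is recalled when a call of the same type lies within
#' \code{tolerance} bases on both breakpoints (partner breakend for
#' translocations).
#'
#' Breakpoint exactness for insertions and complex deletion-insertions is
#' judged up to junction-representation ambiguity: when inserted bases
#' coincide with adjacent reference bases the same mutated sequence has
#' several equivalent (start, end, inserted-sequence) descriptions, so
#' with \code{genome} supplied the reconstructed local alternate
#' sequences are compared instead of raw coordinates.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param truth truth data.frame from \code{applyVariants}.
#' @param tolerance matching tolerance in bases (default 5).
#' @param genome optional named \code{DNAStringSet} for
#'   representation-aware exactness of INS/DELINS calls.
#' @return data.frame: truth rows plus \code{recalled, exact, call_id,
#'   called_zygosity}.
#' @export
matchTruth <- function(callset, truth, tolerance = 5L, genome = NULL) {
  same_alt <- function(ctg, s1, e1, n1, s2, e2, n2, pad = 60L) {
    # reconstruct the alternate sequence over a common reference window
    ref <- as.character(genome[[ctg]])
    lo <- max(0L, min(s1, s2) - pad)
    hi <- min(nchar(ref), max(e1, e2) + pad)
    alt <- function(s, e, nv)
      paste0(substr(ref, lo + 1L, s), nv, substr(ref, e + 1L, hi))
    identical(alt(s1, e1, n1), alt(s2, e2, n2))
  }
  df <- calls(callset)
  out <- truth
  out$recalled <- FALSE
  out$exact <- FALSE
  out$call_id <- NA_character_
  out$called_zygosity <- NA_character_
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    if (t$svtype == "TRA") {
      cand <- which(df$svtype == "TRA" &
                    ((df$contig == t$contig & df$contig2 == t$contig2) |
                     (df$contig == t$contig2 & df$contig2 == t$contig)))
      if (!length(cand)) next
      d <- pmin(
        abs(df$start[cand] - t$start) + abs(df$pos2[cand] - t$pos2),
        abs(df$start[cand] - t$pos2) + abs(df$pos2[cand] - t$start))
      j <- cand[which.min(d)]
      if (min(d) <= 2 * tolerance) {
        out$recalled[i] <- TRUE
        out$exact[i] <- min(d) == 0
        out$call_id[i] <- df$id[j]
        out$called_zygosity[i] <- df$zygosity[j]
      }
      next
    }
    cand <- which(df$svtype == t$svtype & df$contig == t$contig & df$precise)
    if (!length(cand)) next
    d <- abs(df$start[cand] - t$start) + abs(df$end[cand] - t$end)
    j <- cand[which.min(d)]
    if (abs(df$start[j] - t$start) <= tolerance &&
        abs(df$end[j] - t$end) <= tolerance) {
      out$recalled[i] <- TRUE
      exact <- df$start[j] == t$start && df$end[j] == t$end &&
        (!t$svtype %in% c("INS", "DELINS") ||
         identical(df$novel_seq[j], t$novel_seq))
      if (!exact && !is.null(genome) && t$svtype %in% c("INS", "DELINS"))
        exact <- same_alt(t$contig, df$start[j], df$end[j], df$novel_seq[j],
                          t$start, t$end, t$novel_seq)
      out$exact[i] <- exact
      out$call_id[i] <- df$id[j]
      out$called_zygosity[i] <- df$zygosity[j]
    }
  }
  out
}

#' End-to-end detection benchmark on simulated data
#'
#' Simulates a genome, an engineered variant set spanning all variant
#' types, sample and control read sets, runs the full detection pipeline,
#' and scores it: recall, fraction of recalled variants with exact
#' breakpoints, fraction of recalled variants with correct zygosity, and
#' the number of calls produced from a variant-free strain (false
#' positives).
#'
#' @param seed integer master seed (all randomness derives from it).
#' @param contig_lengths named contig lengths (default 600 kb + 400 kb).
#' @param depth total depth (default 20).
#' @param error_rate per-base substitution error rate (default 0).
#' @param n_del,n_dup,n_mult,n_ins,n_delins,n_inv,n_tra variant counts
#'   passed to \code{randomVariantSpecs}.
#' @param config list from \code{pipelineConfig}.
#' @param check_fp also run a variant-free strain and count calls
#'   (default TRUE).
#' @return list \code{recall, exact_fraction, zygosity_accuracy,
#'   false_positives, n_truth, matches, callset}.
#' @export
benchmarkDetection <- function(seed = 1L,
                               contig_lengths = c(chrI = 6e5, chrII = 4e5),
                               depth = 20, error_rate = 0,
                               n_del = 30L, n_dup = 5L, n_mult = 2L,
                               n_ins = 5L, n_delins = 4L, n_inv = 3L,
                               n_tra = 1L,
                               config = pipelineConfig(),
                               check_fp = TRUE) {
  genome <- simulateGenome(contig_lengths, seed = seed)
  specs <- randomVariantSpecs(contig_lengths, n_del = n_del, n_dup = n_dup,
                              n_mult = n_mult, n_ins = n_ins,
                              n_delins = n_delins, n_inv = n_inv,
                              n_tra = n_tra, seed = seed + 101L)
  control <- simulateStrain(genome, NULL, depth = depth,
                            error_rate = error_rate, seed = seed + 202L,
                            prefix = "ctl")
  strain <- simulateStrain(genome, specs, depth = depth,
                           error_rate = error_rate, seed = seed + 303L,
                           prefix = "smp")
  callset <- detectVariants(genome, strain$alignments, control$alignments,
                            config)
  matches <- matchTruth(callset, strain$truth, tolerance = config$tolerance,
                        genome = genome)
  rec <- matches$recalled
  fp <- NA_integer_
  if (check_fp) {
    clean <- simulateStrain(genome, NULL, depth = depth,
                            error_rate = error_rate, seed = seed + 404L,
                            prefix = "cln")
    fp_calls <- detectVariants(genome, clean$alignments, control$alignments,
                               config)
    fp <- length(fp_calls)
  }
  list(
    recall = mean(rec),
    exact_fraction = if (any(rec)) mean(matches$exact[rec]) else NA_real_,
    zygosity_accuracy = if (any(rec))
      mean(matches$called_zygosity[rec] == matches$zygosity[rec]) else NA_real_,
    false_positives = fp,
    n_truth = nrow(matches),
    matches = matches,
    callset = callset
  )
}
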