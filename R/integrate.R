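# Integration of split-read and copy-number evidence into typed variant
# calls, variant frequency and zygosity, and background subtraction.

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

#' Combine split-read evidence with copy-number segments
#'
#' Deletion evidence whose interval reciprocally overlaps a DEL_CN segment
#' by at least \code{reciprocal_overlap} gains copy-number support
#' (\code{cn_ratio_mean} filled, source \code{"split+cn"}); duplication
#' evidence pairs with DUP_CN (type DUP) or MULT_CN (type promoted to
#' MULT).  Split-read-only calls are retained flagged
#' \code{"split_only"}.  Copy-number segments of at least
#' \code{cn_only_min_len} bases with no split support are emitted as
#' imprecise bin-resolution calls.
#'
#' @param evidence split-read evidence (from \code{clusterEvidence}).
#' @param cn_segments row-bound output of \code{callCnSegments}.
#' @param contig_lengths named vector of contig lengths.
#' @param reciprocal_overlap minimal reciprocal overlap (default 0.5).
#' @param cn_only_min_len minimal length of emitted CN-only calls
#'   (default 2000).
#' @param tracks optional named list of \linkS4class{CopyNumberTrack};
#'   when supplied, \code{cn_ratio_mean} is computed over each precise
#'   call's own interval (full bins preferred), independent of whether a
#'   thresholded segment matched.
#' @return An \linkS4class{SVCallSet} (frequency/zygosity not yet set).
#' @export
combineEvidence <- function(evidence, cn_segments, contig_lengths,
                            reciprocal_overlap = 0.5,
                            cn_only_min_len = 2000, tracks = NULL,
                            mult_min = 2.5) {
  interval_ratio <- function(ctg, s, e) {
    tr <- tracks[[ctg]]
    if (is.null(tr)) return(NA_real_)
    bs <- binSize(tr)
    r <- cnRatioValues(tr)
    full <- which((seq_along(r) - 1) * bs >= s & seq_along(r) * bs <= e)
    b <- if (length(full)) full
         else (floor(s / bs) + 1L):min(floor((e - 1) / bs) + 1L, length(r))
    v <- r[b]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  if (is.null(cn_segments) || !nrow(cn_segments)) {
    cn_segments <- data.frame(contig = character(0), start = numeric(0),
                              end = numeric(0), class = character(0),
                              mean_ratio = numeric(0), n_bins = integer(0))
  }
  used_cn <- logical(nrow(cn_segments))
  rows <- list()
  if (!is.null(evidence) && nrow(evidence)) {
    for (i in seq_len(nrow(evidence))) {
      ev <- evidence[i, ]
      cn_mean <- NA_real_
      source <- "split_only"
      svtype <- ev$pattern
      if (svtype %in% c("DEL", "DELINS", "DUP")) {
        want <- if (svtype == "DUP") c("DUP_CN", "MULT_CN") else "DEL_CN"
        cand <- which(cn_segments$contig == ev$contig &
                      cn_segments$class %in% want)
        if (length(cand)) {
          ro <- .reciprocal_overlap(ev$start, ev$end,
                                    cn_segments$start[cand],
                                    cn_segments$end[cand])
          best <- cand[which.max(ro)]
          if (max(ro) >= reciprocal_overlap) {
            cn_mean <- cn_segments$mean_ratio[best]
            source <- "split+cn"
            used_cn[best] <- TRUE
            if (svtype == "DUP" && cn_segments$class[best] == "MULT_CN")
              svtype <- "MULT"
          }
        }
      }
      if (!is.null(tracks) && !svtype %in% c("INS", "TRA") &&
          ev$end > ev$start) {
        iv <- interval_ratio(ev$contig, ev$start, ev$end)
        if (!is.na(iv)) {
          cn_mean <- iv
          if (svtype == "DUP" && iv >= mult_min) svtype <- "MULT"
        }
      }
      len <- if (svtype == "INS") nchar(ev$novel_seq)
             else if (svtype == "TRA") NA_real_
             else ev$end - ev$start
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = svtype, contig = ev$contig, start = ev$start,
        end = ev$end, contig2 = ev$contig2, pos2 = ev$pos2,
        length = len, novel_seq = ev$novel_seq, support = ev$support,
        support_start = ev$support_start, support_end = ev$support_end,
        fwd_support = ev$fwd_support, rev_support = ev$rev_support,
        cn_ratio_mean = cn_mean, precise = TRUE, source = source,
        breakends = ev$breakends, stringsAsFactors = FALSE
      )
    }
  }
  cn_only <- which(!used_cn &
                   (cn_segments$end - cn_segments$start) >= cn_only_min_len)
  for (i in cn_only) {
    svtype <- c(DEL_CN = "DEL", DUP_CN = "DUP", MULT_CN = "MULT")[
      cn_segments$class[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      svtype = unname(svtype), contig = cn_segments$contig[i],
      start = cn_segments$start[i], end = cn_segments$end[i],
      contig2 = NA_character_, pos2 = NA_real_,
      length = cn_segments$end[i] - cn_segments$start[i],
      novel_seq = "", support = 0L, support_start = 0L, support_end = 0L,
      fwd_support = 0L, rev_support = 0L,
      cn_ratio_mean = cn_segments$mean_ratio[i], precise = FALSE,
      source = "cn_only", breakends = NA_integer_, stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else emptySvCalls()
  if (nrow(df)) {
    ord <- order(match(df$contig, names(contig_lengths)), df$start)
    df <- df[ord, , drop = FALSE]
    df$id <- sprintf("SV%05d", seq_len(nrow(df)))
  }
  SVCallSet(df, contigLengths = contig_lengths)
}

#' Variant frequency at the breakpoint
#'
#' The fraction of breakpoint-informative reads supporting the variant
#' junction: junction reads anchored at the breakpoint divided by junction
#' plus reference-spanning reads.  A spanning read must carry at least
#' \code{min_clip_len} aligned bases on both sides of the breakpoint.
#' When the start breakpoint has no informative reads the end breakpoint
#' is used.
#'
#' @param call one row of an \linkS4class{SVCallSet} call table.
#' @param alignments sample alignment data.frame.
#' @param min_clip_len flanking requirement (default 15).
#' @return frequency in [0, 1], or \code{NA} when no read is informative.
#' @export
variantFrequency <- function(call, alignments, min_clip_len = 15L) {
  if (!isTRUE(call$precise)) return(NA_real_)
  spanning <- function(ctg, bp) {
    sum(alignments$contig == ctg &
        alignments$pos <= bp - min_clip_len &
        alignments$ref_end >= bp + min_clip_len)
  }
  # Both clip orientations of a DEL/DUP/INS/DELINS describe the same
  # physical junction, so the full support is the junction count at
  # either breakpoint.  Inversions and translocations have two physical
  # junctions; only the reads clipped at the interrogated breakpoint are
  # comparable with the spanning count there.
  two_junctions <- call$svtype %in% c("INV", "TRA")
  j1 <- if (two_junctions) call$support_start else call$support
  n1 <- spanning(call$contig, call$start)
  if (j1 + n1 > 0) return(j1 / (j1 + n1))
  ctg2 <- if (!is.na(call$contig2)) call$contig2 else call$contig
  bp2 <- if (!is.na(call$pos2)) call$pos2 else call$end
  j2 <- if (two_junctions) call$support_end else call$support
  n2 <- spanning(ctg2, bp2)
  if (j2 + n2 > 0) return(j2 / (j2 + n2))
  NA_real_
}

#' Call zygosity from variant frequency
#'
#' Frequency at or above \code{hom_min} is homozygous; the band
#' \code{[het_min, hom_min)} heterozygous; lower frequencies (likely
#' artifacts) and missing frequencies are \code{"unknown"}.
#'
#' @param frequency numeric vector of variant frequencies.
#' @param hom_min homozygosity threshold (default 0.8).
#' @param het_min lower edge of the heterozygous band (default 0.25).
#' @return character vector: \code{"hom"}, \code{"het"} or
#'   \code{"unknown"}.
#' @export
callZygosity <- function(frequency, hom_min = 0.8, het_min = 0.25) {
  out <- rep("unknown", length(frequency))
  out[!is.na(frequency) & frequency >= hom_min] <- "hom"
  out[!is.na(frequency) & frequency >= het_min & frequency < hom_min] <- "het"
  out
}

# Copy-number based zygosity for copy-gain types, where junction
# frequency is uninformative (the variant haplotype itself carries
# reference-spanning reads across a tandem junction).
.dup_zygosity <- function(svtype, cn_ratio) {
  if (is.na(cn_ratio)) return("unknown")
  if (svtype == "MULT") {
    if (cn_ratio >= 2.75) "hom" else "het"
  } else {
    if (cn_ratio >= 1.75) "hom" else "het"
  }
}

#' Fill variant frequency and zygosity for all calls
#'
#' Frequency-based zygosity for copy-neutral and copy-loss types; for
#' tandem duplications and multiplications the copy-number ratio is used
#' instead (see the methods vignette).
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param alignments sample alignment data.frame.
#' @param min_clip_len,hom_min,het_min see \code{variantFrequency} and
#'   \code{callZygosity}.
#' @param cn_hom_max,cn_het_max copy-number ratio bands used as a
#'   fallback for deletions whose junction frequency is uninformative:
#'   ratio at most \code{cn_hom_max} is homozygous loss, up to
#'   \code{cn_het_max} heterozygous (defaults 0.25 and 0.75, midpoints
#'   between integer copy states).
#' @return the updated \linkS4class{SVCallSet}.
#' @export
assignZygosity <- function(callset, alignments, min_clip_len = 15L,
                           hom_min = 0.8, het_min = 0.25,
                           cn_hom_max = 0.25, cn_het_max = 0.75) {
  df <- calls(callset)
  if (!nrow(df)) return(callset)
  for (i in seq_len(nrow(df))) {
    df$frequency[i] <- variantFrequency(df[i, ], alignments, min_clip_len)
    if (df$svtype[i] %in% c("DUP", "MULT")) {
      df$zygosity[i] <- .dup_zygosity(df$svtype[i], df$cn_ratio_mean[i])
    } else {
      z <- callZygosity(df$frequency[i], hom_min, het_min)
      if (z == "unknown" && df$svtype[i] %in% c("DEL", "DELINS") &&
          !is.na(df$cn_ratio_mean[i])) {
        r <- df$cn_ratio_mean[i]
        z <- if (r <= cn_hom_max) "hom"
             else if (r <= cn_het_max) "het" else "unknown"
      }
      df$zygosity[i] <- z
    }
  }
  initialize(callset, calls = df)
}

#' Subtract background variants shared across strains
#'
#' Calls of identical type whose breakpoints match within
#' \code{tolerance} across at least \code{min_strains} independent strains
#' are attributed to the shared ancestral genotype: they are removed from
#' every strain's call list and reported once in the background set.  The
#' operation is idempotent and symmetric in strain order.
#'
#' @param per_strain named list of \linkS4class{SVCallSet}, one per strain.
#' @param tolerance breakpoint matching tolerance in bases (default 5).
#' @param min_strains minimal number of strains sharing a call for it to
#'   be background (default 2).
#' @return list with \code{filtered} (named list of SVCallSet) and
#'   \code{background} (data.frame of representative background calls
#'   with an \code{n_strains} column).
#' @export
subtractBackground <- function(per_strain, tolerance = 5L, min_strains = 2L) {
  stopifnot(length(per_strain) >= 2L, min_strains >= 2L)
  strains <- names(per_strain) %||% as.character(seq_along(per_strain))
  pooled <- do.call(rbind, lapply(seq_along(per_strain), function(i) {
    df <- calls(per_strain[[i]])
    if (!nrow(df)) return(NULL)
    df$strain <- strains[i]
    df$row_in_strain <- seq_len(nrow(df))
    df
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(list(filtered = per_strain,
                background = cbind(emptySvCalls(), n_strains = integer(0))))
  }
  key <- paste(pooled$svtype, pooled$contig,
               ifelse(is.na(pooled$contig2), "", pooled$contig2))
  pooled$pos_b <- ifelse(pooled$svtype == "TRA", pooled$pos2, pooled$end)
  is_bg <- logical(nrow(pooled))
  bg_rows <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    g <- pooled[idx, , drop = FALSE]
    o <- order(g$start, g$pos_b)
    g <- g[o, , drop = FALSE]
    idx <- idx[o]
    cl <- integer(nrow(g)); cur <- 1L; cl[1L] <- 1L
    for (i in seq_len(nrow(g))[-1L]) {
      if (g$start[i] - g$start[i - 1L] > tolerance ||
          abs(g$pos_b[i] - g$pos_b[i - 1L]) > tolerance) cur <- cur + 1L
      cl[i] <- cur
    }
    for (cid in seq_len(cur)) {
      members <- which(cl == cid)
      ns <- length(unique(g$strain[members]))
      if (ns >= min_strains) {
        is_bg[idx[members]] <- TRUE
        rep_row <- g[members[1L], setdiff(names(g),
                     c("strain", "row_in_strain", "pos_b")), drop = FALSE]
        rep_row$n_strains <- ns
        bg_rows[[length(bg_rows) + 1L]] <- rep_row
      }
    }
  }
  filtered <- lapply(seq_along(per_strain), function(i) {
    drop_rows <- pooled$row_in_strain[is_bg & pooled$strain == strains[i]]
    df <- calls(per_strain[[i]])
    keep <- !(seq_len(nrow(df)) %in% drop_rows)
    per_strain[[i]][keep]
  })
  names(filtered) <- strains
  background <- if (length(bg_rows)) do.call(rbind, bg_rows)
                else cbind(emptySvCalls(), n_strains = integer(0))
  rownames(background) <- NULL
  list(filtered = filtered, background = background)
}
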