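# Binned read depth, normalization and the copy-number-ratio deletion /
# duplication indicator.

#' Binned raw read depth
#'
#' Each retained alignment adds 1 to the bin containing its leftmost
#' aligned base, so bin totals conserve the read count.
#'
#' @param alignments alignment data.frame.
#' @param contig_lengths named vector of contig lengths.
#' @param bin_size bin width in bases (>= 50, default 500).
#' @return named list of integer vectors, one per contig, of length
#'   \code{ceiling(length / bin_size)}.
#' @export
binnedDepth <- function(alignments, contig_lengths, bin_size = 500L) {
  stopifnot(bin_size >= 50L)
  out <- lapply(names(contig_lengths), function(ctg) {
    nb <- ceiling(contig_lengths[[ctg]] / bin_size)
    pos <- alignments$pos[alignments$contig == ctg]
    if (!length(pos)) return(integer(nb))
    tabulate(floor(pos / bin_size) + 1L, nbins = nb)
  })
  names(out) <- names(contig_lengths)
  out
}

#' Normalize binned depth by the genome-wide mean
#'
#' @param raw named list of raw bin counts (from \code{binnedDepth}).
#' @return list of numeric vectors with genome-wide mean 1.
#' @export
normalizeDepth <- function(raw) {
  all_bins <- unlist(raw, use.names = FALSE)
  m <- mean(all_bins)
  if (!is.finite(m) || m == 0) stop("cannot normalize: all bins are zero")
  lapply(raw, function(x) x / m)
}

#' Copy-number ratio of sample over control
#'
#' \code{ratio_i = sample_i / max(control_i, pseudo)}; bins whose control
#' depth is below \code{control_min} are masked (\code{NA}) as unreliable
#' denominators.
#'
#' @param sample_norm,control_norm normalized depth vectors of one contig.
#' @param pseudo denominator floor (default 0.05).
#' @param control_min masking threshold on the control (default 0.25).
#' @return numeric ratio vector with \code{NA} in masked bins.
#' @export
cnRatio <- function(sample_norm, control_norm, pseudo = 0.05,
                    control_min = 0.25) {
  stopifnot(length(sample_norm) == length(control_norm), pseudo > 0)
  r <- sample_norm / pmax(control_norm, pseudo)
  r[control_norm < control_min] <- NA_real_
  r
}

#' Build CopyNumberTrack objects for all contigs
#'
#' @param sample_aln,control_aln alignment data.frames of sample and
#'   control strain.
#' @param contig_lengths named vector of contig lengths.
#' @param bin_size bin width (default 500).
#' @param pseudo,control_min see \code{cnRatio}.
#' @return named list of \linkS4class{CopyNumberTrack}.
#' @export
buildCnTracks <- function(sample_aln, control_aln, contig_lengths,
                          bin_size = 500L, pseudo = 0.05,
                          control_min = 0.25) {
  s <- normalizeDepth(binnedDepth(sample_aln, contig_lengths, bin_size))
  c_ <- normalizeDepth(binnedDepth(control_aln, contig_lengths, bin_size))
  out <- lapply(names(contig_lengths), function(ctg) {
    r <- cnRatio(s[[ctg]], c_[[ctg]], pseudo, control_min)
    new("CopyNumberTrack", contig = ctg,
        contigLength = as.numeric(contig_lengths[[ctg]]),
        binSize = as.integer(bin_size),
        sampleNorm = s[[ctg]], controlNorm = c_[[ctg]],
        ratio = r, masked = is.na(r))
  })
  names(out) <- names(contig_lengths)
  out
}

#' Call copy-number segments by ratio thresholding
#'
#' Maximal runs of at least \code{min_bins} consecutive unmasked bins with
#' ratio at most \code{del_max} become DEL_CN segments; runs in
#' \code{[dup_min, mult_min)} become DUP_CN and runs at or above
#' \code{mult_min} become MULT_CN.  Masked bins break runs.
#'
#' @param track a \linkS4class{CopyNumberTrack}.
#' @param del_max,dup_min,mult_min ratio thresholds (defaults 0.25, 1.5,
#'   2.5; must be increasing).
#' @param min_bins minimal run length (default 2).
#' @return data.frame \code{contig, start, end, class, mean_ratio,
#'   n_bins} with 0-based half-open bin-aligned coordinates.
#' @export
callCnSegments <- function(track, del_max = 0.25, dup_min = 1.5,
                           mult_min = 2.5, min_bins = 2L) {
  stopifnot(del_max < dup_min, dup_min < mult_min)
  r <- cnRatioValues(track)
  state <- rep("NORM", length(r))
  state[!is.na(r) & r <= del_max] <- "DEL_CN"
  state[!is.na(r) & r >= dup_min & r < mult_min] <- "DUP_CN"
  state[!is.na(r) & r >= mult_min] <- "MULT_CN"
  state[is.na(r)] <- "MASK"
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values %in% c("DEL_CN", "DUP_CN", "MULT_CN") &
    runs$lengths >= min_bins
  bs <- binSize(track)
  clen <- track@contigLength
  res <- data.frame(
    contig = rep(contigName(track), sum(keep)),
    start = (starts[keep] - 1L) * bs,
    end = pmin(ends[keep] * bs, clen),
    class = runs$values[keep],
    mean_ratio = vapply(which(keep), function(i)
      mean(r[starts[i]:ends[i]]), numeric(1)),
    n_bins = runs$lengths[keep],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Export copy-number ratio tracks as bedGraph
#'
#' @param tracks list of \linkS4class{CopyNumberTrack}.
#' @param path output bedGraph path.
#' @export
exportRatioBedGraph <- function(tracks, path) {
  grl <- lapply(tracks, function(tr) {
    r <- cnRatioValues(tr)
    ok <- which(!is.na(r))
    if (!length(ok)) return(GenomicRanges::GRanges())
    bs <- binSize(tr)
    GenomicRanges::GRanges(
      contigName(tr),
      IRanges::IRanges(start = (ok - 1L) * bs + 1L,
                       end = pmin(ok * bs, tr@contigLength)),
      score = r[ok]
    )
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
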