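# Split-read breakpoint detection: soft-clip extraction, clip realignment,
# break-site pattern classification and evidence clustering.

#' Extract soft-clipped segments from alignments
#'
#' One segment per soft clip of at least \code{min_clip_len} bases.  The
#' anchor is the reference coordinate of the clip boundary: alignment
#' start for a left clip, alignment end for a right clip.  Hard clips
#' carry no sequence and are ignored.
#'
#' @param alignments alignment data.frame (see \code{readAlignments}).
#' @param min_clip_len minimum clip length in bases (default 15).
#' @return data.frame with columns \code{read_id, side, contig,
#'   anchor_pos, read_strand, clip_seq}.
#' @export
extractClipped <- function(alignments, min_clip_len = 15L) {
  stopifnot(min_clip_len >= 1L)
  if (!nrow(alignments)) {
    return(data.frame(read_id = character(0), side = character(0),
                      contig = character(0), anchor_pos = numeric(0),
                      read_strand = character(0), clip_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  lead <- leadingClip(alignments$cigar)
  trail <- trailingClip(alignments$cigar)
  if (!"ref_end" %in% names(alignments))
    alignments$ref_end <- alignments$pos + cigarRefWidth(alignments$cigar)
  out <- list()
  li <- which(lead >= min_clip_len)
  if (length(li)) {
    out$left <- data.frame(
      read_id = alignments$read_id[li], side = "left",
      contig = alignments$contig[li],
      anchor_pos = alignments$pos[li],
      read_strand = alignments$strand[li],
      clip_seq = substr(alignments$seq[li], 1L, lead[li]),
      stringsAsFactors = FALSE
    )
  }
  ti <- which(trail >= min_clip_len)
  if (length(ti)) {
    n <- nchar(alignments$seq[ti])
    out$right <- data.frame(
      read_id = alignments$read_id[ti], side = "right",
      contig = alignments$contig[ti],
      anchor_pos = alignments$ref_end[ti],
      read_strand = alignments$strand[ti],
      clip_seq = substr(alignments$seq[ti], n - trail[ti] + 1L, n),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- extractClipped(alignments[0, , drop = FALSE], min_clip_len)
  rownames(res) <- NULL
  res
}

.collect_hits <- function(pattern, genome, max.mismatch = 0L) {
  hits <- list()
  p <- Biostrings::DNAString(pattern)
  for (str in c("+", "-")) {
    pat <- if (str == "+") p else Biostrings::reverseComplement(p)
    m <- Biostrings::vmatchPattern(pat, genome, max.mismatch = max.mismatch)
    for (ci in seq_along(m)) {
      mm <- m[[ci]]
      if (!length(mm)) next
      st <- BiocGenerics::start(mm)
      en <- BiocGenerics::end(mm)
      keep <- st >= 1L & en <= Biostrings::width(genome)[ci]
      if (!any(keep)) next
      nm <- if (max.mismatch > 0L) {
        Biostrings::neditStartingAt(pat, genome[[ci]], starting.at = st[keep])
      } else rep(0L, sum(keep))
      hits[[length(hits) + 1L]] <- data.frame(
        contig = names(genome)[ci],
        start = st[keep] - 1L,       # 0-based
        end = en[keep],              # 0-based exclusive
        strand = str, mismatches = nm,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Realign a clipped segment against the reference
#'
#' Finds loci where the clip (or its reverse complement) aligns over its
#' full length with identity at least \code{min_identity}.  A unique best
#' hit is returned; no hit or more than one equally-best hit yields an
#' empty result (ambiguous clips are discarded).  When the full clip has
#' no acceptable locus and \code{side} is given, an anchor-and-extend pass
#' attempts to strip a novel (inserted) prefix of the clip: the terminal
#' \code{anchor_len} bases away from the junction are matched exactly and
#' extended toward the junction; the unmatched remainder is reported as
#' \code{novel}.
#'
#' @param clip_seq clip nucleotide string.
#' @param genome named \code{DNAStringSet}.
#' @param min_identity minimum full-length identity (default 0.95).
#' @param side \code{"left"} or \code{"right"}: which side of the primary
#'   alignment the clip came from (enables novel-prefix recovery), or
#'   \code{NULL} for full-length matching only.
#' @param anchor_len anchor length for novel-prefix recovery (default 18).
#' @param min_anchor minimal aligned clip part after trimming (default 12).
#' @return list with \code{hit} (0- or 1-row data.frame: contig, start,
#'   end, strand, mismatches) and \code{novel} (string, possibly empty).
#' @export
realignClip <- function(clip_seq, genome, min_identity = 0.95, side = NULL,
                        anchor_len = 18L, min_anchor = 12L) {
  empty <- list(hit = .collect_hits("A", genome)[0, ], novel = "")
  L <- nchar(clip_seq)
  if (L < min_anchor) return(empty)
  # 1) exact full-length
  hits <- .collect_hits(clip_seq, genome, 0L)
  if (nrow(hits) == 1L) return(list(hit = hits, novel = ""))
  if (nrow(hits) > 1L) return(empty)  # ambiguous
  # 2) mismatch-tolerant full-length
  mm <- floor(L * (1 - min_identity))
  if (mm >= 1L) {
    hits <- .collect_hits(clip_seq, genome, mm)
    if (nrow(hits)) {
      best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
      if (nrow(best) == 1L) return(list(hit = best, novel = ""))
      return(empty)
    }
  }
  # 3) anchor-and-extend: strip a novel segment adjacent to the junction
  if (is.null(side) || L < min_anchor + 1L) return(empty)
  a <- min(anchor_len, L - 1L)
  if (a < min_anchor) return(empty)
  if (side == "right") {
    anchor <- substr(clip_seq, L - a + 1L, L)
  } else {
    anchor <- substr(clip_seq, 1L, a)
  }
  ah <- .collect_hits(anchor, genome, 0L)
  ah <- ah[ah$strand == "+", , drop = FALSE]
  if (nrow(ah) != 1L) return(empty)
  ctg_seq <- as.character(genome[[ah$contig]])
  if (side == "right") {
    # clip = novel + reference suffix aligned ending at ah$end
    k <- 0L
    while (L - a - k >= 1L && ah$start - k >= 1L &&
           substr(clip_seq, L - a - k, L - a - k) ==
           substr(ctg_seq, ah$start - k, ah$start - k)) {
      k <- k + 1L
    }
    aligned <- a + k
    j <- L - aligned
    if (j < 1L || aligned < min_anchor) return(empty)
    hit <- data.frame(contig = ah$contig, start = ah$start - k,
                      end = ah$end, strand = "+", mismatches = 0L,
                      stringsAsFactors = FALSE)
    list(hit = hit, novel = substr(clip_seq, 1L, j))
  } else {
    # clip = reference prefix aligned starting at ah$start + novel
    k <- 0L
    while (a + 1L + k <= L && ah$end + 1L + k <= nchar(ctg_seq) &&
           substr(clip_seq, a + 1L + k, a + 1L + k) ==
           substr(ctg_seq, ah$end + 1L + k, ah$end + 1L + k)) {
      k <- k + 1L
    }
    aligned <- a + k
    j <- L - aligned
    if (j < 1L || aligned < min_anchor) return(empty)
    hit <- data.frame(contig = ah$contig, start = ah$start,
                      end = ah$end + k, strand = "+", mismatches = 0L,
                      stringsAsFactors = FALSE)
    list(hit = hit, novel = substr(clip_seq, L - j + 1L, L))
  }
}

#' Classify the break-site pattern of a split read
#'
#' Given the primary-anchor side and the realigned clip hit, assigns the
#' junction class in reference geometry: collinear same-contig hits give
#' DEL (gap downstream of a right-side anchor), DUP (hit back upstream),
#' INS (zero gap with a novel segment) or DELINS (positive gap with a
#' novel segment); opposite-strand hits give INV breakends; cross-contig
#' hits give TRA.
#'
#' @param anchor_contig,anchor_pos primary anchor (0-based clip boundary).
#' @param side \code{"left"} or \code{"right"}.
#' @param hit one-row data.frame from \code{realignClip}.
#' @param novel unmatched (inserted) sequence, possibly empty.
#' @param contig_order contig names in declared order (for canonical TRA
#'   breakend ordering); defaults to alphabetical.
#' @param clip_seq the full clip sequence (needed to reconstruct the
#'   inserted sequence of a junction whose representation shifted because
#'   inserted bases coincide with adjacent reference bases).
#' @return one-row data.frame \code{pattern, contig, start, end, contig2,
#'   pos2, novel, anchor_contig, anchor_pos} or \code{NULL} for an
#'   inconsistent combination.
#' @export
classifyPattern <- function(anchor_contig, anchor_pos, side, hit, novel = "",
                            contig_order = NULL, clip_seq = NULL) {
  if (is.null(hit) || nrow(hit) != 1L) return(NULL)
  p <- anchor_pos
  row <- function(pattern, contig, start, end, contig2 = NA_character_,
                  pos2 = NA_real_, nv = "") {
    data.frame(pattern = pattern, contig = contig, start = start, end = end,
               contig2 = contig2, pos2 = pos2, novel = nv,
               anchor_contig = anchor_contig, anchor_pos = anchor_pos,
               stringsAsFactors = FALSE)
  }
  if (hit$contig != anchor_contig) {
    partner <- if (hit$strand == "+") {
      if (side == "right") hit$start else hit$end
    } else {
      if (side == "right") hit$end else hit$start
    }
    ord <- contig_order %||% sort(c(anchor_contig, hit$contig))
    if (match(anchor_contig, ord) <= match(hit$contig, ord))
      return(row("TRA", anchor_contig, p, p, hit$contig, partner, novel))
    return(data.frame(pattern = "TRA", contig = hit$contig, start = partner,
                      end = partner, contig2 = anchor_contig, pos2 = p,
                      novel = novel, anchor_contig = anchor_contig,
                      anchor_pos = anchor_pos, stringsAsFactors = FALSE))
  }
  if (hit$strand == "-") {
    partner <- if (side == "right") hit$end else hit$start
    if (partner == p) return(NULL)
    return(row("INV", anchor_contig, min(p, partner), max(p, partner)))
  }
  L <- nchar(novel)
  if (side == "right") {
    h <- hit$start
    if (h > p) {
      if (nzchar(novel)) return(row("DELINS", anchor_contig, p, h, nv = novel))
      return(row("DEL", anchor_contig, p, h))
    }
    if (h == p) {
      if (nzchar(novel)) return(row("INS", anchor_contig, p, p, nv = novel))
      return(NULL)
    }
    # h < p: a tandem junction, unless a novel segment is present; then
    # this is an insertion whose representation shifted left by k = p - h
    # because its trailing bases coincide with the reference before the
    # junction.  Those k bases were consumed by the clip realignment and
    # sit right after the unmatched prefix in the clip.
    k <- p - h
    if (nzchar(novel) && !is.null(clip_seq) && k <= nchar(clip_seq) - L) {
      nv <- paste0(substr(clip_seq, L + 1L, L + k), substr(novel, 1L, L))
      return(row("INS", anchor_contig, h, h, nv = nv))
    }
    return(row("DUP", anchor_contig, h, p))
  }
  he <- hit$end
  if (he < p) {
    if (nzchar(novel)) return(row("DELINS", anchor_contig, he, p, nv = novel))
    return(row("DEL", anchor_contig, he, p))
  }
  if (he == p) {
    if (nzchar(novel)) return(row("INS", anchor_contig, p, p, nv = novel))
    return(NULL)
  }
  # he > p: mirrored case of the shifted insertion above (shift right);
  # the k bases consumed by the extension precede the unmatched suffix.
  k <- he - p
  Lc <- if (is.null(clip_seq)) 0L else nchar(clip_seq)
  if (nzchar(novel) && !is.null(clip_seq) && k <= Lc - L) {
    nv <- paste0(novel, substr(clip_seq, Lc - L - k + 1L, Lc - L))
    return(row("INS", anchor_contig, he, he, nv = nv))
  }
  row("DUP", anchor_contig, p, he)
}

#' Cluster per-read breakpoints into split-read evidence
#'
#' Breakpoints of the same pattern whose coordinates agree within
#' \code{tolerance} on both anchors merge into one evidence record.
#' Cluster coordinates are the modal values (ties broken by the smallest
#' coordinate); support counts distinct read ids, never alignments.
#' Evidence with support below \code{min_support} is dropped.
#'
#' @param raw per-read classified breakpoints: the row-bound output of
#'   \code{classifyPattern} plus columns \code{read_id} and
#'   \code{read_strand}.
#' @param tolerance clustering tolerance in bases (default 5).
#' @param min_support minimal distinct supporting reads (default 3).
#' @return evidence data.frame: \code{pattern, contig, start, end,
#'   contig2, pos2, novel_seq, support, fwd_support, rev_support,
#'   support_start, support_end, breakends}.
#' @export
clusterEvidence <- function(raw, tolerance = 5L, min_support = 3L) {
  stopifnot(tolerance >= 0L, min_support >= 1L)
  empty <- data.frame(pattern = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      contig2 = character(0), pos2 = numeric(0),
                      novel_seq = character(0), support = integer(0),
                      fwd_support = integer(0), rev_support = integer(0),
                      support_start = integer(0), support_end = integer(0),
                      breakends = integer(0), stringsAsFactors = FALSE)
  if (is.null(raw) || !nrow(raw)) return(empty)
  raw$pos_b <- ifelse(raw$pattern == "TRA", raw$pos2, raw$end)
  key <- paste(raw$pattern, raw$contig,
               ifelse(is.na(raw$contig2), "", raw$contig2))
  out <- list()
  for (k in unique(key)) {
    g <- raw[key == k, , drop = FALSE]
    g <- g[order(g$start, g$pos_b), , drop = FALSE]
    cl_id <- integer(nrow(g))
    cur <- 1L
    cl_id[1L] <- 1L
    for (i in seq_len(nrow(g))[-1L]) {
      if (g$start[i] - g$start[i - 1L] > tolerance ||
          abs(g$pos_b[i] - g$pos_b[i - 1L]) > tolerance) {
        cur <- cur + 1L
      }
      cl_id[i] <- cur
    }
    for (cid in seq_len(cur)) {
      m <- g[cl_id == cid, , drop = FALSE]
      first <- !duplicated(m$read_id)
      start <- modalValue(m$start)
      end_ <- modalValue(m$pos_b)
      # take the inserted sequence from reads agreeing with the modal
      # coordinate pair, so the (start, end, novel) triple stays a
      # self-consistent representation of the junction
      novel <- ""
      consistent <- m[m$start == start & m$pos_b == end_, , drop = FALSE]
      nz <- consistent$novel[nzchar(consistent$novel)]
      if (!length(nz)) nz <- m$novel[nzchar(m$novel)]
      if (length(nz)) novel <- modalValue(nz)
      near <- function(ctg, pos) {
        m$anchor_contig == ctg & abs(m$anchor_pos - pos) <= tolerance & first
      }
      s_start <- sum(near(m$contig[1L], start))
      s_end <- if (m$pattern[1L] == "TRA") {
        sum(near(m$contig2[1L], end_))
      } else sum(near(m$contig[1L], end_))
      brk <- length(unique(ifelse(
        abs(m$anchor_pos - start) <= abs(m$anchor_pos - end_), "s", "e")))
      out[[length(out) + 1L]] <- data.frame(
        pattern = m$pattern[1L], contig = m$contig[1L],
        start = start,
        end = if (m$pattern[1L] == "TRA") start else end_,
        contig2 = m$contig2[1L],
        pos2 = if (m$pattern[1L] == "TRA") end_ else NA_real_,
        novel_seq = novel,
        support = sum(first),
        fwd_support = sum(first & m$read_strand == "+"),
        rev_support = sum(first & m$read_strand == "-"),
        support_start = as.integer(s_start),
        support_end = as.integer(s_end),
        breakends = as.integer(brk),
        stringsAsFactors = FALSE
      )
    }
  }
  ev <- do.call(rbind, out)
  ev <- ev[ev$support >= min_support, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect split-read evidence from alignments
#'
#' Convenience wrapper running soft-clip extraction, clip realignment,
#' break-site classification and clustering.
#'
#' @param alignments alignment data.frame.
#' @param genome named \code{DNAStringSet}.
#' @param min_clip_len,min_identity,tolerance,min_support see the
#'   individual steps.
#' @return evidence data.frame (see \code{clusterEvidence}).
#' @export
detectSplitReads <- function(alignments, genome, min_clip_len = 15L,
                             min_identity = 0.95, tolerance = 5L,
                             min_support = 3L) {
  clips <- extractClipped(alignments, min_clip_len)
  if (!nrow(clips)) return(clusterEvidence(NULL, tolerance, min_support))
  contig_order <- names(genome)
  rows <- vector("list", nrow(clips))
  for (i in seq_len(nrow(clips))) {
    ra <- realignClip(clips$clip_seq[i], genome, min_identity,
                      side = clips$side[i])
    if (!nrow(ra$hit)) next
    cls <- classifyPattern(clips$contig[i], clips$anchor_pos[i],
                           clips$side[i], ra$hit, ra$novel, contig_order,
                           clip_seq = clips$clip_seq[i])
    if (is.null(cls)) next
    cls$read_id <- clips$read_id[i]
    cls$read_strand <- clips$read_strand[i]
    rows[[i]] <- cls
  }
  raw <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  clusterEvidence(raw, tolerance, min_support)
}
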