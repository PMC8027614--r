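# Synthetic data generation: random genomes, engineered variants applied
# as haplotype block chains, single-end read simulation with alignment
# emulation (reads crossing an engineered junction are emitted as
# reference alignments with exact soft clips), and labeled candidate sets
# for the machine-learning filter.

#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with \code{P(A) = P(T) = at_fraction / 2} and
#' \code{P(C) = P(G) = (1 - at_fraction) / 2}.  Deterministic given
#' \code{seed}.
#'
#' @param contig_lengths named vector of contig lengths (>= 10 kb total).
#' @param at_fraction genome A+T fraction (default 0.645, nematode-like).
#' @param seed integer seed.
#' @return named \code{DNAStringSet}.
#' @export
simulateGenome <- function(contig_lengths = c(chrI = 1e6), at_fraction = 0.645,
                           seed = 1L) {
  stopifnot(sum(contig_lengths) >= 1e4, at_fraction >= 0, at_fraction <= 1,
            !is.null(names(contig_lengths)))
  withSeed(seed, {
    p <- c(A = at_fraction / 2, T = at_fraction / 2,
           C = (1 - at_fraction) / 2, G = (1 - at_fraction) / 2)
    seqs <- vapply(contig_lengths, function(len) {
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

.ref_block <- function(src, s, e, strand = "+") {
  data.frame(src = src, s = s, e = e, strand = strand, novel = "",
             stringsAsFactors = FALSE)
}

.novel_block <- function(seq) {
  data.frame(src = NA_character_, s = NA_real_, e = NA_real_, strand = "+",
             novel = seq, stringsAsFactors = FALSE)
}

.block_lengths <- function(blocks) {
  ifelse(is.na(blocks$src), nchar(blocks$novel), blocks$e - blocks$s)
}

# Assemble the block chain of one contig carrying the given (sorted,
# non-overlapping) intra-contig variants.
.contig_blocks <- function(ctg, ctg_len, vars) {
  blocks <- list()
  cursor <- 0
  add <- function(b) if (nrow(b) && all(.block_lengths(b) > 0))
    blocks[[length(blocks) + 1L]] <<- b
  if (nrow(vars)) {
    vars <- vars[order(vars$start), , drop = FALSE]
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      s <- v$start; L <- v$length
      switch(v$svtype,
        DEL = {
          add(.ref_block(ctg, cursor, s)); cursor <- s + L
        },
        DELINS = {
          add(.ref_block(ctg, cursor, s)); add(.novel_block(v$novel_seq))
          cursor <- s + L
        },
        INS = {
          add(.ref_block(ctg, cursor, s)); add(.novel_block(v$novel_seq))
          cursor <- s
        },
        DUP = {
          add(.ref_block(ctg, cursor, s + L)); add(.ref_block(ctg, s, s + L))
          cursor <- s + L
        },
        MULT = {
          add(.ref_block(ctg, cursor, s + L)); add(.ref_block(ctg, s, s + L))
          add(.ref_block(ctg, s, s + L)); cursor <- s + L
        },
        INV = {
          add(.ref_block(ctg, cursor, s))
          add(.ref_block(ctg, s, s + L, strand = "-"))
          cursor <- s + L
        },
        stop("unsupported intra-contig svtype: ", v$svtype)
      )
    }
  }
  add(.ref_block(ctg, cursor, ctg_len))
  do.call(rbind, blocks)
}

# Split a block chain at a reference coordinate (must fall inside a
# forward reference block); returns list(head, tail).
.split_chain <- function(blocks, refpos) {
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (!is.na(b$src) && b$strand == "+" && b$s <= refpos && refpos < b$e) {
      head <- blocks[seq_len(i - 1L), , drop = FALSE]
      tail <- blocks[-seq_len(i), , drop = FALSE]
      if (refpos > b$s) head <- rbind(head, .ref_block(b$src, b$s, refpos))
      tail <- rbind(.ref_block(b$src, refpos, b$e), tail)
      return(list(head = head, tail = tail))
    }
  }
  stop("translocation breakpoint does not fall in a forward reference block")
}

#' Apply engineered variants to a genome
#'
#' Builds the pair of haplotype block chains: homozygous variants are
#' applied to both haplotypes, heterozygous to one.  The returned truth
#' table records the reference coordinates of every engineered junction.
#'
#' @param genome named \code{DNAStringSet}.
#' @param specs data.frame with columns \code{svtype, contig, start,
#'   length, novel_seq, zygosity} and, for TRA, \code{contig2, pos2}.
#'   Specs must be non-overlapping per contig.
#' @return list with \code{haplotypes} (list of two per-contig block-chain
#'   lists) and \code{truth} (data.frame \code{svtype, contig, start, end,
#'   novel_seq, zygosity, contig2, pos2}).
#' @export
applyVariants <- function(genome, specs) {
  cl <- genomeContigLengths(genome)
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  if (!"contig2" %in% names(specs)) specs$contig2 <- NA_character_
  if (!"pos2" %in% names(specs)) specs$pos2 <- NA_real_
  if (!"novel_seq" %in% names(specs)) specs$novel_seq <- ""
  specs$novel_seq[is.na(specs$novel_seq)] <- ""
  # overlap validation (intra-contig footprint; INS counts as 1 base)
  for (ctg in unique(specs$contig)) {
    v <- specs[specs$contig == ctg & specs$svtype != "TRA", , drop = FALSE]
    if (nrow(v) > 1L) {
      span <- ifelse(v$svtype == "INS", 1, v$length)
      o <- order(v$start)
      if (any(v$start[o][-1L] < (v$start + span)[o][-nrow(v)]))
        stop("overlapping variant specs on ", ctg)
    }
    if (any(v$start + ifelse(v$svtype == "INS", 0, v$length) > cl[[ctg]]))
      stop("variant spec exceeds contig length on ", ctg)
  }
  build <- function(sub) {
    chains <- lapply(names(cl), function(ctg) {
      .contig_blocks(ctg, cl[[ctg]],
                     sub[sub$contig == ctg & sub$svtype != "TRA", , drop = FALSE])
    })
    names(chains) <- names(cl)
    tra <- sub[sub$svtype == "TRA", , drop = FALSE]
    for (i in seq_len(nrow(tra))) {
      a <- tra$contig[i]; b <- tra$contig2[i]
      sa <- .split_chain(chains[[a]], tra$start[i])
      sb <- .split_chain(chains[[b]], tra$pos2[i])
      chains[[a]] <- rbind(sa$head, sb$tail)
      chains[[b]] <- rbind(sb$head, sa$tail)
    }
    chains
  }
  h1 <- build(specs)                                    # all variants
  h2 <- build(specs[specs$zygosity == "hom", , drop = FALSE])
  truth <- data.frame(
    svtype = specs$svtype, contig = specs$contig, start = specs$start,
    end = ifelse(specs$svtype %in% c("INS", "TRA"), specs$start,
                 specs$start + specs$length),
    novel_seq = specs$novel_seq, zygosity = specs$zygosity,
    contig2 = specs$contig2, pos2 = specs$pos2,
    stringsAsFactors = FALSE
  )
  list(haplotypes = list(h1 = h1, h2 = h2), truth = truth)
}

# Character sequence of a block chain.
.chain_seq <- function(blocks, genome_chr) {
  pieces <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    if (is.na(b$src)) return(b$novel)
    s <- substr(genome_chr[[b$src]], b$s + 1L, b$e)
    if (b$strand == "-") s <- reverseComplementChar(s)
    s
  }, character(1))
  paste(pieces, collapse = "")
}

.apply_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads[1L])
  n_err <- stats::rbinom(length(reads), rl, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(rl, n_err[i])
    r <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in at) r[p] <- sample(setdiff(bases, r[p]), 1L)
    reads[i] <- paste(r, collapse = "")
  }
  reads
}

#' Simulate single-end reads aligned to the original reference
#'
#' Reads are drawn uniformly from both haplotypes at the configured total
#' depth.  Reads lying inside a single reference block are emitted as
#' plain full-length alignments; reads crossing an engineered junction are
#' emitted as reference alignments of their longest reference piece with
#' exact soft clips at the junction (alignment emulation; no external
#' aligner).  Reads whose longest reference piece is shorter than
#' \code{min_anchor} bases, or which lie inside novel (inserted)
#' sequence, are treated as unmappable and skipped.  Deterministic given
#' \code{seed}.
#'
#' @param haplotypes haplotype block chains from \code{applyVariants}.
#' @param genome named \code{DNAStringSet} (the original reference).
#' @param read_length read length in bases (default 120).
#' @param depth total target depth (default 20; split evenly across the
#'   two haplotypes).
#' @param error_rate per-base substitution error rate (default 0).
#' @param seed integer seed.
#' @param min_anchor minimal aligned piece for a read to be mappable
#'   (default 25).
#' @param prefix read-name prefix (default \code{"r"}).
#' @return alignment data.frame (same columns as \code{readAlignments}).
#' @export
simulateReads <- function(haplotypes, genome, read_length = 120L, depth = 20,
                          error_rate = 0, seed = 1L, min_anchor = 25L,
                          prefix = "r") {
  genome_chr <- as.list(as.character(genome))
  withSeed(seed, {
    out <- list()
    for (h in seq_along(haplotypes)) {
      chains <- haplotypes[[h]]
      for (ctg in names(chains)) {
        blocks <- chains[[ctg]]
        lens <- .block_lengths(blocks)
        bstart <- cumsum(c(0, lens))[seq_along(lens)]
        hap_len <- sum(lens)
        if (hap_len < read_length) next
        n <- round(depth / 2 * hap_len / read_length)
        if (n < 1L) next
        rs <- sample.int(hap_len - read_length + 1L, n, replace = TRUE) - 1L
        hapseq <- .chain_seq(blocks, genome_chr)
        reads <- substring(hapseq, rs + 1L, rs + read_length)
        reads <- .apply_errors(reads, error_rate)
        ids <- sprintf("%s_h%d_%s_%06d", prefix, h, ctg, seq_len(n))
        b1 <- findInterval(rs, bstart)
        b2 <- findInterval(rs + read_length - 1L, bstart)
        simple <- b1 == b2 & !is.na(blocks$src[b1])
        # vectorized single-block reads
        si <- which(simple)
        if (length(si)) {
          bi <- b1[si]
          off <- rs[si] - bstart[bi]
          fwd <- blocks$strand[bi] == "+"
          pos <- ifelse(fwd, blocks$s[bi] + off,
                        blocks$e[bi] - off - read_length)
          seqs <- reads[si]
          if (any(!fwd)) seqs[!fwd] <- reverseComplementChar(seqs[!fwd])
          out[[length(out) + 1L]] <- data.frame(
            read_id = ids[si], contig = blocks$src[bi], pos = pos,
            strand = ifelse(fwd, "+", "-"),
            cigar = sprintf("%dM", read_length), mapq = 60L, seq = seqs,
            supplementary = FALSE, ref_end = pos + read_length,
            stringsAsFactors = FALSE
          )
        }
        # junction-crossing (or novel-block) reads
        for (i in which(!simple)) {
          pieces <- list()
          for (k in b1[i]:b2[i]) {
            ov_s <- max(rs[i], bstart[k])
            ov_e <- min(rs[i] + read_length, bstart[k] + lens[k])
            pl <- ov_e - ov_s
            if (pl <= 0) next
            o <- ov_s - bstart[k]
            if (is.na(blocks$src[k])) next   # novel sequence: unalignable
            ref_start <- if (blocks$strand[k] == "+") blocks$s[k] + o
                         else blocks$e[k] - o - pl
            pieces[[length(pieces) + 1L]] <- list(
              q0 = ov_s - rs[i], pl = pl, contig = blocks$src[k],
              ref_start = ref_start, strand = blocks$strand[k])
          }
          if (!length(pieces)) next
          plens <- vapply(pieces, `[[`, numeric(1), "pl")
          pr <- pieces[[which.max(plens)]]
          if (pr$pl < min_anchor) next
          lead <- pr$q0
          trail <- read_length - pr$q0 - pr$pl
          seq_out <- reads[i]
          if (pr$strand == "-") {
            seq_out <- reverseComplementChar(seq_out)
            tmp <- lead; lead <- trail; trail <- tmp
          }
          cig <- paste0(if (lead > 0) sprintf("%dS", lead) else "",
                        sprintf("%dM", pr$pl),
                        if (trail > 0) sprintf("%dS", trail) else "")
          out[[length(out) + 1L]] <- data.frame(
            read_id = ids[i], contig = pr$contig, pos = pr$ref_start,
            strand = pr$strand, cigar = cig, mapq = 60L, seq = seq_out,
            supplementary = FALSE, ref_end = pr$ref_start + pr$pl,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(read_id = character(0), contig = character(0),
                        pos = numeric(0), strand = character(0),
                        cigar = character(0), mapq = integer(0),
                        seq = character(0), supplementary = logical(0),
                        ref_end = numeric(0), stringsAsFactors = FALSE)
    }
    rownames(res) <- NULL
    res
  })
}

.random_seq <- function(n, at_fraction = 0.5) {
  p <- c(A = at_fraction / 2, T = at_fraction / 2,
         C = (1 - at_fraction) / 2, G = (1 - at_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Draw a random set of engineered variant specs
#'
#' Places non-overlapping variants with generous spacing so that
#' junctions do not interact: log-uniform deletion sizes of 60-5000 bp,
#' duplications 1000-4000 bp, multiplications (triplications) 1500-4000
#' bp, insertions of 20-40 novel bases, deletion-insertions (60-2000 bp
#' deleted, 10-30 inserted), inversions 500-5000 bp and reciprocal
#' translocations between two contigs.  Heterozygosity is assigned with
#' probability \code{het_fraction} to copy-neutral and copy-loss types;
#' copy-gain variants are kept homozygous (see the methods vignette).
#'
#' @param contig_lengths named vector of contig lengths.
#' @param n_del,n_dup,n_mult,n_ins,n_delins,n_inv,n_tra variant counts
#'   (defaults 30/5/2/5/4/3/1, a deletion-dominated spectrum).
#' @param het_fraction probability of a heterozygous spec (default 0.3).
#' @param min_gap minimal spacing between variant footprints (default
#'   1500).
#' @param margin distance kept free at contig ends (default 3000).
#' @param seed integer seed.
#' @return spec data.frame accepted by \code{applyVariants}.
#' @export
randomVariantSpecs <- function(contig_lengths, n_del = 30L, n_dup = 5L,
                               n_mult = 2L, n_ins = 5L, n_delins = 4L,
                               n_inv = 3L, n_tra = 1L, het_fraction = 0.3,
                               min_gap = 1500L, margin = 3000L, seed = 1L) {
  if (n_tra > 0L && length(contig_lengths) < 2L)
    stop("translocations require at least two contigs")
  withSeed(seed, {
    types <- c(rep("DEL", n_del), rep("DUP", n_dup), rep("MULT", n_mult),
               rep("INS", n_ins), rep("DELINS", n_delins), rep("INV", n_inv))
    sizes <- vapply(types, function(tp) {
      switch(tp,
        DEL = round(exp(stats::runif(1, log(60), log(5000)))),
        DUP = round(stats::runif(1, 1000, 4000)),
        MULT = round(stats::runif(1, 1500, 4000)),
        INS = 0,
        DELINS = round(exp(stats::runif(1, log(60), log(2000)))),
        INV = round(stats::runif(1, 500, 5000)))
    }, numeric(1))
    taken <- lapply(names(contig_lengths), function(x) NULL)
    names(taken) <- names(contig_lengths)
    place <- function(ctg, span) {
      lo <- margin
      hi <- contig_lengths[[ctg]] - margin - span
      if (hi <= lo) return(NA_real_)
      for (try in 1:200) {
        s <- round(stats::runif(1, lo, hi))
        iv <- c(s - min_gap, s + span + min_gap)
        ok <- TRUE
        for (t in taken[[ctg]]) if (iv[1] < t[2] && t[1] < iv[2]) { ok <- FALSE; break }
        if (ok) {
          taken[[ctg]][[length(taken[[ctg]]) + 1L]] <<- c(s, s + span)
          return(s)
        }
      }
      NA_real_
    }
    rows <- list()
    for (i in seq_along(types)) {
      ctg <- sample(names(contig_lengths), 1L,
                    prob = as.numeric(contig_lengths))
      span <- max(sizes[i], 1)
      s <- place(ctg, span)
      if (is.na(s)) next
      tp <- types[i]
      nv <- switch(tp,
        INS = .random_seq(round(stats::runif(1, 20, 40))),
        DELINS = .random_seq(round(stats::runif(1, 10, 30))),
        "")
      zyg <- if (tp %in% c("DUP", "MULT")) "hom"
             else if (stats::runif(1) < het_fraction) "het" else "hom"
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = tp, contig = ctg, start = s, length = sizes[i],
        novel_seq = nv, zygosity = zyg, contig2 = NA_character_,
        pos2 = NA_real_, is_background = FALSE, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_tra)) {
      cts <- sample(names(contig_lengths), 2L)
      a <- place(cts[1L], 1)
      b <- place(cts[2L], 1)
      if (is.na(a) || is.na(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = "TRA", contig = cts[1L], start = a, length = NA_real_,
        novel_seq = "", zygosity = "hom", contig2 = cts[2L], pos2 = b,
        is_background = FALSE, stringsAsFactors = FALSE)
    }
    specs <- do.call(rbind, rows)
    rownames(specs) <- NULL
    specs
  })
}

#' Simulate one strain: apply variants and draw reads
#'
#' @param genome named \code{DNAStringSet}.
#' @param specs variant specs (possibly empty for a control strain).
#' @param depth,read_length,error_rate,seed,min_anchor see
#'   \code{simulateReads}.
#' @param prefix read-name prefix.
#' @return list \code{alignments, truth, haplotypes}.
#' @export
simulateStrain <- function(genome, specs = NULL, depth = 20,
                           read_length = 120L, error_rate = 0, seed = 1L,
                           min_anchor = 25L, prefix = "s") {
  if (is.null(specs) || !nrow(specs)) {
    specs <- data.frame(svtype = character(0), contig = character(0),
                        start = numeric(0), length = numeric(0),
                        novel_seq = character(0), zygosity = character(0),
                        contig2 = character(0), pos2 = numeric(0),
                        stringsAsFactors = FALSE)
  }
  av <- applyVariants(genome, specs)
  aln <- simulateReads(av$haplotypes, genome, read_length = read_length,
                       depth = depth, error_rate = error_rate, seed = seed,
                       min_anchor = min_anchor, prefix = prefix)
  list(alignments = aln, truth = av$truth, haplotypes = av$haplotypes)
}

#' Generate a labeled synthetic candidate set for the ML filter
#'
#' True candidates emulate confirmed homozygous deletions (high variant
#' frequency, copy-number ratio near zero, strong split-read support,
#' balanced strands); false candidates emulate unconfirmed artifacts (low
#' frequency, near-normal ratio, weak skewed support).  Positions are
#' uniform over the genome and deletion lengths log-normal; both are
#' class-uninformative by construction.
#'
#' @param n_true,n_false class sizes (each >= 10).
#' @param seed integer seed.
#' @param genome_size genome size used for absolute positions.
#' @return data.frame of feature columns \code{abs_pos, log_del_len,
#'   log_ins_len, cn_ratio, depth_diff, frequency, split_total,
#'   strand_bias} plus \code{label} (1 = confirmed, 0 = not).
#' @export
makeMlDataset <- function(n_true = 250L, n_false = 250L, seed = 1L,
                          genome_size = assayConstants()$genome_size) {
  stopifnot(n_true >= 10L, n_false >= 10L)
  withSeed(seed, {
    n <- n_true + n_false
    label <- rep(c(1L, 0L), c(n_true, n_false))
    tr <- label == 1L
    cn <- numeric(n)
    cn[tr] <- pmax(stats::rnorm(n_true, 0.05, 0.05), 0)
    cn[!tr] <- pmax(stats::rnorm(n_false, 0.9, 0.15), 0)
    freq <- numeric(n)
    freq[tr] <- stats::rbeta(n_true, 8, 2)
    freq[!tr] <- stats::rbeta(n_false, 2, 8)
    split_total <- integer(n)
    split_total[tr] <- stats::rpois(n_true, 8) + 3L
    split_total[!tr] <- stats::rpois(n_false, 2) + 1L
    sb <- numeric(n)
    sb[tr] <- stats::rbeta(n_true, 2, 2)
    sb[!tr] <- 1 - stats::rbeta(n_false, 1, 5)
    del_len <- round(stats::rlnorm(n, log(200), 1)) + 50
    ins_len <- ifelse(stats::runif(n) < 0.1,
                      round(stats::rlnorm(n, log(10), 0.8)), 0)
    depth_diff <- (1 - cn) + stats::rnorm(n, 0, 0.05)
    df <- data.frame(
      abs_pos = round(stats::runif(n, 0, genome_size)),
      log_del_len = log10(del_len + 1),
      log_ins_len = log10(ins_len + 1),
      cn_ratio = cn,
      depth_diff = depth_diff,
      frequency = freq,
      split_total = split_total,
      strand_bias = sb,
      label = label,
      stringsAsFactors = FALSE
    )
    df[sample.int(n), , drop = FALSE] -> df
    rownames(df) <- NULL
    df
  })
}
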