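#' Read a reference genome from FASTA
#'
#' Loads all contigs, uppercases the sequence and maps any base outside
#' \{A,C,G,T,N\} to N.  Contig names are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path FASTA file.
#' @return A named \code{DNAStringSet} (the package's genome reference).
#' @export
#' @importFrom Biostrings readDNAStringSet DNAStringSet width
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  if (length(x) == 0L) stop("malformed FASTA: no records in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate contig names in ", path)
  if (any(Biostrings::width(x) == 0L)) stop("empty contig in ", path)
  s <- toupper(as.character(x))
  s <- gsub("[^ACGTN]", "N", s)
  Biostrings::DNAStringSet(s)
}

#' Contig lengths of a genome reference
#' @param genome named \code{DNAStringSet} from \code{readGenome}.
#' @return named numeric vector, in declared order.
#' @export
genomeContigLengths <- function(genome) {
  stats::setNames(as.numeric(Biostrings::width(genome)), names(genome))
}

#' Read alignments from SAM or BAM
#'
#' Unmapped and secondary records are skipped; supplementary records are
#' retained and flagged.  Coordinates are converted to 0-based.  Records
#' whose CIGAR query span disagrees with the stored sequence length are
#' dropped with a warning giving the count.
#'
#' @param path SAM (converted internally) or BAM file.
#' @return data.frame with columns \code{read_id, contig, pos} (0-based),
#'   \code{strand, cigar, mapq, seq, supplementary, ref_end} (0-based
#'   exclusive).
#' @export
#' @importFrom Rsamtools asBam BamFile scanBam ScanBamParam scanBamFlag
readAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  )
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)[[1]]
  keep <- bitwAnd(res$flag, 4L) == 0L & bitwAnd(res$flag, 256L) == 0L
  df <- data.frame(
    read_id = res$qname[keep],
    contig = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L,
    strand = as.character(res$strand[keep]),
    cigar = res$cigar[keep],
    mapq = res$mapq[keep],
    seq = as.character(res$seq[keep]),
    supplementary = bitwAnd(res$flag[keep], 2048L) > 0L,
    stringsAsFactors = FALSE
  )
  df <- .validate_alignment_records(df)
  df$ref_end <- df$pos + cigarRefWidth(df$cigar)
  rownames(df) <- NULL
  df
}

# Record-level sanity: the query-consuming CIGAR span must equal the
# stored sequence length; offending records are skipped with a count.
# (htslib-backed readers reject such records at parse time; this guard
# covers in-memory producers and any laxer upstream.)
.validate_alignment_records <- function(df) {
  qw <- cigarQueryWidth(df$cigar)
  has_seq <- df$seq != "" & df$seq != "*"
  bad <- has_seq & qw != nchar(df$seq)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: CIGAR/sequence length mismatch")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Write alignments as SAM
#'
#' @param alignments alignment data.frame (see \code{readAlignments}).
#' @param contig_lengths named vector of reference contig lengths.
#' @param path output SAM path.
#' @export
writeSam <- function(alignments, contig_lengths, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths))
  )
  flag <- ifelse(alignments$strand == "-", 16L, 0L) +
    ifelse(isTRUE(alignments$supplementary) | (alignments$supplementary %in% TRUE),
           2048L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   alignments$read_id, flag, alignments$contig,
                   alignments$pos + 1L, alignments$mapq,
                   alignments$cigar, alignments$seq)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write structural variant calls as VCF 4.2
#'
#' Symbolic ALT alleles with SVTYPE/SVLEN/END INFO keys.  POS is the
#' 1-based base before the breakpoint, i.e. numerically equal to the
#' internal 0-based start.  Complex deletion-insertions are emitted as
#' DEL records carrying the inserted sequence in INSSEQ; translocations
#' carry the partner breakend in CHR2/POS2.  Input must be sorted by
#' contig (declared order) then start.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param path output VCF path.
#' @param genome optional \code{DNAStringSet}; supplies REF bases.
#' @export
writeVariantVcf <- function(callset, path, genome = NULL) {
  stopifnot(is(callset, "SVCallSet"))
  df <- calls(callset)
  cl <- contigLengths(callset)
  if (nrow(df)) {
    ord_contig <- match(df$contig, names(cl))
    if (any(order(ord_contig, df$start) != seq_len(nrow(df))))
      stop("calls must be sorted by contig then start")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svharvest",
    sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=MULT,Description=\"Multiplication (>2 copies)\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=TRA,Description=\"Translocation breakend pair\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant (1-based inclusive of the last deleted base)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed variant length\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner contig of a translocation\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Partner breakpoint (1-based base before break)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Distinct split reads supporting the junction\">",
    "##INFO=<ID=FWD,Number=1,Type=Integer,Description=\"Forward-strand supporting reads\">",
    "##INFO=<ID=REV,Number=1,Type=Integer,Description=\"Reverse-strand supporting reads\">",
    "##INFO=<ID=FREQ,Number=1,Type=Float,Description=\"Variant frequency at the breakpoint\">",
    "##INFO=<ID=CNR,Number=1,Type=Float,Description=\"Mean copy-number ratio over the variant\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity call\">",
    "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Evidence source\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Bin-resolution coordinates only\">",
    "##INFO=<ID=CATEGORY,Number=1,Type=String,Description=\"Overlapped feature category\">",
    "##INFO=<ID=SUBCATEGORY,Number=1,Type=String,Description=\"Intergenic subcategory\">",
    "##INFO=<ID=GENES,Number=1,Type=String,Description=\"Affected gene ids\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(df)) {
    emit_type <- ifelse(df$svtype == "DELINS", "DEL", df$svtype)
    pos <- as.integer(df$start)            # 1-based base before breakpoint
    refbase <- rep("N", nrow(df))
    if (!is.null(genome)) {
      ok <- df$start >= 1
      refbase[ok] <- vapply(which(ok), function(i) {
        as.character(Biostrings::subseq(genome[[df$contig[i]]],
                                        start = df$start[i], width = 1L))
      }, character(1))
    }
    svlen <- ifelse(df$svtype %in% c("DEL", "DELINS"), -(df$end - df$start),
             ifelse(df$svtype %in% c("DUP", "MULT", "INV"), df$end - df$start,
             ifelse(df$svtype == "INS", nchar(df$novel_seq), NA)))
    info <- vapply(seq_len(nrow(df)), function(i) {
      kv <- c(sprintf("SVTYPE=%s", emit_type[i]))
      if (df$svtype[i] != "TRA")
        kv <- c(kv, sprintf("END=%d", as.integer(df$end[i])))
      if (!is.na(svlen[i])) kv <- c(kv, sprintf("SVLEN=%d", as.integer(svlen[i])))
      if (nzchar(df$novel_seq[i])) kv <- c(kv, sprintf("INSSEQ=%s", df$novel_seq[i]))
      if (df$svtype[i] == "TRA")
        kv <- c(kv, sprintf("CHR2=%s", df$contig2[i]),
                sprintf("POS2=%d", as.integer(df$pos2[i])))
      kv <- c(kv, sprintf("SUPPORT=%d", df$support[i]),
              sprintf("FWD=%d", df$fwd_support[i]),
              sprintf("REV=%d", df$rev_support[i]))
      if (!is.na(df$frequency[i])) kv <- c(kv, sprintf("FREQ=%.4f", df$frequency[i]))
      if (!is.na(df$cn_ratio_mean[i])) kv <- c(kv, sprintf("CNR=%.4f", df$cn_ratio_mean[i]))
      kv <- c(kv, sprintf("ZYG=%s", df$zygosity[i]),
              sprintf("SOURCE=%s", df$source[i]))
      if (!df$precise[i]) kv <- c(kv, "IMPRECISE")
      for (key in c("CATEGORY", "SUBCATEGORY", "GENES")) {
        lkey <- tolower(key)
        if (lkey %in% names(df) && !is.na(df[[lkey]][i]) && nzchar(df[[lkey]][i]))
          kv <- c(kv, sprintf("%s=%s", key, df[[lkey]][i]))
      }
      paste(kv, collapse = ";")
    }, character(1))
    body <- sprintf("%s\t%d\t%s\t%s\t<%s>\t.\t%s\t%s",
                    df$contig, pos, df$id, refbase, emit_type,
                    df$filter, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

.vcf_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Read structural variant calls from a VCF written by writeVariantVcf
#'
#' Restores typed fields, including DELINS records emitted as DEL with an
#' INSSEQ key, so that \code{readVariantVcf(writeVariantVcf(x))} preserves
#' type, coordinates and length.
#'
#' @param path VCF file.
#' @return An \linkS4class{SVCallSet}.
#' @export
readVariantVcf <- function(path) {
  lines <- readLines(path)
  ctg <- regmatches(lines, regexec("^##contig=<ID=([^,>]+),length=(\\d+)>", lines))
  ctg <- ctg[lengths(ctg) == 3L]
  cl <- stats::setNames(as.numeric(vapply(ctg, `[`, "", 3L)),
                        vapply(ctg, `[`, "", 2L))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body)) return(SVCallSet(contigLengths = cl))
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[`, "", 8L)
  svtype <- .vcf_info_field(info, "SVTYPE")
  insseq <- .vcf_info_field(info, "INSSEQ")
  insseq[is.na(insseq)] <- ""
  svtype[svtype == "DEL" & nzchar(insseq)] <- "DELINS"
  start <- as.numeric(vapply(f, `[`, "", 2L))
  end <- as.numeric(.vcf_info_field(info, "END"))
  num <- function(key) suppressWarnings(as.numeric(.vcf_info_field(info, key)))
  int <- function(key) {
    v <- suppressWarnings(as.integer(.vcf_info_field(info, key)))
    ifelse(is.na(v), 0L, v)
  }
  chr_ <- function(key, default = NA_character_) {
    v <- .vcf_info_field(info, key)
    ifelse(is.na(v), default, v)
  }
  len <- ifelse(svtype == "INS", nchar(insseq),
         ifelse(svtype == "TRA", NA_real_, end - start))
  df <- data.frame(
    id = vapply(f, `[`, "", 3L),
    svtype = svtype,
    contig = vapply(f, `[`, "", 1L),
    start = start,
    end = ifelse(is.na(end), start, end),
    contig2 = chr_("CHR2"),
    pos2 = num("POS2"),
    length = len,
    novel_seq = insseq,
    frequency = num("FREQ"),
    zygosity = chr_("ZYG", "unknown"),
    support = int("SUPPORT"),
    fwd_support = int("FWD"),
    rev_support = int("REV"),
    cn_ratio_mean = num("CNR"),
    precise = !grepl("(^|;)IMPRECISE(;|$)", info),
    source = chr_("SOURCE", "split_only"),
    filter = vapply(f, `[`, "", 7L),
    stringsAsFactors = FALSE
  )
  SVCallSet(df, contigLengths = cl)
}

#' Build a FeatureDB from GFF3 gene models and a regulatory BED
#'
#' Gene-linked features are classified as CDS, UTR, exon (exonic sequence
#' outside CDS/UTR) and intron (gene span minus exons, derived when the
#' GFF3 lacks explicit introns); pseudogene spans are kept as their own
#' kind.  Regulatory regions come from a BED-like file with a fifth
#' \code{kind} column (see \code{readRegulatoryBed}).
#'
#' @param gff_path GFF3 gene models.
#' @param regulatory_bed optional regulatory BED+kind file.
#' @return A \linkS4class{FeatureDB}.
#' @export
#' @importFrom GenomicRanges GRanges reduce setdiff start end
#' @importFrom IRanges IRanges
readFeatureDB <- function(gff_path, regulatory_bed = NULL) {
  if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1))

  is_gene <- type %in% c("gene", "pseudogene")
  gene_ids <- ids[is_gene]
  genes <- gr[is_gene]
  genes$gene_id <- gene_ids

  # transcript -> gene map
  is_tx <- type %in% c("mRNA", "transcript", "pseudogenic_transcript",
                       "ncRNA", "tRNA", "rRNA")
  tx2gene <- stats::setNames(parents[is_tx], ids[is_tx])
  owner_gene <- function(i) {
    p <- parents[i]
    if (is.na(p)) return(NA_character_)
    if (p %in% gene_ids) return(p)
    g <- tx2gene[p]
    if (!is.na(g) && g %in% gene_ids) return(unname(g))
    NA_character_
  }

  feat_list <- list()
  add_feat <- function(ranges, kind, gid) {
    if (!length(ranges)) return()
    ranges <- GenomicRanges::granges(ranges)
    ranges$kind <- kind
    ranges$gene_id <- gid
    feat_list[[length(feat_list) + 1L]] <<- ranges
  }

  idx_cds <- which(type == "CDS")
  idx_utr <- which(type %in% c("five_prime_UTR", "three_prime_UTR"))
  idx_exon <- which(type == "exon")
  for (i in idx_cds) add_feat(gr[i], "CDS", owner_gene(i))
  for (i in idx_utr) add_feat(gr[i], "UTR", owner_gene(i))

  # exon parts outside CDS/UTR, and introns = gene span minus exons
  pseudo <- type[is_gene] == "pseudogene"
  for (g in seq_along(genes)) {
    gid <- genes$gene_id[g]
    # exons of this gene (via its transcripts or direct parentage)
    g_exons <- idx_exon[vapply(idx_exon, function(i)
      identical(owner_gene(i), gid), logical(1))]
    if (pseudo[g]) {
      add_feat(genes[g], "pseudogene", gid)
      next
    }
    exon_r <- GenomicRanges::reduce(GenomicRanges::granges(gr[g_exons]))
    if (length(exon_r)) {
      cds_utr <- GenomicRanges::granges(gr[c(idx_cds, idx_utr)])
      cds_utr <- cds_utr[vapply(c(idx_cds, idx_utr), function(i)
        identical(owner_gene(i), gid), logical(1))]
      exon_only <- GenomicRanges::setdiff(exon_r,
                                          GenomicRanges::reduce(cds_utr),
                                          ignore.strand = TRUE)
      add_feat(exon_only, "exon", gid)
      introns <- GenomicRanges::setdiff(GenomicRanges::granges(genes[g]),
                                        exon_r, ignore.strand = TRUE)
      add_feat(introns, "intron", gid)
    }
  }
  features <- if (length(feat_list))
    suppressWarnings(do.call(c, feat_list)) else GenomicRanges::GRanges()

  reg <- if (is.null(regulatory_bed)) GenomicRanges::GRanges()
         else readRegulatoryBed(regulatory_bed)
  new("FeatureDB", genes = GenomicRanges::granges(genes, use.mcols = FALSE) |>
        (\(g) { g$gene_id <- genes$gene_id; g })(),
      features = features, regulatory = reg)
}

#' Read regulatory regions from a BED+kind file
#'
#' A neutral 5-column dialect: contig, start (0-based), end (exclusive),
#' name, kind; kind is one of enhancer, promoter, splice_leader, TSS,
#' TF_binding_site.  The fifth column carries text, so this is not
#' standard BED5 (whose fifth column is a numeric score).
#'
#' @param path BED+kind file.
#' @return \code{GRanges} with \code{name} and \code{kind} columns.
#' @export
readRegulatoryBed <- function(path) {
  if (!file.exists(path)) stop("regulatory BED not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end", "name", "kind"))
  ok <- c("enhancer", "promoter", "splice_leader", "TSS", "TF_binding_site")
  if (!all(df$kind %in% ok))
    stop("unknown regulatory kind: ",
         paste(setdiff(unique(df$kind), ok), collapse = ", "))
  if (any(df$start >= df$end)) stop("regulatory intervals must have start < end")
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end))
  gr$name <- df$name
  gr$kind <- df$kind
  gr
}

#' Write split-read evidence as TSV
#' @param evidence evidence data.frame from \code{clusterEvidence}.
#' @param path output TSV.
#' @export
writeEvidenceTsv <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a call table as TSV
#' @param callset an \linkS4class{SVCallSet}.
#' @param path output TSV.
#' @export
writeCallsTsv <- function(callset, path) {
  utils::write.table(calls(callset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read PCR-confirmation labels
#' @param path TSV with columns \code{call_id} and \code{label} (0/1).
#' @return data.frame.
#' @export
readLabelsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("call_id", "label") %in% names(df)))
    stop("labels TSV must have call_id and label columns")
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  df
}
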