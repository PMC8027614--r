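#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' CopyNumberTrack: binned normalized depth along one contig
#'
#' Holds the binned, genome-wide-normalized read depth of a sample and a
#' control strain along one contig, together with their ratio, the
#' deletion/duplication indicator used for copy-number support of variant
#' calls.  Bins whose control depth falls below a reliability floor are
#' masked (ratio set to \code{NA}).
#'
#' @slot contig contig name.
#' @slot contigLength contig length in bases.
#' @slot binSize bin width in bases.
#' @slot sampleNorm,controlNorm normalized depths, genome-wide mean 1.
#' @slot ratio per-bin \code{sampleNorm / max(controlNorm, pseudo)};
#'   \code{NA} in masked bins.
#' @slot masked logical, \code{TRUE} where the control depth is unreliable.
#'
#' @exportClass CopyNumberTrack
setClass("CopyNumberTrack",
  slots = c(
    contig = "character",
    contigLength = "numeric",
    binSize = "integer",
    sampleNorm = "numeric",
    controlNorm = "numeric",
    ratio = "numeric",
    masked = "logical"
  )
)

setValidity("CopyNumberTrack", function(object) {
  n <- length(object@sampleNorm)
  msg <- character(0)
  if (length(object@controlNorm) != n || length(object@ratio) != n ||
      length(object@masked) != n)
    msg <- c(msg, "sampleNorm, controlNorm, ratio and masked must have equal length")
  if (object@binSize < 50L)
    msg <- c(msg, "binSize must be >= 50")
  if (n != ceiling(object@contigLength / object@binSize))
    msg <- c(msg, "number of bins must equal ceiling(contigLength / binSize)")
  if (any(object@sampleNorm < 0) || any(object@controlNorm < 0))
    msg <- c(msg, "normalized depths must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FeatureDB: gene models and regulatory regions
#'
#' Container for the annotation intervals used to classify variants:
#' gene-linked features (CDS, UTR, exon parts, introns, pseudogenes),
#' gene spans, and regulatory regions (enhancer, promoter, splice leader,
#' TSS, transcription-factor binding sites).  All ranges are stored as
#' \code{GRanges} (1-based closed, the Bioconductor convention); package
#' coordinates on variant calls are 0-based half-open and are converted at
#' the overlap boundary.
#'
#' @slot genes \code{GRanges} of gene spans with metadata column
#'   \code{gene_id}.
#' @slot features \code{GRanges} with metadata columns \code{kind} (one of
#'   CDS, UTR, exon, intron, pseudogene) and \code{gene_id}.
#' @slot regulatory \code{GRanges} with metadata column \code{kind} (one of
#'   enhancer, promoter, splice_leader, TSS, TF_binding_site).
#'
#' @exportClass FeatureDB
setClass("FeatureDB",
  slots = c(
    genes = "GRanges",
    features = "GRanges",
    regulatory = "GRanges"
  )
)

setValidity("FeatureDB", function(object) {
  msg <- character(0)
  if (length(object@genes) && is.null(object@genes$gene_id))
    msg <- c(msg, "genes must carry a gene_id metadata column")
  if (length(object@features)) {
    if (is.null(object@features$kind) || is.null(object@features$gene_id))
      msg <- c(msg, "features must carry kind and gene_id metadata columns")
    else if (!all(object@features$kind %in%
                  c("CDS", "UTR", "exon", "intron", "pseudogene")))
      msg <- c(msg, "unknown feature kind")
  }
  if (length(object@regulatory) && !is.null(object@regulatory$kind) &&
      !all(object@regulatory$kind %in%
           c("enhancer", "promoter", "splice_leader", "TSS", "TF_binding_site")))
    msg <- c(msg, "unknown regulatory kind")
  if (length(msg)) msg else TRUE
})

# Canonical column set of the call table inside an SVCallSet.
.sv_call_columns <- c(
  id = "character", svtype = "character", contig = "character",
  start = "numeric", end = "numeric", contig2 = "character",
  pos2 = "numeric", length = "numeric", novel_seq = "character",
  frequency = "numeric", zygosity = "character", support = "integer",
  support_start = "integer", support_end = "integer",
  fwd_support = "integer", rev_support = "integer",
  cn_ratio_mean = "numeric", depth_diff = "numeric",
  size_class = "character", precise = "logical", source = "character",
  breakends = "integer", confirmed = "character", filter = "character"
)

.sv_types <- c("DEL", "DUP", "MULT", "INS", "DELINS", "INV", "TRA")

emptySvCalls <- function() {
  cols <- lapply(.sv_call_columns, function(tp) vector(tp, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' SVCallSet: a set of structural variant calls
#'
#' The central result container of the detection pipeline: one row per
#' typed structural variant (DEL, DUP, MULT, INS, DELINS, INV, TRA) with
#' 0-based half-open coordinates, breakpoint support metrics, variant
#' frequency, zygosity and copy-number support.  Translocations carry a
#' second breakend in \code{contig2}/\code{pos2} and have no defined
#' length.
#'
#' @slot calls data.frame with the canonical call columns (see
#'   \code{calls}).
#' @slot contigLengths named numeric vector of reference contig lengths,
#'   in declared order.
#'
#' @exportClass SVCallSet
setClass("SVCallSet",
  slots = c(calls = "data.frame", contigLengths = "numeric")
)

setValidity("SVCallSet", function(object) {
  df <- object@calls
  msg <- character(0)
  missing_cols <- setdiff(names(.sv_call_columns), names(df))
  if (length(missing_cols))
    return(paste("missing call columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$svtype %in% .sv_types))
      msg <- c(msg, "unknown svtype")
    intra <- df$svtype != "TRA"
    bad <- intra & !(df$start < df$end | df$svtype == "INS")
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "start must be < end for intra-contig variants")
    fr <- df$frequency
    if (any(!is.na(fr) & (fr < 0 | fr > 1)))
      msg <- c(msg, "frequency must lie in [0, 1]")
    len_known <- !is.na(df$length)
    if (any((df$length[len_known] >= 50) != (df$size_class[len_known] == "large")))
      msg <- c(msg, "size_class must be 'large' iff length >= 50")
    if (is.null(names(object@contigLengths)))
      msg <- c(msg, "contigLengths must be named")
    else if (!all(df$contig %in% names(object@contigLengths)))
      msg <- c(msg, "call contig absent from contigLengths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SVCallSet
#'
#' Missing canonical columns are filled with sensible defaults so that
#' upstream producers only need to supply what they know.
#'
#' @param calls data.frame of calls (possibly partial columns).
#' @param contigLengths named vector of reference contig lengths.
#' @return An \linkS4class{SVCallSet}.
#' @export
SVCallSet <- function(calls = emptySvCalls(), contigLengths = numeric(0)) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  n <- nrow(calls)
  defaults <- list(
    id = if (n) sprintf("SV%05d", seq_len(n)) else character(0),
    contig2 = NA_character_, pos2 = NA_real_, length = NA_real_,
    novel_seq = "", frequency = NA_real_, zygosity = "unknown",
    support = 0L, support_start = 0L, support_end = 0L,
    fwd_support = 0L, rev_support = 0L, cn_ratio_mean = NA_real_,
    depth_diff = NA_real_, size_class = NA_character_, precise = TRUE,
    source = "split_only", breakends = NA_integer_,
    confirmed = "untested", filter = "PASS"
  )
  for (nm in names(.sv_call_columns)) {
    if (!nm %in% names(calls)) {
      if (!nm %in% names(defaults))
        stop("column '", nm, "' must be supplied")
      calls[[nm]] <- rep(defaults[[nm]], length.out = n)
    }
  }
  len_known <- !is.na(calls$length)
  calls$size_class[len_known] <- ifelse(calls$length[len_known] >= 50,
                                        "large", "small")
  calls$size_class[!len_known] <- "large"  # breakend-only types (TRA)
  calls <- calls[, names(.sv_call_columns)]
  new("SVCallSet", calls = calls, contigLengths = contigLengths)
}
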