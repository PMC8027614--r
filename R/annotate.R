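# Variant annotation against gene models and regulatory regions, and the
# per-strain summary statistics (variants per strain, genes affected,
# chromosomes carrying variants, deletion size distribution, AT-content
# correlation).

.category_order <- c("CDS", "UTR", "exon", "intron", "pseudogene")
.subcategory_order <- c("enhancer", "promoter", "TSS", "TF_binding_site",
                        "splice_leader")

.call_granges <- function(df) {
  # 0-based half-open -> GRanges (1-based closed); breakend-only calls
  # (TRA, INS) get the base on each side of the break.
  start1 <- ifelse(df$svtype %in% c("INS", "TRA"),
                   pmax(df$start, 1), df$start + 1)
  end1 <- ifelse(df$svtype %in% c("INS", "TRA"), df$start + 1, df$end)
  GenomicRanges::GRanges(df$contig, IRanges::IRanges(start1, end1))
}

#' Annotate variants by overlapped genomic features
#'
#' Each call receives exactly one category by the precedence
#' CDS > UTR > exon > intron > pseudogene > intergenic over all features
#' overlapping its interval; intergenic calls additionally receive a
#' subcategory by the precedence enhancer > promoter > TSS >
#' TF_binding_site > splice_leader > other.  All genes whose features
#' overlap the call are listed.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param db a \linkS4class{FeatureDB}.
#' @return data.frame \code{call_id, category, subcategory,
#'   affected_genes} (comma-separated gene ids, empty for intergenic).
#' @export
#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
annotateVariants <- function(callset, db) {
  df <- calls(callset)
  if (!nrow(df)) {
    return(data.frame(call_id = character(0), category = character(0),
                      subcategory = character(0),
                      affected_genes = character(0),
                      stringsAsFactors = FALSE))
  }
  known_ctg <- unique(c(
    as.character(GenomicRanges::seqnames(db@genes)),
    as.character(GenomicRanges::seqnames(db@features)),
    as.character(GenomicRanges::seqnames(db@regulatory))))
  missing_ctg <- setdiff(df$contig, known_ctg)
  if (length(missing_ctg))
    stop("contig(s) absent from annotation db: ",
         paste(missing_ctg, collapse = ", "))
  gr <- .call_granges(df)
  feat <- featureRanges(db)
  genes <- geneRanges(db)
  reg <- regulatoryRanges(db)
  fo <- GenomicRanges::findOverlaps(gr, feat)
  go <- GenomicRanges::findOverlaps(gr, genes)
  ro <- GenomicRanges::findOverlaps(gr, reg)
  category <- character(nrow(df))
  subcategory <- rep(NA_character_, nrow(df))
  affected <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    kinds <- feat$kind[S4Vectors::subjectHits(fo)[S4Vectors::queryHits(fo) == i]]
    hit_rank <- match(kinds, .category_order)
    if (length(hit_rank) && any(!is.na(hit_rank))) {
      category[i] <- .category_order[min(hit_rank, na.rm = TRUE)]
      gids <- unique(c(
        feat$gene_id[S4Vectors::subjectHits(fo)[S4Vectors::queryHits(fo) == i]],
        genes$gene_id[S4Vectors::subjectHits(go)[S4Vectors::queryHits(go) == i]]
      ))
      affected[i] <- paste(sort(gids[!is.na(gids)]), collapse = ",")
    } else {
      category[i] <- "intergenic"
      rkinds <- reg$kind[S4Vectors::subjectHits(ro)[S4Vectors::queryHits(ro) == i]]
      rr <- match(rkinds, .subcategory_order)
      subcategory[i] <- if (length(rr) && any(!is.na(rr)))
        .subcategory_order[min(rr, na.rm = TRUE)] else "other"
    }
  }
  data.frame(call_id = df$id, category = category,
             subcategory = subcategory, affected_genes = affected,
             stringsAsFactors = FALSE)
}

#' Count genes partially or completely deleted
#'
#' The number of distinct gene ids whose span intersects any deletion
#' (DEL or DELINS) interval of one strain's calls.
#'
#' @param callset an \linkS4class{SVCallSet} of one strain.
#' @param db a \linkS4class{FeatureDB}.
#' @return integer count.
#' @export
genesAffected <- function(callset, db) {
  df <- calls(callset)
  df <- df[df$svtype %in% c("DEL", "DELINS") & df$precise, , drop = FALSE]
  if (!nrow(df)) return(0L)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1, df$end))
  genes <- geneRanges(db)
  hits <- GenomicRanges::findOverlaps(gr, genes)
  length(unique(genes$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Chromosomes carrying large variants
#'
#' Counts are computed over large (>= 50 bp) calls only.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @return list with \code{n_chromosomes} and \code{per_chromosome}
#'   (named integer vector of variant counts).
#' @export
chromosomeStats <- function(callset) {
  df <- calls(callset)
  df <- df[df$size_class == "large", , drop = FALSE]
  if (!nrow(df)) {
    return(list(n_chromosomes = 0L,
                per_chromosome = stats::setNames(integer(0), character(0))))
  }
  tab <- table(df$contig)
  per <- stats::setNames(as.integer(tab), names(tab))
  list(n_chromosomes = length(per), per_chromosome = per)
}

#' Deletion size distribution
#'
#' Median and interquartile range of deletion lengths (DEL and DELINS,
#' precise calls only); the raw values are returned for plotting.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @return list \code{median, iqr, values}; all \code{NA}/empty when the
#'   set has no deletions.
#' @export
sizeDistribution <- function(callset) {
  df <- calls(callset)
  v <- df$length[df$svtype %in% c("DEL", "DELINS") & df$precise]
  v <- v[!is.na(v)]
  if (!length(v)) return(list(median = NA_real_, iqr = NA_real_,
                              values = numeric(0)))
  list(median = stats::median(v), iqr = stats::IQR(v), values = v)
}

#' Correlation between variant density and AT content
#'
#' Least-squares R-squared between the per-window A/T base fraction and
#' the per-window variant count, over non-overlapping windows of
#' \code{window} bases.  A degenerate regressor (constant AT content)
#' yields 0 by convention.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param genome named \code{DNAStringSet}.
#' @param window window size in bases (>= 1000; default 100000).
#' @return R-squared in [0, 1].
#' @export
#' @importFrom Biostrings letterFrequency
atContentCorrelation <- function(callset, genome, window = 100000L) {
  stopifnot(window >= 1000L)
  df <- calls(callset)
  at <- numeric(0)
  count <- numeric(0)
  for (ctg in names(genome)) {
    len <- Biostrings::width(genome[ctg])
    nw <- floor(len / window)
    if (nw < 1L) next
    v <- Biostrings::Views(genome[[ctg]],
                           start = (seq_len(nw) - 1L) * window + 1L,
                           width = window)
    freq <- Biostrings::letterFrequency(v, letters = c("A", "T"))
    at <- c(at, rowSums(freq) / window)
    pos <- df$start[df$contig == ctg]
    w <- floor(pos / window) + 1L
    count <- c(count, tabulate(w[w <= nw], nbins = nw))
  }
  if (length(at) < 3L) stop("fewer than 3 windows; increase genome size or reduce window")
  if (stats::var(at) == 0) return(0)
  fit <- stats::lm(count ~ at)
  summary(fit)$r.squared
}
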