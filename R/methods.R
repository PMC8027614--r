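#' @rdname accessors
setMethod("cnRatioValues", "CopyNumberTrack", function(x) x@ratio)

#' @rdname accessors
setMethod("sampleNorm", "CopyNumberTrack", function(x) x@sampleNorm)

#' @rdname accessors
setMethod("controlNorm", "CopyNumberTrack", function(x) x@controlNorm)

#' @rdname accessors
setMethod("binSize", "CopyNumberTrack", function(x) x@binSize)

#' @rdname accessors
setMethod("maskedBins", "CopyNumberTrack", function(x) x@masked)

#' @rdname accessors
setMethod("contigName", "CopyNumberTrack", function(x) x@contig)

setMethod("show", "CopyNumberTrack", function(object) {
  ok <- !object@masked
  cat("CopyNumberTrack on", object@contig,
      sprintf("(%d bins of %d bp, %d masked)\n",
              length(object@ratio), object@binSize, sum(object@masked)))
  if (any(ok))
    cat(sprintf("  ratio: median %.3f [%.3f, %.3f]\n",
                stats::median(object@ratio[ok]),
                min(object@ratio[ok]), max(object@ratio[ok])))
  invisible(NULL)
})

#' @rdname accessors
setMethod("calls", "SVCallSet", function(x) x@calls)

#' @rdname accessors
setMethod("contigLengths", "SVCallSet", function(x) x@contigLengths)

#' @describeIn SVCallSet number of calls
#' @param x an SVCallSet
#' @export
setMethod("length", "SVCallSet", function(x) nrow(x@calls))

#' @describeIn SVCallSet subset calls by index or logical mask
#' @param i row index
#' @param j,drop,... ignored
#' @export
setMethod("[", "SVCallSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, calls = x@calls[i, , drop = FALSE],
             contigLengths = x@contigLengths)
})

setMethod("show", "SVCallSet", function(object) {
  df <- object@calls
  cat("SVCallSet with", nrow(df), "calls on",
      length(object@contigLengths), "contigs\n")
  if (nrow(df)) {
    tab <- table(factor(df$svtype, levels = .sv_types))
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat("  zygosity:", paste(sprintf("%s=%d",
        names(table(df$zygosity)), table(df$zygosity)), collapse = " "), "\n")
  }
  invisible(NULL)
})

#' @rdname accessors
setMethod("geneRanges", "FeatureDB", function(x) x@genes)

#' @rdname accessors
setMethod("featureRanges", "FeatureDB", function(x) x@features)

#' @rdname accessors
setMethod("regulatoryRanges", "FeatureDB", function(x) x@regulatory)

setMethod("show", "FeatureDB", function(object) {
  cat("FeatureDB:", length(unique(object@genes$gene_id)), "genes,",
      length(object@features), "gene features,",
      length(object@regulatory), "regulatory regions\n")
  invisible(NULL)
})
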