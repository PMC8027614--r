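# Internal helpers: CIGAR arithmetic, seeded evaluation, modal statistics.

# Split CIGAR strings into op/length pairs. Returns a list of data.frames.
cigarOps <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  toks <- regmatches(cigar, m)
  lapply(toks, function(tk) {
    n <- length(tk)
    data.frame(
      op = substr(tk, nchar(tk), nchar(tk)),
      len = as.integer(substr(tk, 1L, nchar(tk) - 1L)),
      stringsAsFactors = FALSE
    )
  })
}

.cigar_width <- function(cigar, ops) {
  vapply(cigarOps(cigar), function(df) {
    sum(df$len[df$op %in% ops])
  }, integer(1))
}

# Reference-consuming span of each CIGAR.
cigarRefWidth <- function(cigar) .cigar_width(cigar, c("M", "D", "N", "=", "X"))

# Query(read)-consuming span of each CIGAR (soft clips included).
cigarQueryWidth <- function(cigar) .cigar_width(cigar, c("M", "I", "S", "=", "X"))

# Length of the leading / trailing soft clip (0 when absent).
# A hard clip may precede/follow the soft clip; it consumes no SEQ bases.
leadingClip <- function(cigar) {
  m <- regmatches(cigar, regexec("^(?:\\d+H)?(\\d+)S", cigar))
  vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else 0L, integer(1))
}

trailingClip <- function(cigar) {
  m <- regmatches(cigar, regexec("(\\d+)S(?:\\d+H)?$", cigar))
  vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else 0L, integer(1))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Most frequent value; ties broken by the smallest value (determinism).
modalValue <- function(x) {
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  v <- suppressWarnings(as.numeric(best))
  if (!anyNA(v)) return(min(v))
  sort(best)[1L]
}

# Cumulative 0-based offsets of contigs in declared order.
contigOffsets <- function(contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  off <- cumsum(c(0, as.numeric(contig_lengths)))[seq_along(contig_lengths)]
  names(off) <- names(contig_lengths)
  off
}

reverseComplementChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
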