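# Genome-wide mutation-number extrapolation from reporter-assay rates,
# and deletion size-class statistics.

#' Assay constants for the forward-mutation extrapolation
#'
#' Genome size and reporter target sizes used to scale assay rates to
#' expected mutations per haploid genome: the full genome (100,272,607
#' bases), the coding region of the twitching reporter gene (21,477
#' bases) and the total region amplified by the PCR deletion screen
#' (89,840 bases).
#'
#' @return named list \code{genome_size, unc22_coding, amplified_total}.
#' @export
assayConstants <- function() {
  list(genome_size = 100272607, unc22_coding = 21477,
       amplified_total = 89840)
}

#' Extrapolate the number of mutations per haploid genome
#'
#' A forward-mutation rate measured on a reporter target of
#' \code{target_size} bases is scaled to the whole genome:
#' \code{rate * genome_size / target_size}.  Rates are accepted as
#' percentages by default (the unit in which assay tables are printed);
#' set \code{unit = "fraction"} for proportions.
#'
#' @param rate mutation rate (percent by default).
#' @param target_size size of the assayed target in bases.
#' @param genome_size genome size in bases.
#' @param unit \code{"percent"} or \code{"fraction"}.
#' @return expected mutations per haploid genome.
#' @export
estimateMutationCount <- function(rate, target_size,
                                  genome_size = assayConstants()$genome_size,
                                  unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  if (any(target_size <= 0)) stop("target_size must be positive")
  if (unit == "percent") {
    if (any(rate < 0 | rate > 100)) stop("percent rate must lie in [0, 100]")
    rate <- rate / 100
  } else if (any(rate < 0 | rate > 1)) {
    stop("fractional rate must lie in [0, 1]")
  }
  rate * genome_size / target_size
}

#' Fraction of deletions below a size threshold
#'
#' @param deletion_sizes vector of deletion sizes in bases (nonempty).
#' @param threshold size threshold (default 50).
#' @return fraction of sizes strictly below \code{threshold}.
#' @export
sizeClassFraction <- function(deletion_sizes, threshold = 50) {
  if (!length(deletion_sizes)) stop("deletion_sizes must be nonempty")
  mean(deletion_sizes < threshold)
}

#' Compare deletion size classes between two groups
#'
#' Builds the 2x2 table of counts below/at-or-above \code{threshold}
#' (rows = groups, columns = \code{<threshold}, \code{>=threshold}) and
#' applies the two-sided Fisher exact test.
#'
#' @param group_a_sizes,group_b_sizes nonempty size vectors.
#' @param threshold size threshold (default 50).
#' @return list with \code{table} (2x2 matrix) and \code{p.value}.
#' @export
sizeClassTest <- function(group_a_sizes, group_b_sizes, threshold = 50) {
  stopifnot(length(group_a_sizes) > 0, length(group_b_sizes) > 0)
  tab <- rbind(
    a = c(sum(group_a_sizes < threshold), sum(group_a_sizes >= threshold)),
    b = c(sum(group_b_sizes < threshold), sum(group_b_sizes >= threshold))
  )
  colnames(tab) <- c("small", "large")
  list(table = tab, p.value = stats::fisher.test(tab)$p.value)
}
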