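# Pipeline configuration and the command-level entry points wiring the
# modules into the full workflow (detect -> annotate -> filter-ml;
# simulate; estimate).  A thin shell front-end over these functions is
# installed at inst/cli/svharvest.R.

#' Pipeline configuration
#'
#' All tunable thresholds with validated defaults.  Unknown keys are
#' rejected.
#'
#' @param ... named overrides of the defaults: \code{min_clip_len} (15),
#'   \code{min_identity} (0.95), \code{tolerance} (5), \code{min_support}
#'   (3), \code{bin_size} (500), \code{del_max} (0.25), \code{dup_min}
#'   (1.5), \code{mult_min} (2.5), \code{min_bins} (2), \code{pseudo}
#'   (0.05), \code{control_min} (0.25), \code{hom_min} (0.8),
#'   \code{het_min} (0.25), \code{reciprocal_overlap} (0.5),
#'   \code{min_strains} (2), \code{cn_only_min_len} (2000),
#'   \code{ml_algorithms} (all seven), \code{seed} (1).
#' @return named list of validated settings.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    min_clip_len = 15L, min_identity = 0.95, tolerance = 5L,
    min_support = 3L, bin_size = 500L, del_max = 0.25, dup_min = 1.5,
    mult_min = 2.5, min_bins = 2L, pseudo = 0.05, control_min = 0.25,
    hom_min = 0.8, het_min = 0.25, reciprocal_overlap = 0.5,
    min_strains = 2L, cn_only_min_len = 2000, ml_algorithms = .ml_algorithms,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(min_clip_len >= 1, min_identity > 0.5, min_identity <= 1,
              tolerance >= 0, min_support >= 1, bin_size >= 50,
              del_max < dup_min, dup_min < mult_min, min_bins >= 1,
              pseudo > 0, hom_min > het_min, het_min >= 0, hom_min <= 1,
              reciprocal_overlap > 0, reciprocal_overlap <= 1,
              min_strains >= 2)
  })
  if (!all(cfg$ml_algorithms %in% .ml_algorithms))
    stop("unknown ML algorithm(s)")
  cfg
}

#' Detect structural variants in one sample against a control
#'
#' Runs the full per-strain detection: soft-clip extraction, clip
#' realignment and break-site classification, evidence clustering,
#' binned copy-number-ratio analysis against the control, evidence
#' integration, variant frequency and zygosity.
#'
#' @param genome named \code{DNAStringSet}.
#' @param sample_aln,control_aln alignment data.frames.
#' @param config list from \code{pipelineConfig}.
#' @return An \linkS4class{SVCallSet}.
#' @export
detectVariants <- function(genome, sample_aln, control_aln,
                           config = pipelineConfig()) {
  cl <- genomeContigLengths(genome)
  if (!nrow(sample_aln) || !nrow(control_aln))
    return(SVCallSet(contigLengths = cl))
  evidence <- detectSplitReads(sample_aln, genome,
                               min_clip_len = config$min_clip_len,
                               min_identity = config$min_identity,
                               tolerance = config$tolerance,
                               min_support = config$min_support)
  tracks <- buildCnTracks(sample_aln, control_aln, cl,
                          bin_size = config$bin_size,
                          pseudo = config$pseudo,
                          control_min = config$control_min)
  segs <- do.call(rbind, lapply(tracks, callCnSegments,
                                del_max = config$del_max,
                                dup_min = config$dup_min,
                                mult_min = config$mult_min,
                                min_bins = config$min_bins))
  callset <- combineEvidence(evidence, segs, cl,
                             reciprocal_overlap = config$reciprocal_overlap,
                             cn_only_min_len = config$cn_only_min_len,
                             tracks = tracks, mult_min = config$mult_min)
  assignZygosity(callset, sample_aln,
                 min_clip_len = config$min_clip_len,
                 hom_min = config$hom_min, het_min = config$het_min)
}

#' Detect command: files in, VCF and evidence TSV out
#'
#' @param genome_path reference FASTA.
#' @param sample_path,control_path SAM/BAM alignments.
#' @param out_dir output directory (created if needed).
#' @param config list from \code{pipelineConfig}.
#' @return the \linkS4class{SVCallSet}, invisibly.
#' @export
cmdDetect <- function(genome_path, sample_path, control_path, out_dir,
                      config = pipelineConfig()) {
  genome <- readGenome(genome_path)
  sample_aln <- readAlignments(sample_path)
  control_aln <- readAlignments(control_path)
  if (!nrow(sample_aln)) warning("no alignments in ", sample_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  callset <- detectVariants(genome, sample_aln, control_aln, config)
  message(sprintf("detected %d call(s) from %d sample alignment(s)",
                  length(callset), nrow(sample_aln)))
  writeVariantVcf(callset, file.path(out_dir, "calls.vcf"), genome)
  writeCallsTsv(callset, file.path(out_dir, "calls.tsv"))
  invisible(callset)
}

#' Annotate command: classify calls and write summary statistics
#'
#' @param callset an \linkS4class{SVCallSet} (or a VCF path).
#' @param gff_path GFF3 gene models.
#' @param regulatory_bed optional BED+kind regulatory file.
#' @param out_dir output directory.
#' @return list with the annotation data.frame and the summary list,
#'   invisibly.
#' @export
cmdAnnotate <- function(callset, gff_path, regulatory_bed = NULL, out_dir) {
  if (is.character(callset)) callset <- readVariantVcf(callset)
  if (is.null(regulatory_bed))
    warning("no regulatory BED supplied; intergenic subcategory will be 'other'")
  db <- readFeatureDB(gff_path, regulatory_bed)
  ann <- annotateVariants(callset, db)
  df <- calls(callset)
  df$category <- ann$category[match(df$id, ann$call_id)]
  df$subcategory <- ann$subcategory[match(df$id, ann$call_id)]
  df$genes <- ann$affected_genes[match(df$id, ann$call_id)]
  annotated <- initialize(callset, calls = df)
  cs <- chromosomeStats(callset)
  sd_ <- sizeDistribution(callset)
  summary <- list(
    n_calls = length(callset),
    genes_affected = genesAffected(callset, db),
    n_chromosomes_with_variant = cs$n_chromosomes,
    per_chromosome = cs$per_chromosome,
    deletion_size_median = sd_$median,
    deletion_size_iqr = sd_$iqr,
    category_counts = table(ann$category),
    subcategory_counts = table(ann$subcategory[!is.na(ann$subcategory)])
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeVariantVcf(annotated, file.path(out_dir, "annotated.vcf"))
  utils::write.table(ann, file.path(out_dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sum_df <- data.frame(
    metric = c("n_calls", "genes_affected", "n_chromosomes_with_variant",
               "deletion_size_median", "deletion_size_iqr"),
    value = c(summary$n_calls, summary$genes_affected,
              summary$n_chromosomes_with_variant,
              summary$deletion_size_median, summary$deletion_size_iqr)
  )
  utils::write.table(sum_df, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(annotation = ann, summary = summary, callset = annotated))
}

#' Filter-ML command: train classifiers and flag candidates
#'
#' Trains the configured algorithms on labeled training candidates,
#' writes the per-algorithm accuracy report, and applies the selected
#' algorithm's predictions to the candidate set (FILTER column
#' \code{PASS} / \code{ml_fail}).
#'
#' @param train_features,train_labels labeled training candidates.
#' @param candidates feature data.frame of candidates to triage.
#' @param callset optional \linkS4class{SVCallSet} matching
#'   \code{candidates} by \code{call_id}; its FILTER column is updated.
#' @param select algorithm whose predictions are applied (default SVM).
#' @param out_dir output directory.
#' @param config list from \code{pipelineConfig}.
#' @return list \code{report, predictions, callset}, invisibly.
#' @export
cmdFilterMl <- function(train_features, train_labels, candidates,
                        callset = NULL, select = "SVM", out_dir,
                        config = pipelineConfig()) {
  if (!is.null(candidates$call_id) && anyDuplicated(candidates$call_id))
    stop("duplicate candidate ids: ",
         paste(unique(candidates$call_id[duplicated(candidates$call_id)]),
               collapse = ", "))
  models <- lapply(config$ml_algorithms, function(a)
    mlTrain(train_features, train_labels, a, seed = config$seed))
  names(models) <- config$ml_algorithms
  report <- data.frame(
    algorithm = config$ml_algorithms,
    accuracy_train = vapply(models, function(m) m$accuracy_train, numeric(1)),
    stringsAsFactors = FALSE
  )
  sel <- models[[match.arg(select, config$ml_algorithms)]]
  pred <- mlPredict(sel, candidates)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report, file.path(out_dir, "ml_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(callset)) {
    df <- calls(callset)
    idx <- match(df$id, candidates$call_id)
    ok <- !is.na(idx)
    df$filter[ok] <- ifelse(pred[idx[ok]] == 1L, "PASS", "ml_fail")
    callset <- initialize(callset, calls = df)
    writeVariantVcf(callset, file.path(out_dir, "filtered.vcf"))
  }
  invisible(list(report = report, predictions = pred, callset = callset))
}

#' Simulate command: write a desk-scale fixture bundle
#'
#' Writes the reference FASTA, sample and control SAM files and the truth
#' table for a simulated strain.
#'
#' @param out_dir output directory.
#' @param contig_lengths named contig lengths (default one 100 kb contig
#'   plus one 60 kb contig).
#' @param depth,read_length,error_rate,seed see \code{simulateReads}.
#' @param specs optional variant specs; drawn with
#'   \code{randomVariantSpecs} when \code{NULL}.
#' @return list of written paths, invisibly.
#' @export
cmdSimulate <- function(out_dir, contig_lengths = c(chrI = 1e5, chrII = 6e4),
                        depth = 20, read_length = 120L, error_rate = 0,
                        seed = 1L, specs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulateGenome(contig_lengths, seed = seed)
  if (is.null(specs))
    specs <- randomVariantSpecs(contig_lengths, n_del = 5L, n_dup = 1L,
                                n_mult = 0L, n_ins = 1L, n_delins = 1L,
                                n_inv = 1L, n_tra = 1L, seed = seed + 1L)
  strain <- simulateStrain(genome, specs, depth = depth,
                           read_length = read_length,
                           error_rate = error_rate, seed = seed + 2L,
                           prefix = "smp")
  control <- simulateStrain(genome, NULL, depth = depth,
                            read_length = read_length,
                            error_rate = error_rate, seed = seed + 3L,
                            prefix = "ctl")
  paths <- list(
    genome = file.path(out_dir, "reference.fa"),
    sample = file.path(out_dir, "sample.sam"),
    control = file.path(out_dir, "control.sam"),
    truth = file.path(out_dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  cl <- genomeContigLengths(genome)
  writeSam(strain$alignments, cl, paths$sample)
  writeSam(control$alignments, cl, paths$control)
  utils::write.table(strain$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("simulated %d variant(s); %d sample / %d control reads",
                  nrow(strain$truth), nrow(strain$alignments),
                  nrow(control$alignments)))
  invisible(paths)
}

#' Estimate command: genome-wide mutation-count extrapolation
#'
#' @param rate assay mutation rate in percent.
#' @param assay \code{"twitching"} (reporter-gene coding region),
#'   \code{"pcr"} (total amplified region) or \code{"custom"}.
#' @param target_size target size in bases (required for
#'   \code{"custom"}).
#' @return expected mutations per haploid genome.
#' @export
cmdEstimate <- function(rate, assay = c("twitching", "pcr", "custom"),
                        target_size = NULL) {
  assay <- match.arg(assay)
  k <- assayConstants()
  target <- switch(assay,
    twitching = k$unc22_coding,
    pcr = k$amplified_total,
    custom = target_size %||% stop("target_size required for custom assay"))
  estimateMutationCount(rate, target, k$genome_size)
}
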