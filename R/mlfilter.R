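# Machine-learning triage of candidate variants: feature construction,
# training of seven classical classifiers, and evaluation.

.ml_feature_names <- c("abs_pos", "log_del_len", "log_ins_len", "cn_ratio",
                       "depth_diff", "frequency", "split_total",
                       "strand_bias")

.ml_algorithms <- c("LR", "DT", "kNN", "RF", "LDA", "NB", "SVM")

#' Build the candidate feature table from variant calls
#'
#' One row per call with the eight explanatory variables: genome-wide
#' absolute start position (cumulative contig offsets in declared order),
#' log10 of deletion and of inserted length (+1), mean copy-number ratio,
#' control-minus-sample normalized depth difference over the variant,
#' variant frequency, total split-read support and strand bias
#' \code{|fwd - rev| / (fwd + rev)}.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param tracks optional named list of \linkS4class{CopyNumberTrack}
#'   (fills \code{depth_diff}; left \code{NA} otherwise and imputed at
#'   training time).
#' @return data.frame with \code{call_id} plus the eight features.
#' @export
buildFeatures <- function(callset, tracks = NULL) {
  df <- calls(callset)
  cl <- contigLengths(callset)
  off <- contigOffsets(cl)
  del_len <- ifelse(df$svtype %in% c("DEL", "DELINS") & !is.na(df$length),
                    df$length, 0)
  ins_len <- nchar(df$novel_seq)
  tot <- df$fwd_support + df$rev_support
  sb <- ifelse(tot > 0, abs(df$fwd_support - df$rev_support) / tot, NA_real_)
  dd <- rep(NA_real_, nrow(df))
  if (!is.null(tracks)) {
    for (i in seq_len(nrow(df))) {
      tr <- tracks[[df$contig[i]]]
      if (is.null(tr) || df$svtype[i] == "TRA") next
      bs <- binSize(tr)
      b <- (floor(df$start[i] / bs) + 1L):max(floor((df$end[i] - 1) / bs) + 1L,
                                              floor(df$start[i] / bs) + 1L)
      b <- b[b >= 1L & b <= length(sampleNorm(tr))]
      if (length(b))
        dd[i] <- mean(controlNorm(tr)[b] - sampleNorm(tr)[b])
    }
  }
  data.frame(
    call_id = df$id,
    abs_pos = off[df$contig] + df$start,
    log_del_len = log10(del_len + 1),
    log_ins_len = log10(ins_len + 1),
    cn_ratio = df$cn_ratio_mean,
    depth_diff = dd,
    frequency = df$frequency,
    split_total = df$support,
    strand_bias = sb,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

.feature_matrix <- function(features) {
  miss <- setdiff(.ml_feature_names, names(features))
  if (length(miss))
    stop("feature schema mismatch; missing: ", paste(miss, collapse = ", "))
  as.matrix(features[, .ml_feature_names])
}

.impute <- function(m, medians) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- medians[j]
  }
  m
}

#' Train a candidate-triage classifier
#'
#' Features are imputed with the training-set median and z-score
#' standardized with training statistics (stored in the model, so
#' evaluation on new data never leaks test information).  Seven
#' algorithms are available: logistic regression (LR), decision tree
#' (DT), k-nearest neighbours (kNN, k = 5), random forest (RF, 100
#' trees), linear discriminant analysis (LDA), Gaussian naive Bayes (NB)
#' and a linear support vector machine (SVM, cost 1).  Deterministic
#' given \code{seed}.
#'
#' @param features data.frame containing the eight feature columns.
#' @param labels 0/1 vector, one per row (>= 2 examples per class).
#' @param algorithm one of \code{"LR", "DT", "kNN", "RF", "LDA", "NB",
#'   "SVM"}.
#' @param seed integer seed.
#' @return an object of class \code{svhModel} with the fitted model,
#'   preprocessing statistics and training accuracy.
#' @export
mlTrain <- function(features, labels, algorithm = "SVM", seed = 1L) {
  algorithm <- match.arg(algorithm, .ml_algorithms)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("training set must contain at least 2 examples of each class")
  m <- .feature_matrix(features)
  medians <- apply(m, 2, stats::median, na.rm = TRUE)
  medians[is.na(medians)] <- 0
  m <- .impute(m, medians)
  center <- colMeans(m)
  scale_ <- apply(m, 2, stats::sd)
  keep <- is.finite(scale_) & scale_ > 0
  if (!any(keep)) stop("all features are constant in the training set")
  # constant features carry no information and break LDA; drop them
  m <- m[, keep, drop = FALSE]
  center <- center[keep]
  scale_ <- scale_[keep]
  z <- sweep(sweep(m, 2, center), 2, scale_, "/")
  y <- factor(labels, levels = c(0L, 1L))
  dtrain <- data.frame(z, y = y)
  fit <- withSeed(seed, switch(algorithm,
    LR = stats::glm(y ~ ., data = dtrain, family = stats::binomial()),
    DT = rpart::rpart(y ~ ., data = dtrain, method = "class",
                      control = rpart::rpart.control(minsplit = 2L,
                                                     minbucket = 1L,
                                                     cp = 0)),
    kNN = list(train = z, labels = y, k = 5L),
    RF = randomForest::randomForest(y ~ ., data = dtrain, ntree = 100L),
    LDA = MASS::lda(y ~ ., data = dtrain),
    NB = e1071::naiveBayes(y ~ ., data = dtrain),
    SVM = e1071::svm(y ~ ., data = dtrain, kernel = "linear", cost = 1,
                     scale = FALSE)
  ))
  model <- structure(
    list(algorithm = algorithm, fit = fit, center = center,
         scale = scale_, medians = medians, keep = keep, seed = seed),
    class = "svhModel"
  )
  model$accuracy_train <- mean(mlPredict(model, features) == labels)
  model
}

#' Predict candidate labels with a trained model
#'
#' @param model an \code{svhModel} from \code{mlTrain}.
#' @param features data.frame with the same feature schema as training.
#' @return integer vector of 0/1 predictions.
#' @export
mlPredict <- function(model, features) {
  m <- .impute(.feature_matrix(features), model$medians)
  m <- m[, model$keep, drop = FALSE]
  z <- sweep(sweep(m, 2, model$center), 2, model$scale, "/")
  dnew <- data.frame(z)
  pred <- switch(model$algorithm,
    LR = as.integer(stats::predict(model$fit, dnew, type = "response") >= 0.5),
    DT = as.integer(as.character(stats::predict(model$fit, dnew,
                                                type = "class"))),
    kNN = as.integer(as.character(class::knn(model$fit$train, z,
                                             model$fit$labels,
                                             k = model$fit$k))),
    RF = as.integer(as.character(stats::predict(model$fit, dnew))),
    LDA = as.integer(as.character(stats::predict(model$fit, dnew)$class)),
    NB = as.integer(as.character(stats::predict(model$fit, dnew))),
    SVM = as.integer(as.character(stats::predict(model$fit, dnew)))
  )
  unname(pred)
}

#' Evaluate a trained model on labeled candidates
#'
#' @param model an \code{svhModel}.
#' @param features labeled feature data.frame.
#' @param labels 0/1 truth vector.
#' @return list \code{algorithm, accuracy, predictions}.
#' @export
mlEvaluate <- function(model, features, labels) {
  pred <- mlPredict(model, features)
  list(algorithm = model$algorithm,
       accuracy = mean(pred == as.integer(labels)),
       predictions = pred)
}

#' Train and evaluate a panel of classifiers
#'
#' Trains each requested algorithm on the training set and reports
#' training and held-out test accuracy, mirroring a
#' train-on-confirmed / test-on-new-candidates protocol with explicit
#' disjoint inputs.
#'
#' @param train_features,train_labels training data.
#' @param test_features,test_labels held-out data.
#' @param algorithms algorithms to run (default: all seven).
#' @param seed integer seed.
#' @return data.frame \code{algorithm, accuracy_train, accuracy_test}.
#' @export
classifierReport <- function(train_features, train_labels, test_features,
                             test_labels, algorithms = .ml_algorithms,
                             seed = 1L) {
  rows <- lapply(algorithms, function(a) {
    model <- mlTrain(train_features, train_labels, a, seed = seed)
    ev <- mlEvaluate(model, test_features, test_labels)
    data.frame(algorithm = a, accuracy_train = model$accuracy_train,
               accuracy_test = ev$accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.svhModel <- function(x, ...) {
  cat("svharvest classifier:", x$algorithm,
      sprintf("(train accuracy %.3f)\n", x$accuracy_train))
  invisible(x)
}
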