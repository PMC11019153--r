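# coerce a feature data.frame to a numeric matrix, dropping provenance
feature_matrix <- function(features, keep_aux = TRUE) {
  df <- as.data.frame(features)
  df <- df[, setdiff(colnames(df), non_feature_columns()), drop = FALSE]
  if (!keep_aux) {
    df <- df[, !feature_is_auxiliary(colnames(df)), drop = FALSE]
  }
  as.matrix(as.data.frame(lapply(df, as.numeric),
                          check.names = FALSE, optional = TRUE))
}

#' Column-wise z-score standardization
#'
#' Fits per-column mean/sd on the given matrix, or applies previously
#' fitted statistics (so held-out data is always transformed with the
#' training statistics, never refit). Zero-variance columns are mapped to
#' 0 and flagged.
#'
#' @param x numeric matrix (or feature data.frame).
#' @param fit_stats optional statistics from a previous call.
#' @return A list with `x` (transformed matrix) and `stats`
#'   (`mean`, `sd`, `zero_variance`).
#' @export
standardize <- function(x, fit_stats = NULL) {
  x <- if (is.matrix(x)) x else feature_matrix(x)
  if (is.null(fit_stats)) {
    if (nrow(x) < 2) stop("standardize() needs >= 2 rows to fit")
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    zero <- !is.finite(sd) | sd <= 0
    fit_stats <- list(mean = mu, sd = sd, zero_variance = zero)
  }
  z <- sweep(x, 2, fit_stats$mean, "-")
  sd_safe <- ifelse(fit_stats$zero_variance, 1, fit_stats$sd)
  z <- sweep(z, 2, sd_safe, "/")
  z[, fit_stats$zero_variance] <- 0
  list(x = z, stats = fit_stats)
}

# median imputation of missing features (degenerate-slice sentinels)
impute_median <- function(x, medians = NULL) {
  x <- if (is.matrix(x)) x else feature_matrix(x)
  if (is.null(medians)) {
    medians <- apply(x, 2, function(col) {
      m <- stats::median(col, na.rm = TRUE)
      if (is.finite(m)) m else 0
    })
  }
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- medians[j]
  }
  list(x = x, medians = medians)
}

stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

# smallest threshold t with precision(p >= t => positive) >= target among
# thresholds keeping at least min_support predictions (a handful of
# top-scored points must not certify the target on their own);
# NA when unattainable
calibrate_threshold <- function(p_pos, is_pos, target, min_support = 20L) {
  cand <- sort(unique(p_pos))
  for (t in cand) {
    pred <- p_pos >= t
    tp <- sum(pred & is_pos)
    fp <- sum(pred & !is_pos)
    if (tp + fp >= min_support && tp / (tp + fp) >= target) return(t)
  }
  NA_real_
}

#' Train the image quality-control classifier
#'
#' Fits a random forest to standardized full feature vectors (auxiliary
#' features included) of labelled good/bad images, collects out-of-fold
#' good-class probabilities over stratified cross-validation, and selects
#' the smallest probability threshold whose out-of-fold precision for the
#' good class (TP / (TP + FP)) reaches `target_precision`. If no
#' threshold achieves it, a reject-all sentinel threshold (> 1) is stored
#' and a warning raised.
#'
#' @param features feature data.frame or matrix (one row per image).
#' @param labels character/factor vector with values `"good"`/`"bad"`.
#' @param target_precision calibration target for the good class.
#' @param n_folds number of stratified CV folds.
#' @param n_trees random-forest size.
#' @param min_support smallest number of kept out-of-fold predictions a
#'   candidate threshold must retain to be eligible (guards the
#'   calibration against certifying the target on a handful of
#'   top-scored points).
#' @param seed integer seed for folds and forests.
#' @return A `qc_model` with the fitted forest, calibrated `threshold`,
#'   imputation medians, standardization statistics, and the out-of-fold
#'   calibration curve (`oof`).
#' @export
train_qc <- function(features, labels, target_precision = 0.95,
                     n_folds = 5L, n_trees = 500L, min_support = 20L,
                     seed = 1L) {
  labels <- factor(as.character(labels), levels = c("bad", "good"))
  if (any(is.na(labels))) stop("labels must be 'good' or 'bad'")
  if (nlevels(droplevels(labels)) < 2) {
    stop("both 'good' and 'bad' images are required to train QC")
  }
  x_raw <- feature_matrix(features)
  if (nrow(x_raw) < 2 * n_folds) stop("need at least 2 rows per fold")
  imp <- impute_median(x_raw)
  std <- standardize(imp$x)

  fold <- stratified_folds(labels, n_folds, split_seed(seed, 101))
  oof <- rep(NA_real_, length(labels))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    rf <- with_seed(split_seed(seed, 200 + f),
                    randomForest::randomForest(x = std$x[tr, , drop = FALSE],
                                               y = droplevels(labels[tr]),
                                               ntree = n_trees))
    oof[!tr] <- stats::predict(rf, std$x[!tr, , drop = FALSE],
                               type = "prob")[, "good"]
  }
  threshold <- calibrate_threshold(oof, labels == "good", target_precision,
                                   min_support)
  if (is.na(threshold)) {
    warning("no threshold reaches the target precision; ",
            "storing a reject-all sentinel")
    threshold <- 1 + 1e-9
  }
  forest <- with_seed(split_seed(seed, 300),
                      randomForest::randomForest(x = std$x, y = labels,
                                                 ntree = n_trees))
  structure(list(forest = forest, threshold = threshold,
                 target_precision = target_precision, n_folds = n_folds,
                 seed = seed, impute_medians = imp$medians,
                 std_stats = std$stats,
                 feature_names = colnames(x_raw),
                 oof = data.frame(p_good = oof, label = labels)),
            class = "qc_model")
}

#' Apply the calibrated quality-control classifier
#'
#' @param model a [train_qc()] model.
#' @param features feature data.frame/matrix with the training schema.
#' @return A data.frame with `p_good`, `keep` (`p_good >= threshold`) and
#'   `reason` (`"kept"` or `"below_threshold"`).
#' @export
apply_qc <- function(model, features) {
  x <- feature_matrix(features)
  if (!identical(colnames(x), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(x))
    extra <- setdiff(colnames(x), model$feature_names)
    if (length(missing) || length(extra)) {
      stop("feature schema mismatch; missing: ",
           paste(missing, collapse = ", "), "; unexpected: ",
           paste(extra, collapse = ", "))
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  x <- impute_median(x, model$impute_medians)$x
  z <- standardize(x, model$std_stats)$x
  p <- stats::predict(model$forest, z, type = "prob")[, "good"]
  data.frame(p_good = as.numeric(p), keep = p >= model$threshold,
             reason = ifelse(p >= model$threshold, "kept",
                             "below_threshold"))
}

#' Two-dimensional t-SNE embedding of non-auxiliary features
#'
#' @param features feature data.frame/matrix; auxiliary and provenance
#'   columns are dropped, remaining columns median-imputed and
#'   standardized before embedding.
#' @param perplexity t-SNE perplexity; requires `n > 3 * perplexity`.
#' @param seed integer seed (embedding is deterministic per seed).
#' @param max_iter gradient-descent iterations.
#' @return An `embedding_result`: `coords` (n x 2), `perplexity`, `seed`.
#' @export
embed_features <- function(features, perplexity = 30, seed = 1L,
                           max_iter = 500L) {
  x <- feature_matrix(features, keep_aux = FALSE)
  if (nrow(x) <= 3 * perplexity) {
    stop("t-SNE needs n > 3 * perplexity (n = ", nrow(x),
         ", perplexity = ", perplexity, ")")
  }
  z <- standardize(impute_median(x)$x)$x
  fit <- with_seed(seed,
                   Rtsne::Rtsne(z, dims = 2, perplexity = perplexity,
                                check_duplicates = FALSE, pca = TRUE,
                                max_iter = max_iter, verbose = FALSE))
  structure(list(coords = fit$Y, perplexity = perplexity, seed = seed),
            class = "embedding_result")
}

#' Train the proliferating-vs-senescent condition classifier
#'
#' Fits an RBF support-vector machine on standardized non-auxiliary
#' features of the two reference classes. Treated samples must never be
#' part of `features` here; they are scored later with
#' [classify_treated()].
#'
#' @param features feature data.frame of reference samples.
#' @param labels vector with values `"proliferating"`/`"senescent"`.
#' @param kernel,cost SVM kernel and regularization (libsvm via e1071).
#' @param cross folds for the reported CV accuracy (0 to skip).
#' @param seed integer seed.
#' @return A `condition_model` with the SVM, preprocessing statistics,
#'   `cv_accuracy` and `training_accuracy`.
#' @export
train_condition <- function(features, labels, kernel = "radial", cost = 1,
                            cross = 5L, seed = 1L) {
  labels <- factor(as.character(labels),
                   levels = c("proliferating", "senescent"))
  if (any(is.na(labels)) || nlevels(droplevels(labels)) < 2) {
    stop("both 'proliferating' and 'senescent' samples are required")
  }
  x <- feature_matrix(features, keep_aux = FALSE)
  imp <- impute_median(x)
  std <- standardize(imp$x)
  fit <- with_seed(seed,
                   e1071::svm(x = std$x, y = labels, kernel = kernel,
                              cost = cost, cross = cross, scale = FALSE))
  train_pred <- stats::predict(fit, std$x)
  structure(list(svm = fit, kernel = kernel, cost = cost,
                 impute_medians = imp$medians, std_stats = std$stats,
                 feature_names = colnames(x),
                 classes = levels(labels),
                 cv_accuracy = if (cross > 0) fit$tot.accuracy / 100 else NA,
                 training_accuracy = mean(train_pred == labels)),
            class = "condition_model")
}

# score feature rows with a condition model; returns a factor
predict_condition <- function(model, features) {
  x <- feature_matrix(features, keep_aux = FALSE)
  x <- x[, model$feature_names, drop = FALSE]
  x <- impute_median(x, model$impute_medians)$x
  z <- standardize(x, model$std_stats)$x
  stats::predict(model$svm, z)
}

#' Classify treated cells against the reference classes
#'
#' Applies the condition SVM per cell and summarizes, per treatment
#' group, the fraction classified as proliferating-like vs
#' senescent-like. A group is called `"ambiguous"` when neither fraction
#' reaches 0.7.
#'
#' @param model a [train_condition()] model.
#' @param features feature data.frame of treated cells.
#' @param groups character vector of group labels (one per row).
#' @return A data.frame with `group`, `n`, `fraction_proliferating`,
#'   `fraction_senescent`, `call`; fractions sum to 1 per group.
#' @export
classify_treated <- function(model, features, groups) {
  stopifnot(length(groups) == nrow(as.data.frame(features)))
  if (is.factor(groups)) {
    empty <- setdiff(levels(groups), as.character(groups))
    if (length(empty)) warning("omitting empty group(s): ",
                               paste(empty, collapse = ", "))
  }
  present <- unique(as.character(groups))
  pred <- predict_condition(model, features)
  out <- do.call(rbind, lapply(present, function(g) {
    sel <- groups == g
    fp <- mean(pred[sel] == "proliferating")
    fs <- mean(pred[sel] == "senescent")
    data.frame(group = g, n = sum(sel),
               fraction_proliferating = fp, fraction_senescent = fs,
               call = if (fp >= 0.7) "proliferating"
                      else if (fs >= 0.7) "senescent" else "ambiguous")
  }))
  rownames(out) <- NULL
  out
}

#' Per-condition distribution summaries of selected features
#'
#' Produces a box-plot-ready table (n, median, quartiles) per condition
#' for the default trio of nuclear size, GLCM energy at distance 4 along
#' the x-axis, and GLCM dissimilarity at distance 2 along the y-axis.
#'
#' @param features feature data.frame.
#' @param labels condition label per row.
#' @param feature_names features to summarize.
#' @return A data.frame with `condition`, `feature`, `n`, `median`,
#'   `q25`, `q75`.
#' @export
condition_summaries <- function(features, labels,
                                feature_names = c("area_px",
                                                  "glcm_energy_d4_a0",
                                                  "glcm_dissimilarity_d2_a90")) {
  df <- as.data.frame(features)
  if (nrow(df) == 0) {
    return(data.frame(condition = character(0), feature = character(0),
                      n = integer(0), median = numeric(0),
                      q25 = numeric(0), q75 = numeric(0)))
  }
  missing <- setdiff(feature_names, colnames(df))
  if (length(missing)) stop("features not present: ",
                            paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(unique(labels), function(cond) {
    sel <- labels == cond
    do.call(rbind, lapply(feature_names, function(f) {
      v <- df[sel, f]
      v <- v[is.finite(v)]
      data.frame(condition = cond, feature = f, n = length(v),
                 median = stats::median(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 q75 = unname(stats::quantile(v, 0.75)))
    }))
  }))
  rownames(out) <- NULL
  out
}
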