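# Random-forest subtype classification: repeated stratified cross-validation,
# impurity importance, and thresholded screening of external populations.

#' Cross-validation configuration
#'
#' Defaults follow the evaluation protocol of the study design this package
#' implements: 10-fold stratified cross-validation repeated 100 times, 500
#' trees per forest. Tree hyperparameters beyond the ensemble size use the
#' randomForest defaults (unlimited depth, square-root features per split)
#' unless overridden.
#'
#' @param n_folds folds per repeat (>= 2); folds preserve class proportions
#'   to within one sample.
#' @param n_repeats number of repeated fold assignments.
#' @param n_trees trees per forest.
#' @param seed integer seed; identical configurations give bit-identical
#'   reports.
#' @param mtry features per split (`NULL` = `sqrt(p)` default).
#' @export
cv_config <- function(n_folds = 10, n_repeats = 100, n_trees = 500,
                      seed = 1L, mtry = NULL) {
  stopifnot(n_folds >= 2, n_repeats >= 1, n_trees >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed), mtry = mtry),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin, so
#' every fold's class proportions are within one sample of the global
#' proportions. Uses the current RNG stream.
#'
#' @param labels class label per sample.
#' @param n_folds number of folds.
#' @return integer fold id per sample.
#' @export
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(sample(n_folds), length(idx))
  }
  folds
}

#' Metrics from a confusion matrix
#'
#' @param cm square confusion matrix, truth in rows, prediction in columns.
#' @return list with per-class `sensitivity`, `specificity`, `precision`,
#'   overall `accuracy`, Cohen's `kappa`, and the class-size-weighted
#'   averages `sensitivity_w`, `specificity_w`, `precision_w`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  po <- sum(tp) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  w <- rowSums(cm) / total
  list(
    sensitivity = sens, specificity = spec, precision = prec,
    accuracy = po, kappa = kappa,
    sensitivity_w = sum(w * sens, na.rm = TRUE),
    specificity_w = sum(w * spec, na.rm = TRUE),
    precision_w = sum(w * prec, na.rm = TRUE)
  )
}

# one-vs-rest AUROC per class from a probability matrix
.class_auc <- function(truth, prob) {
  vapply(colnames(prob), function(cls) {
    resp <- truth == cls
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cls], quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  }, numeric(1))
}

.fit_rf <- function(xtr, ytr, config) {
  mtry <- config$mtry %||% max(1, floor(sqrt(ncol(xtr))))
  randomForest::randomForest(
    x = xtr, y = ytr, ntree = config$n_trees, mtry = mtry, importance = FALSE
  )
}

# map subtype labels to the case/control collapse ("C" = control)
.collapse_labels <- function(lab) {
  factor(ifelse(as.character(lab) == "C", "CONTROL", "CASE"),
         levels = c("CASE", "CONTROL"))
}

#' Repeated stratified cross-validation of the subtype classifier
#'
#' Trains one multi-class random forest per fold and evaluates held-out
#' predictions. Two views of the same fit are reported: the full multi-class
#' contrast over the subtype labels ("model 2" when labels are A/B/C) and,
#' when a control class `"C"` is present, the case-versus-control collapse
#' obtained by pooling the non-control classes ("model 1").
#'
#' In `"naive"` mode the feature schema (the selected profile) is taken as
#' given — the selection was made on the full cohort, as in the original
#' study design. In `"honest"` mode the profile is re-selected inside every
#' training fold from `cohort` so that held-out samples never influence the
#' control-absence criterion; this removes the selection leak at the price
#' of fold-dependent schemas.
#'
#' @param features numeric feature matrix from [encode_genotypes()] (samples
#'   in rows); may be `NULL` in honest mode.
#' @param labels class label per sample (e.g. `"A"`, `"B"`, `"C"`).
#' @param config a [cv_config()].
#' @param mode `"naive"` (default) or `"honest"`.
#' @param cohort the filtered `cohort_matrix`, required in honest mode.
#' @param profile_cfg a [profile_config()] for honest-mode reselection.
#' @return an object of class `cv_report`; see Details. Key components:
#'   `summary` / `summary_collapsed` (mean and min-max range of accuracy,
#'   kappa and per-class rates across repeats), `pooled_confusion` /
#'   `pooled_confusion_collapsed` (counts summed over repeats), `mdi`
#'   (per-variant mean decrease in impurity, normalised to sum 1 per fit and
#'   averaged), and `per_repeat`.
#' @export
cross_validate <- function(features, labels, config = cv_config(),
                           mode = c("naive", "honest"), cohort = NULL,
                           profile_cfg = profile_config()) {
  mode <- match.arg(mode)
  if (mode == "honest" && is.null(cohort)) stop("honest mode requires `cohort`")
  samples <- if (!is.null(features)) rownames(features) else cohort$samples
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("cross-validation requires at least two classes")
  n <- length(labels)
  if (!is.null(features)) stopifnot(nrow(features) == n)

  n_folds <- config$n_folds
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    n_folds <- max(2L, min_class)
    warning("smallest class has ", min_class,
            " members; folds reduced to ", n_folds)
  }
  classes <- levels(labels)
  has_control <- "C" %in% classes && length(classes) > 2

  set.seed(config$seed)
  per_repeat <- vector("list", config$n_repeats)
  pooled <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  mdi_sum <- NULL
  mdi_fits <- 0L

  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_folds(labels, n_folds)
    pred <- factor(rep(classes[1], n), levels = classes)
    prob <- matrix(NA_real_, n, length(classes), dimnames = list(samples, classes))
    for (f in seq_len(n_folds)) {
      tr <- folds != f; te <- !tr
      if (mode == "honest") {
        prof <- suppressWarnings(
          select_profile(subset_cohort(cohort, samples = samples[tr]), profile_cfg)
        )
        if (nrow(prof$variants) == 0) {
          # no variant qualifies in this fold: predict the majority class
          maj <- names(which.max(table(labels[tr])))
          pred[te] <- maj
          prob[te, ] <- 0; prob[te, maj] <- 1
          next
        }
        schema <- variant_key(prof$variants)
        xtr <- encode_genotypes(subset_cohort(cohort, samples = samples[tr]), schema)
        xte <- encode_genotypes(subset_cohort(cohort, samples = samples[te]), schema)
      } else {
        xtr <- features[tr, , drop = FALSE]
        xte <- features[te, , drop = FALSE]
      }
      colnames(xtr) <- colnames(xte) <- paste0("V", seq_len(ncol(xtr)))
      fit <- .fit_rf(xtr, droplevels(labels[tr]), config)
      pr <- predict(fit, xte, type = "prob")
      prob[te, colnames(pr)] <- pr
      prob[te, setdiff(classes, colnames(pr))] <- 0
      pred[te] <- colnames(pr)[max.col(pr, ties.method = "first")]
      imp <- fit$importance[, "MeanDecreaseGini"]
      if (mode == "naive") {
        imp_norm <- if (sum(imp) > 0) imp / sum(imp) else imp
        if (is.null(mdi_sum)) mdi_sum <- numeric(length(imp_norm))
        mdi_sum <- mdi_sum + imp_norm
        mdi_fits <- mdi_fits + 1L
      }
    }
    cm <- table(truth = labels, pred = factor(pred, levels = classes))
    pooled <- pooled + cm
    met <- confusion_metrics(cm)
    auc <- .class_auc(labels, prob)
    row <- data.frame(repeat_ = r, accuracy = met$accuracy, kappa = met$kappa)
    for (cls in classes) {
      row[[paste0("sens_", cls)]] <- met$sensitivity[cls]
      row[[paste0("spec_", cls)]] <- met$specificity[cls]
      row[[paste0("prec_", cls)]] <- met$precision[cls]
      row[[paste0("auc_", cls)]] <- auc[cls]
    }
    if (has_control) {
      cmc <- table(truth = .collapse_labels(labels),
                   pred = .collapse_labels(pred))
      metc <- confusion_metrics(cmc)
      prob_case <- rowSums(prob[, setdiff(classes, "C"), drop = FALSE])
      aucc <- .class_auc(.collapse_labels(labels),
                         cbind(CASE = prob_case, CONTROL = 1 - prob_case))
      row$accuracy_cc <- metc$accuracy
      row$kappa_cc <- metc$kappa
      row$sens_case <- metc$sensitivity["CASE"]
      row$spec_case <- metc$specificity["CASE"]
      row$prec_case <- metc$precision["CASE"]
      row$auc_case <- aucc["CASE"]
    }
    per_repeat[[r]] <- row
  }
  per_repeat <- do.call(rbind, per_repeat)

  summarise <- function(cols) {
    do.call(rbind, lapply(cols, function(cn) {
      v <- per_repeat[[cn]]
      data.frame(metric = cn, mean = mean(v, na.rm = TRUE),
                 min = suppressWarnings(min(v, na.rm = TRUE)),
                 max = suppressWarnings(max(v, na.rm = TRUE)))
    }))
  }
  metric_cols <- setdiff(names(per_repeat), "repeat_")
  cc_cols <- grep("_cc$|_case$", metric_cols, value = TRUE)

  pooled_cc <- NULL
  if (has_control) {
    truth_c <- .collapse_labels(labels)
    pooled_cc <- matrix(0, 2, 2, dimnames = list(levels(truth_c), levels(truth_c)))
    pooled_cc["CASE", "CASE"] <- sum(pooled[setdiff(classes, "C"), setdiff(classes, "C")])
    pooled_cc["CASE", "CONTROL"] <- sum(pooled[setdiff(classes, "C"), "C"])
    pooled_cc["CONTROL", "CASE"] <- sum(pooled["C", setdiff(classes, "C")])
    pooled_cc["CONTROL", "CONTROL"] <- pooled["C", "C"]
  }
  mdi <- NULL
  if (!is.null(mdi_sum) && !is.null(features)) {
    mdi <- data.frame(variant = colnames(features),
                      mdi = mdi_sum / mdi_fits)
    mdi <- mdi[order(-mdi$mdi), ]
    rownames(mdi) <- NULL
  }
  structure(list(
    summary = summarise(setdiff(metric_cols, cc_cols)),
    summary_collapsed = if (has_control) summarise(cc_cols) else NULL,
    pooled_confusion = pooled,
    pooled_confusion_collapsed = pooled_cc,
    mdi = mdi,
    per_repeat = per_repeat,
    classes = classes, n_folds = n_folds, mode = mode, config = config
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d repeats x %d folds (%s mode), classes: %s\n",
              x$config$n_repeats, x$n_folds, x$mode,
              paste(x$classes, collapse = "/")))
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("multi-class accuracy: %.3f (range %.3f-%.3f)\n",
              acc$mean, acc$min, acc$max))
  if (!is.null(x$summary_collapsed)) {
    acc2 <- x$summary_collapsed[x$summary_collapsed$metric == "accuracy_cc", ]
    cat(sprintf("case-vs-control accuracy: %.3f (range %.3f-%.3f)\n",
                acc2$mean, acc2$min, acc2$max))
  }
  invisible(x)
}

#' Train the final subtype model on all samples
#'
#' @param features numeric feature matrix from [encode_genotypes()].
#' @param labels class label per sample.
#' @param config a [cv_config()] (uses `n_trees`, `mtry`, `seed`).
#' @return an object of class `subtype_model` embedding the forest and the
#'   ordered feature schema (variant keys with the 0/1/2 encoding).
#' @export
train_final <- function(features, labels, config = cv_config()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training requires at least two classes")
  schema <- colnames(features)
  x <- features
  colnames(x) <- paste0("V", seq_along(schema))
  set.seed(config$seed)
  fit <- .fit_rf(x, labels, config)
  structure(list(forest = fit, schema = schema, classes = levels(labels),
                 config = config), class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("subtype_model: %d-tree forest over %d profile variants, classes %s\n",
              x$config$n_trees, length(x$schema),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Per-variant mean decrease in impurity
#'
#' Impurity (Gini) importance of the fitted ensemble, normalised to sum 1
#' and reported in descending order.
#'
#' @param model a `subtype_model`.
#' @export
mdi_importance <- function(model) {
  imp <- model$forest$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  out <- data.frame(variant = model$schema, mdi = as.numeric(imp))
  out <- out[order(-out$mdi), ]
  rownames(out) <- NULL
  out
}

#' Class probabilities of a subtype model on new samples
#'
#' @param model a `subtype_model`.
#' @param newdata a `cohort_matrix` or an encoded matrix whose columns are
#'   variant keys; variants absent from the new data encode as 0.
#' @return probability matrix (rows sum to 1), samples in rows.
#' @export
predict_subtype <- function(model, newdata) {
  enc <- if (inherits(newdata, "cohort_matrix")) {
    encode_genotypes(newdata, model$schema)
  } else {
    m <- matrix(0L, nrow(newdata), length(model$schema),
                dimnames = list(rownames(newdata), model$schema))
    shared <- intersect(colnames(newdata), model$schema)
    m[, shared] <- as.matrix(newdata[, shared, drop = FALSE])
    m
  }
  colnames(enc) <- paste0("V", seq_along(model$schema))
  predict(model$forest, enc, type = "prob")
}

#' Screen an external population with a score threshold
#'
#' Each individual is assigned the class with the highest predictive score
#' when that score reaches the threshold, else `"UNASSIGNED"`.
#'
#' @param model a `subtype_model`.
#' @param newdata a `cohort_matrix` or encoded matrix (see
#'   [predict_subtype()]); zero rows give an empty result.
#' @param score_threshold minimum class probability for assignment
#'   (default 0.9).
#' @return data.frame (`sample`, `class`, `score`) with a `counts` attribute
#'   tabulating assignments per class.
#' @export
screen_population <- function(model, newdata, score_threshold = 0.9) {
  stopifnot(score_threshold > 0, score_threshold <= 1)
  n <- if (inherits(newdata, "cohort_matrix")) length(newdata$samples) else nrow(newdata)
  lv <- c(model$classes, "UNASSIGNED")
  if (n == 0) {
    out <- data.frame(sample = character(0), class = character(0),
                      score = numeric(0))
    attr(out, "counts") <- setNames(rep(0L, length(lv)), lv)
    return(out)
  }
  prob <- predict_subtype(model, newdata)
  ids <- rownames(prob) %||% sprintf("X%04d", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in external data")
  best <- max.col(prob, ties.method = "first")
  score <- prob[cbind(seq_len(n), best)]
  cls <- ifelse(score >= score_threshold, colnames(prob)[best], "UNASSIGNED")
  out <- data.frame(sample = ids, class = cls, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(cls, levels = lv))
  out
}
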