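#' Confusion metrics for a binary SS classifier
#'
#' @param predictions,truth Equal-length vectors, `"SS"`/`"nonSS"` (or
#'   logical, `TRUE` = SS).
#' @return Object of class `eval_result`: counts `tp`, `fp`, `tn`, `fn` and
#'   percents `sensitivity`, `specificity`, `accuracy` (unrounded; display
#'   rounding to integers is left to the caller). When the truth contains only
#'   one class the undefined metric is `NA`.
#' @examples
#' evaluate_classifier(c("SS", "SS", "nonSS"), c("SS", "nonSS", "nonSS"))
#' @export
evaluate_classifier <- function(predictions, truth) {
  as_pos <- function(x) if (is.character(x)) x == "SS" else as.logical(x)
  pred <- as_pos(predictions); tr <- as_pos(truth)
  if (length(pred) != length(tr) || length(pred) == 0)
    stop_param("predictions and truth must be non-empty and equal length")
  if (anyNA(pred) || anyNA(tr)) stop_param("predictions/truth must be binary, no NA")
  tp <- sum(pred & tr); fp <- sum(pred & !tr)
  tn <- sum(!pred & !tr); fn <- sum(!pred & tr)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / length(pred)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("tp %d fp %d tn %d fn %d | sens/spec/acc = %s/%s/%s\n",
              x$tp, x$fp, x$tn, x$fn,
              ifelse(is.na(x$sensitivity), "NA", round_half_up(x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", round_half_up(x$specificity)),
              round_half_up(x$accuracy)))
  invisible(x)
}

truth_labels <- function(cohort, label = c("clinical", "aecg", "acr")) {
  label <- match.arg(label)
  status <- cohort[[paste0(label, "_ss")]]
  if (any(status == "unknown"))
    stop_param("every patient must be labeled SS/nonSS in ", paste0(label, "_ss"))
  status
}

#' Configuration grids for the classifier families
#'
#' The four families compared: `acr_eular` (score threshold; the published
#' rule fixes it at 4, cross-validation searches 1-9), `us` (grade threshold
#' 1-4), `simple` (conjunction of ACR/EULAR at 4 and US at grade threshold
#' 1-4), and `integrated` (grade threshold 1-4 x assigned US score x
#' integrated threshold 4-7).
#'
#' @param family One of `"acr_eular"`, `"us"`, `"simple"`, `"integrated"`.
#' @param acr_eular_thresholds Thresholds searched for the `acr_eular` family.
#' @param assigned_scores Assigned US scores spanned by the `integrated` grid.
#' @return Data frame with columns `family`, `acr_eular_threshold`,
#'   `us_grade_threshold`, `assigned_us_score`, `integrated_threshold` (`NA`
#'   where not applicable), in lexicographic order.
#' @export
config_grid <- function(family = c("acr_eular", "us", "simple", "integrated"),
                        acr_eular_thresholds = 4, assigned_scores = 1:3) {
  family <- match.arg(family)
  g <- switch(family,
    acr_eular = data.frame(acr_eular_threshold = acr_eular_thresholds,
                           us_grade_threshold = NA_integer_,
                           assigned_us_score = NA_integer_,
                           integrated_threshold = NA_integer_),
    us = data.frame(acr_eular_threshold = NA_integer_,
                    us_grade_threshold = 1:4,
                    assigned_us_score = NA_integer_,
                    integrated_threshold = NA_integer_),
    simple = data.frame(acr_eular_threshold = 4L,
                        us_grade_threshold = 1:4,
                        assigned_us_score = NA_integer_,
                        integrated_threshold = NA_integer_),
    integrated = {
      g <- expand.grid(us_grade_threshold = 1:4,
                       assigned_us_score = assigned_scores,
                       integrated_threshold = 4:7, KEEP.OUT.ATTRS = FALSE)
      g <- g[order(g$us_grade_threshold, g$assigned_us_score,
                   g$integrated_threshold), ]
      data.frame(acr_eular_threshold = 4L, g)
    })
  cbind(family = family, g, stringsAsFactors = FALSE)
}

# predict "SS"/"nonSS" for one grid row given per-patient acr scores + grades
predict_config <- function(row, acr_score, grade) {
  switch(as.character(row$family),
    acr_eular = classify_acr_eular(acr_score, row$acr_eular_threshold),
    us = classify_us(grade, row$us_grade_threshold),
    simple = classify_simple_combination(
      classify_acr_eular(acr_score, row$acr_eular_threshold),
      classify_us(grade, row$us_grade_threshold)),
    integrated = {
      cfg <- integrated_config(row$us_grade_threshold, row$assigned_us_score,
                               row$integrated_threshold, row$acr_eular_threshold)
      classify_integrated(integrated_score(acr_score, grade, cfg), cfg)
    },
    stop_param("unknown classifier family: ", row$family))
}

#' Threshold-grid sweep over all classifier families
#'
#' Evaluates, against a chosen truth label, the ACR/EULAR classifier at
#' threshold 4, the US-grade classifier at thresholds 1-4, the simple
#' conjunction at the four US thresholds, and the integrated system over the
#' full grid (4 grade thresholds x 3 assigned scores x 4 integrated
#' thresholds), i.e. 57 rows. Patients with unknown ACR/EULAR items are
#' excluded (with a message giving the count).
#'
#' @param cohort An [ss_cohort] with items and the truth label.
#' @param model A [us_model].
#' @param label Truth label column: `"clinical"` (default), `"aecg"`, `"acr"`.
#' @param families Families to include.
#' @return Data frame of class `sweep_result`: one row per configuration with
#'   the grid columns, confusion counts, `sensitivity`, `specificity`,
#'   `accuracy` (unrounded percents) and `best` flagging the
#'   accuracy-maximal row(s).
#' @export
sweep_configurations <- function(cohort, model,
                                 label = c("clinical", "aecg", "acr"),
                                 families = c("acr_eular", "us", "simple",
                                              "integrated")) {
  label <- match.arg(label)
  items <- as.matrix(cohort[, ITEMS, drop = FALSE])
  keep <- rowSums(is.na(items)) == 0
  if (any(!keep))
    message(sum(!keep), " patient(s) excluded for unknown ACR/EULAR items")
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0) stop_param("no patients with complete items")
  truth <- truth_labels(cohort, label)
  acr_score <- acr_eular_score(cohort)
  grade <- assign_grade(patient_score_sum(cohort, model), model)

  grid <- do.call(rbind, lapply(families, config_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ev <- evaluate_classifier(predict_config(grid[i, ], acr_score, grade), truth)
    cbind(grid[i, ], tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn,
          sensitivity = ev$sensitivity, specificity = ev$specificity,
          accuracy = ev$accuracy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$best <- out$accuracy == max(out$accuracy)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Partition patients into k folds of near-equal size
#'
#' A seeded uniform shuffle (not stratified) split into `k` folds whose sizes
#' differ by at most one.
#'
#' @param n Number of patients.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per patient index.
#' @examples
#' table(kfold_partition(62, 7, seed = 1))  # six folds of 9, one of 8
#' @export
kfold_partition <- function(n, k, seed = 1L) {
  if (k < 2 || k > n) stop_param("need 2 <= k <= n")
  run_with_seed(seed, {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
    fold
  })
}

#' K-fold cross-validated accuracy of a classifier family
#'
#' For each fold in turn, the family's free thresholds are selected by
#' maximizing training-set accuracy over the family's configuration grid
#' (ties broken by the lexicographically smallest configuration), the selected
#' configuration classifies the held-out fold, and the held-out predictions
#' are pooled over all folds into a single accuracy. US model coefficients
#' are held fixed throughout; only thresholds are trained.
#'
#' @inheritParams sweep_configurations
#' @param family Classifier family (see [config_grid]). The `acr_eular`
#'   family searches its score threshold over 1-9.
#' @param k Number of folds.
#' @param seed Seed for the fold partition.
#' @param grid Optional replacement configuration grid for the family.
#' @return List of class `cv_result`: `accuracy` (pooled percent, unrounded),
#'   `accuracy_1dp`, `fold` assignment, `selected` (per-fold chosen
#'   configuration rows), `family`, `k`, `seed`.
#' @export
cross_validate <- function(cohort, model, family = "integrated", k = 7,
                           seed = 1L, label = c("clinical", "aecg", "acr"),
                           grid = NULL) {
  label <- match.arg(label)
  items <- as.matrix(cohort[, ITEMS, drop = FALSE])
  keep <- rowSums(is.na(items)) == 0
  cohort <- cohort[keep, , drop = FALSE]
  truth <- truth_labels(cohort, label)
  acr_score <- acr_eular_score(cohort)
  grade <- assign_grade(patient_score_sum(cohort, model), model)
  n <- nrow(cohort)
  if (is.null(grid)) {
    grid <- if (family == "acr_eular") config_grid("acr_eular", acr_eular_thresholds = 1:9)
            else config_grid(family)
  }
  fold <- kfold_partition(n, k, seed)
  pred <- character(n)
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fold != f
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      evaluate_classifier(predict_config(grid[i, ], acr_score[train],
                                         grade[train]), truth[train])$accuracy
    }, numeric(1))
    best <- which(acc == max(acc))[1]  # grid is in lexicographic order
    selected[[f]] <- cbind(fold = f, grid[best, ], train_accuracy = acc[best])
    pred[!train] <- predict_config(grid[best, ], acr_score[!train], grade[!train])
  }
  accuracy <- evaluate_classifier(pred, truth)$accuracy
  structure(list(accuracy = accuracy,
                 accuracy_1dp = round_half_up(accuracy, 1),
                 fold = fold,
                 selected = do.call(rbind, selected),
                 family = family, k = k, seed = seed), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s family, seed %d): pooled accuracy %.1f%%\n",
              x$k, x$family, x$seed, x$accuracy_1dp))
  invisible(x)
}
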