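#' Per-gland US score, logit and probability
#'
#' A gland's US score is the number of positive scored findings (0/1 each);
#' which findings are scored depends on the model basis and gland type (see
#' [used_findings]). The gland logit is the linear predictor
#' `intercept + sum(beta_f * finding_f)` over the scored findings, and the
#' gland probability of SS is the logistic transform `1 / (1 + exp(-logit))`.
#'
#' @param findings Named numeric vector or list with entries among `hypo`,
#'   `band`, `irreg`, each 0 or 1. Unscored findings may be present (for a
#'   parotid gland an `irreg` entry is ignored).
#' @param gland_type `"parotid"` or `"submandibular"`.
#' @param model A [us_model].
#' @param basis `"AECG"` or `"ACR"` (a `us_model` is also accepted).
#' @return `gland_score()`: integer count of positive scored findings;
#'   `gland_logit()`: the linear predictor; `gland_probability()`: a
#'   probability in (0, 1).
#' @examples
#' m <- us_model("ACR")
#' gland_logit(c(hypo = 1, band = 1, irreg = 1), "submandibular", m)  # 2.38
#' gland_probability(0)  # 0.5
#' @export
gland_score <- function(findings, gland_type, basis) {
  used <- used_findings(basis, gland_type)
  vals <- unlist(findings)[used]
  if (anyNA(vals)) stop_param("missing value for scored finding(s): ",
                              paste(used[is.na(vals)], collapse = ", "))
  if (!all(vals %in% c(0, 1))) stop_param("findings must be 0 or 1")
  as.integer(sum(vals))
}

#' @rdname gland_score
#' @export
gland_logit <- function(findings, gland_type, model) {
  stopifnot(inherits(model, "us_model"))
  gland_type <- match.arg(gland_type, c("parotid", "submandibular"))
  cf <- model$coef[[gland_type]]
  used <- setdiff(names(cf), "intercept")
  vals <- unlist(findings)[used]
  if (anyNA(vals)) stop_param("missing value for scored finding(s): ",
                              paste(used[is.na(vals)], collapse = ", "))
  unname(cf[["intercept"]] + sum(cf[used] * vals))
}

#' @rdname gland_score
#' @param logit A finite linear-predictor value.
#' @export
gland_probability <- function(logit) {
  if (any(!is.finite(logit))) stop_param("logit must be finite")
  stats::plogis(logit)
}

# per-patient gland matrices: list of 4 matrices n x |used findings|,
# one per gland column prefix
cohort_gland_values <- function(cohort, model, gland) {
  gt <- gland_type_of(gland)
  used <- used_findings(model, gt)
  m <- as.matrix(cohort[, paste(gland, used, sep = "_"), drop = FALSE])
  if (anyNA(m))
    stop_param("cohort has missing scored findings for gland ", gland)
  colnames(m) <- used
  m
}

#' Patient-level US score sum, probability and grade
#'
#' The patient score sum adds the four gland scores (left/right parotid and
#' submandibular); its maximum is 10 under the AECG basis and 8 under the ACR
#' basis. The patient probability of SS is the arithmetic mean of the four
#' gland logistic probabilities. `assign_grade()` maps score sums to the
#' ordinal US grade 0-4 through the model's score-sum intervals.
#'
#' @param cohort An [ss_cohort] data frame (all 12 finding columns must be
#'   non-missing for the scored findings).
#' @param model A [us_model], or for `patient_score_sum()` a basis string.
#' @return Integer vector of score sums, numeric vector of probabilities, or
#'   integer vector of grades, one element per patient.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 5, seed = 1))
#' m <- us_model("AECG")
#' data.frame(sum = patient_score_sum(cohort, m),
#'            grade = assign_grade(patient_score_sum(cohort, m), m),
#'            prob = patient_probability(cohort, m))
#' @export
patient_score_sum <- function(cohort, model) {
  if (!inherits(model, "us_model")) model <- us_model(model)
  sums <- Reduce(`+`, lapply(GLANDS, function(g) {
    rowSums(cohort_gland_values(cohort, model, g))
  }))
  as.integer(sums)
}

#' @rdname patient_score_sum
#' @export
patient_probability <- function(cohort, model) {
  stopifnot(inherits(model, "us_model"))
  probs <- lapply(GLANDS, function(g) {
    cf <- model$coef[[gland_type_of(g)]]
    vals <- cohort_gland_values(cohort, model, g)
    eta <- cf[["intercept"]] + drop(vals %*% cf[colnames(vals)])
    stats::plogis(eta)
  })
  Reduce(`+`, probs) / length(probs)
}

#' @rdname patient_score_sum
#' @param score_sum Integer vector of patient score sums.
#' @export
assign_grade <- function(score_sum, model) {
  stopifnot(inherits(model, "us_model"))
  max_sum <- us_max_sum(model)
  if (any(is.na(score_sum) | score_sum < 0 | score_sum > max_sum | score_sum != floor(score_sum)))
    stop_param(sprintf("score sums must be integers in 0..%d", max_sum))
  gt <- model$grade_table
  gt$grade[findInterval(score_sum, gt$lower)]
}

#' Grade-wise summary of counts, probabilities and SS risk
#'
#' Groups a labeled cohort by US grade and reports, per grade, the SS and
#' non-SS counts, the mean/s.d./range of the patient probabilities, and the
#' empirical risk of SS, `100 * n_SS / (n_SS + n_nonSS)`, rounded half away
#' from zero to one decimal. Grades with no patients get `NA` risk (never 0).
#'
#' @inheritParams patient_score_sum
#' @param label Which status column defines SS: `"clinical"`, `"aecg"` or
#'   `"acr"`. Every patient must be labeled `SS` or `nonSS` in that column.
#' @return A data frame of class `grade_summary` with one row per grade 0-4:
#'   columns `grade`, `n_ss`, `n_nonss`, `prob_mean`, `prob_sd`, `prob_min`,
#'   `prob_max`, `risk_pct`.
#' @export
grade_summary <- function(cohort, model, label = c("aecg", "acr", "clinical")) {
  label <- match.arg(label)
  col <- paste0(label, "_ss")
  status <- cohort[[col]]
  if (any(status == "unknown"))
    stop_param("grade_summary requires every patient labeled SS/nonSS in ", col)
  grade <- assign_grade(patient_score_sum(cohort, model), model)
  prob <- patient_probability(cohort, model)
  out <- do.call(rbind, lapply(0:4, function(g) {
    in_g <- grade == g
    n_ss <- sum(in_g & status == "SS")
    n_nonss <- sum(in_g & status == "nonSS")
    p <- prob[in_g]
    data.frame(
      grade = g, n_ss = n_ss, n_nonss = n_nonss,
      prob_mean = if (length(p) > 0) mean(p) else NA_real_,
      prob_sd = if (length(p) > 1) stats::sd(p) else NA_real_,
      prob_min = if (length(p) > 0) min(p) else NA_real_,
      prob_max = if (length(p) > 0) max(p) else NA_real_,
      risk_pct = risk_percent(n_ss, n_nonss)
    )
  }))
  class(out) <- c("grade_summary", "data.frame")
  out
}

#' Empirical risk of SS as a percentage
#'
#' `100 * n_ss / (n_ss + n_nonss)`, rounded half away from zero to one
#' decimal; `NA` when the grade is empty.
#'
#' @param n_ss,n_nonss Patient counts.
#' @export
risk_percent <- function(n_ss, n_nonss) {
  total <- n_ss + n_nonss
  ifelse(total > 0, round_half_up(100 * n_ss / total, 1), NA_real_)
}

#' Exhaustive enumeration of patient finding configurations
#'
#' Enumerates every combination of the scored findings across the four glands
#' (4 x 4 x 8 x 8 = 1024 rows under the AECG basis; 2 x 2 x 8 x 8 = 256 under
#' ACR) and computes each configuration's score sum, grade and patient
#' probability. This brute-force table is the oracle for the theoretical
#' probability range attainable within each grade.
#'
#' @param model A [us_model].
#' @return A data frame with one row per configuration: the finding columns
#'   (as in [ss_cohort]), `score_sum`, `grade`, `probability`.
#' @examples
#' cfg <- enumerate_configurations(us_model("ACR"))
#' nrow(cfg)              # 256
#' max(cfg$probability)   # highest attainable patient probability
#' @export
enumerate_configurations <- function(model) {
  stopifnot(inherits(model, "us_model"))
  per_gland <- lapply(GLANDS, function(g) {
    used <- used_findings(model, gland_type_of(g))
    grid <- expand.grid(rep(list(0:1), length(used)), KEEP.OUT.ATTRS = FALSE)
    names(grid) <- paste(g, used, sep = "_")
    grid
  })
  idx <- expand.grid(lapply(per_gland, function(g) seq_len(nrow(g))),
                     KEEP.OUT.ATTRS = FALSE)
  conf <- do.call(cbind, lapply(seq_along(per_gland), function(i) {
    per_gland[[i]][idx[[i]], , drop = FALSE]
  }))
  rownames(conf) <- NULL
  # unscored findings fixed at 0 so the table is a valid cohort
  for (col in setdiff(finding_cols(), names(conf))) conf[[col]] <- 0L
  conf$patient_id <- sprintf("cfg%04d", seq_len(nrow(conf)))
  cohort <- as_ss_cohort(conf)
  conf$score_sum <- patient_score_sum(cohort, model)
  conf$grade <- assign_grade(conf$score_sum, model)
  conf$probability <- patient_probability(cohort, model)
  conf[, c(finding_cols(), "score_sum", "grade", "probability")]
}
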