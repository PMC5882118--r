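#' ACR/EULAR classification-criteria item score
#'
#' The weighted item score of the 2016 ACR/EULAR classification: 3 points each
#' for positive anti-SSA/Ro serology and labial gland biopsy, 1 point each for
#' positive ocular staining, Schirmer's test and the salivary flow test
#' (range 0-9). Records with unknown items are rejected, never imputed.
#'
#' @param cohort An [ss_cohort] data frame, or a named vector/list with the
#'   five item values.
#' @return Integer vector of scores in 0..9, one per patient.
#' @examples
#' acr_eular_score(c(anti_ssa = 1, labial_biopsy = 0, ocular_staining = 1,
#'                   schirmer = 0, salivary_flow = 0))  # 4
#' @export
acr_eular_score <- function(cohort) {
  weights <- c(anti_ssa = 3, labial_biopsy = 3, ocular_staining = 1,
               schirmer = 1, salivary_flow = 1)
  if (is.data.frame(cohort)) {
    items <- as.matrix(cohort[, ITEMS, drop = FALSE])
  } else {
    vals <- unlist(cohort)[ITEMS]
    items <- matrix(vals, 1, dimnames = list(NULL, ITEMS))
  }
  if (anyNA(items))
    stop_param("unknown ACR/EULAR item value(s) in row(s): ",
               paste(which(rowSums(is.na(items)) > 0), collapse = ", "))
  if (!all(items %in% c(0, 1))) stop_param("item values must be 0 or 1")
  as.integer(drop(items %*% weights[colnames(items)]))
}

#' Classify by the ACR/EULAR score alone
#'
#' @param score Integer vector of ACR/EULAR scores (0-9).
#' @param threshold Score threshold for SS (default 4, the published rule).
#' @return Character vector `"SS"`/`"nonSS"`.
#' @export
classify_acr_eular <- function(score, threshold = 4) {
  stopifnot(all(score %in% 0:9))
  ifelse(score >= threshold, "SS", "nonSS")
}

#' Classify by the US grade alone
#'
#' @param grade Integer vector of US grades (0-4).
#' @param grade_threshold Grade threshold for SS (1-4).
#' @return Character vector `"SS"`/`"nonSS"`.
#' @export
classify_us <- function(grade, grade_threshold) {
  stopifnot(all(grade %in% 0:4), grade_threshold %in% 1:4)
  ifelse(grade >= grade_threshold, "SS", "nonSS")
}

#' Simple conjunction of the ACR/EULAR and US classifications
#'
#' SS only when both component classifiers are positive.
#'
#' @param acr_eular_positive,us_positive Logical vectors (or `"SS"`/`"nonSS"`
#'   character vectors).
#' @return Character vector `"SS"`/`"nonSS"`.
#' @export
classify_simple_combination <- function(acr_eular_positive, us_positive) {
  as_pos <- function(x) if (is.character(x)) x == "SS" else as.logical(x)
  ifelse(as_pos(acr_eular_positive) & as_pos(us_positive), "SS", "nonSS")
}

#' Integrated score configuration
#'
#' The integrated system adds an assigned US score to the ACR/EULAR item score
#' when the patient's US grade reaches a threshold, and declares SS when the
#' sum reaches the integrated threshold. The recommended configuration
#' assigns US score 3 at US grade >= 2 and uses integrated threshold >= 5.
#'
#' @param us_grade_threshold US grade (1-4) at or above which the US score is
#'   assigned.
#' @param assigned_us_score US score (1-3) added when the grade threshold is
#'   met. A value of 4 is accepted with a warning (the evaluated grid caps at
#'   3); 0 degenerates to the ACR/EULAR classifier.
#' @param integrated_threshold Integrated score (4-12) at or above which SS is
#'   declared.
#' @param acr_eular_threshold Threshold for the ACR/EULAR-alone comparator
#'   (default 4).
#' @return An object of class `integrated_config`.
#' @examples
#' recommended_config()  # grade >= 2, assign 3, integrated threshold >= 5
#' @export
integrated_config <- function(us_grade_threshold = 2, assigned_us_score = 3,
                              integrated_threshold = 5, acr_eular_threshold = 4) {
  if (!us_grade_threshold %in% 1:4) stop_param("us_grade_threshold must be 1-4")
  if (!assigned_us_score %in% 0:4) stop_param("assigned_us_score must be 0-4")
  if (assigned_us_score == 4)
    warning("assigned_us_score 4 is outside the evaluated 1-3 range", call. = FALSE)
  if (!integrated_threshold %in% 4:12) stop_param("integrated_threshold must be 4-12")
  structure(list(us_grade_threshold = as.integer(us_grade_threshold),
                 assigned_us_score = as.integer(assigned_us_score),
                 integrated_threshold = as.integer(integrated_threshold),
                 acr_eular_threshold = as.integer(acr_eular_threshold)),
            class = "integrated_config")
}

#' @rdname integrated_config
#' @export
recommended_config <- function() integrated_config(2, 3, 5)

#' Integrated ACR/EULAR + US score and classification
#'
#' `integrated_score()` returns `acr_score + assigned_us_score * (grade >=
#' us_grade_threshold)` (range 0-12 for assigned scores up to 3);
#' `classify_integrated()` declares SS at `integrated_threshold`.
#'
#' @param acr_score Integer vector of ACR/EULAR scores (0-9).
#' @param grade Integer vector of US grades (0-4).
#' @param config An [integrated_config].
#' @param score Integer vector of integrated scores.
#' @return Integer score vector, or character `"SS"`/`"nonSS"` vector.
#' @examples
#' integrated_score(2, 3, recommended_config())      # 5
#' classify_integrated(5, recommended_config())      # "SS"
#' @export
integrated_score <- function(acr_score, grade, config = recommended_config()) {
  stopifnot(inherits(config, "integrated_config"),
            all(acr_score %in% 0:9), all(grade %in% 0:4))
  as.integer(acr_score +
    ifelse(grade >= config$us_grade_threshold, config$assigned_us_score, 0L))
}

#' @rdname integrated_score
#' @export
classify_integrated <- function(score, config = recommended_config()) {
  stopifnot(inherits(config, "integrated_config"), all(score >= 0))
  ifelse(score >= config$integrated_threshold, "SS", "nonSS")
}
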