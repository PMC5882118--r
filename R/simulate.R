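#' Synthetic cohort parameters
#'
#' Describes the statistical structure the scoring system assumes: disease
#' prevalence, per-status occurrence probabilities of the ultrasound findings
#' for each gland type, the probability that left and right glands of the same
#' type share identical findings, and the sensitivity/specificity of the five
#' ACR/EULAR items against clinical SS status.
#'
#' @param n_patients Number of patients (>= 1).
#' @param ss_prevalence Probability a patient has clinical SS.
#' @param finding_prob Nested list `finding_prob[[status]][[gland_type]]`, a
#'   named probability vector over `hypo`, `band`, `irreg`, with statuses
#'   `"SS"` and `"nonSS"` and gland types `"parotid"` and `"submandibular"`.
#' @param lr_concordance Probability that the right gland copies the left
#'   gland's findings exactly rather than being drawn independently. Mirrors
#'   the observation that disease severity matches between the left and right
#'   glands of the same type.
#' @param item_sens,item_spec Named probability vectors over the five item
#'   names (`anti_ssa`, `labial_biopsy`, `ocular_staining`, `schirmer`,
#'   `salivary_flow`): P(item positive | SS) and P(item negative | nonSS).
#' @param label_noise Probability that each of the AECG and ACR labels,
#'   independently, disagrees with the clinical status (criteria-based and
#'   clinical diagnoses of SS are concordant but not identical).
#' @param primary_frac Fraction of SS patients with primary (vs secondary) SS.
#' @param seed Integer seed; identical parameters give byte-identical cohorts.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients,
                          ss_prevalence = 0.6,
                          finding_prob = default_finding_prob(),
                          lr_concordance = 0.9,
                          item_sens = c(anti_ssa = 0.65, labial_biopsy = 0.68,
                                        ocular_staining = 0.55, schirmer = 0.52,
                                        salivary_flow = 0.55),
                          item_spec = c(anti_ssa = 0.88, labial_biopsy = 0.86,
                                        ocular_staining = 0.72, schirmer = 0.65,
                                        salivary_flow = 0.62),
                          label_noise = 0.03,
                          primary_frac = 0.64,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1 ||
      n_patients != floor(n_patients))
    stop_param("'n_patients' must be a single integer >= 1")
  check_prob(ss_prevalence, "ss_prevalence")
  check_prob(lr_concordance, "lr_concordance")
  check_prob(label_noise, "label_noise")
  check_prob(primary_frac, "primary_frac")
  for (st in c("SS", "nonSS")) for (gt in c("parotid", "submandibular")) {
    p <- finding_prob[[st]][[gt]]
    if (is.null(p) || !all(FINDINGS %in% names(p)))
      stop_param(sprintf("finding_prob$%s$%s must name all of %s",
                         st, gt, paste(FINDINGS, collapse = ", ")))
    for (f in FINDINGS) check_prob(unname(p[[f]]), sprintf("finding_prob$%s$%s[%s]", st, gt, f))
  }
  for (v in list(item_sens, item_spec)) {
    if (!all(ITEMS %in% names(v))) stop_param("item_sens/item_spec must name all five items")
    for (it in ITEMS) check_prob(unname(v[[it]]), it)
  }
  structure(list(
    n_patients = as.integer(n_patients), ss_prevalence = ss_prevalence,
    finding_prob = finding_prob, lr_concordance = lr_concordance,
    item_sens = item_sens[ITEMS], item_spec = item_spec[ITEMS],
    label_noise = label_noise, primary_frac = primary_frac,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @rdname cohort_params
#' @export
default_finding_prob <- function() {
  list(
    SS = list(
      parotid       = c(hypo = 0.75, band = 0.60, irreg = 0.30),
      submandibular = c(hypo = 0.78, band = 0.65, irreg = 0.60)
    ),
    nonSS = list(
      parotid       = c(hypo = 0.22, band = 0.15, irreg = 0.06),
      submandibular = c(hypo = 0.22, band = 0.18, irreg = 0.12)
    )
  )
}

#' Reference parameter set emulating the development cohort
#'
#' Returns [cohort_params] calibrated so that simulated cohorts of around
#' n = 213 patients reproduce, qualitatively, the grade structure the built-in
#' US models were derived from: SS risk strictly increasing with US grade,
#' grade-4 risk above 90%, and a substantial share of SS patients at high
#' grades.
#'
#' @param n_patients Cohort size (default 213).
#' @param seed Integer seed.
#' @return A `cohort_params` object.
#' @export
reference_cohort_params <- function(n_patients = 213, seed = 1L) {
  cohort_params(n_patients = n_patients, ss_prevalence = 133 / 213, seed = seed)
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort
#'
#' Draws clinical SS status from the prevalence; for each gland type draws the
#' left gland's findings independently given status, then copies them to the
#' right gland with probability `lr_concordance` (otherwise draws the right
#' gland independently); draws the five ACR/EULAR items from their
#' sensitivity (SS) or 1 - specificity (nonSS); and derives AECG/ACR labels
#' from the clinical status with flip probability `label_noise`.
#'
#' @param params A [cohort_params] object.
#' @return An [ss_cohort] data frame with `params$n_patients` rows.
#' @examples
#' cohort <- generate_cohort(reference_cohort_params(seed = 7))
#' table(cohort$clinical_ss)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  run_with_seed(params$seed, {
    ss <- stats::rbinom(n, 1, params$ss_prevalence) == 1
    status <- ifelse(ss, "SS", "nonSS")

    out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)))
    for (gtype in c("parotid", "submandibular")) {
      prefix <- if (gtype == "parotid") "pg" else "smg"
      p <- t(vapply(status, function(st) params$finding_prob[[st]][[gtype]][FINDINGS],
                    numeric(3)))
      left <- matrix(stats::rbinom(n * 3, 1, p), n, 3)
      fresh <- matrix(stats::rbinom(n * 3, 1, p), n, 3)
      copy <- stats::rbinom(n, 1, params$lr_concordance) == 1
      right <- ifelse(matrix(copy, n, 3), left, fresh)
      colnames(left) <- paste(prefix, "l", FINDINGS, sep = "_")
      colnames(right) <- paste(prefix, "r", FINDINGS, sep = "_")
      out <- cbind(out, left, right)
    }

    for (it in ITEMS) {
      p_pos <- ifelse(ss, params$item_sens[[it]], 1 - params$item_spec[[it]])
      out[[it]] <- stats::rbinom(n, 1, p_pos)
    }

    out$clinical_ss <- status
    for (col in c("aecg_ss", "acr_ss")) {
      flip <- stats::rbinom(n, 1, params$label_noise) == 1
      out[[col]] <- ifelse(flip, ifelse(ss, "nonSS", "SS"), status)
    }
    out$ss_subtype <- ifelse(ss,
      ifelse(stats::rbinom(n, 1, params$primary_frac) == 1, "primary", "secondary"),
      "none")
    as_ss_cohort(out)
  })
}
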