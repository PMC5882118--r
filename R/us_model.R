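#' Per-gland logistic US models for Sjogren's syndrome
#'
#' A US model carries, for each salivary gland type (parotid, submandibular),
#' an intercept and a log-odds coefficient for every ultrasound finding used by
#' that gland type, together with the score-sum intervals that map a patient's
#' summed gland scores to an ordinal US grade 0-4. Two reference coefficient
#' sets are built in, one fitted against AECG-based SS diagnoses and one
#' against ACR-based diagnoses.
#'
#' The scored binary findings are `hypo` (hypoechoic areas), `band`
#' (hyperechoic bands) and `irreg` (irregular gland border). Under the AECG
#' basis the parotid model uses `hypo` and `band`; under the ACR basis it uses
#' `hypo` only; the submandibular model uses all three findings under either
#' basis. An irregular border recorded for a parotid gland is carried through
#' input/output but never scored.
#'
#' @param basis `"AECG"` or `"ACR"`: which diagnostic criteria the model
#'   coefficients were fitted against.
#' @return An object of class `us_model`: a list with elements `basis`,
#'   `coef` (per gland type, named vector `intercept` plus one entry per used
#'   finding), `grade_table` (data frame of grade, lower and upper score-sum
#'   bounds) and `version`.
#' @examples
#' m <- us_model("AECG")
#' us_max_sum(m)       # 10: 2 findings x 2 parotids + 3 findings x 2 SMGs
#' us_model("ACR")$coef$submandibular
#' @export
us_model <- function(basis = c("AECG", "ACR")) {
  basis <- match.arg(basis)
  coef <- switch(basis,
    AECG = list(
      parotid       = c(intercept = -0.33, hypo = 1.65, band = 0.52),
      submandibular = c(intercept = -1.23, hypo = 1.91, band = 0.69, irreg = 0.89)
    ),
    ACR = list(
      parotid       = c(intercept = -0.51, hypo = 2.20),
      submandibular = c(intercept = -1.61, hypo = 1.98, band = 0.65, irreg = 1.36)
    )
  )
  grade_table <- switch(basis,
    AECG = data.frame(grade = 0:4, lower = c(0, 1, 3, 6, 9), upper = c(0, 2, 5, 8, 10)),
    ACR  = data.frame(grade = 0:4, lower = c(0, 1, 3, 6, 8), upper = c(0, 2, 5, 7, 8))
  )
  new_us_model(basis, coef, grade_table)
}

new_us_model <- function(basis, coef, grade_table, version = "1") {
  m <- structure(
    list(basis = basis, coef = coef, grade_table = grade_table, version = version),
    class = "us_model"
  )
  validate_us_model(m)
  m
}

validate_us_model <- function(m) {
  if (!m$basis %in% c("AECG", "ACR")) stop_param("basis must be AECG or ACR")
  for (gt in c("parotid", "submandibular")) {
    cf <- m$coef[[gt]]
    if (is.null(cf) || !"intercept" %in% names(cf))
      stop_param(sprintf("model lacks an intercept for %s glands", gt))
    beta <- cf[setdiff(names(cf), "intercept")]
    if (length(beta) == 0) stop_param(sprintf("no findings used for %s glands", gt))
    if (!all(names(beta) %in% c("hypo", "band", "irreg")))
      stop_param("unknown finding name in model coefficients")
  }
  gt <- m$grade_table
  if (!identical(gt$grade, 0:4)) stop_param("grade table must cover grades 0-4")
  # intervals contiguous, disjoint, covering 0..max_sum
  if (gt$lower[1] != 0 || any(gt$lower[-1] != gt$upper[-5] + 1) ||
      any(gt$upper < gt$lower))
    stop_param("grade intervals must be disjoint, contiguous and start at 0")
  if (gt$upper[5] != us_max_sum(m))
    stop_param("grade intervals must cover 0..max score sum")
  invisible(m)
}

#' @rdname us_model
#' @param model A `us_model` object.
#' @export
us_max_sum <- function(model) {
  sum(vapply(model$coef, function(cf) length(cf) - 1L, integer(1)) * 2L)
}

#' Findings used by a US model for a gland type
#'
#' @param basis `"AECG"` or `"ACR"`, or a `us_model` object.
#' @param gland_type `"parotid"` or `"submandibular"`.
#' @return Character vector of scored finding names, a subset of
#'   `c("hypo", "band", "irreg")`.
#' @examples
#' used_findings("ACR", "parotid")        # "hypo"
#' used_findings("AECG", "submandibular") # "hypo" "band" "irreg"
#' @export
used_findings <- function(basis, gland_type = c("parotid", "submandibular")) {
  gland_type <- match.arg(gland_type)
  model <- if (inherits(basis, "us_model")) basis else us_model(basis)
  setdiff(names(model$coef[[gland_type]]), "intercept")
}

#' @export
print.us_model <- function(x, ...) {
  cat(sprintf("US salivary gland model (%s basis, schema v%s)\n", x$basis, x$version))
  for (gt in names(x$coef)) {
    cf <- x$coef[[gt]]
    terms <- paste(sprintf("%+.2f*%s", cf[-1], names(cf)[-1]), collapse = " ")
    cat(sprintf("  %-13s logit = %.2f %s\n", gt, cf[["intercept"]], terms))
  }
  iv <- sprintf("%d-%d", x$grade_table$lower, x$grade_table$upper)
  iv[x$grade_table$lower == x$grade_table$upper] <-
    x$grade_table$lower[x$grade_table$lower == x$grade_table$upper]
  cat("  grades 0-4 at score sums:", paste(iv, collapse = ", "), "\n")
  invisible(x)
}

#' Read and write US model files
#'
#' Models are stored as human-readable YAML carrying a schema version and the
#' diagnostic basis, so a refitted coefficient set can be dropped in wherever
#' the built-in models are used. `read_us_model()` refuses files whose basis
#' does not match `expect_basis`.
#'
#' @param model A `us_model` object.
#' @param path File path.
#' @param expect_basis Optional basis the caller requires; a mismatch is an
#'   error.
#' @return `read_us_model()` returns a `us_model`; `write_us_model()` returns
#'   `path` invisibly.
#' @export
write_us_model <- function(model, path) {
  stopifnot(inherits(model, "us_model"))
  obj <- list(
    schema = "sgusdx-us-model",
    version = model$version,
    basis = model$basis,
    coefficients = lapply(model$coef, as.list),
    grade_table = list(
      grade = model$grade_table$grade,
      lower = model$grade_table$lower,
      upper = model$grade_table$upper
    )
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_us_model
#' @export
read_us_model <- function(path, expect_basis = NULL) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "sgusdx-us-model"))
    stop_param("not a sgusdx US model file: ", path)
  if (!is.null(expect_basis) && !identical(obj$basis, expect_basis))
    stop_param(sprintf("model file basis is %s but %s was required",
                       obj$basis, expect_basis))
  coef <- lapply(obj$coefficients, function(cf) unlist(cf))
  gt <- data.frame(grade = unlist(obj$grade_table$grade),
                   lower = unlist(obj$grade_table$lower),
                   upper = unlist(obj$grade_table$upper))
  new_us_model(obj$basis, coef, gt, version = as.character(obj$version %||% "1"))
}
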