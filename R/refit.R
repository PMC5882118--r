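#' Gland-level data for regression
#'
#' Pools the left and right glands of one gland type across a labeled cohort
#' into a per-gland data frame: the regression unit is the gland, not the
#' patient, and intra-patient correlation is deliberately ignored (the model
#' is a per-gland probability model).
#'
#' @param cohort An [ss_cohort] data frame.
#' @param gland_type `"parotid"` or `"submandibular"`.
#' @param label Which status column labels the glands: `"aecg"`, `"acr"` or
#'   `"clinical"`.
#' @return Data frame with columns `hypo`, `band`, `irreg`, `label` (0/1),
#'   two rows per patient.
#' @export
gland_data <- function(cohort, gland_type = c("parotid", "submandibular"),
                       label = c("aecg", "acr", "clinical")) {
  gland_type <- match.arg(gland_type)
  label <- match.arg(label)
  status <- cohort[[paste0(label, "_ss")]]
  if (any(status == "unknown"))
    stop_param("every patient must be labeled SS/nonSS in ", paste0(label, "_ss"))
  prefix <- if (gland_type == "parotid") "pg" else "smg"
  rows <- lapply(c("l", "r"), function(side) {
    d <- cohort[, paste(prefix, side, FINDINGS, sep = "_")]
    names(d) <- FINDINGS
    d$label <- as.integer(status == "SS")
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

or_wald <- function(tab) {
  # tab: 2x2 with rows finding 0/1, cols label 0/1
  a <- tab[2, 2]; b <- tab[2, 1]; c <- tab[1, 2]; d <- tab[1, 1]
  zero <- any(tab == 0)
  or <- (a * d) / (b * c)
  se <- if (zero) NA_real_ else sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = if (zero) NA_real_ else exp(log(or) - 1.96 * se),
       ci_high = if (zero) NA_real_ else exp(log(or) + 1.96 * se),
       zero_cell = zero)
}

#' Univariate screening of ultrasound findings
#'
#' For each finding, fits a single-predictor logistic regression of the gland
#' label and computes the closed-form 2x2 odds ratio with Wald 95% CI and a
#' chi-square test. Findings with logistic p < `alpha` are flagged as
#' candidates for the multivariable model. Tables with a zero cell report an
#' infinite or undefined odds ratio with a flag rather than failing.
#'
#' @param glands Data frame from [gland_data] (columns `hypo`, `band`,
#'   `irreg`, `label`).
#' @param alpha Candidate threshold on the logistic p-value (default 0.05).
#' @return Data frame with one row per finding: `finding`, `odds_ratio`,
#'   `ci95_low`, `ci95_high`, `p_logistic`, `p_chisq`, `candidate`,
#'   `zero_cell`, `separation`.
#' @export
univariate_screen <- function(glands, alpha = 0.05) {
  stopifnot(all(c(FINDINGS, "label") %in% names(glands)))
  if (length(unique(glands$label)) < 2)
    stop_param("labels must include both classes")
  out <- do.call(rbind, lapply(FINDINGS, function(f) {
    x <- glands[[f]]
    tab <- table(factor(x, levels = 0:1), factor(glands$label, levels = 0:1))
    orw <- or_wald(tab)
    p_chisq <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
    if (length(unique(x)) < 2) {
      return(data.frame(finding = f, odds_ratio = NA_real_, ci95_low = NA_real_,
                        ci95_high = NA_real_, p_logistic = NA_real_,
                        p_chisq = p_chisq, candidate = FALSE,
                        zero_cell = orw$zero_cell, separation = FALSE))
    }
    fit <- suppressWarnings(stats::glm(glands$label ~ x, family = stats::binomial(),
                                       control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    sm <- summary(fit)$coefficients
    p_log <- sm["x", "Pr(>|z|)"]
    sep <- any(abs(stats::coef(fit)) > 15) || orw$zero_cell
    # under (quasi-)separation the Wald p-value collapses toward 1;
    # gate on the chi-square p-value instead
    p_gate <- if (sep) p_chisq else p_log
    data.frame(finding = f, odds_ratio = orw$or, ci95_low = orw$ci_low,
               ci95_high = orw$ci_high, p_logistic = p_log, p_chisq = p_chisq,
               candidate = !is.na(p_gate) && p_gate < alpha,
               zero_cell = orw$zero_cell, separation = sep)
  }))
  rownames(out) <- NULL
  out
}

#' Multivariable logistic fit of gland label on candidate findings
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance 1e-8, at most 100 iterations) of the gland
#' label on the candidate findings, with Wald 95% confidence intervals and
#' p-values. Complete separation is flagged, with the coefficients still
#' reported.
#'
#' @param glands Data frame from [gland_data].
#' @param findings Non-empty character vector of candidate findings (no
#'   duplicates), a subset of `c("hypo", "band", "irreg")`.
#' @return Object of class `us_fit`: list with `intercept`, `coef` (data
#'   frame: `finding`, `estimate`, `se`, `odds_ratio`, `ci95_low`,
#'   `ci95_high`, `p_value`), `converged`, `separation`, `n`, `loglik`.
#' @export
fit_multivariable <- function(glands, findings) {
  if (length(findings) == 0) stop_param("'findings' must be non-empty")
  if (anyDuplicated(findings)) stop_param("duplicate findings")
  stopifnot(all(findings %in% FINDINGS))
  if (length(unique(glands$label)) < 2)
    stop_param("labels must include both classes")
  fml <- stats::reformulate(findings, response = "label")
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm(fml, data = glands, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(cond) { w <<- conditionMessage(cond); invokeRestart("muffleWarning") }
  )
  sm <- summary(fit)$coefficients
  est <- sm[findings, "Estimate"]
  se <- sm[findings, "Std. Error"]
  separation <- !is.null(w) && grepl("fitted probabilities numerically 0 or 1", w) ||
    any(abs(stats::coef(fit)) > 15)
  if (separation)
    warning("possible complete separation; coefficients unreliable", call. = FALSE)
  structure(list(
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    intercept_se = unname(sm["(Intercept)", "Std. Error"]),
    coef = data.frame(
      finding = findings, estimate = unname(est), se = unname(se),
      odds_ratio = exp(unname(est)),
      ci95_low = exp(unname(est) - 1.96 * unname(se)),
      ci95_high = exp(unname(est) + 1.96 * unname(se)),
      p_value = unname(sm[findings, "Pr(>|z|)"])
    ),
    converged = fit$converged, separation = separation,
    n = nrow(glands), loglik = as.numeric(stats::logLik(fit))
  ), class = "us_fit")
}

#' @export
print.us_fit <- function(x, ...) {
  cat(sprintf("Gland logistic fit (n = %d glands, %s%s)\n", x$n,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) ", separation suspected" else ""))
  cat(sprintf("  intercept %.3f\n", x$intercept))
  print(x$coef, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Refit the US model from a labeled cohort
#'
#' Re-derives a [us_model] from data: per gland type, univariate screening
#' selects candidate findings (logistic p < `alpha`), a multivariable
#' logistic fit estimates the coefficients, and the basis's score-sum grade
#' intervals are attached. When screening selects a finding set whose maximum
#' score sum differs from the built-in basis model, the grade intervals are
#' rebuilt as {0} plus four near-equal contiguous bins over 1..max.
#'
#' @inheritParams gland_data
#' @param basis `"AECG"` or `"ACR"` (sets the default label column and the
#'   grade intervals).
#' @param alpha Screening threshold.
#' @param screen If `FALSE`, skip screening and use the basis's canonical
#'   finding sets.
#' @return List with `model` (a `us_model`), `screen` and `fit` (per gland
#'   type).
#' @export
refit_us_model <- function(cohort, basis = c("AECG", "ACR"),
                           label = c("aecg", "acr", "clinical"),
                           alpha = 0.05, screen = TRUE) {
  basis <- match.arg(basis)
  label <- if (missing(label)) tolower(basis) else match.arg(label)
  canonical <- us_model(basis)
  screens <- list(); fits <- list(); coefs <- list()
  for (gt in c("parotid", "submandibular")) {
    gl <- gland_data(cohort, gt, label)
    sc <- univariate_screen(gl, alpha)
    screens[[gt]] <- sc
    cand <- if (screen) sc$finding[sc$candidate] else used_findings(basis, gt)
    if (length(cand) == 0)
      stop_param("no candidate findings survive screening for ", gt, " glands")
    fit <- fit_multivariable(gl, cand)
    fits[[gt]] <- fit
    coefs[[gt]] <- c(intercept = fit$intercept,
                     stats::setNames(fit$coef$estimate, fit$coef$finding))
  }
  max_sum <- 2 * sum(vapply(coefs, function(cf) length(cf) - 1L, integer(1)))
  if (max_sum == us_max_sum(canonical)) {
    gt_table <- canonical$grade_table
  } else {
    breaks <- round(seq(0, max_sum, length.out = 5))
    gt_table <- data.frame(
      grade = 0:4,
      lower = c(0, 1, breaks[2] + 1, breaks[3] + 1, breaks[4] + 1),
      upper = c(0, breaks[2], breaks[3], breaks[4], max_sum)
    )
  }
  model <- new_us_model(basis, coefs, gt_table, version = "refit-1")
  list(model = model, screen = screens, fit = fits)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, computes the tie-corrected standardized Wilcoxon
#' rank-sum statistic on the two groups alone and refers `sqrt(2) * |z|` to
#' the studentized range distribution with `k` groups (infinite degrees of
#' freedom), giving familywise-adjusted two-sided p-values. With
#' `method = "permutation"` the pairwise null distribution of `|z|` is
#' estimated by permuting the pooled values (unadjusted; used to validate the
#' large-sample approximation on small samples).
#'
#' @param groups List of >= 2 numeric vectors.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Permutations per pair for `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List of class `steel_dwass`: symmetric matrices `p` and
#'   `statistic` (z), and `method`. Pairs where either group has fewer than 2
#'   observations are `NA` (not testable).
#' @examples
#' set.seed(1)
#' g <- list(rnorm(20), rnorm(20, 5))
#' steel_dwass(g)$p[1, 2]   # far below 0.001
#' @export
steel_dwass <- function(groups, method = c("asymptotic", "permutation"),
                        n_perm = 2000, seed = 1L) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2) stop_param("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop_param("empty group")
  nm <- names(groups) %||% as.character(seq_len(k))
  p <- z <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pair_z <- function(x, y) {
    ni <- length(x); nj <- length(y); N <- ni + nj
    r <- rank(c(x, y))
    Ri <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    if (V <= 0) return(0)
    (Ri - E) / sqrt(V)
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- groups[[i]]; y <- groups[[j]]
    if (length(x) < 2 || length(y) < 2) next
    zz <- pair_z(x, y)
    z[i, j] <- z[j, i] <- zz
    if (method == "asymptotic") {
      pp <- stats::ptukey(sqrt(2) * abs(zz), nmeans = k, df = Inf,
                          lower.tail = FALSE)
    } else {
      pooled <- c(x, y); ni <- length(x)
      pp <- run_with_seed(seed + i * 1000L + j, {
        ref <- replicate(n_perm, {
          s <- sample(pooled)
          abs(pair_z(s[seq_len(ni)], s[-seq_len(ni)]))
        })
        (sum(ref >= abs(zz)) + 1) / (n_perm + 1)
      })
    }
    p[i, j] <- p[j, i] <- min(1, pp)
  }
  structure(list(p = p, statistic = z, method = method), class = "steel_dwass")
}

#' @export
print.steel_dwass <- function(x, ...) {
  cat(sprintf("Steel-Dwass all-pairs comparison (%s)\n", x$method))
  print(round(x$p, 4))
  invisible(x)
}
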