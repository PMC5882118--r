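# frozen oracle values computed directly from the logistic closed form
# 1/(1+exp(-x)) at the printed intercepts/coefficients
P_NEG_AECG <- 0.322211    # mean of plogis(-0.33), plogis(-1.23) over 4 glands
P_NEG_ACR  <- 0.2708911
P_POS_ACR  <- 0.8797568
P_POS_AECG <- 0.8842292

test_that("gland score counts only the findings the basis uses", {
  expect_identical(gland_score(all_findings(1), "submandibular", "AECG"), 3L)
  expect_identical(gland_score(c(hypo = 0, band = 1, irreg = 0), "parotid", "ACR"), 0L)
  expect_identical(gland_score(all_findings(0), "parotid", "AECG"), 0L)
  expect_identical(gland_score(c(hypo = 1, band = 0, irreg = 1), "parotid", "AECG"), 1L)
  expect_error(gland_score(c(hypo = NA, band = 0, irreg = 0), "parotid", "AECG"),
               "missing")
})

test_that("gland logits reproduce the printed linear predictors", {
  acr <- us_model("ACR")
  aecg <- us_model("AECG")
  expect_equal(gland_logit(all_findings(0), "submandibular", acr), -1.61)
  expect_equal(gland_logit(all_findings(1), "submandibular", acr), 2.38)
  expect_equal(gland_logit(all_findings(0), "parotid", aecg), -0.33)
  expect_equal(gland_logit(c(hypo = 1, band = 0, irreg = 1), "parotid", aecg),
               -0.33 + 1.65)  # irregular border never scored for parotids
})

test_that("gland probability is the logistic transform, monotone in the logit", {
  expect_equal(gland_probability(0), 0.5)
  expect_equal(gland_probability(-0.33), 0.4182406, tolerance = 1e-6)
  expect_equal(gland_probability(2.38), 0.9152894, tolerance = 1e-6)
  x <- seq(-6, 6, by = 0.5)
  expect_true(all(diff(gland_probability(x)) > 0))
  expect_true(all(gland_probability(x) > 0 & gland_probability(x) < 1))
  expect_error(gland_probability(Inf), "finite")
})

test_that("patient probabilities at the scoring extremes match the printed values", {
  neg <- uniform_cohort(1, 0)
  pos <- uniform_cohort(1, 1)
  expect_equal(patient_probability(neg, us_model("AECG")), P_NEG_AECG,
               tolerance = 1e-5)
  expect_equal(patient_probability(neg, us_model("ACR")), P_NEG_ACR,
               tolerance = 1e-5)
  expect_equal(patient_probability(pos, us_model("ACR")), P_POS_ACR,
               tolerance = 1e-5)
  expect_equal(patient_probability(pos, us_model("AECG")), P_POS_AECG,
               tolerance = 1e-5)
  # printed table values, at the paper's own rounding tolerance
  expect_equal(patient_probability(neg, us_model("AECG")), 0.322, tolerance = 0.002)
  expect_equal(patient_probability(neg, us_model("ACR")), 0.271, tolerance = 0.002)
  expect_equal(patient_probability(pos, us_model("ACR")), 0.879, tolerance = 0.0021)
  expect_equal(patient_probability(pos, us_model("AECG")), 0.884, tolerance = 0.002)
})

test_that("patient score sums span 0..10 (AECG) and 0..8 (ACR)", {
  expect_identical(patient_score_sum(uniform_cohort(1, 1), us_model("AECG")), 10L)
  expect_identical(patient_score_sum(uniform_cohort(1, 1), us_model("ACR")), 8L)
  expect_identical(patient_score_sum(uniform_cohort(1, 0), us_model("ACR")), 0L)
})

test_that("assign_grade is total and single-valued over the score range", {
  for (basis in c("AECG", "ACR")) {
    m <- us_model(basis)
    g <- assign_grade(0:us_max_sum(m), m)
    expect_length(g, us_max_sum(m) + 1)
    expect_true(all(g %in% 0:4))
    expect_true(all(diff(g) >= 0))  # grades are ordered in the score sum
    expect_error(assign_grade(us_max_sum(m) + 1, m))
    expect_error(assign_grade(-1, m))
  }
  m <- us_model("AECG")
  expect_identical(assign_grade(5L, m), 2L)
  expect_identical(assign_grade(0L, m), 0L)
  expect_identical(assign_grade(8L, us_model("ACR")), 4L)
})

test_that("flipping a used finding raises gland probability and never lowers patient outputs", {
  set.seed(42)
  for (basis in c("AECG", "ACR")) {
    m <- us_model(basis)
    for (rep in 1:25) {
      vals <- setNames(as.list(rbinom(12, 1, 0.5)), sgusdx:::finding_cols())
      base <- as_ss_cohort(cbind(data.frame(patient_id = "x"), as.data.frame(vals)))
      # pick a used finding currently 0 on a random gland
      g <- sample(sgusdx:::GLANDS, 1)
      used <- used_findings(m, sgusdx:::gland_type_of(g))
      cols <- paste(g, used, sep = "_")
      off <- cols[base[1, cols] == 0]
      if (length(off) == 0) next
      flip <- sample(off, 1)
      flipped <- base
      flipped[[flip]] <- 1L
      gt <- sgusdx:::gland_type_of(g)
      f0 <- unlist(base[1, paste(g, sgusdx:::FINDINGS, sep = "_")])
      f1 <- unlist(flipped[1, paste(g, sgusdx:::FINDINGS, sep = "_")])
      names(f0) <- names(f1) <- sgusdx:::FINDINGS
      expect_gt(gland_probability(gland_logit(f1, gt, m)),
                gland_probability(gland_logit(f0, gt, m)))
      expect_gte(patient_probability(flipped, m), patient_probability(base, m))
      s0 <- patient_score_sum(base, m); s1 <- patient_score_sum(flipped, m)
      expect_gte(s1, s0)
      expect_gte(assign_grade(s1, m), assign_grade(s0, m))
    }
  }
})

test_that("grade summary reports per-grade counts, probabilities and risks", {
  co <- separable_cohort(n_ss = 3, n_nonss = 5)
  gs <- grade_summary(co, us_model("AECG"), "clinical")
  expect_identical(gs$n_ss, c(0L, 0L, 0L, 0L, 3L))
  expect_identical(gs$n_nonss, c(5L, 0L, 0L, 0L, 0L))
  expect_equal(gs$risk_pct, c(0, NA, NA, NA, 100))  # empty grades NA, never 0
  expect_equal(gs$prob_mean[5], P_POS_AECG, tolerance = 1e-5)
  expect_true(all(is.na(gs$prob_mean[2:4])))
  expect_true(all(gs$prob_min <= gs$prob_mean & gs$prob_mean <= gs$prob_max,
                  na.rm = TRUE))
})

test_that("risks recomputed from the development-cohort counts match at one decimal", {
  aecg_ss    <- c(7, 17, 21, 39, 49)
  aecg_nonss <- c(21, 31, 17, 7, 4)
  expect_equal(risk_percent(aecg_ss, aecg_nonss), c(25.0, 35.4, 55.3, 84.8, 92.5))
  acr_ss    <- c(3, 20, 21, 30, 54)
  acr_nonss <- c(25, 36, 16, 6, 2)
  expect_equal(risk_percent(acr_ss, acr_nonss), c(10.7, 35.7, 56.8, 83.3, 96.4))
  expect_true(is.na(risk_percent(0, 0)))
})

test_that("enumeration covers every configuration consistently with the scorers", {
  for (basis in c("AECG", "ACR")) {
    m <- us_model(basis)
    e <- enumerate_configurations(m)
    expect_identical(nrow(e), if (basis == "AECG") 1024L else 256L)
    expect_identical(anyDuplicated(e[, sgusdx:::finding_cols()]), 0L)
    # rows consistent with the patient-level operations
    co <- as_ss_cohort(cbind(patient_id = sprintf("c%04d", seq_len(nrow(e))),
                             e[, sgusdx:::finding_cols()]))
    expect_identical(e$score_sum, patient_score_sum(co, m))
    expect_identical(e$grade, assign_grade(e$score_sum, m))
    expect_equal(e$probability, patient_probability(co, m))
  }
})

test_that("enumeration extremes equal the closed-form all-negative/all-positive means", {
  for (basis in c("AECG", "ACR")) {
    m <- us_model(basis)
    e <- enumerate_configurations(m)
    p_gland <- function(v) {
      mean(c(gland_probability(gland_logit(all_findings(v), "parotid", m)),
             gland_probability(gland_logit(all_findings(v), "submandibular", m))))
    }
    expect_equal(min(e$probability), p_gland(0), tolerance = 1e-12)
    expect_equal(max(e$probability), p_gland(1), tolerance = 1e-12)
    expect_equal(e$probability[e$score_sum == 0], p_gland(0))
    expect_equal(e$probability[e$score_sum == us_max_sum(m)], p_gland(1))
  }
})

test_that("theoretical per-grade probability intervals contain the printed ranges", {
  printed <- list(
    AECG = list(`0` = c(0.322, 0.322), `1` = c(0.358, 0.541),
                `2` = c(0.438, 0.768), `3` = c(0.652, 0.848),
                `4` = c(0.805, 0.884)),
    ACR = list(`0` = c(0.271, 0.271), `1` = c(0.298, 0.495),
               `2` = c(0.406, 0.782), `3` = c(0.645, 0.863),
               `4` = c(0.879, 0.879))
  )
  for (basis in names(printed)) {
    e <- enumerate_configurations(us_model(basis))
    for (g in names(printed[[basis]])) {
      theo <- range(e$probability[e$grade == as.integer(g)])
      rng <- printed[[basis]][[g]]
      expect_lte(theo[1], rng[1] + 0.002)
      expect_gte(theo[2], rng[2] - 0.002)
    }
  }
})
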