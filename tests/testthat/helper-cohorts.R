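# fixture builders used across test files

# a cohort where every patient has the same finding value in every gland
uniform_cohort <- function(n, value, items = NULL, labels = "unknown") {
  d <- data.frame(patient_id = sprintf("U%03d", seq_len(n)))
  for (col in sgusdx:::finding_cols()) d[[col]] <- value
  if (!is.null(items)) for (it in names(items)) d[[it]] <- items[[it]]
  d$clinical_ss <- labels
  as_ss_cohort(d)
}

# build one patient row from per-gland finding vectors (named hypo/band/irreg)
patient_row <- function(id, pg_l, pg_r = pg_l, smg_l = pg_l, smg_r = smg_l,
                        items = NULL, clinical = "unknown") {
  d <- data.frame(patient_id = id)
  glands <- list(pg_l = pg_l, pg_r = pg_r, smg_l = smg_l, smg_r = smg_r)
  for (g in names(glands)) {
    v <- glands[[g]]
    for (f in c("hypo", "band", "irreg"))
      d[[paste(g, f, sep = "_")]] <- unname(v[[f]])
  }
  if (!is.null(items)) for (it in names(items)) d[[it]] <- items[[it]]
  d$clinical_ss <- clinical
  d
}

all_findings <- function(value) c(hypo = value, band = value, irreg = value)

# small labeled cohort with known grade composition: SS patients all-positive,
# nonSS all-negative
separable_cohort <- function(n_ss, n_nonss) {
  rows <- c(
    lapply(seq_len(n_ss), function(i)
      patient_row(sprintf("S%02d", i), all_findings(1), clinical = "SS")),
    lapply(seq_len(n_nonss), function(i)
      patient_row(sprintf("N%02d", i), all_findings(0), clinical = "nonSS"))
  )
  d <- do.call(rbind, rows)
  d$aecg_ss <- d$clinical_ss
  d$acr_ss <- d$clinical_ss
  for (it in sgusdx:::ITEMS) d[[it]] <- 0L
  as_ss_cohort(d)
}
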