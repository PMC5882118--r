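#' Patient cohorts
#'
#' A cohort is a data frame (class `ss_cohort`) with one row per patient. The
#' twelve ultrasound finding columns are named `<gland>_<side>_<finding>` with
#' gland `pg` (parotid) or `smg` (submandibular), side `l`/`r`, and finding
#' `hypo` (hypoechoic area), `band` (hyperechoic band) or `irreg` (irregular
#' border), each coded 0/1 (NA = not recorded). The five ACR/EULAR item
#' columns (`anti_ssa`, `labial_biopsy`, `ocular_staining`, `schirmer`,
#' `salivary_flow`) are coded 0/1 with NA meaning unknown; scoring functions
#' reject unknown items rather than imputing. Label columns `clinical_ss`,
#' `aecg_ss`, `acr_ss` take values `"SS"`, `"nonSS"` or `"unknown"`, and
#' `ss_subtype` takes `"primary"`, `"secondary"`, `"none"` or `"unknown"`.
#'
#' @name ss_cohort
NULL

GLANDS <- c("pg_l", "pg_r", "smg_l", "smg_r")
FINDINGS <- c("hypo", "band", "irreg")
ITEMS <- c("anti_ssa", "labial_biopsy", "ocular_staining", "schirmer", "salivary_flow")
LABELS <- c("clinical_ss", "aecg_ss", "acr_ss")

finding_cols <- function() {
  as.vector(t(outer(GLANDS, FINDINGS, paste, sep = "_")))
}

cohort_cols <- function() {
  c("patient_id", finding_cols(), ITEMS, LABELS, "ss_subtype")
}

# map a gland column prefix to its gland type
gland_type_of <- function(gland) ifelse(startsWith(gland, "pg"), "parotid", "submandibular")

#' Construct and validate a cohort
#'
#' @param data A data frame with the columns described in [ss_cohort]. Label
#'   and item columns that are absent are added filled with `"unknown"`/`NA`.
#' @return A validated `ss_cohort` data frame with the canonical column order.
#' @export
as_ss_cohort <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("patient_id", finding_cols())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0)
    stop_param("cohort lacks required column(s): ", paste(missing, collapse = ", "))
  for (col in ITEMS) if (!col %in% names(data)) data[[col]] <- NA_integer_
  for (col in LABELS) if (!col %in% names(data)) data[[col]] <- "unknown"
  if (!"ss_subtype" %in% names(data)) data$ss_subtype <- "unknown"

  data$patient_id <- as.character(data$patient_id)
  if (anyDuplicated(data$patient_id))
    stop_param("duplicate patient_id: ",
               paste(unique(data$patient_id[duplicated(data$patient_id)]), collapse = ", "))

  bad <- character(0)
  for (col in c(finding_cols(), ITEMS)) {
    v <- data[[col]]
    ok <- is.na(v) | v %in% c(0, 1)
    if (!all(ok))
      bad <- c(bad, sprintf("row %d, column %s: %s",
                            which(!ok), col, v[!ok]))
    data[[col]] <- as.integer(v)
  }
  for (col in LABELS) {
    v <- as.character(data[[col]])
    v[is.na(v)] <- "unknown"
    ok <- v %in% c("SS", "nonSS", "unknown")
    if (!all(ok))
      bad <- c(bad, sprintf("row %d, column %s: %s", which(!ok), col, v[!ok]))
    data[[col]] <- v
  }
  v <- as.character(data$ss_subtype)
  v[is.na(v)] <- "unknown"
  ok <- v %in% c("primary", "secondary", "none", "unknown")
  if (!all(ok))
    bad <- c(bad, sprintf("row %d, column ss_subtype: %s", which(!ok), v[!ok]))
  data$ss_subtype <- v

  if (length(bad) > 0)
    stop_param("invalid cohort values:\n  ", paste(bad, collapse = "\n  "))

  data <- data[, cohort_cols()]
  class(data) <- c("ss_cohort", "data.frame")
  data
}

#' Read and write cohort CSV files
#'
#' One row per patient; see [ss_cohort] for the schema. Values `0`/`1` for
#' findings and items (empty or `NA` = unknown), `SS`/`nonSS`/`unknown` for
#' labels. A header is required.
#'
#' @param path File path.
#' @param cohort An `ss_cohort` data frame.
#' @return `read_cohort()` returns an `ss_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_param("cohort file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("patient_id", finding_cols()), names(data))
  if (length(missing) > 0)
    stop_param("cohort file ", path, " lacks column(s): ",
               paste(missing, collapse = ", "))
  for (col in c(finding_cols(), ITEMS)) {
    if (!col %in% names(data)) next
    v <- trimws(data[[col]])
    v[v %in% c("", "NA", "unknown")] <- NA
    num <- suppressWarnings(as.numeric(v))
    ok <- is.na(v) | (!is.na(num) & num %in% c(0, 1))
    if (!all(ok))
      stop_param("invalid cohort values:\n  ",
                 paste(sprintf("row %d, column %s: %s", which(!ok), col, v[!ok]),
                       collapse = "\n  "))
    data[[col]] <- as.integer(num)
  }
  as_ss_cohort(data)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_ss_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
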