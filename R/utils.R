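`%||%` <- function(a, b) if (is.null(a)) b else a

DAYS_PER_YEAR <- 365.25

#' Stop with a configuration error naming the offending field
#' @noRd
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_proportion <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    config_error(field, "must be a single proportion in [0, 1]")
  invisible(x)
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a single finite number")
  invisible(x)
}

#' Hash of an R object, via serialization to a temporary file
#'
#' Used to stamp every pipeline artifact with a digest of the run
#' configuration so reruns can be matched to their settings.
#' @param x any serializable R object
#' @return a 32-character md5 string
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Empty prototype tables for the four EHR inputs
#' @noRd
empty_tables <- function() {
  list(
    patients = data.table(patient_id = character(),
                          birth_date = as.Date(character()),
                          sex = character(), race = character()),
    labs = data.table(patient_id = character(), date = as.Date(character()),
                      lab_type = character(), value = numeric(),
                      inpatient = logical()),
    codes = data.table(patient_id = character(), date = as.Date(character()),
                       icd9 = character()),
    meds = data.table(patient_id = character(), date = as.Date(character()),
                      drug_class = character(), drug_name = character())
  )
}

#' Validate that the four input tables have the expected columns
#' @noRd
validate_tables <- function(tables) {
  need <- list(
    patients = c("patient_id", "birth_date", "sex", "race"),
    labs = c("patient_id", "date", "lab_type", "value", "inpatient"),
    codes = c("patient_id", "date", "icd9"),
    meds = c("patient_id", "date", "drug_class", "drug_name")
  )
  for (nm in names(need)) {
    if (is.null(tables[[nm]]))
      stop(sprintf("missing input table '%s'", nm), call. = FALSE)
    missing_cols <- setdiff(need[[nm]], names(tables[[nm]]))
    if (length(missing_cols))
      stop(sprintf("table '%s' lacks required column(s): %s",
                   nm, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

as_dt <- function(x) {
  x <- as.data.table(x)
  # normalise every calendar column to plain Date (fread yields IDate,
  # whose arithmetic does not mix with Date)
  for (cc in intersect(c("date", "birth_date", "median_ldl_date"),
                       names(x)))
    if (!identical(class(x[[cc]]), "Date"))
      set(x, j = cc, value = as.Date(x[[cc]]))
  x
}
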