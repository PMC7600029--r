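# shared fixtures: tiny hand-built cohorts and a toy fracture catalog,
# constructed in code at test time

suppressMessages(library(data.table))

idate <- function(x) data.table::as.IDate(x)

# write a CSV from rows of strings and return the path
write_csv_fixture <- function(header, rows = character(0)) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, rows), path)
  path
}

# an ehr_cohort built directly from event vectors
make_cohort <- function(diag, demo = NULL, meds = NULL) {
  dd <- data.table::as.data.table(diag)
  dd[, date := idate(date)]
  if (!is.null(meds)) {
    meds <- data.table::as.data.table(meds)
    meds[, date := idate(date)]
  }
  if (!is.null(demo)) {
    demo <- data.table::as.data.table(demo)
    demo[, birth_date := idate(birth_date)]
  }
  assemble_records(dd, meds, demo)
}

# a one-patient record with given diagnosis dates/codes
make_record <- function(dates, codes, birth = "1950-01-01", sex = "female",
                        id = "P1") {
  co <- make_cohort(
    data.table(patient_id = id, date = dates, code = codes),
    demo = data.table(patient_id = id, birth_date = birth, sex = sex))
  patient_record(co, id)
}

# 20-token toy fracture catalog: 10 fracture patterns, 10 non-fracture tokens
toy_catalog <- function() {
  cat <- data.table::data.table(
    code_pattern = c("ICD10:S72.0", "ICD10:S72.1", "ICD10:S52", "ICD10:S42",
                     "ICD10:S22.0", "ICD10:S32.0", "ICD10:S32.3", "ICD9:820",
                     "ICD9:813", "ICD9:805"),
    site = c("hip", "hip", "wrist/forearm", "humerus", "vertebral",
             "vertebral", "pelvis", "hip", "wrist/forearm", "vertebral"))
  cat <- cat[order(-nchar(code_pattern), code_pattern)]
  structure(cat, class = c("fracture_catalog", class(cat)))
}

toy_nonfracture_tokens <- function() {
  c("ICD10:E11.9", "ICD10:I10", "ICD10:J45", "ICD10:M17.0", "ICD10:K21.9",
    "ICD9:401.9", "ICD9:250.00", "SYN:0001", "SYN:0042", "CPT:77080")
}

# small deterministic synthetic cohorts shared across test files (cached)
.synth_cache <- new.env(parent = emptyenv())
cached_synth <- function(key, config) {
  if (!exists(key, .synth_cache)) {
    assign(key, generate_cohort(config), .synth_cache)
  }
  get(key, .synth_cache)
}

default_pan_1000 <- function() {
  cached_synth("pan1000", generator_config(n_patients = 1000, seed = 2024L))
}

# brute-force AUROC by pairwise concordance (independent oracle)
brute_force_auroc <- function(p, y) {
  pos <- p[as.logical(y)]
  neg <- p[!as.logical(y)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
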