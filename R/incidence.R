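# Internal incidence helpers shared by the PheWAS, pair and score stages.

# first diagnosis date per (person, code), optionally restricted to codes
code_first_dates <- function(registry, codes = NULL) {
  dx <- registry$diagnoses
  if (!is.null(codes)) dx <- dx[code %chin% codes]
  dx[, .(first_date = min(date)), by = .(person_id, code)]
}

# For the exposed arm of a cohort: integer-date matrix (person x code) of
# first diagnoses plus logical matrices `prior` (first diagnosis before
# follow-up start) and `during` (first diagnosis inside the follow-up
# window). Row order follows the exposed rows of the cohort.
exposed_incidence <- function(cohort, registry, codes) {
  expo <- cohort[role == "exposed", .(person_id, fu_start, fu_end)]
  n <- nrow(expo)
  K <- length(codes)
  fdate <- matrix(NA_integer_, n, K, dimnames = list(NULL, codes))
  if (n > 0L && K > 0L) {
    fd <- code_first_dates(registry, codes)
    fd <- fd[expo, on = "person_id", nomatch = NULL]
    fd[, `:=`(row = match(person_id, expo$person_id), col = match(code, codes))]
    fdate[cbind(fd$row, fd$col)] <- as.integer(fd$first_date)
  }
  prior <- !is.na(fdate) & fdate < as.integer(expo$fu_start)
  during <- !is.na(fdate) &
    fdate >= as.integer(expo$fu_start) & fdate <= as.integer(expo$fu_end)
  list(persons = expo, first_date = fdate, prior = prior, during = during)
}

# candidate outcome codes: everything in the registry except exposure prefixes
candidate_codes <- function(registry, exposure_codes) {
  codes <- sort(unique(registry$diagnoses$code))
  codes[!matches_prefix(codes, exposure_codes)]
}
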