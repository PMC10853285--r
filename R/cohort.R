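#' Configuration for matched-cohort construction
#'
#' @param exposure_codes character vector of ICD-10 code prefixes defining the
#'   exposure (index diagnosis), e.g. `c("F40", "F41", "F43")`.
#' @param match_ratio maximum number of matched unexposed controls per exposed
#'   person (default 10, the classic 1:10 register design).
#' @param washout_days days between the index date and the start of outcome
#'   follow-up; the 183-day default approximates the 6-month washout that
#'   guards against reverse causality.
#' @param exclusion_codes code prefixes whose occurrence strictly before the
#'   index date disqualifies a person (history of other psychiatric disorders
#'   or severe somatic disease in the motivating design).
#' @param seed integer seed for control sampling.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(exposure_codes,
                          match_ratio = 10L,
                          washout_days = 183L,
                          exclusion_codes = character(),
                          seed = 1L) {
  if (length(exposure_codes) == 0L)
    stopf("`exposure_codes` must contain at least one code prefix")
  match_ratio <- assert_count(match_ratio, "match_ratio", min = 1L)
  if (!is.numeric(washout_days) || washout_days < 0)
    stopf("`washout_days` must be >= 0")
  structure(list(exposure_codes = as.character(exposure_codes),
                 match_ratio = match_ratio,
                 washout_days = as.integer(washout_days),
                 exclusion_codes = as.character(exclusion_codes),
                 seed = assert_count(seed, "seed")),
            class = "cohort_config")
}

matches_prefix <- function(codes, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

# first date per person of any diagnosis matching the prefixes (Inf-free:
# persons without a match are absent)
first_prefix_date <- function(diagnoses, prefixes) {
  dx <- diagnoses[matches_prefix(code, prefixes)]
  if (nrow(dx) == 0L)
    return(data.table(person_id = integer(), first_date = as.IDate(integer())))
  dx[, .(first_date = min(date)), by = person_id]
}

#' Identify exposed persons and their index dates
#'
#' The index date is the first diagnosis matching any exposure prefix.
#' Persons with any exclusion-prefix diagnosis strictly before their index
#' date are removed.
#'
#' @param registry a `registry`.
#' @param cfg a [cohort_config()].
#' @return data.table (person_id, index_date), one row per exposed person.
#' @export
identify_exposed <- function(registry, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  exposed <- first_prefix_date(registry$diagnoses, cfg$exposure_codes)
  setnames(exposed, "first_date", "index_date")
  if (nrow(exposed) == 0L) return(exposed[])
  if (length(cfg$exclusion_codes) > 0L) {
    excl <- first_prefix_date(registry$diagnoses, cfg$exclusion_codes)
    exposed <- excl[exposed, on = "person_id"]
    exposed <- exposed[is.na(first_date) | first_date >= index_date]
    exposed[, first_date := NULL]
  }
  setorder(exposed, index_date, person_id)
  exposed[]
}

#' Sample matched controls by incidence-density sampling
#'
#' For each exposed person, the risk set at the index date consists of all
#' persons of the same sex and birth year who are alive, not dropped out, not
#' yet exposed, and free of exclusion-code history at that date.  Up to
#' `match_ratio` controls are sampled uniformly without replacement within the
#' set; a person may serve as a control in several sets and a person exposed
#' later may serve as a control for an earlier index date (the incidence-
#' density contract).  Controls inherit the set's index date.  Sets with zero
#' eligible controls keep the exposed member only and are counted in the
#' `n_unmatched` attribute.
#'
#' @inheritParams identify_exposed
#' @param exposed output of [identify_exposed()].
#' @return data.table (set_id, person_id, role, index_date, sex, birth_year),
#'   class `matched_cohort`.
#' @export
sample_matched_controls <- function(registry, exposed, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (nrow(exposed) == 0L) stopf("`exposed` is empty")
  set.seed(cfg$seed)
  persons <- registry$persons
  inf_day <- as.IDate(.Machine$integer.max %/% 4L)
  # per-person event dates, Inf-coded for "never"
  all_exp <- first_prefix_date(registry$diagnoses, cfg$exposure_codes)
  excl <- first_prefix_date(registry$diagnoses, cfg$exclusion_codes)
  attrs <- copy(persons)
  attrs[, death := fifelse(is.na(death_date), inf_day, death_date)]
  attrs[, dropout := fifelse(is.na(dropout_date), inf_day, dropout_date)]
  attrs[all_exp, exp_date := i.first_date, on = "person_id"]
  attrs[, exp_date := fifelse(is.na(exp_date), inf_day, exp_date)]
  attrs[excl, excl_date := i.first_date, on = "person_id"]
  attrs[, excl_date := fifelse(is.na(excl_date), inf_day, excl_date)]

  exp_tab <- attrs[exposed, on = "person_id",
                   .(person_id, index_date = i.index_date, sex, birth_year)]
  setorder(exp_tab, index_date, person_id)
  out <- vector("list", nrow(exp_tab))
  n_unmatched <- 0L
  groups <- split(seq_len(nrow(exp_tab)),
                  list(exp_tab$sex, exp_tab$birth_year), drop = TRUE)
  for (g in groups) {
    gsex <- exp_tab$sex[g[1L]]
    gyr <- exp_tab$birth_year[g[1L]]
    pool <- attrs[sex == gsex & birth_year == gyr]
    for (i in g) {
      idx <- exp_tab$index_date[i]
      elig <- pool[death > idx & dropout > idx & exp_date > idx &
                     excl_date >= idx, person_id]
      k <- min(cfg$match_ratio, length(elig))
      ctrl <- if (k > 0L) elig[sample.int(length(elig), k)] else integer()
      if (k == 0L) n_unmatched <- n_unmatched + 1L
      out[[i]] <- data.table(
        set_id = i,
        person_id = c(exp_tab$person_id[i], ctrl),
        role = c("exposed", rep("control", k)),
        index_date = idx, sex = gsex, birth_year = gyr)
    }
  }
  cohort <- rbindlist(out)
  setattr(cohort, "n_unmatched", n_unmatched)
  setattr(cohort, "class", c("matched_cohort", class(cohort)))
  cohort[]
}

#' Apply follow-up window rules to a matched cohort
#'
#' Follow-up starts `washout_days` after the index date and ends at the
#' earliest of death, dropout (emigration), the person's own exposure
#' (controls only), and the administrative study end.  Rows whose end
#' precedes their start are dropped and counted in the `n_dropped` attribute.
#'
#' @param cohort a `matched_cohort`.
#' @param registry the `registry` the cohort was drawn from.
#' @param cfg a [cohort_config()] (supplies washout and exposure codes).
#' @param study_end end of the study period (default: the registry's).
#' @return the cohort with columns fu_start, fu_end, end_reason added.
#' @export
apply_followup <- function(cohort, registry, cfg, study_end = registry$study_end) {
  stopifnot(inherits(cfg, "cohort_config"))
  cohort <- copy(cohort)
  inf_day <- as.IDate(.Machine$integer.max %/% 4L)
  persons <- registry$persons
  all_exp <- first_prefix_date(registry$diagnoses, cfg$exposure_codes)
  cohort[persons, `:=`(death = i.death_date, dropout = i.dropout_date),
         on = "person_id"]
  cohort[all_exp, own_exp := i.first_date, on = "person_id"]
  cohort[, `:=`(
    death = fifelse(is.na(death), inf_day, death),
    dropout = fifelse(is.na(dropout), inf_day, dropout),
    own_exp = fifelse(is.na(own_exp) | role == "exposed", inf_day, own_exp))]
  cohort[, fu_start := index_date + cfg$washout_days]
  ends <- cohort[, cbind(as.integer(death), as.integer(dropout),
                         as.integer(own_exp), as.integer(as.IDate(study_end)))]
  reason <- c("death", "dropout", "exposure", "study_end")
  which_end <- max.col(-ends, ties.method = "first")
  cohort[, fu_end := as.IDate(ends[cbind(.I, which_end)])]
  cohort[, end_reason := reason[which_end]]
  cohort[, c("death", "dropout", "own_exp") := NULL]
  n_dropped <- cohort[fu_end < fu_start, .N]
  cohort <- cohort[fu_end >= fu_start]
  setattr(cohort, "n_dropped", n_dropped)
  setattr(cohort, "class", unique(c("matched_cohort", class(cohort))))
  cohort[]
}

#' Build the full matched cohort in one call
#'
#' Chains [identify_exposed()], [sample_matched_controls()] and
#' [apply_followup()].
#'
#' @inheritParams apply_followup
#' @return a `matched_cohort` with follow-up windows.
#' @export
build_cohort <- function(registry, cfg, study_end = registry$study_end) {
  exposed <- identify_exposed(registry, cfg)
  if (nrow(exposed) == 0L) {
    empty <- data.table(set_id = integer(), person_id = integer(),
                        role = character(), index_date = as.IDate(integer()),
                        sex = character(), birth_year = integer(),
                        fu_start = as.IDate(integer()),
                        fu_end = as.IDate(integer()), end_reason = character())
    setattr(empty, "class", c("matched_cohort", class(empty)))
    return(empty[])
  }
  cohort <- sample_matched_controls(registry, exposed, cfg)
  apply_followup(cohort, registry, cfg, study_end)
}
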