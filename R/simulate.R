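#' Simulate a registry with planted cluster structure
#'
#' Runs the discrete-time competing-hazard simulation described in
#' [sim_config()].  Time advances in 30-day ticks from 1 January of
#' `study_start` to 31 December of `study_end`.  Within a tick the order of
#' events is: exposure onset, disease events (in catalog order), death,
#' dropout, so a diagnosis may share its date with the person's death.  Only
#' the first occurrence of each (person, code) is recorded: downstream
#' analyses condition on first diagnoses throughout.  Cascade boosts are
#' evaluated against the state at the start of the tick, so an upstream event
#' can influence its downstream code no earlier than the next tick.
#'
#' @param config a [sim_config()].
#' @return An object of class `registry`: a list with data.tables `persons`
#'   (person_id, sex, birth_year, death_date, dropout_date) and `diagnoses`
#'   (person_id, code, date).  Dates are `IDate`.
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  origin <- as.IDate(sprintf("%d-01-01", config$study_start))
  last_day <- as.IDate(sprintf("%d-12-31", config$study_end))
  n_ticks <- as.integer(last_day - origin) %/% TICK_DAYS + 1L

  sex <- ifelse(runif(n) < config$p_female, "F", "M")
  byr <- config$birth_year_range
  birth_year <- byr[1L] + as.integer(floor(runif(n) * (byr[2L] - byr[1L] + 1L)))

  codes <- config$disease_catalog$code
  K <- length(codes)
  base_p <- pmin(config$disease_catalog$hazard / TICKS_PER_YEAR, 1)
  p_exp <- min(config$p_exposure / TICKS_PER_YEAR, 1)
  p_death <- min(config$death_hazard / TICKS_PER_YEAR, 1)
  p_drop <- min(config$dropout_hazard / TICKS_PER_YEAR, 1)

  # per-code boost structure from the planted clusters
  exp_hr <- rep(1, K)                     # exposure hazard ratio per code
  cascade_hr <- rep(1, K)                 # cascade hazard ratio per code
  upstream_cols <- vector("list", K)      # catalog indices of upstream codes
  lag_days <- rep(0L, K)
  code_idx <- function(x) match(x, codes)
  for (cl in config$clusters) {
    members <- code_idx(c(cl$root_codes, cl$downstream_codes))
    exp_hr[members] <- cl$hr_exposure
    ds <- code_idx(cl$downstream_codes)
    for (p in seq_along(ds)) {
      k <- ds[p]
      cascade_hr[k] <- cl$hr_cascade
      # all roots plus every earlier downstream code are upstream of k; the
      # boost compounds per occurred upstream member, planting a preferred
      # order for every (earlier, later) member pair
      upstream_cols[[k]] <- c(code_idx(cl$root_codes), ds[seq_len(p - 1L)])
      lag_days[k] <- cl$lag_days
    }
  }
  alive <- rep(TRUE, n)
  active <- rep(TRUE, n)                  # not dropped out
  exp_day <- rep(NA_integer_, n)          # day offset of exposure onset
  death_day <- rep(NA_integer_, n)
  drop_day <- rep(NA_integer_, n)
  event_day <- matrix(NA_integer_, n, K)  # first diagnosis day per code

  for (t in seq_len(n_ticks)) {
    d <- (t - 1L) * TICK_DAYS
    at_risk <- alive & active
    # exposure onset
    u <- runif(n)
    newly <- at_risk & is.na(exp_day) & (u < p_exp)
    exp_day[newly] <- d
    exposed_now <- !is.na(exp_day)
    # disease events, catalog order
    for (k in seq_len(K)) {
      p <- base_p[k]
      u <- runif(n)
      mult <- rep(1, n)
      if (exp_hr[k] > 1) mult[exposed_now] <- exp_hr[k]
      if (cascade_hr[k] > 1) {
        up <- upstream_cols[[k]]
        n_up <- rep(0L, n)
        for (j in up) {
          ed <- event_day[, j]
          n_up <- n_up + (!is.na(ed) & ed + lag_days[k] <= d)
        }
        mult <- mult * cascade_hr[k]^n_up
      }
      hit <- at_risk & is.na(event_day[, k]) & (u < pmin(p * mult, 1))
      event_day[hit, k] <- d
    }
    # death, then dropout
    u <- runif(n)
    dying <- at_risk & (u < p_death)
    death_day[dying] <- d
    alive[dying] <- FALSE
    u <- runif(n)
    dropping <- alive & active & (u < p_drop)
    drop_day[dropping] <- d
    active[dropping] <- FALSE
  }

  persons <- data.table(
    person_id = seq_len(n),
    sex = sex,
    birth_year = birth_year,
    death_date = origin + death_day,
    dropout_date = origin + drop_day
  )
  dx_list <- vector("list", K + 1L)
  has_exp <- which(!is.na(exp_day))
  dx_list[[1L]] <- data.table(person_id = has_exp,
                              code = config$exposure_code,
                              date = origin + exp_day[has_exp])
  for (k in seq_len(K)) {
    hit <- which(!is.na(event_day[, k]))
    dx_list[[k + 1L]] <- data.table(person_id = hit, code = codes[k],
                                    date = origin + event_day[hit, k])
  }
  diagnoses <- rbindlist(dx_list)
  setorder(diagnoses, person_id, date, code)
  structure(list(persons = persons, diagnoses = diagnoses,
                 study_start = origin, study_end = last_day),
            class = "registry")
}

#' Assemble a registry from raw tables
#'
#' Builds a `registry` object from person and diagnosis tables, e.g. for
#' registry extracts or hand-built examples.  `persons` needs columns
#' person_id, sex, birth_year and optionally death_date / dropout_date;
#' `diagnoses` needs person_id, code, date.  Dates are coerced with
#' [data.table::as.IDate()].
#'
#' @param persons,diagnoses data.frames as described above.
#' @param study_start,study_end the study window.
#' @return a `registry` object.
#' @export
as_registry <- function(persons, diagnoses, study_start, study_end) {
  persons <- as.data.table(persons)
  diagnoses <- as.data.table(diagnoses)
  need_p <- c("person_id", "sex", "birth_year")
  if (!all(need_p %in% names(persons)))
    stopf("`persons` needs columns %s", paste(need_p, collapse = ", "))
  if (!all(c("person_id", "code", "date") %in% names(diagnoses)))
    stopf("`diagnoses` needs columns person_id, code, date")
  if (anyDuplicated(persons$person_id)) stopf("duplicate person ids")
  for (col in c("death_date", "dropout_date"))
    if (!col %in% names(persons))
      persons[, (col) := as.IDate(NA_integer_)] else
        set(persons, j = col, value = as.IDate(persons[[col]]))
  set(diagnoses, j = "date", value = as.IDate(diagnoses[["date"]]))
  setorder(diagnoses, person_id, date, code)
  structure(list(persons = persons, diagnoses = diagnoses,
                 study_start = as.IDate(study_start),
                 study_end = as.IDate(study_end)),
            class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  cat(sprintf("<registry> %d persons, %d diagnoses, %s to %s\n",
              nrow(x$persons), nrow(x$diagnoses),
              format(x$study_start), format(x$study_end)))
  invisible(x)
}

#' Write / read a registry as tab-delimited text
#'
#' `write_registry()` writes `persons.tsv` and `diagnoses.tsv` (ISO-8601
#' dates, header row) into `dir`; `read_registry()` reads them back.  The
#' study window is stored in `study.json`.
#'
#' @param registry a `registry` object.
#' @param dir directory (created if missing).
#' @return `write_registry()` returns `dir` invisibly; `read_registry()`
#'   returns a `registry`.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(registry$persons, file.path(dir, "persons.tsv"), sep = "\t")
  fwrite(registry$diagnoses, file.path(dir, "diagnoses.tsv"), sep = "\t")
  jsonlite::write_json(
    list(study_start = format(registry$study_start),
         study_end = format(registry$study_end)),
    file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  pf <- file.path(dir, "persons.tsv")
  df <- file.path(dir, "diagnoses.tsv")
  for (f in c(pf, df)) if (!file.exists(f)) stopf("registry file not found: %s", f)
  persons <- fread(pf, sep = "\t",
                   colClasses = list(character = "sex", integer = "birth_year"))
  diagnoses <- fread(df, sep = "\t", colClasses = list(character = "code"))
  for (col in c("death_date", "dropout_date"))
    set(persons, j = col, value = as.IDate(persons[[col]]))
  set(diagnoses, j = "date", value = as.IDate(diagnoses[["date"]]))
  if (anyDuplicated(persons$person_id)) stopf("duplicate person ids in %s", pf)
  sj <- file.path(dir, "study.json")
  window <- if (file.exists(sj)) jsonlite::read_json(sj) else
    list(study_start = min(diagnoses$date), study_end = max(diagnoses$date))
  structure(list(persons = persons, diagnoses = diagnoses,
                 study_start = as.IDate(window$study_start),
                 study_end = as.IDate(window$study_end)),
            class = "registry")
}
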