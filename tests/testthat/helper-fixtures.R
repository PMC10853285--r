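library(data.table)

# -- hand-built toy registries -----------------------------------------------

# small registry around one exposed woman and assorted candidates, used by
# the cohort eligibility tests
toy_registry <- function() {
  persons <- data.table(
    person_id = 1:6,
    sex = c("F", "F", "F", "M", "F", "F"),
    birth_year = c(1950L, 1950L, 1950L, 1950L, 1950L, 1960L),
    death_date = as.IDate(c(NA, NA, "2004-06-01", NA, NA, NA)),
    dropout_date = as.IDate(rep(NA_integer_, 6)))
  diagnoses <- data.table(
    person_id = c(1L, 1L, 5L),
    code = c("F41", "C01", "F41"),
    date = as.IDate(c("2005-03-01", "2007-01-01", "2010-06-01")))
  as_registry(persons, diagnoses, "2001-01-01", "2012-12-31")
}

# registry realising exact exposed-arm disease indicator patterns: `patterns`
# is a list of lists with fields d1/d2 ("during", "prior", "none")
pattern_registry <- function(patterns, code1 = "D10", code2 = "D20") {
  n <- length(patterns)
  persons <- data.table(person_id = seq_len(n), sex = "F",
                        birth_year = 1950L)
  dx <- list(data.table(person_id = seq_len(n), code = "F41",
                        date = as.IDate("2004-01-01")))
  add <- function(pid, code, when) {
    d <- switch(when,
                during = as.IDate("2006-01-01") + pid,  # after washout
                prior = as.IDate("2004-02-01"),         # before fu start
                none = return(NULL))
    data.table(person_id = pid, code = code, date = d)
  }
  for (i in seq_len(n)) {
    dx[[length(dx) + 1L]] <- add(i, code1, patterns[[i]]$d1 %||% "none")
    dx[[length(dx) + 1L]] <- add(i, code2, patterns[[i]]$d2 %||% "none")
  }
  as_registry(persons, rbindlist(dx), "2001-01-01", "2012-12-31")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# cohort with every person exposed (no controls), for pair-level tests
all_exposed_cohort <- function(registry) {
  build_cohort(registry,
               cohort_config("F41", match_ratio = 1, washout_days = 183,
                             seed = 1))
}

# registry with a chosen number of forward / backward / tied orderings of
# two codes among exposed patients
ordered_registry <- function(n_forward, n_backward, n_tied = 0L) {
  n <- n_forward + n_backward + n_tied
  persons <- data.table(person_id = seq_len(n), sex = "F",
                        birth_year = 1950L)
  base <- as.IDate("2006-01-01")
  dx <- list(data.table(person_id = seq_len(n), code = "F41",
                        date = as.IDate("2004-01-01")))
  d1 <- c(rep(base, n_forward),                    # D1 first
          rep(base + 100L, n_backward),            # D1 second
          rep(base, n_tied))
  d2 <- c(rep(base + 100L, n_forward),
          rep(base, n_backward),
          rep(base, n_tied))
  dx[[2]] <- data.table(person_id = seq_len(n), code = "D10", date = d1)
  dx[[3]] <- data.table(person_id = seq_len(n), code = "D20", date = d2)
  as_registry(persons, rbindlist(dx), "2001-01-01", "2010-12-31")
}

# -- shared simulated fixture (built once per test run) ----------------------

.fixture_env <- new.env(parent = emptyenv())

# moderate two-cluster registry + cohort reused across module tests
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cls <- list(planted_cluster("C01", c("C02", "C03"), 3, 4, 30),
                planted_cluster(c("C05", "C06"), c("C07", "C08"), 3, 4, 30))
    cfg <- sim_config(seed = 7, n_persons = 20000, study_start = 2001,
                      study_end = 2010, clusters = cls)
    reg <- simulate_registry(cfg)
    coh <- build_cohort(reg, cohort_config("F41", match_ratio = 5, seed = 2))
    .fixture_env$small <- list(cfg = cfg, reg = reg, coh = coh)
  }
  .fixture_env$small
}

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force control eligibility for the incidence-density contract
brute_eligible <- function(registry, cfg, index_date, sex, birth_year) {
  p <- registry$persons
  dx <- registry$diagnoses
  ok <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    pid <- p$person_id[i]
    mine <- dx[person_id == pid]
    exp_dates <- mine[matches_any(code, cfg$exposure_codes), date]
    excl_dates <- mine[matches_any(code, cfg$exclusion_codes), date]
    ok[i] <- p$sex[i] == sex && p$birth_year[i] == birth_year &&
      (is.na(p$death_date[i]) || p$death_date[i] > index_date) &&
      (is.na(p$dropout_date[i]) || p$dropout_date[i] > index_date) &&
      (length(exp_dates) == 0L || min(exp_dates) > index_date) &&
      (length(excl_dates) == 0L || min(excl_dates) >= index_date)
  }
  p$person_id[ok]
}

matches_any <- function(codes, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  Reduce(`|`, lapply(prefixes, function(pr) startsWith(codes, pr)))
}

# random small registries for property-style cohort tests
random_toy_registry <- function(seed, n = 10L) {
  set.seed(seed)
  persons <- data.table(
    person_id = seq_len(n),
    sex = sample(c("F", "M"), n, TRUE),
    birth_year = sample(1950:1952, n, TRUE),
    death_date = as.IDate(ifelse(runif(n) < 0.3,
                                 as.IDate("2003-01-01") + sample(0:2000, n, TRUE),
                                 NA_integer_)),
    dropout_date = as.IDate(ifelse(runif(n) < 0.3,
                                   as.IDate("2003-01-01") + sample(0:2000, n, TRUE),
                                   NA_integer_)))
  n_dx <- 2L * n
  diagnoses <- data.table(
    person_id = sample(seq_len(n), n_dx, TRUE),
    code = sample(c("F41", "K50", "Z99"), n_dx, TRUE,
                  prob = c(0.4, 0.3, 0.3)),
    date = as.IDate("2002-01-01") + sample(0:2500, n_dx, TRUE))
  as_registry(persons, diagnoses, "2001-01-01", "2010-12-31")
}
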