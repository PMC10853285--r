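#' Describe a planted disease cluster
#'
#' A planted cluster seeds the synthetic registry with a group of diagnosis
#' codes that (a) become more likely after the exposure and (b) cascade in a
#' preferred temporal order.  Root codes form the intended first layer: their
#' hazard is multiplied by `hr_exposure` once a person is exposed.  Downstream
#' codes form an ordered cascade: the hazard of a downstream code is
#' additionally multiplied by `hr_cascade` for every upstream member (all
#' roots plus every earlier downstream code) that occurred at least
#' `lag_days` earlier, so the boost compounds as the cascade progresses.
#' This plants a preferred temporal order for every implied ground-truth
#' directed pair: each (root, downstream) pair and each ordered downstream
#' pair.
#'
#' @param root_codes character vector of root diagnosis codes (intended D1).
#' @param downstream_codes character vector of downstream codes, in cascade
#'   order. Must be disjoint from `root_codes`.
#' @param hr_exposure hazard ratio applied to all member codes after exposure
#'   (>= 1; 1 gives a null cluster).
#' @param hr_cascade hazard ratio applied to a downstream code once its
#'   upstream member has occurred (>= 1).
#' @param lag_days minimum gap in days between an upstream event and the start
#'   of the boosted hazard of its downstream code.
#' @return An object of class `planted_cluster`.
#' @export
planted_cluster <- function(root_codes, downstream_codes,
                            hr_exposure = 3, hr_cascade = 4, lag_days = 30L) {
  root_codes <- as.character(root_codes)
  downstream_codes <- as.character(downstream_codes)
  if (length(root_codes) == 0L)
    stopf("a planted cluster needs at least one root code")
  if (length(intersect(root_codes, downstream_codes)) > 0L)
    stopf("root and downstream codes of a planted cluster must be disjoint")
  if (anyDuplicated(c(root_codes, downstream_codes)))
    stopf("duplicated codes within a planted cluster")
  if (!is.numeric(hr_exposure) || hr_exposure < 1)
    stopf("`hr_exposure` must be >= 1")
  if (!is.numeric(hr_cascade) || hr_cascade < 1)
    stopf("`hr_cascade` must be >= 1")
  if (!is.numeric(lag_days) || lag_days < 0)
    stopf("`lag_days` must be >= 0")
  structure(list(root_codes = root_codes,
                 downstream_codes = downstream_codes,
                 hr_exposure = as.numeric(hr_exposure),
                 hr_cascade = as.numeric(hr_cascade),
                 lag_days = as.integer(lag_days)),
            class = "planted_cluster")
}

#' Configuration for the synthetic registry generator
#'
#' Defines a discrete-time (30-day tick) competing-hazard simulation of a
#' national-register-like cohort: persons enter at the study start, may be
#' exposed (receive the index diagnosis), accumulate dated ICD-10-style
#' diagnoses from a code catalog, and exit by death, dropout (emigration) or
#' the administrative study end.  All hazards are annual probabilities,
#' converted to per-tick probabilities by dividing by 12 (capped at 1).
#' The seed fully determines the generated tables.
#'
#' @param seed integer seed; the same config (including seed) reproduces the
#'   registry byte for byte.
#' @param n_persons number of persons.
#' @param study_start,study_end first/last calendar year of the study period.
#' @param exposure_code diagnosis code recorded at exposure onset.
#' @param p_exposure annual probability of exposure onset while unexposed.
#' @param disease_catalog data.frame with columns `code` and `hazard`
#'   (annual baseline hazard per code).
#' @param clusters list of [planted_cluster()] objects; member codes must be
#'   drawn from the catalog and be disjoint across clusters.
#' @param death_hazard,dropout_hazard annual probabilities of death and
#'   dropout (emigration).
#' @param p_female probability that a person is female; the default echoes the
#'   roughly 63% female share typical of anxiety/stress-disorder cohorts.
#' @param birth_year_range inclusive range of birth years, sampled uniformly.
#' @return An object of class `sim_config`.
#' @seealso [simulate_registry()], [ground_truth()]
#' @export
sim_config <- function(seed,
                       n_persons,
                       study_start = 2001L,
                       study_end = 2010L,
                       exposure_code = "F41",
                       p_exposure = 0.03,
                       disease_catalog = default_catalog(),
                       clusters = list(),
                       death_hazard = 0.005,
                       dropout_hazard = 0.01,
                       p_female = 0.627,
                       birth_year_range = c(1940L, 1970L)) {
  seed <- assert_count(seed, "seed")
  n_persons <- assert_count(n_persons, "n_persons", min = 1L)
  if (study_end < study_start) stopf("`study_end` must be >= `study_start`")
  assert_prob(p_exposure, "p_exposure")
  assert_prob(death_hazard, "death_hazard")
  assert_prob(dropout_hazard, "dropout_hazard")
  assert_prob(p_female, "p_female")
  disease_catalog <- as.data.table(disease_catalog)
  if (!all(c("code", "hazard") %in% names(disease_catalog)))
    stopf("`disease_catalog` needs columns `code` and `hazard`")
  if (anyDuplicated(disease_catalog$code)) stopf("duplicated catalog codes")
  if (any(disease_catalog$hazard < 0 | disease_catalog$hazard > 1))
    stopf("catalog hazards must lie in [0, 1]")
  if (exposure_code %in% disease_catalog$code)
    stopf("`exposure_code` must not appear in the disease catalog")
  if (!is.list(clusters) ||
      !all(vapply(clusters, inherits, logical(1), "planted_cluster")))
    stopf("`clusters` must be a list of planted_cluster objects")
  member_codes <- unlist(lapply(clusters, function(cl)
    c(cl$root_codes, cl$downstream_codes)))
  if (anyDuplicated(member_codes))
    stopf("planted clusters must have disjoint member codes")
  if (!all(member_codes %in% disease_catalog$code))
    stopf("planted cluster codes must be drawn from the disease catalog")
  structure(list(seed = seed, n_persons = n_persons,
                 study_start = as.integer(study_start),
                 study_end = as.integer(study_end),
                 exposure_code = exposure_code,
                 p_exposure = p_exposure,
                 disease_catalog = disease_catalog,
                 clusters = clusters,
                 death_hazard = death_hazard,
                 dropout_hazard = dropout_hazard,
                 p_female = p_female,
                 birth_year_range = as.integer(birth_year_range)),
            class = "sim_config")
}

#' Default disease catalog for the generator
#'
#' `n_codes` synthetic 3-character codes ("C01", "C02", ...) with annual
#' baseline hazards cycling through `hazards`.
#'
#' @param n_codes number of codes.
#' @param hazards recycled vector of annual baseline hazards.
#' @return data.table with columns `code`, `hazard`.
#' @export
default_catalog <- function(n_codes = 20L, hazards = c(0.010, 0.015, 0.020)) {
  data.table(code = sprintf("C%02d", seq_len(n_codes)),
             hazard = rep_len(hazards, n_codes))
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [sim_config()] arguments;
#' `disease_catalog` is a list of (code, hazard) records and `clusters` a
#' list of [planted_cluster()] argument sets.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
load_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the `yaml` package is required to read config files")
  args <- yaml::read_yaml(path)
  if (!is.null(args$disease_catalog))
    args$disease_catalog <- rbindlist(lapply(args$disease_catalog, as.data.table))
  if (!is.null(args$clusters))
    args$clusters <- lapply(args$clusters, function(a)
      do.call(planted_cluster, a))
  if (!is.null(args$birth_year_range))
    args$birth_year_range <- unlist(args$birth_year_range)
  do.call(sim_config, args)
}

#' Ground truth of a simulation configuration
#'
#' Returns the planted cluster memberships and the planted directed code
#' pairs for recovery scoring: for each cluster, every (root, downstream)
#' pair and every ordered (downstream_i, downstream_j), i < j, pair.
#'
#' @param config a [sim_config()].
#' @return list with `membership` (named list: cluster id -> member codes)
#'   and `directed_pairs` (data.table with columns `from`, `to`).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  membership <- list()
  pairs <- list()
  for (k in seq_along(config$clusters)) {
    cl <- config$clusters[[k]]
    id <- sprintf("planted_%d", k)
    membership[[id]] <- c(cl$root_codes, cl$downstream_codes)
    ds <- cl$downstream_codes
    pk <- list()
    if (length(ds) > 0L) {
      pk[[1L]] <- CJ(from = cl$root_codes, to = ds)
      if (length(ds) > 1L) {
        idx <- which(upper.tri(diag(length(ds))), arr.ind = TRUE)
        pk[[2L]] <- data.table(from = ds[idx[, 1L]], to = ds[idx[, 2L]])
      }
    }
    if (length(pk)) pairs[[id]] <- rbindlist(pk)
  }
  directed <- if (length(pairs)) rbindlist(pairs) else
    data.table(from = character(), to = character())
  list(membership = membership, directed_pairs = directed[order(from, to)])
}
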