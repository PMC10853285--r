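#' Benjamini-Hochberg q-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: the
#' step-up false-discovery-rate adjustment with monotonicity enforcement
#' used throughout the pipeline.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed:
#'   non-estimable tests carry NA and are excluded from the family).
#' @return vector of q-values, same length and order as `pvals`.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stopf("`pvals` must be numeric")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Prevalence filter for candidate conditions
#'
#' Retains a code iff the share of exposed cohort members with at least one
#' diagnosis of the code during follow-up is at least `threshold`.
#'
#' @param cohort a `matched_cohort` with follow-up windows.
#' @param registry the source `registry`.
#' @param threshold prevalence threshold in (0, 1\]; the 0.005 default is the
#'   0.5% floor used for condition screening. `threshold = 0` keeps every
#'   code with at least one exposed case.
#' @param codes candidate codes (default: all non-missing codes in the
#'   registry; exposure codes should be excluded by the caller, as
#'   [run_phewas()] does).
#' @return character vector of retained codes.
#' @export
prevalence_filter <- function(cohort, registry, threshold = 0.005,
                              codes = sort(unique(registry$diagnoses$code))) {
  if (threshold < 0 || threshold >= 1) stopf("`threshold` must lie in [0, 1)")
  n_exposed <- cohort[role == "exposed", .N]
  if (n_exposed == 0L) stopf("cohort has no exposed members")
  inc <- exposed_incidence(cohort, registry, codes)
  prev <- colSums(inc$during) / n_exposed
  keep <- if (threshold > 0) prev >= threshold else colSums(inc$during) >= 1L
  codes[keep]
}

#' Stratified Cox model for one condition
#'
#' Association between the exposure and first post-washout diagnosis of
#' `code`, on the time scale of days since follow-up start.  Persons with the
#' code before their follow-up start are excluded; persons whose follow-up
#' ends before an event are censored.  The model is stratified by matched-set
#' id by default (`strata_by = "set"`), or by the sex-by-birth-year
#' cross-classification (`strata_by = "sex_year"`).  Ties use the Breslow
#' approximation unless `ties` says otherwise.  The fit is flagged
#' non-estimable when either arm has zero events.
#'
#' @inheritParams prevalence_filter
#' @param code the condition code.
#' @param covariates optional character vector of cohort column names entered
#'   as linear terms.
#' @param strata_by `"set"` or `"sex_year"`.
#' @param ties tie handling passed to [survival::coxph()].
#' @return list(code, hr, ci_low, ci_high, p, n_events_exposed,
#'   n_events_control, n_at_risk, estimable).
#' @export
fit_condition_cox <- function(cohort, registry, code, covariates = NULL,
                              strata_by = c("set", "sex_year"),
                              ties = "breslow") {
  strata_by <- match.arg(strata_by)
  fd <- code_first_dates(registry, code)
  dat <- copy(as.data.table(cohort))
  dat[fd, event_date := i.first_date, on = "person_id"]
  dat <- dat[is.na(event_date) | event_date >= fu_start]
  dat[, event := !is.na(event_date) & event_date <= fu_end]
  dat[, time := fifelse(event, as.numeric(event_date - fu_start),
                        as.numeric(fu_end - fu_start))]
  dat[, time := pmax(time, 0.5)]  # events on the first follow-up day
  dat[, exposed := as.integer(role == "exposed")]
  n_ev <- dat[, .(n = sum(event)), by = role]
  ne <- function(r) { v <- n_ev[role == r, n]; if (length(v)) v else 0L }
  res <- list(code = code, hr = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, p = NA_real_,
              n_events_exposed = ne("exposed"),
              n_events_control = ne("control"),
              n_at_risk = nrow(dat), estimable = FALSE)
  if (res$n_events_exposed == 0L || res$n_events_control == 0L) return(res)
  strat <- if (strata_by == "set") "strata(set_id)" else
    "strata(sex, birth_year)"
  rhs <- paste(c("exposed", covariates, strat), collapse = " + ")
  fml <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = ties),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    # refit without warning trapping: convergence warnings on sparse strata
    # still yield usable estimates; true failures return NULL above
    fit <- tryCatch(survival::coxph(fml, data = dat, ties = ties),
                    error = function(e) NULL)
  }
  if (is.null(fit)) return(res)
  beta <- coef(fit)[["exposed"]]
  se <- sqrt(diag(vcov(fit)))[["exposed"]]
  if (!is.finite(beta) || !is.finite(se) || se > 50) return(res)
  res$hr <- exp(beta)
  res$ci_low <- exp(beta - 1.96 * se)
  res$ci_high <- exp(beta + 1.96 * se)
  res$p <- 2 * pnorm(-abs(beta / se))
  res$estimable <- TRUE
  res
}

#' Phenome-wide screen of conditions after the index diagnosis
#'
#' Applies the prevalence filter, fits one stratified Cox model per retained
#' code, adjusts p-values across all estimable codes with
#' Benjamini-Hochberg, and flags codes with HR > 1 and q < `alpha` as
#' selected.
#'
#' @inheritParams fit_condition_cox
#' @param exposure_codes prefixes excluded from the candidate code set.
#' @param prevalence_threshold minimum prevalence among the exposed.
#' @param alpha FDR threshold for selection.
#' @param verbose emit progress messages.
#' @return data.table (code, n_cases, prevalence, hr, ci_low, ci_high, p, q,
#'   estimable, selected); non-estimable codes keep NA statistics and are
#'   never selected.
#' @export
run_phewas <- function(cohort, registry, exposure_codes,
                       prevalence_threshold = 0.005, alpha = 0.05,
                       covariates = NULL, strata_by = "set",
                       ties = "breslow", verbose = FALSE) {
  cands <- candidate_codes(registry, exposure_codes)
  keep <- prevalence_filter(cohort, registry, prevalence_threshold, cands)
  if (length(keep) == 0L)
    return(data.table(code = character(), n_cases = integer(),
                      prevalence = numeric(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(), p = numeric(),
                      q = numeric(), estimable = logical(),
                      selected = logical()))
  n_exposed <- cohort[role == "exposed", .N]
  inc <- exposed_incidence(cohort, registry, keep)
  fits <- lapply(keep, function(cd) {
    msgf(verbose, "phewas: fitting %s", cd)
    fit_condition_cox(cohort, registry, cd, covariates, strata_by, ties)
  })
  res <- rbindlist(lapply(fits, function(f)
    f[c("code", "hr", "ci_low", "ci_high", "p", "estimable")]))
  res[, n_cases := colSums(inc$during)[code]]
  res[, prevalence := n_cases / n_exposed]
  res[, q := bh_adjust(fifelse(estimable, p, NA_real_))]
  res[, selected := estimable & !is.na(q) & hr > 1 & q < alpha]
  setcolorder(res, c("code", "n_cases", "prevalence", "hr", "ci_low",
                     "ci_high", "p", "q", "estimable", "selected"))
  res[]
}
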