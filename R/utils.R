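#' @importFrom stats binom.test coef cor glm p.adjust pnorm rbinom runif
#'   setNames vcov as.formula confint qnorm binomial
#' @importFrom survival coxph clogit Surv strata
#' @importFrom utils head
#' @import data.table
NULL

utils::globalVariables(c(
  ".", ".I", ".N", "C_i", "C_ij", "C_j", "N_ij", "birth_year", "case",
  "code", "code_i", "code_j", "confirmed", "date", "death", "death_date",
  "defined", "direction", "dropout", "dropout_date",
  "estimable", "event", "event_date", "excl_date", "exp_date", "exposed",
  "first_date", "from", "fu_end", "fu_start", "i.death_date",
  "i.dropout_date", "i.first_date", "i.index_date", "index_date",
  "informative", "majority", "n", "n_cases", "own_exp", "p_phi", "p_rr",
  "person_id", "phi", "prevalence", "q", "q_phi", "q_rr", "retained",
  "role", "rr", "selected", "set_id", "sex", "time", "to", "z_phi", "z_rr"))

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

# scalar check helpers used by the config validators
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1], got %s",
          name, paste(format(x), collapse = ", "))
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# days per simulation tick; year-scale follow-up at monthly resolution
TICK_DAYS <- 30L
TICKS_PER_YEAR <- 12L
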