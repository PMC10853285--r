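#' Sub-cohort counts for one disease pair
#'
#' For a pair (D1, D2) the sub-cohort consists of exposed cohort members with
#' neither code diagnosed before their follow-up start.  Counts are of at
#' least one diagnosis during follow-up: `C_i` with D1, `C_j` with D2,
#' `C_ij` with both, `N_ij` the sub-cohort size.
#'
#' @param cohort a `matched_cohort` with follow-up windows.
#' @param registry the source `registry`.
#' @param code_i,code_j the two condition codes.
#' @return list(C_i, C_j, C_ij, N_ij).
#' @export
pair_subcohort_counts <- function(cohort, registry, code_i, code_j) {
  known <- unique(registry$diagnoses$code)
  for (cd in c(code_i, code_j))
    if (!cd %in% known) stopf("unknown code: %s", cd)
  inc <- exposed_incidence(cohort, registry, c(code_i, code_j))
  sub <- !inc$prior[, 1L] & !inc$prior[, 2L]
  list(C_i = sum(inc$during[sub, 1L]),
       C_j = sum(inc$during[sub, 2L]),
       C_ij = sum(inc$during[sub, 1L] & inc$during[sub, 2L]),
       N_ij = sum(sub))
}

#' Comorbidity strength of a disease pair: relative risk and phi-correlation
#'
#' Evaluates, exactly as printed in the source statistics,
#' \deqn{RR_{ij} = \frac{C_{ij} N_{ij}}{C_i C_j}, \qquad
#'   \Phi_{ij} = \frac{C_{ij} N_{ij} - C_i C_j}
#'   {\sqrt{C_i C_j (N_{ij}-C_i)(N_{ij}-C_j)}}.}
#' \eqn{\Phi_{ij}} equals the Pearson correlation of the two per-person
#' binary disease indicators.  The pair is flagged undefined when any margin
#' is 0 or equals the sub-cohort size (zero denominator).
#'
#' All arguments are vectorized.
#'
#' @param C_ij persons with both conditions.
#' @param C_i,C_j persons with each condition.
#' @param N_ij sub-cohort size.
#' @return data.table (rr, phi, defined).
#' @export
pair_strength <- function(C_ij, C_i, C_j, N_ij) {
  if (any(C_ij > pmin(C_i, C_j)) || any(pmax(C_i, C_j) > N_ij) || any(C_ij < 0))
    stopf("counts must satisfy 0 <= C_ij <= min(C_i, C_j) <= N_ij")
  # double arithmetic: the phi denominator overflows 32-bit integers
  C_ij <- as.numeric(C_ij); C_i <- as.numeric(C_i)
  C_j <- as.numeric(C_j); N_ij <- as.numeric(N_ij)
  defined <- C_i > 0 & C_j > 0 & N_ij > C_i & N_ij > C_j
  rr <- ifelse(defined, (C_ij * N_ij) / (C_i * C_j), NA_real_)
  phi <- ifelse(defined,
                (C_ij * N_ij - C_i * C_j) /
                  sqrt(C_i * C_j * (N_ij - C_i) * (N_ij - C_j)),
                NA_real_)
  data.table(rr = rr, phi = phi, defined = defined)
}

#' z-scores and p-values for pair comorbidity strength
#'
#' Evaluates the printed large-sample z statistics
#' \deqn{z^{RR} = \frac{\ln RR}{\sqrt{1/C_{ij} - 1/N_{ij}
#'   + 1/(C_i C_j / N_{ij}) - 1/N_{ij}}}, \qquad
#'   z^{\Phi} = \frac{\Phi\sqrt{\max(C_{ij}, C_j) - 2}}{\sqrt{1 - \Phi^2}}}
#' with two-sided standard-normal p-values.  The printed \eqn{z^{\Phi}}
#' uses \eqn{\max(C_{ij}, C_j)}, which is asymmetric in the pair order; it is
#' reproduced verbatim by default, with `phi_max_rule = "symmetric"` offering
#' the symmetric \eqn{\max(C_i, C_j)} variant.  `z_rr` is undefined when
#' `C_ij = 0`; `z_phi` is undefined when \eqn{|\Phi| \ge 1} or the max term
#' is \eqn{\le 2}.
#'
#' @inheritParams pair_strength
#' @param rr,phi outputs of [pair_strength()].
#' @param phi_max_rule `"printed"` (max(C_ij, C_j)) or `"symmetric"`
#'   (max(C_i, C_j)).
#' @return data.table (z_rr, z_phi, p_rr, p_phi).
#' @export
pair_z <- function(rr, phi, C_ij, C_i, C_j, N_ij,
                   phi_max_rule = c("printed", "symmetric")) {
  phi_max_rule <- match.arg(phi_max_rule)
  C_ij <- as.numeric(C_ij); C_i <- as.numeric(C_i)
  C_j <- as.numeric(C_j); N_ij <- as.numeric(N_ij)
  var_rr <- 1 / C_ij - 1 / N_ij + 1 / (C_i * C_j / N_ij) - 1 / N_ij
  z_rr <- ifelse(C_ij > 0 & is.finite(rr) & rr > 0 & var_rr > 0,
                 log(rr) / sqrt(var_rr), NA_real_)
  mx <- if (phi_max_rule == "printed") pmax(C_ij, C_j) else pmax(C_i, C_j)
  z_phi <- ifelse(!is.na(phi) & abs(phi) < 1 & mx > 2,
                  phi * sqrt(mx - 2) / sqrt(1 - phi^2), NA_real_)
  data.table(z_rr = z_rr, z_phi = z_phi,
             p_rr = 2 * pnorm(-abs(z_rr)), p_phi = 2 * pnorm(-abs(z_phi)))
}

#' Enumerate and screen disease pairs for comorbidity strength
#'
#' Evaluates every unordered pair of `codes` whose co-occurrence prevalence
#' (`C_ij` over the number of exposed cohort members) is at least
#' `pair_prevalence`, computes RR, phi and their z statistics on the pair
#' sub-cohort, applies Benjamini-Hochberg separately to the z_RR and z_phi
#' p-value families, and retains pairs with strong comorbidity strength.
#' The default retention rule (`q_rule = "both"`) requires RR > 1, phi > 0,
#' q_RR < alpha and q_phi < alpha; the alternatives relax which of the two
#' tests must pass.
#'
#' @inheritParams pair_subcohort_counts
#' @param codes codes to pair (typically the PheWAS-selected set).
#' @param pair_prevalence minimum co-occurrence prevalence among all exposed
#'   patients (default 0.0025, the 0.25% floor).
#' @param alpha FDR threshold.
#' @param q_rule which q-values must pass: "both", "either", "rr_only",
#'   "phi_only".
#' @param phi_max_rule see [pair_z()].
#' @return data.table with one row per evaluated pair: code_i, code_j, the
#'   four counts, rr, phi, z_rr, z_phi, p_rr, p_phi, q_rr, q_phi, defined,
#'   retained.  Attribute `n_candidate_pairs` records the pre-filter pair
#'   count.
#' @export
screen_pairs <- function(cohort, registry, codes, pair_prevalence = 0.0025,
                         alpha = 0.05, q_rule = c("both", "either", "rr_only",
                                                  "phi_only"),
                         phi_max_rule = "printed") {
  q_rule <- match.arg(q_rule)
  codes <- sort(unique(codes))
  empty <- data.table(code_i = character(), code_j = character(),
                      C_i = integer(), C_j = integer(), C_ij = integer(),
                      N_ij = integer(), rr = numeric(), phi = numeric(),
                      z_rr = numeric(), z_phi = numeric(), p_rr = numeric(),
                      p_phi = numeric(), q_rr = numeric(), q_phi = numeric(),
                      defined = logical(), retained = logical())
  if (length(codes) < 2L) {
    setattr(empty, "n_candidate_pairs", 0L)
    return(empty[])
  }
  n_exposed <- cohort[role == "exposed", .N]
  inc <- exposed_incidence(cohort, registry, codes)
  P <- inc$prior * 1L     # history before follow-up start
  D <- inc$during * 1L    # first diagnosis inside follow-up
  # pairwise counts by cross-products; D implies not-P for the same code,
  # so co-occurrence within the pair sub-cohort is just crossprod(D)
  co_during <- crossprod(D)
  co_prior <- crossprod(P)
  d_and_p <- crossprod(D, P)   # [i, j] = #{D_i during & P_j prior}
  n_prior <- colSums(P)
  n_during <- colSums(D)
  idx <- which(upper.tri(co_during), arr.ind = TRUE)
  res <- data.table(code_i = codes[idx[, 1L]], code_j = codes[idx[, 2L]])
  res[, C_ij := co_during[idx]]
  res[, N_ij := as.integer(n_exposed - n_prior[idx[, 1L]] -
                             n_prior[idx[, 2L]] + co_prior[idx])]
  res[, C_i := as.integer(n_during[idx[, 1L]] - d_and_p[idx])]
  res[, C_j := as.integer(n_during[idx[, 2L]] - d_and_p[cbind(idx[, 2L], idx[, 1L])])]
  n_candidates <- nrow(res)
  res <- res[C_ij / n_exposed >= pair_prevalence]
  if (nrow(res) == 0L) {
    setattr(empty, "n_candidate_pairs", n_candidates)
    return(empty[])
  }
  res[, c("rr", "phi", "defined") := pair_strength(C_ij, C_i, C_j, N_ij)]
  res[, c("z_rr", "z_phi", "p_rr", "p_phi") :=
        pair_z(rr, phi, C_ij, C_i, C_j, N_ij, phi_max_rule)]
  res[, q_rr := bh_adjust(p_rr)]
  res[, q_phi := bh_adjust(p_phi)]
  pass_rr <- with(res, !is.na(q_rr) & q_rr < alpha)
  pass_phi <- with(res, !is.na(q_phi) & q_phi < alpha)
  pass_q <- switch(q_rule,
                   both = pass_rr & pass_phi,
                   either = pass_rr | pass_phi,
                   rr_only = pass_rr,
                   phi_only = pass_phi)
  res[, retained := defined & !is.na(rr) & !is.na(phi) &
        rr > 1 & phi > 0 & pass_q]
  setcolorder(res, names(empty))
  setattr(res, "n_candidate_pairs", n_candidates)
  res[]
}
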