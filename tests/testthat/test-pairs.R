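# direct arithmetic oracle for the printed pair formulas
oracle_pair <- function(C_ij, C_i, C_j, N) {
  rr <- C_ij * N / (C_i * C_j)
  phi <- (C_ij * N - C_i * C_j) /
    sqrt(C_i * C_j * (N - C_i) * (N - C_j))
  z_rr <- log(rr) / sqrt(1 / C_ij - 1 / N + 1 / (C_i * C_j / N) - 1 / N)
  z_phi <- phi * sqrt(max(C_ij, C_j) - 2) / sqrt(1 - phi^2)
  list(rr = rr, phi = phi, z_rr = z_rr, z_phi = z_phi)
}

# expand counts into two binary indicator vectors
expand_indicators <- function(C_ij, C_i, C_j, N) {
  x <- c(rep(1, C_i), rep(0, N - C_i))
  y <- c(rep(1, C_ij), rep(0, C_i - C_ij),
         rep(1, C_j - C_ij), rep(0, N - C_i - (C_j - C_ij)))
  list(x = x, y = y)
}

test_that("sub-cohort counts follow the history-exclusion predicate", {
  patterns <- list(list(d1 = "during"),                     # D1 only
                   list(d2 = "during"),                     # D2 only
                   list(d1 = "during", d2 = "during"),      # both
                   list(),                                  # neither
                   list(d1 = "prior"))                      # excluded
  reg <- pattern_registry(patterns)
  coh <- all_exposed_cohort(reg)
  cnt <- pair_subcohort_counts(coh, reg, "D10", "D20")
  expect_equal(cnt, list(C_i = 2L, C_j = 2L, C_ij = 1L, N_ij = 4L))
  expect_error(pair_subcohort_counts(coh, reg, "D10", "NOPE"), "unknown")
  # boundary: everyone has both
  reg2 <- pattern_registry(rep(list(list(d1 = "during", d2 = "during")), 4))
  coh2 <- all_exposed_cohort(reg2)
  expect_equal(pair_subcohort_counts(coh2, reg2, "D10", "D20"),
               list(C_i = 4L, C_j = 4L, C_ij = 4L, N_ij = 4L))
  # nobody in the cohort has either code (the codes exist in the registry
  # through a never-exposed person)
  reg3 <- pattern_registry(rep(list(list()), 5))
  extra <- data.table(person_id = 99L, sex = "F", birth_year = 1950L)
  reg3$persons <- rbind(reg3$persons, extra, fill = TRUE)
  reg3$diagnoses <- rbind(reg3$diagnoses,
                          data.table(person_id = 99L, code = c("D10", "D20"),
                                     date = as.IDate("2006-01-01")))
  coh3 <- all_exposed_cohort(reg3)
  expect_equal(pair_subcohort_counts(coh3, reg3, "D10", "D20"),
               list(C_i = 0L, C_j = 0L, C_ij = 0L, N_ij = 5L))
})

test_that("worked pair example matches the frozen oracle values", {
  s <- pair_strength(10, 50, 40, 1000)
  z <- pair_z(s$rr, s$phi, 10, 50, 40, 1000)
  # frozen from the direct-arithmetic oracle
  expect_equal(s$rr, 5.0, tolerance = 1e-12)
  expect_equal(s$phi, 0.1873172, tolerance = 1e-6)
  expect_equal(z$z_rr, 2.0812471, tolerance = 1e-6)
  expect_equal(z$z_phi, 1.1755076, tolerance = 1e-6)
  o <- oracle_pair(10, 50, 40, 1000)
  expect_equal(s$rr, o$rr, tolerance = 1e-12)
  expect_equal(s$phi, o$phi, tolerance = 1e-12)
  expect_equal(z$z_rr, o$z_rr, tolerance = 1e-12)
  expect_equal(z$z_phi, o$z_phi, tolerance = 1e-12)
})

test_that("independence point gives RR 1, phi 0, z 0, p 1", {
  s <- pair_strength(2, 50, 40, 1000)   # C_ij * N == C_i * C_j
  expect_equal(s$rr, 1)
  expect_equal(s$phi, 0)
  z <- pair_z(s$rr, s$phi, 2, 50, 40, 1000)
  expect_equal(z$z_rr, 0)
  expect_equal(z$z_phi, 0)
  expect_equal(z$p_rr, 1)
  expect_equal(z$p_phi, 1)
})

test_that("degenerate margins are flagged undefined", {
  s <- pair_strength(5, 5, 5, 5)
  expect_false(s$defined)
  expect_true(is.na(s$rr))
  z <- pair_z(NA_real_, NA_real_, 0, 10, 10, 100)
  expect_true(is.na(z$z_rr))     # C_ij = 0
  expect_error(pair_strength(10, 5, 40, 100), "counts")
})

test_that("phi equals the Pearson correlation of expanded indicators", {
  set.seed(1)
  for (i in 1:500) {
    N <- sample(10:400, 1)
    C_i <- sample(1:(N - 1), 1)
    C_j <- sample(1:(N - 1), 1)
    C_ij <- sample(max(0, C_i + C_j - N):min(C_i, C_j), 1)
    s <- pair_strength(C_ij, C_i, C_j, N)
    ind <- expand_indicators(C_ij, C_i, C_j, N)
    expect_equal(s$phi, cor(ind$x, ind$y), tolerance = 1e-10)
    expect_equal(sign(s$phi), sign(s$rr - 1))
  }
})

test_that("pair statistics are symmetric in the pair order except z_phi", {
  s1 <- pair_strength(10, 50, 40, 1000)
  s2 <- pair_strength(10, 40, 50, 1000)
  expect_equal(s1$rr, s2$rr)
  expect_equal(s1$phi, s2$phi)
  z1 <- pair_z(s1$rr, s1$phi, 10, 50, 40, 1000)
  z2 <- pair_z(s2$rr, s2$phi, 10, 40, 50, 1000)
  expect_equal(z1$z_rr, z2$z_rr)
  # printed rule uses max(C_ij, C_j): order matters
  expect_false(isTRUE(all.equal(z1$z_phi, z2$z_phi)))
  # the symmetric option restores exchangeability
  z1s <- pair_z(s1$rr, s1$phi, 10, 50, 40, 1000, phi_max_rule = "symmetric")
  z2s <- pair_z(s2$rr, s2$phi, 10, 40, 50, 1000, phi_max_rule = "symmetric")
  expect_equal(z1s$z_phi, z2s$z_phi)
})

test_that("pair screening enumerates, filters and retains correctly", {
  x <- small_sim()
  sel <- c("C01", "C02", "C03", "C05", "C06", "C07", "C08")
  prs <- screen_pairs(x$coh, x$reg, sel)
  expect_lte(nrow(prs), choose(length(sel), 2))
  expect_equal(attr(prs, "n_candidate_pairs"), choose(length(sel), 2))
  # counts invariant
  expect_true(all(prs[, C_ij <= pmin(C_i, C_j)]))
  expect_true(all(prs[, pmax(C_i, C_j) <= N_ij]))
  expect_true(all(abs(prs$phi) <= 1, na.rm = TRUE))
  # planted within-cluster pairs are retained at this n
  gt <- ground_truth(x$cfg)
  planted <- gt$directed_pairs[, paste(pmin(from, to), pmax(from, to))]
  expect_true(all(prs[paste(code_i, code_j) %in% planted, retained]))
  # fewer than two codes: empty result
  expect_equal(nrow(screen_pairs(x$coh, x$reg, "C01")), 0L)
  # pair prevalence floor removes rare pairs
  prs2 <- screen_pairs(x$coh, x$reg, sel, pair_prevalence = 0.9)
  expect_equal(nrow(prs2), 0L)
})

test_that("screened pair counts agree with the per-pair scalar routine", {
  x <- small_sim()
  prs <- screen_pairs(x$coh, x$reg, c("C01", "C02", "C05"),
                      pair_prevalence = 0)
  for (r in seq_len(nrow(prs))) {
    cnt <- pair_subcohort_counts(x$coh, x$reg, prs$code_i[r], prs$code_j[r])
    expect_equal(unlist(prs[r, .(C_i, C_j, C_ij, N_ij)]),
                 unlist(cnt[c("C_i", "C_j", "C_ij", "N_ij")]))
  }
})
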