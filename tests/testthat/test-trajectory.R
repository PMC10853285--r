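# exact two-sided binomial tail oracle via choose()
binom_two_sided <- function(k, n) {
  tail_ge <- sum(choose(n, k:n)) / 2^n
  tail_le <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * min(tail_ge, tail_le))
}

test_that("direction test matches the exact binomial tail oracle", {
  reg <- ordered_registry(15, 5)
  coh <- all_exposed_cohort(reg)
  dt <- direction_test(coh, reg, "D10", "D20")
  expect_equal(dt$n_forward, 15L)
  expect_equal(dt$n_backward, 5L)
  expect_equal(dt$p, binom_two_sided(15, 20), tolerance = 1e-10)
  expect_equal(dt$p, 0.041389465, tolerance = 1e-6)  # frozen: 2*21700/2^20
  expect_equal(dt$majority, "i->j")

  # perfect ordering
  reg2 <- ordered_registry(20, 0)
  coh2 <- all_exposed_cohort(reg2)
  dt2 <- direction_test(coh2, reg2, "D10", "D20")
  expect_equal(dt2$p, 2 / 2^20, tolerance = 1e-12)

  # balanced counts: capped p of 1, no majority
  reg3 <- ordered_registry(10, 10)
  coh3 <- all_exposed_cohort(reg3)
  dt3 <- direction_test(coh3, reg3, "D10", "D20")
  expect_equal(dt3$p, 1)
  expect_equal(dt3$majority, "none")
})

test_that("same-day pairs count as ties and are excluded from the test", {
  reg <- ordered_registry(6, 2, 4)
  coh <- all_exposed_cohort(reg)
  dt <- direction_test(coh, reg, "D10", "D20")
  expect_equal(dt$n_tied, 4L)
  expect_equal(dt$n_forward + dt$n_backward + dt$n_tied, 12L)
  expect_equal(dt$p, binom_two_sided(6, 8), tolerance = 1e-10)
  # nobody untied: p 1, direction none
  reg2 <- ordered_registry(0, 0, 5)
  coh2 <- all_exposed_cohort(reg2)
  dt2 <- direction_test(coh2, reg2, "D10", "D20")
  expect_equal(dt2$p, 1)
  expect_equal(dt2$majority, "none")
})

test_that("direction counts agree with brute force on random fixtures", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30L
    f <- sample(0:12, 1); b <- sample(0:12, 1); t <- sample(0:3, 1)
    reg <- ordered_registry(f, b, t)
    coh <- all_exposed_cohort(reg)
    dt <- direction_test(coh, reg, "D10", "D20")
    expect_equal(c(dt$n_forward, dt$n_backward, dt$n_tied), c(f, b, t))
  }
})

test_that("nested case-control matching honours the risk-set predicate", {
  # two strata; in the 1950 stratum the only eligible control for the
  # first case is person 3 (person 2 is already a D2 case earlier)
  persons <- data.table(person_id = 1:4, sex = "F",
                        birth_year = c(1950L, 1950L, 1950L, 1960L))
  base <- as.IDate("2006-06-01")
  dx <- rbind(
    data.table(person_id = 1:4, code = "F41", date = as.IDate("2004-01-01")),
    data.table(person_id = 1L, code = "D20", date = base + 30L),
    data.table(person_id = 2L, code = "D20", date = base),
    data.table(person_id = 1L, code = "D10", date = base))
  reg <- as_registry(persons, dx, "2001-01-01", "2010-12-31")
  coh <- all_exposed_cohort(reg)
  sets <- nested_case_control(coh, reg, "D10", "D20", n_controls = 2)
  s1 <- sets[set_id == sets[person_id == 1L & case == 1L, set_id]]
  expect_equal(s1[case == 0L, person_id], 3L)
  # person 1's D1 lands exactly on person 2's case date: not strictly
  # before, so unexposed in that set; strictly before their own later date
  s2 <- sets[set_id == sets[person_id == 2L & case == 1L, set_id]]
  if (1L %in% s2$person_id) expect_equal(s2[person_id == 1L, exposed], 0L)
  # in their own set the case's D1 (at base) is strictly before the case
  # date (base + 30): exposed
  expect_equal(s1[case == 1L, exposed], 1L)
  expect_error(nested_case_control(coh, reg, "D10", "D20", n_controls = 0),
               "n_controls")
})

test_that("conditional logistic OR equals the discordant-pair ratio", {
  mk_sets <- function(n_case_exposed, n_ctrl_exposed, n_concordant = 0L) {
    n <- n_case_exposed + n_ctrl_exposed + n_concordant
    data.table(
      set_id = rep(seq_len(n), each = 2L),
      person_id = seq_len(2L * n),
      case = rep(c(1L, 0L), n),
      exposed = c(rep(c(1L, 0L), n_case_exposed),
                  rep(c(0L, 1L), n_ctrl_exposed),
                  rep(c(1L, 1L), n_concordant)))
  }
  fit <- conditional_logistic_or(mk_sets(30L, 10L))
  expect_true(fit$estimable)
  expect_equal(fit$or, 3, tolerance = 1e-6)
  # all-concordant sets carry no information
  fit2 <- conditional_logistic_or(mk_sets(0L, 0L, 15L))
  expect_false(fit2$estimable)
  # random discordant splits reproduce the closed form
  set.seed(4)
  for (i in 1:5) {
    a <- sample(5:40, 1); b <- sample(5:40, 1)
    f <- conditional_logistic_or(mk_sets(a, b))
    expect_equal(f$or, a / b, tolerance = 1e-6)
  }
})

test_that("trajectory assembly derives the first layer from in-degrees", {
  ed <- data.table(from = c("A", "A", "B"), to = c("B", "C", "C"),
                   or = 2, retained = TRUE)
  tr <- build_trajectory(ed)
  expect_equal(tr$d1, "A")
  expect_length(tr$cyclic_nodes, 0L)
  # empty edge set
  tr0 <- build_trajectory(ed[0])
  expect_equal(tr0$d1, character())
  expect_equal(igraph::vcount(tr0$graph), 0L)
  # a two-cycle is reported and excluded from D1
  ed2 <- data.table(from = c("A", "B", "A"), to = c("B", "A", "C"),
                    or = 2, retained = TRUE)
  tr2 <- build_trajectory(ed2)
  expect_equal(sort(tr2$cyclic_nodes), c("A", "B"))
  expect_length(tr2$d1, 0L)
})

test_that("planted directed pairs are recovered end to end", {
  x <- small_sim()
  sel <- c("C01", "C02", "C03", "C05", "C06", "C07", "C08")
  prs <- screen_pairs(x$coh, x$reg, sel)
  dirs <- test_directions(x$coh, x$reg, prs)
  gt <- ground_truth(x$cfg)
  m <- merge(gt$directed_pairs, dirs, by.x = c("from", "to"),
             by.y = c("code_i", "code_j"))
  # every oriented planted pair points the planted way at this n
  expect_true(all(m[direction != "none", direction] == "i->j"))
  expect_gt(mean(m$direction == "i->j"), 0.5)
  te <- trajectory_edges(x$coh, x$reg, dirs, seed = 3)
  tr <- build_trajectory(te)
  expect_true(all(c("C01") %in% tr$d1))
  expect_false("C02" %in% tr$d1)
})
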