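# exhaustive hypergeometric enumeration: the independent oracle for the
# two-sided Fisher p-value with fixed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("pairwise reporter tests mirror the F-pretest/t-test idiom with
           Bonferroni", {
  g <- list(a = c(10, 12, 11), b = c(2, 3, 2), c = c(10, 12, 11))
  res <- pairwise_reporter_tests(g)
  expect_equal(nrow(res), 3L)           # all pairs of three groups
  ab <- res[res$group_a == "a" & res$group_b == "b", ]
  # hand-checked: variances equal at alpha 0.05, pooled t applies
  ref <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(ab$t, unname(ref$statistic))
  expect_equal(ab$p_raw, ref$p.value)
  expect_equal(ab$p_adj, min(1, 3 * ref$p.value))
  # identical groups: t = 0, p = 1
  ac <- res[res$group_a == "a" & res$group_b == "c", ]
  expect_equal(ac$t, 0)
  expect_equal(ac$p_raw, 1)
  expect_error(pairwise_reporter_tests(g[1]), "two groups")
  expect_error(pairwise_reporter_tests(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("regional tests adjust one-tailed p-values over regions and
           reject only real losses", {
  regions <- list(
    head = list(control = c(10, 11, 12, 10), mutant = c(4, 5, 4, 5)),
    tail = list(control = c(10, 11, 12, 10), mutant = c(10, 12, 11, 10)))
  res <- regional_reporter_tests(regions)
  expect_true(res$reject[res$region == "head"])
  expect_false(res$reject[res$region == "tail"])
  expect_true(all(res$p_adj >= res$p_raw))
  same <- list(r1 = list(control = c(5, 6, 5), mutant = c(5, 6, 5)))
  expect_false(regional_reporter_tests(same)$reject)
})

test_that("a region shifted down three sigmas is detected with high
           power", {
  set.seed(171)
  hits <- vapply(1:50, function(r) {
    regions <- list(
      shifted = list(control = rnorm(10, 30, 2),
                     mutant = rnorm(10, 24, 2)),
      flat = list(control = rnorm(10, 30, 2), mutant = rnorm(10, 30, 2)))
    regional_reporter_tests(regions)$reject[1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fold changes divide by the reference mean and are
           scale-invariant", {
  g <- list(ref = c(40, 60), mut = c(20, 30))
  fc <- fold_changes(g, "ref")
  expect_equal(fc$reference_mean, 50)
  expect_equal(fc$per_animal$mut, c(0.4, 0.6))
  st <- fc$stats
  expect_equal(st$mean_fc[st$genotype == "mut"], 0.5)
  expect_equal(st$mean_fc[st$genotype == "ref"], 1)
  scaled <- fold_changes(lapply(g, `*`, 7), "ref")
  expect_equal(scaled$per_animal, fc$per_animal)
  expect_error(fold_changes(g, "zz"), "not among")
  expect_error(fold_changes(list(ref = c(0, 0), m = 1), "ref"), "positive")
})

test_that("the multiplicative expectation and its propagated error follow
           the product rule", {
  a <- list(mean_fc = 0.5, sd_fc = 0.1, n = 10)    # rel err 0.2
  b <- list(mean_fc = 0.8, sd_fc = 0.1, n = 10)    # rel err 0.125
  em <- expected_multiplicative(a, b)
  expect_equal(em$E, 0.4)
  expect_equal(em$sd_expected, 0.4 * 0.325)
  # symmetric in its arguments
  em2 <- expected_multiplicative(b, a)
  expect_equal(em2, em)
  # identity factor
  id <- list(mean_fc = 1, sd_fc = 0, n = 10)
  expect_equal(expected_multiplicative(id, b),
               list(E = 0.8, sd_expected = 0.8 * 0.125))
  expect_equal(expected_multiplicative(id, id),
               list(E = 1, sd_expected = 0))
  # quadrature and SEM modes
  emq <- expected_multiplicative(a, b, mode = "quadrature")
  expect_equal(emq$sd_expected, 0.4 * sqrt(0.2^2 + 0.125^2))
  ems <- expected_multiplicative(a, b, error = "sem")
  expect_equal(ems$sd_expected, 0.4 * (0.2 + 0.125) / sqrt(10))
  expect_error(expected_multiplicative(list(mean_fc = 0, sd_fc = 0), b),
               "positive")
})

test_that("the synergy verdict reflects observed vs expected fold
           change", {
  # observed mean exactly at the expectation: t = 0, p = 1
  triple <- c(8, 12, 10, 10)    # mean 10, ref mean 50 -> fc mean 0.2
  sy <- synergy_test(triple, 50, E = 0.2)
  expect_equal(sy$t_statistic, 0)
  expect_equal(sy$p_value, 1)
  expect_equal(sy$verdict, "consistent_with_multiplicative")
  # strong loss
  sy2 <- synergy_test(c(1, 2, 1, 2, 1, 2), 50, E = 0.5)
  expect_equal(sy2$verdict, "synergistic_loss")
  # degenerate zero-variance input
  sy3 <- synergy_test(c(10, 10, 10), 50, E = 0.2)
  expect_true(sy3$degenerate)
  expect_equal(sy3$p_value, 1)
  sy4 <- synergy_test(c(10, 10, 10), 50, E = 0.4)
  expect_equal(sy4$verdict, "degenerate")
  # conservative mode widens the test
  sy5 <- synergy_test(c(8, 12, 10, 11), 50, E = 0.3, sd_expected = 0.05,
                      conservative = TRUE)
  sy6 <- synergy_test(c(8, 12, 10, 11), 50, E = 0.3)
  expect_gt(sy5$p_value, sy6$p_value)
  expect_error(synergy_test(5, 50, 0.2), ">= 2")
})

test_that("Fisher rescue tests match exhaustive hypergeometric
           enumeration", {
  flat <- rescue_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$odds_ratio, 1)
  tab <- matrix(c(9, 2, 1, 8), 2)
  expect_equal(rescue_test(tab)$p_value, oracle_fisher(tab),
               tolerance = 1e-10)
  set.seed(181)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    expect_equal(rescue_test(tab)$p_value, oracle_fisher(tab),
                 tolerance = 1e-10)
  }
  zero <- rescue_test(matrix(c(10, 0, 3, 7), 2))
  expect_true(is.finite(zero$p_value))
  expect_equal(zero$odds_ratio, Inf)
  expect_error(rescue_test(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("behavior indexes compute the literal formulas and respect
           their bounds", {
  expect_equal(behavior_index("response", responses = 10, strokes = 50)$value,
               0.2)
  expect_equal(behavior_index("chemotaxis_quadrant", t1 = 30, t2 = 20,
                              c1 = 0, c2 = 0, total = 50)$value, 1)
  expect_equal(behavior_index("chemotaxis_halves", t = 30, c = 10,
                              total = 50)$value, 0.4)
  expect_equal(behavior_index("avoidance_sectors", sector_a = 5,
                              sector_b = 5, sector_e = 20, sector_f = 20,
                              total = 60)$value, -0.5)
  expect_equal(behavior_index("avoidance_drop", responses = 12,
                              drops = 20)$value, 0.6)
  expect_equal(behavior_index("dauer_fraction", dauer = 30,
                              total = 100)$value, 0.3)
  expect_error(behavior_index("response", responses = 1, strokes = 0),
               "denominator")
  expect_error(behavior_index("response", responses = 1), "needs")
  # bounds hold for arbitrary non-negative inputs
  set.seed(191)
  for (i in 1:20) {
    x <- sample(0:30, 5, replace = TRUE)
    total <- sum(x) + 1
    ci <- behavior_index("chemotaxis_quadrant", t1 = x[1], t2 = x[2],
                         c1 = x[3], c2 = x[4], total = total)$value
    expect_true(ci >= -1 && ci <= 1)
    ri <- behavior_index("response", responses = min(x[1], x[2] + 1),
                         strokes = x[2] + 1)$value
    expect_true(ri >= 0 && ri <= 1)
  }
})

test_that("dauer fold induction contrasts genotypes as a ratio of
           fractions", {
  wt <- dauer_fold_induction(
    behavior_index("dauer_fraction", dauer = 30, total = 100),
    behavior_index("dauer_fraction", dauer = 5, total = 100))
  mut <- dauer_fold_induction(0.15, 0.05)
  expect_equal(wt, 6)
  expect_equal(mut, 3)
  expect_error(dauer_fold_induction(0.3, 0), "positive")
})
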