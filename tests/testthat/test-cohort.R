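test_that("the Friedman test handles degenerate and textbook cases", {
  X <- matrix(5, 6, 3)
  ft <- friedman_test(X)
  expect_equal(unname(ft$statistic), 0)
  expect_equal(ft$p.value, 1)
  # 3 patients ranking 3 stages identically, no ties -> Q = 6
  X <- rbind(c(1, 2, 3), c(4, 5, 6), c(2, 4, 9))
  ft <- friedman_test(X)
  expect_equal(unname(ft$statistic), 6)
  expect_equal(unname(ft$statistic), friedman_stat_oracle(X))
  expect_error(friedman_test(rbind(c(1, NA, 2), c(3, 2, 1))), "missing")
})

test_that("the Friedman statistic and p agree with stats::friedman.test", {
  set.seed(31)
  for (i in 1:20) {
    X <- matrix(rnorm(8 * 3), 8, 3)  # continuous -> no ties
    ours <- friedman_test(X)
    ref <- stats::friedman.test(X)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Friedman p matches full permutation enumeration", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    if (i %% 5 == 0) X[1, 2] <- X[1, 1]  # inject ties sometimes
    ours <- friedman_test(X, exact = TRUE)
    expect_equal(ours$p.value, friedman_p_oracle(X), tolerance = 1e-12)
    expect_equal(unname(ours$statistic), friedman_stat_oracle(X),
                 tolerance = 1e-12)
  }
})

test_that("the Friedman statistic is invariant to monotone transforms", {
  set.seed(4)
  X <- matrix(rnorm(10 * 3, 10), 10, 3)
  q0 <- unname(friedman_test(X)$statistic)
  expect_equal(unname(friedman_test(exp(X))$statistic), q0)
  expect_equal(unname(friedman_test(X^3)$statistic), q0)
})

test_that("the signed-rank test matches 2^n enumeration and wilcox.test", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 3) next
    ours <- signed_rank_test(d)
    orc <- signed_rank_oracle(d)
    expect_equal(unname(ours$statistic), orc$W)
    expect_equal(ours$p.value, orc$p, tolerance = 1e-12)
    if (!any(duplicated(abs(d)))) {
      ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
  zeros <- signed_rank_test(rep(0, 6))
  expect_true(zeros$degenerate)
  expect_equal(zeros$p.value, 1)
})

test_that("post-hoc pairs carry the Bonferroni factor of 3", {
  set.seed(8)
  X <- cbind(staging = rnorm(10, 10), interim = rnorm(10, 12),
             eot = rnorm(10, 10))
  ph <- posthoc_pairwise(X)
  expect_equal(nrow(ph), 3)
  for (i in 1:3) {
    raw <- signed_rank_test(X[, utils::combn(3, 2)[1, i]],
                            X[, utils::combn(3, 2)[2, i]])$p.value
    expect_equal(ph$adjusted_p[i], min(1, 3 * raw))
  }
  same <- posthoc_pairwise(cbind(a = 1:6, b = 1:6, c = 1:6))
  expect_true(all(same$adjusted_p == 1))
  expect_true(all(same$degenerate))
})

test_that("point-biserial equals Pearson with 0/1 coding", {
  set.seed(12)
  for (i in 1:15) {
    x <- rnorm(20)
    g <- rep(c("A", "B"), each = 10)
    ours <- point_biserial(x, g)
    expect_equal(unname(ours$estimate),
                 cor(x, rep(c(0, 1), each = 10)), tolerance = 1e-12)
    ref <- stats::cor.test(x, rep(c(0, 1), each = 10))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
  # equal group means -> r = 0
  x <- c(1, 2, 3, 1, 2, 3)
  expect_equal(unname(point_biserial(x, rep(c("A", "B"), each = 3))$estimate),
               0)
  # perfect separation -> |r| = 1, sign flips with label order
  x <- c(1, 1, 1, 2, 2, 2)
  r1 <- unname(point_biserial(x, rep(c("A", "B"), each = 3))$estimate)
  r2 <- unname(point_biserial(x, rep(c("B", "A"), each = 3))$estimate)
  expect_equal(r1, 1); expect_equal(r2, -1)
  expect_error(point_biserial(rep(1, 6), rep(c("A", "B"), each = 3)),
               "variance")
  expect_error(point_biserial(rnorm(6), rep("A", 6)), "two")
})

test_that("cohort summaries report mean, sample SD and n per group", {
  rec <- data.frame(
    patient_id = rep(1:4, each = 3),
    regimen = rep(c("R-CHOP", "ABVD"), each = 6),
    stage = rep(c("staging", "interim", "eot"), 4),
    slur = c(80, 85, 78, 82, 88, 76, 79, 84, 75, 81, 86, 77))
  s <- summarize_cohort(rec, metrics = "slur")
  expect_setequal(unique(s$group), c("R-CHOP", "ABVD", "Both"))
  both_staging <- s[s$group == "Both" & s$stage == "staging", ]
  expect_equal(both_staging$mean, mean(c(80, 82, 79, 81)))
  expect_equal(both_staging$sd, sd(c(80, 82, 79, 81)))
  expect_equal(both_staging$n, 4)
  # two-record closed form
  two <- s[s$group == "R-CHOP" & s$stage == "eot", ]
  expect_equal(two$sd, abs(78 - 76) / sqrt(2))
  # single record -> NA sd
  one <- rec[rec$patient_id == 1, ]
  s1 <- summarize_cohort(one, metrics = "slur")
  expect_true(all(is.na(s1$sd)))
})

test_that("simulated cohort metrics recover their generating mean", {
  X <- simulate_cohort(n_patients = 200, baseline_mean = 80, between_sd = 8,
                       within_sd = 5, seed = 99)
  expect_identical(dim(X), c(200L, 3L))
  total_sd <- sqrt(8^2 + 5^2)
  expect_lt(abs(mean(X[, "staging"]) - 80), 3 * total_sd / sqrt(200))
  # determinism under seed
  Y <- simulate_cohort(n_patients = 200, baseline_mean = 80, between_sd = 8,
                       within_sd = 5, seed = 99)
  expect_identical(X, Y)
})
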