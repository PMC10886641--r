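lines5 <- c("Control", "LRRK2", "PINK1", "PinkParkin", "A53T")

sim_cells <- function(seed, n_per = 12, shift = NULL) {
  set.seed(seed)
  d <- data.frame(line = rep(lines5, each = n_per),
                  condition = "normal",
                  value = rnorm(5 * n_per))
  if (!is.null(shift)) d$value[d$line == names(shift)] <-
    d$value[d$line == names(shift)] + shift[[1]]
  d
}

test_that("the normality gate reports per-group Shapiro-Wilk results", {
  d <- sim_cells(1)
  ng <- suppressWarnings(normality_gate(d, "value"))  # chance gate trips
  expect_identical(sort(ng$group), sort(lines5))
  expect_true(all(ng$p_value >= 0 & ng$p_value <= 1))
  expect_true(is.logical(attr(ng, "all_normal")))
})

test_that("the gate rejects degenerate or tiny groups by name", {
  d <- data.frame(line = rep(c("A", "B"), each = 5),
                  value = c(rnorm(5), rep(1, 5)))
  expect_error(normality_gate(d, "value"), "degenerate")
  d2 <- data.frame(line = c("A", "A", "B", "B", "B"),
                   value = c(1, 2, rnorm(3)))
  expect_error(normality_gate(d2, "value"), "fewer than 3")
})

test_that("a skewed group trips the gate with a warning", {
  set.seed(5)
  d <- data.frame(line = rep(c("A", "B"), each = 50),
                  value = c(rnorm(50), rexp(50)))
  expect_warning(ng <- normality_gate(d, "value"), "normality gate failed")
  expect_false(attr(ng, "all_normal"))
})

test_that("five groups give a Bonferroni-adjusted alpha of exactly 0.005", {
  expect_identical(adjusted_alpha(5), 0.05 / 10)
  cr <- compare_groups(sim_cells(2), "value")
  expect_identical(cr$adjusted_alpha, 0.005)
  expect_identical(cr$n_groups, 5L)
  expect_identical(nrow(cr$pairwise), 10L)
  # explicit comparison family, as in a 6-pair design
  expect_equal(adjusted_alpha(family_size = 6, k = 2), 0.05 / 6,
               tolerance = 1e-12)
})

test_that("a strongly shifted group is detected by ANOVA and Tukey", {
  cr <- compare_groups(sim_cells(3, shift = c(PINK1 = 3)), "value")
  expect_lt(cr$anova$p_value[1], 1e-6)
  hits <- cr$pairwise$significant[grepl("PINK1", cr$pairwise$comparison)]
  expect_true(all(hits))
  expect_false(any(cr$pairwise$significant[
    !grepl("PINK1", cr$pairwise$comparison)]))
})

test_that("the two-way design crosses line and condition, empty cells error", {
  d <- sim_cells(4)
  d$condition <- rep(c("normal", "H2O2"), length.out = nrow(d))
  cr <- compare_groups(d, "value", design = "two_way")
  expect_setequal(cr$anova$term[1:3], c(".line", ".cond", ".line:.cond"))
  d2 <- d[!(d$line == "A53T" & d$condition == "H2O2"), ]
  expect_error(compare_groups(d2, "value", design = "two_way"), "empty")
})

test_that("the before/after test is an equal-variance Student t-test", {
  set.seed(6)
  d <- data.frame(line = "PINK1",
                  condition = rep(c("normal", "H2O2"), each = 10),
                  value = c(rnorm(10, 5), rnorm(10, 5)))
  res <- paired_condition_test(d, "value", "PINK1")
  a <- d$value[1:10]; b <- d$value[11:20]
  sp <- sqrt(((9 * var(a)) + (9 * var(b))) / 18)
  t_closed <- (mean(a) - mean(b)) / (sp * sqrt(1 / 10 + 1 / 10))
  expect_equal(res$statistic, t_closed, tolerance = 1e-12)
  expect_identical(res$df, 18)
  # identical samples: zero difference, p = 1
  d$value[11:20] <- d$value[1:10]
  same <- paired_condition_test(d, "value", "PINK1")
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_error(paired_condition_test(d[1:10, ], "value", "PINK1"),
               "lacks condition")
})

test_that("ANCOVA line effects are invariant to shifting all donor ages", {
  set.seed(7)
  d <- data.frame(line = rep(c("Control", "PINK1"), each = 30),
                  age = runif(60, 40, 70),
                  sex = sample(c("male", "female"), 60, TRUE),
                  value = rnorm(60))
  d$value <- d$value + 0.1 * (d$line == "PINK1")
  a1 <- ancova_covariates(d, "value")
  d2 <- d; d2$age <- d2$age + 100
  a2 <- ancova_covariates(d2, "value")
  expect_equal(a1$terms$statistic[a1$terms$term == "line"],
               a2$terms$statistic[a2$terms$term == "line"],
               tolerance = 1e-9)
  expect_false(a1$confounded)
  expect_true(is.finite(a1$interaction_p))
})

test_that("one donor per line is flagged as a confounded design", {
  donors <- data.frame(line = lines5,
                       age = c(56, 55, 52, 72, 52),
                       sex = c("male", "male", "female", "male", "female"))
  set.seed(8)
  d <- donors[rep(1:5, each = 12), ]
  d$value <- rnorm(60)
  expect_warning(a <- ancova_covariates(d, "value"), "confounded")
  expect_true(a$confounded)
})

test_that("ANCOVA recovers a simulated age slope within 3 SE", {
  set.seed(9)
  d <- data.frame(line = rep(c("Control", "PINK1"), each = 30),
                  age = runif(60, 30, 70),
                  sex = sample(c("male", "female"), 60, TRUE))
  d$value <- 0.5 * d$age + rnorm(60)
  a <- ancova_covariates(d, "value")
  est <- summary(a$model)$coefficients["age", ]
  expect_lt(abs(est[["Estimate"]] - 0.5), 3 * est[["Std. Error"]])
})

test_that("fold changes reproduce the worked ratios, rounded half-up", {
  fc <- fold_change(c(Control = 2.9, PINK1 = 6.1, PinkParkin = 7.6),
                    "Control")
  expect_equal(fc$fold_change[fc$group == "PINK1"], 2.1)
  expect_equal(fc$fold_change[fc$group == "PinkParkin"], 2.6)
  expect_equal(fc$fold_change[fc$group == "Control"], 1.0)
  # half-up, not banker's rounding
  expect_equal(fold_change(c(r = 1, x = 0.25), "r")$fold_change[2], 0.3)
  expect_error(fold_change(c(r = 0, x = 1), "r"), "positive")
  expect_error(fold_change(c(x = 1), "r"), "reference")
})

test_that("null rejection rates sit near nominal alpha (quick calibration)", {
  set.seed(10)
  n_rep <- 2000
  rej_sw <- rej_t <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(20)
    if (stats::shapiro.test(x)$p.value < 0.05) rej_sw <- rej_sw + 1
    d <- data.frame(line = "L",
                    condition = rep(c("normal", "H2O2"), each = 12),
                    value = rnorm(24))
    if (paired_condition_test(d, "value", "L")$p_value < 0.05)
      rej_t <- rej_t + 1
  }
  expect_gt(rej_sw / n_rep, 0.035); expect_lt(rej_sw / n_rep, 0.065)
  expect_gt(rej_t / n_rep, 0.035); expect_lt(rej_t / n_rep, 0.065)
})
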