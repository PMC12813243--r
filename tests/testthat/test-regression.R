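# data whose saturated logistic fit must reproduce a 2x2 table exactly
table_data <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(x = cbind(`(Intercept)` = 1, exposure = x), y = y)
}

test_that("a single-binary-predictor fit reproduces the 2x2 closed form", {
  d <- table_data(20, 80, 10, 90)
  f <- fit_logistic(d$x, d$y)
  expect_true(f$converged)
  expect_equal(f$table[term == "exposure"]$aor, 2.25, tolerance = 1e-10)
  expect_equal(f$table[term == "exposure"]$se,
               sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90), tolerance = 1e-10)
  expect_equal(f$n_events, 30)
})

test_that("IRLS agrees with an independent Newton oracle and with glm", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(60:500, 1)
    p <- sample(1:5, 1)
    x <- cbind(1, matrix(rnorm(n * p), n, p))
    beta <- rnorm(p + 1, sd = 0.7)
    y <- rbinom(n, 1, plogis(drop(x %*% beta)))
    if (sum(y) < 5 || sum(y) > n - 5) next
    f <- fit_logistic(x, y)
    expect_true(f$converged)
    oracle <- newton_logit(x, y)
    expect_equal(unname(f$coefficients), unname(oracle), tolerance = 1e-6)
  }
  # spot cross-check against the reference GLM fitter
  set.seed(8)
  x <- cbind(1, rnorm(300), rbinom(300, 1, 0.4))
  y <- rbinom(300, 1, plogis(0.3 * x[, 2] - 0.5 * x[, 3]))
  f <- fit_logistic(x, y)
  g <- glm(y ~ x[, 2] + x[, 3], family = binomial)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
})

test_that("estimates are invariant to case order", {
  set.seed(12)
  n <- 400
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(0.5 * x[, 2]))
  f1 <- fit_logistic(x, y)
  perm <- sample(n)
  f2 <- fit_logistic(x[perm, ], y[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("null data recover odds ratios near 1", {
  set.seed(33)
  n <- 20000
  x <- cbind(1, rbinom(n, 1, 0.5))
  colnames(x) <- c("(Intercept)", "z")
  y <- rbinom(n, 1, 0.2)  # independent of z
  f <- fit_logistic(x, y)
  expect_equal(f$table[term == "z"]$aor, 1, tolerance = 0.1)
})

test_that("separation is flagged, never silently estimated", {
  x <- cbind(1, c(rep(1, 20), rep(0, 20)))
  y <- c(rep(1, 20), rep(0, 20))  # all events in one stratum
  f <- fit_logistic(x, y)
  expect_true(f$separation)
  expect_false(f$converged)
})

test_that("constant and collinear columns are dropped with a record", {
  set.seed(4)
  n <- 200
  z <- rbinom(n, 1, 0.5)
  x <- cbind(`(Intercept)` = 1, z = z, konst = 0, z2 = z)
  y <- rbinom(n, 1, plogis(-1 + z))
  f <- fit_logistic(x, y)
  expect_setequal(f$dropped, c("konst", "z2"))
  expect_true(f$converged)
})

test_that("univariate selection is strict at the threshold", {
  expect_false(faersage:::select_rule(0.05))
  expect_true(faersage:::select_rule(0.049))
  expect_false(faersage:::select_rule(NA_real_))

  # age category is selected even when uninformative
  set.seed(21)
  n <- 4000
  cases <- data.table::data.table(
    age_group = sample(c("lt65", "65_74", "75_84", "ge85"), n, TRUE),
    endocrine = rbinom(n, 1, 0.4) == 1,
    chemotherapy = rbinom(n, 1, 0.1) == 1,
    other_targeted = FALSE)  # constant -> cannot be selected
  y <- rbinom(n, 1, plogis(-2 + 1.0 * cases$endocrine))
  uni <- univariate_screen(cases, y)
  expect_true(uni[term == "age_group"]$selected)
  expect_gt(uni[term == "age_group"]$p_value, 0.05)
  expect_true(uni[term == "endocrine"]$selected)
  expect_false(uni[term == "other_targeted"]$selected)
  expect_true(is.na(uni[term == "other_targeted"]$p_value))
})

test_that("with no covariates the age aOR equals the crude odds ratio", {
  set.seed(9)
  n <- 6000
  cases <- data.table::data.table(
    age_group = sample(c("lt65", "65_74", "75_84", "ge85"), n, TRUE,
                       prob = c(0.5, 0.25, 0.15, 0.1)))
  p <- c(lt65 = 0.10, `65_74` = 0.18, `75_84` = 0.25, ge85 = 0.30)
  y <- rbinom(n, 1, p[cases$age_group])
  f <- fit_logistic(faersage:::build_design(cases), y)
  for (g in c("65_74", "75_84", "ge85")) {
    sub <- cases$age_group %in% c(g, "lt65")
    crude <- table(factor(cases$age_group[sub] == g), y[sub])
    or <- (crude["TRUE", "1"] * crude["FALSE", "0"]) /
      (crude["TRUE", "0"] * crude["FALSE", "1"])
    trm <- c(`65_74` = "age_65_74", `75_84` = "age_75_84",
             ge85 = "age_ge85")[g]
    expect_equal(f$table[term == trm]$aor, unname(or), tolerance = 1e-8)
  }
})

test_that("the cascade applies the 60-event rule at the boundary", {
  set.seed(55)
  n <- 4000
  cohort <- data.table::data.table(
    primaryid = 1:n, exposure_drug = "abemaciclib",
    age_group = sample(c("lt65", "65_74", "75_84", "ge85"), n, TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)),
    endocrine = rbinom(n, 1, 0.4) == 1,
    chemotherapy = rbinom(n, 1, 0.05) == 1,
    other_targeted = rbinom(n, 1, 0.05) == 1)
  pairs <- data.table::data.table(drug = "abemaciclib", smq_code = c(1L, 2L))
  flags59 <- data.table::data.table(PRIMARYID = 1:59, smq_code = 1L)
  flags60 <- data.table::data.table(PRIMARYID = sample(n, 60), smq_code = 2L)
  res <- multivariate_cascade(cohort, pairs, rbind(flags59, flags60),
                              min_events = 60L)
  expect_equal(unique(res[smq_code == 1]$status), "min_events")
  expect_true(all(is.na(res[smq_code == 1]$aor)))
  expect_true(all(res[smq_code == 2]$status %in%
                    c("ok", "dropped", "separation")))
  expect_equal(unique(res[smq_code == 2]$n_events), 60)
})

test_that("the cascade recovers a planted age effect end to end", {
  dict <- synthetic_smq_dictionary(4)
  pl <- rbind(planted_effect("palbociclib", 91000001, "65_74", log(2)),
              planted_effect("palbociclib", 91000001, "75_84", log(2)),
              planted_effect("palbociclib", 91000001, "ge85", log(2)))
  cfg <- synthetic_config(n_cases = 40000, duplicate_fraction = 0, seed = 14,
                          smq_dictionary = dict, planted_log_or = pl)
  b <- generate_bundle(cfg)
  co <- build_cohort(b, load_drug_lexicon())
  cs <- map_case_smqs(b$reac, expand_smq_hierarchy(dict))
  res <- multivariate_cascade(
    co$cases, data.table::data.table(drug = "palbociclib",
                                     smq_code = 91000001L), cs)
  expect_true(all(res$status == "ok"))
  expect_equal(res[age_group == "65_74"]$aor, 2, tolerance = 0.25)
  expect_equal(res[age_group == "75_84"]$aor, 2, tolerance = 0.25)
  expect_equal(res[age_group == "ge85"]$aor, 2, tolerance = 0.35)
})
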