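lex <- load_drug_lexicon()

test_that("age strata route boundary values as defined", {
  expect_equal(assign_age_group(c(18, 64.9, 65, 74.9, 75, 84.9, 85, 100)),
               c("lt65", "lt65", "65_74", "65_74", "75_84", "75_84",
                 "ge85", "ge85"))
  expect_error(assign_age_group(17.9), "\\[18, 100\\]")
  expect_error(assign_age_group(100.1), "\\[18, 100\\]")
  expect_error(assign_age_group(NA_real_), "\\[18, 100\\]")
})

test_that("selection filters exclude with the stated reasons", {
  b <- bundle_from_cases(
    eligible_case(1L),                                   # retained
    eligible_case(2L, sex = "M"),                        # sex
    eligible_case(3L, role = "SS"),                      # role: CDK only SS
    eligible_case(4L, drugname = "METFORMIN"),           # role: PS not CDK
    eligible_case(5L, age = "17.5"),                     # age < 18
    eligible_case(6L, age = "101"),                      # age > 100
    eligible_case(7L, age = NA_character_,
                  age_cod = NA_character_),              # age missing
    eligible_case(8L, indi_pt = "Rheumatoid arthritis"), # indication
    eligible_case(9L, fda = 20141231L))                  # before window
  co <- build_cohort(b, lex)
  expect_equal(co$cases$primaryid, 1L)
  expect_equal(co$cases$exposure_drug, "palbociclib")
  excl <- co$exclusions
  expect_equal(excl$sex, 1L)
  expect_equal(excl$role, 2L)
  expect_equal(excl$age, 3L)
  expect_equal(excl$indication, 1L)
  expect_equal(excl$date, 1L)
  expect_equal(excl$retained + excl$sex + excl$role + excl$age +
                 excl$indication + excl$date + excl$ambiguous_exposure,
               excl$input)
})

test_that("two distinct CDK4/6i primary suspects exclude the case", {
  amb <- eligible_case(1L)
  amb$drug <- rbind(amb$drug, data.table::data.table(
    PRIMARYID = 1L, CASEID = 1L, DRUG_SEQ = 2L, ROLE_COD = "PS",
    DRUGNAME = "KISQALI", DECHAL = "U"))
  co <- build_cohort(bundle_from_cases(amb), lex)
  expect_equal(nrow(co$cases), 0)
  expect_equal(co$exclusions$ambiguous_exposure, 1L)
  # ... but the same CDK4/6i listed twice as PS stays unambiguous
  twice <- eligible_case(2L)
  twice$drug <- rbind(twice$drug, data.table::data.table(
    PRIMARYID = 2L, CASEID = 2L, DRUG_SEQ = 2L, ROLE_COD = "PS",
    DRUGNAME = "Palbociclib", DECHAL = "U"))
  co2 <- build_cohort(bundle_from_cases(twice), lex)
  expect_equal(nrow(co2$cases), 1)
})

test_that("ages in other unit codes are normalized before the filter", {
  b <- bundle_from_cases(eligible_case(1L, age = "792", age_cod = "MON"))
  co <- build_cohort(b, lex)
  expect_equal(co$cases$age_years, 66)
  expect_equal(co$cases$age_group, "65_74")
})

test_that("covariates derive from co-administered roles only", {
  rows <- data.table::data.table(
    PRIMARYID = 1L, CASEID = 1L, DRUG_SEQ = 1:4,
    ROLE_COD = c("PS", "C", "I", "SS"),
    DRUGNAME = c("IBRANCE", "letrozole", "Trastuzumab", "Some supplement"),
    DECHAL = NA_character_)
  flags <- derive_covariates(rows, lex)
  expect_true(flags[["endocrine"]])
  expect_true(flags[["other_targeted"]])
  expect_false(flags[["chemotherapy"]])
  # primary-suspect rows never set covariates
  ps_only <- rows[1]
  ps_only$DRUGNAME <- "XELODA"
  expect_false(any(derive_covariates(ps_only, lex)))
  # no co-administered rows at all
  expect_false(any(derive_covariates(rows[1], lex)))
})

test_that("cohort summary computes interpolated quantiles and category shares", {
  cases <- data.table::data.table(
    primaryid = 1:4, caseid = 1:4, age_years = c(50, 60, 70, 80),
    age_group = assign_age_group(c(50, 60, 70, 80)), sex = "F",
    exposure_drug = "palbociclib", endocrine = FALSE, chemotherapy = FALSE,
    other_targeted = FALSE, immune_checkpoint = FALSE,
    dechal = NA_character_, outcome_codes = "",
    time_to_onset_days = NA_integer_)
  s <- summarize_cohort(cases)
  all_rows <- s[drug == "all"]
  expect_equal(all_rows[metric == "age_median"]$value, 65)
  expect_equal(all_rows[metric == "age_q1"]$value, 57.5)
  expect_equal(all_rows[metric == "age_q3"]$value, 72.5)
  # all dechallenge fields blank -> 100% unknown
  expect_equal(all_rows[metric == "pct_dechal_unknown"]$value, 100)
  # age groups partition the cohort
  expect_equal(sum(all_rows[metric %in% paste0("n_", c("lt65", "65_74",
                                                       "75_84", "ge85"))]$value),
               nrow(cases))

  # one death among 10 cases -> 10%
  ten <- cases[rep(1, 10)][, primaryid := 1:10][, caseid := 1:10]
  ten$outcome_codes <- c("DE", rep("", 9))
  s10 <- summarize_cohort(ten)
  expect_equal(s10[drug == "all" & metric == "pct_outcome_death"]$value, 10)
  expect_equal(s10[drug == "all" & metric == "outcome_any_serious"]$value, 1)

  expect_equal(nrow(summarize_cohort(cases[0])), 0)
})

test_that("cohort retention matches the generator's eligibility rates", {
  cfg <- synthetic_config(n_cases = 20000, duplicate_fraction = 0, seed = 77)
  b <- generate_bundle(cfg)
  co <- build_cohort(b, lex)
  # eligible = CDK4/6i exposure & female & age reported
  p_eligible <- (1 - cfg$drug_mix[["other"]]) * cfg$sex_female_prob *
    (1 - cfg$missing_age_fraction)
  frac <- nrow(co$cases) / cfg$n_cases
  expect_gt(frac, p_eligible - 3 * sqrt(p_eligible * (1 - p_eligible) / 20000))
  expect_lt(frac, p_eligible + 3 * sqrt(p_eligible * (1 - p_eligible) / 20000))
  # age groups partition the retained cohort
  expect_equal(sum(table(co$cases$age_group)), nrow(co$cases))
  expect_true(all(co$cases$exposure_drug %in%
                    c("palbociclib", "ribociclib", "abemaciclib")))
})
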