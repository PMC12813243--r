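#' Configuration for the synthetic FAERS-like generator
#'
#' The generator emulates the structure of FAERS quarterly data at desk scale:
#' unique cases with demographics, one primary-suspect exposure drug,
#' co-medication rows, indication rows, SMQ-driven reaction terms, therapy
#' start dates, outcomes, dechallenge codes, and superseded report versions
#' sharing a `CASEID`. Reporting-odds effects are planted on
#' (drug, SMQ, age-group) triples so that downstream signal detection can be
#' checked against known truth.
#'
#' Default marginals follow the published descriptive profile of the CDK4/6
#' inhibitor breast-cancer reports: age strata 45.8/31.0/18.8/4.4%, the three
#' inhibitors in ratio 77.2:12.8:10.0 within a 30% exposure share (the
#' remaining 70% of reports form the "rest of database" comparator pool),
#' endocrine/chemotherapy/other-targeted co-medication at 42.8/0.8/1.2%.
#'
#' @param n_cases Number of unique cases (distinct `CASEID`s).
#' @param duplicate_fraction Proportion in `[0,1)` of cases also emitted as a
#'   superseded earlier report version.
#' @param drug_mix Named probability vector over exposure drugs; must include
#'   an `other` entry for the background pool and sum to 1.
#' @param age_group_probs Named probability vector over the four strata
#'   `lt65`, `65_74`, `75_84`, `ge85`; sums to 1.
#' @param sex_female_prob Probability a case is female.
#' @param covariate_prevalence Named probabilities for `endocrine`,
#'   `chemotherapy`, `other_targeted` co-medication.
#' @param ici_prevalence Probability of immune-checkpoint-inhibitor
#'   co-medication (descriptive only; not a planted-effect channel).
#' @param baseline_event_logit Named numeric: per-SMQ baseline log-odds of
#'   reporting that SMQ; names are `smq_code`s of `smq_dictionary`. `NULL`
#'   gives every SMQ logit `qlogis(0.08)`.
#' @param planted_log_or `data.frame` with columns `drug`, `smq_code`,
#'   `age_group`, `log_or`: log reporting-odds shifts added to the baseline
#'   logit for cases with that drug and age group. `NULL` means no effects.
#' @param missing_age_fraction Proportion of reports with a blank age.
#' @param alt_age_unit_fraction Proportion of non-missing ages coded in
#'   `MON`/`DY`/`DEC` units instead of `YR` (exercises unit conversion).
#' @param event_dt_missing_fraction Proportion of reports with no event date
#'   (time to onset then missing).
#' @param date_window Integer `c(from, to)` as `YYYYMMDD`; FDA receipt dates
#'   fall inside it.
#' @param smq_dictionary `smq_dictionary` whose narrow terms the generator
#'   draws reaction PTs from; `NULL` uses [synthetic_smq_dictionary()] with 8
#'   flat SMQs.
#' @param seed Integer RNG seed; identical configurations produce identical
#'   bundles.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 50000L,
                             duplicate_fraction = 0.10,
                             drug_mix = c(other = 0.70,
                                          palbociclib = 0.2316,
                                          ribociclib = 0.0384,
                                          abemaciclib = 0.0300),
                             age_group_probs = c(lt65 = 0.458, `65_74` = 0.310,
                                                 `75_84` = 0.188, ge85 = 0.044),
                             sex_female_prob = 0.90,
                             covariate_prevalence = c(endocrine = 0.428,
                                                      chemotherapy = 0.008,
                                                      other_targeted = 0.012),
                             ici_prevalence = 4e-4,
                             baseline_event_logit = NULL,
                             planted_log_or = NULL,
                             missing_age_fraction = 0.10,
                             alt_age_unit_fraction = 0.05,
                             event_dt_missing_fraction = 0.20,
                             date_window = c(20150101L, 20250331L),
                             smq_dictionary = NULL,
                             seed = 1L) {
  if (is.null(smq_dictionary)) smq_dictionary <- synthetic_smq_dictionary()
  stopifnot(inherits(smq_dictionary, "smq_dictionary"))
  if (is.null(baseline_event_logit)) {
    codes <- smq_dictionary$smqs$smq_code
    baseline_event_logit <- setNames(rep(qlogis(0.08), length(codes)),
                                     as.character(codes))
  }
  cfg <- list(n_cases = as.integer(n_cases),
              duplicate_fraction = duplicate_fraction,
              drug_mix = drug_mix,
              age_group_probs = age_group_probs,
              sex_female_prob = sex_female_prob,
              covariate_prevalence = covariate_prevalence,
              ici_prevalence = ici_prevalence,
              baseline_event_logit = baseline_event_logit,
              planted_log_or = normalize_planted(planted_log_or),
              missing_age_fraction = missing_age_fraction,
              alt_age_unit_fraction = alt_age_unit_fraction,
              event_dt_missing_fraction = event_dt_missing_fraction,
              date_window = as.integer(date_window),
              smq_dictionary = smq_dictionary,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

normalize_planted <- function(planted) {
  if (is.null(planted))
    return(data.table::data.table(drug = character(), smq_code = integer(),
                                  age_group = character(), log_or = numeric()))
  planted <- data.table::as.data.table(planted)
  stopifnot(all(c("drug", "smq_code", "age_group", "log_or") %in% names(planted)))
  planted[, smq_code := as.integer(smq_code)]
  planted[, .(drug, smq_code, age_group, log_or)]
}

#' Build rows for `planted_log_or`
#'
#' Convenience constructor; `age_group = "all"` expands to all four strata.
#'
#' @param drug,smq_code,age_group,log_or Recycled to a common length.
#' @return `data.table` suitable for [synthetic_config()]'s `planted_log_or`.
#' @export
planted_effect <- function(drug, smq_code, age_group = "all", log_or) {
  dt <- data.table::data.table(drug = drug, smq_code = as.integer(smq_code),
                               age_group = age_group, log_or = log_or)
  expand <- dt[age_group == "all",
               .(age_group = AGE_GROUPS), by = .(drug, smq_code, log_or)]
  out <- rbind(dt[age_group != "all"],
               expand[, .(drug, smq_code, age_group, log_or)])
  out[, .(drug, smq_code, age_group, log_or)]
}

validate_synthetic_config <- function(cfg) {
  chk_prob_vec <- function(p, nm) {
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("invalid configuration: ", nm,
           " must be a nonnegative probability vector summing to 1")
  }
  if (cfg$n_cases < 1L) stop("invalid configuration: n_cases must be >= 1")
  if (cfg$duplicate_fraction < 0 || cfg$duplicate_fraction >= 1)
    stop("invalid configuration: duplicate_fraction must be in [0,1)")
  chk_prob_vec(cfg$drug_mix, "drug_mix")
  if (!"other" %in% names(cfg$drug_mix))
    stop("invalid configuration: drug_mix needs an 'other' background entry")
  chk_prob_vec(cfg$age_group_probs, "age_group_probs")
  if (!identical(names(cfg$age_group_probs), AGE_GROUPS))
    stop("invalid configuration: age_group_probs names must be ",
         paste(AGE_GROUPS, collapse = ", "))
  for (p in c(cfg$sex_female_prob, cfg$covariate_prevalence,
              cfg$missing_age_fraction, cfg$alt_age_unit_fraction,
              cfg$event_dt_missing_fraction, cfg$ici_prevalence))
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("invalid configuration: probabilities must lie in [0,1]")
  codes <- as.character(cfg$smq_dictionary$smqs$smq_code)
  if (!all(names(cfg$baseline_event_logit) %in% codes))
    stop("invalid configuration: baseline_event_logit names must be dictionary smq_codes")
  planted <- cfg$planted_log_or
  if (nrow(planted)) {
    if (!all(planted$age_group %in% AGE_GROUPS))
      stop("invalid configuration: planted age_group must be one of ",
           paste(AGE_GROUPS, collapse = ", "))
    if (!all(planted$drug %in% names(cfg$drug_mix)))
      stop("invalid configuration: planted drug not in drug_mix")
    if (!all(as.character(planted$smq_code) %in% names(cfg$baseline_event_logit)))
      stop("invalid configuration: planted smq_code without a baseline logit")
  }
  invisible(cfg)
}

## Uniform age bounds per stratum (years); all generated ages lie in [18,100]
AGE_BOUNDS <- list(lt65 = c(18, 65), `65_74` = c(65, 75),
                   `75_84` = c(75, 85), ge85 = c(85, 100))

## co-medication exemplars drawn per covariate class; all resolve through the
## packaged lexicon
COMED_NAMES <- list(
  endocrine = c("LETROZOLE", "FEMARA", "Tamoxifen", "FULVESTRANT", "Anastrozole"),
  chemotherapy = c("CAPECITABINE", "Paclitaxel", "XELODA"),
  other_targeted = c("HERCEPTIN", "Everolimus", "TRASTUZUMAB"),
  immune_checkpoint = c("KEYTRUDA", "Atezolizumab"))

## background primary-suspect drugs deliberately absent from the lexicon
BACKGROUND_DRUGS <- c("METFORMIN", "LISINOPRIL", "ATORVASTATIN", "OMEPRAZOLE",
                      "ADALIMUMAB", "WARFARIN", "LEVOTHYROXINE", "RITUXIMAB")

#' Generate a synthetic FAERS-like bundle
#'
#' Draws `n_cases` unique cases, plants the configured reporting-odds
#' effects, and emits the six FAERS tables plus superseded report versions.
#' For a duplicated case the latest version (highest `FDA_DT`, ties broken by
#' `PRIMARYID`) carries the true content; superseded versions perturb the
#' reported age so that deduplication correctness is observable. The final
#' version of case `i` always has `PRIMARYID = 100*i + 5`, superseded
#' versions `100*i + 1`.
#'
#' @param config A [synthetic_config()].
#' @return A `faers_bundle`: list of `data.table`s `demo`, `drug`, `reac`,
#'   `ther`, `outc`, `indi`, with the generating `config` as an attribute.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_cases
  caseid <- seq_len(n)
  pid <- 100L * caseid + 5L
  exposure <- sample(names(config$drug_mix), n, TRUE, config$drug_mix)
  age_group <- sample(AGE_GROUPS, n, TRUE, config$age_group_probs)
  lo <- vapply(AGE_BOUNDS, `[`, numeric(1), 1)[age_group]
  hi <- vapply(AGE_BOUNDS, `[`, numeric(1), 2)[age_group]
  age_years <- floor(runif(n, lo, hi))
  sex <- ifelse(runif(n) < config$sex_female_prob, "F", "M")

  # demographics table (final versions)
  start_dt <- sample(seq(ymd_to_date(config$date_window[1]),
                         ymd_to_date(config$date_window[2]) - 30L, by = "day"),
                     n, TRUE)
  onset_days <- pmin(round(rlnorm(n, meanlog = log(73), sdlog = 1.1)), 2000L)
  event_date <- start_dt + onset_days
  fda_date <- pmin(event_date + sample(5:120, n, TRUE),
                   ymd_to_date(config$date_window[2]))
  event_dt <- date_to_ymd(event_date)
  event_dt[runif(n) < config$event_dt_missing_fraction] <- NA_integer_

  age_chr <- as.character(age_years)
  age_cod <- rep("YR", n)
  alt <- runif(n) < config$alt_age_unit_fraction
  alt_code <- sample(c("MON", "DY", "DEC"), sum(alt), TRUE)
  alt_val <- ifelse(alt_code == "MON", age_years[alt] * 12,
             ifelse(alt_code == "DY", age_years[alt] * 365.25,
                    age_years[alt] / 10))
  age_chr[alt] <- as.character(alt_val)
  age_cod[alt] <- alt_code
  miss <- runif(n) < config$missing_age_fraction
  age_chr[miss] <- NA_character_
  age_cod[miss] <- NA_character_

  demo <- data.table::data.table(
    PRIMARYID = pid, CASEID = caseid, FDA_DT = date_to_ymd(fda_date),
    EVENT_DT = event_dt, AGE = age_chr, AGE_COD = age_cod, SEX = sex)

  # primary-suspect drug rows; CDK4/6i names alternate brand/generic spellings
  ps_spellings <- list(
    palbociclib = c("IBRANCE", "PALBOCICLIB", "Palbociclib"),
    ribociclib = c("KISQALI", "RIBOCICLIB", "Ribociclib succinate"),
    abemaciclib = c("VERZENIO", "ABEMACICLIB", "Abemaciclib"))
  ps_name <- character(n)
  for (d in names(ps_spellings)) {
    idx <- which(exposure == d)
    ps_name[idx] <- sample(ps_spellings[[d]], length(idx), TRUE)
  }
  idx <- which(exposure == "other")
  ps_name[idx] <- sample(BACKGROUND_DRUGS, length(idx), TRUE)
  dechal <- sample(c("Y", "N", "D", "U"), n, TRUE, c(0.16, 0.07, 0.15, 0.62))
  drug <- data.table::data.table(
    PRIMARYID = pid, CASEID = caseid, DRUG_SEQ = 1L, ROLE_COD = ROLE_PS,
    DRUGNAME = ps_name, DECHAL = dechal)

  # co-medication rows (SS/C/I roles) per covariate flag
  comed_rows <- list()
  seq_counter <- rep(1L, n)
  for (cov in names(config$covariate_prevalence)) {
    flag <- runif(n) < config$covariate_prevalence[[cov]]
    idx <- which(flag)
    if (!length(idx)) next
    seq_counter[idx] <- seq_counter[idx] + 1L
    comed_rows[[cov]] <- data.table::data.table(
      PRIMARYID = pid[idx], CASEID = caseid[idx], DRUG_SEQ = seq_counter[idx],
      ROLE_COD = sample(ROLE_COADMIN, length(idx), TRUE),
      DRUGNAME = sample(COMED_NAMES[[cov]], length(idx), TRUE),
      DECHAL = NA_character_)
  }
  ici <- which(runif(n) < config$ici_prevalence)
  if (length(ici)) {
    seq_counter[ici] <- seq_counter[ici] + 1L
    comed_rows[["ici"]] <- data.table::data.table(
      PRIMARYID = pid[ici], CASEID = caseid[ici], DRUG_SEQ = seq_counter[ici],
      ROLE_COD = sample(ROLE_COADMIN, length(ici), TRUE),
      DRUGNAME = sample(COMED_NAMES$immune_checkpoint, length(ici), TRUE),
      DECHAL = NA_character_)
  }
  drug <- rbind(drug, data.table::rbindlist(comed_rows))

  # reactions: per-SMQ Bernoulli with planted logit shifts; every case also
  # reports one background PT outside any SMQ so REAC is never empty
  dict <- expand_smq_hierarchy(config$smq_dictionary)
  planted <- config$planted_log_or
  reac_rows <- list(data.table::data.table(
    PRIMARYID = pid, CASEID = caseid, PT = "Background reaction NOS"))
  smq_flags <- list()
  for (code_chr in names(config$baseline_event_logit)) {
    code <- as.integer(code_chr)
    logit <- rep(config$baseline_event_logit[[code_chr]], n)
    eff <- planted[smq_code == code]
    if (nrow(eff)) {
      m <- match(paste(exposure, age_group),
                 paste(eff$drug, eff$age_group))
      shift <- ifelse(is.na(m), 0, eff$log_or[m])
      logit <- logit + shift
    }
    flag <- runif(n) < plogis(logit)
    smq_flags[[code_chr]] <- flag
    idx <- which(flag)
    if (!length(idx)) next
    terms <- dict$terms[smq_code == code & scope == "narrow"]$pt_name
    if (!length(terms)) terms <- dict$terms[smq_code == code]$pt_name
    reac_rows[[code_chr]] <- data.table::data.table(
      PRIMARYID = pid[idx], CASEID = caseid[idx],
      PT = sample(terms, length(idx), TRUE))
  }
  reac <- data.table::rbindlist(reac_rows)
  data.table::setorder(reac, PRIMARYID, PT)

  ther <- data.table::data.table(
    PRIMARYID = pid, CASEID = caseid, DSG_DRUG_SEQ = 1L,
    START_DT = date_to_ymd(start_dt))

  # serious outcomes, independent draws per code
  outc_probs <- c(DE = 0.14, HO = 0.19, LT = 0.015, DS = 0.007, OT = 0.373)
  outc_rows <- lapply(names(outc_probs), function(code) {
    idx <- which(runif(n) < outc_probs[[code]])
    data.table::data.table(PRIMARYID = pid[idx], CASEID = caseid[idx],
                           OUTC_COD = code)
  })
  outc <- data.table::rbindlist(outc_rows)
  data.table::setorder(outc, PRIMARYID, OUTC_COD)

  indi <- data.table::data.table(
    PRIMARYID = pid, CASEID = caseid, INDI_DRUG_SEQ = 1L,
    INDI_PT = ifelse(exposure == "other", "Product used for unknown indication",
                     "Breast cancer"))

  # superseded versions: same CASEID, earlier (or tied) FDA_DT, lower
  # PRIMARYID, perturbed age
  n_dup <- round(config$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_case <- sort(sample.int(n, n_dup))
    dup_pid <- 100L * dup_case + 1L
    tie <- runif(n_dup) < 0.3
    dup_fda <- demo$FDA_DT[dup_case]
    earlier <- date_to_ymd(ymd_to_date(dup_fda[!tie]) -
                             sample(30:400, sum(!tie), TRUE))
    dup_fda[!tie] <- pmax(earlier, config$date_window[1])
    dup_demo <- demo[dup_case]
    dup_demo[, `:=`(PRIMARYID = dup_pid, FDA_DT = dup_fda,
                    AGE = ifelse(is.na(AGE), AGE, as.character(
                      suppressWarnings(as.numeric(AGE)) + 1)))]
    demo <- rbind(demo, dup_demo)
    drug <- rbind(drug, data.table::data.table(
      PRIMARYID = dup_pid, CASEID = dup_case, DRUG_SEQ = 1L,
      ROLE_COD = ROLE_PS, DRUGNAME = ps_name[dup_case],
      DECHAL = dechal[dup_case]))
    reac <- rbind(reac, data.table::data.table(
      PRIMARYID = dup_pid, CASEID = dup_case, PT = "Background reaction NOS"))
    indi <- rbind(indi, data.table::data.table(
      PRIMARYID = dup_pid, CASEID = dup_case, INDI_DRUG_SEQ = 1L,
      INDI_PT = indi$INDI_PT[dup_case]))
  }

  for (tab in list(demo, drug, reac, ther, outc, indi))
    data.table::setorder(tab, PRIMARYID)
  data.table::setorder(drug, PRIMARYID, DRUG_SEQ)

  bundle <- structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                           outc = outc, indi = indi),
                      class = "faers_bundle")
  attr(bundle, "config") <- config
  attr(bundle, "truth") <- data.table::data.table(
    caseid = caseid, exposure = exposure, age_group = age_group,
    age_years = age_years, sex = sex,
    data.table::as.data.table(smq_flags))
  bundle
}

#' Ground-truth reporting odds ratios of a synthetic configuration
#'
#' Returns the planted odds ratio `exp(log_or)` for every
#' (drug, SMQ, age-group) triple over the exposure drugs (every `drug_mix`
#' entry except the `other` background pool), with 1.0 for unplanted triples.
#' Used as the recovery oracle for the screening and regression stages.
#'
#' @param config A [synthetic_config()].
#' @return `data.table` with columns `drug`, `smq_code`, `age_group`,
#'   `true_or`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  drugs <- setdiff(names(config$drug_mix), "other")
  grid <- data.table::CJ(drug = drugs,
                         smq_code = config$smq_dictionary$smqs$smq_code,
                         age_group = AGE_GROUPS)
  out <- merge(grid, config$planted_log_or,
               by = c("drug", "smq_code", "age_group"), all.x = TRUE)
  out[, true_or := exp(data.table::fifelse(is.na(log_or), 0, log_or))]
  out[, log_or := NULL]
  data.table::setorder(out, drug, smq_code, age_group)
  out[]
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("FAERS-style bundle:\n")
  for (nm in names(x))
    cat(sprintf("  %-5s %8d rows\n", toupper(nm), nrow(x[[nm]])))
  invisible(x)
}
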