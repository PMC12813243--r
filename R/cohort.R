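#' Assign the four age strata
#'
#' Strata: `[18,65)` -> `lt65`, `[65,75)` -> `65_74`, `[75,85)` -> `75_84`,
#' `[85,100]` -> `ge85`.
#'
#' @param age_years Numeric vector, each value in `[18, 100]`.
#' @return Character vector of stratum labels.
#' @export
assign_age_group <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 18) || any(age_years > 100))
    stop("age_years must lie in [18, 100]")
  AGE_GROUPS[findInterval(age_years, c(65, 75, 85)) + 1L]
}

#' Default indication patterns identifying breast cancer
#'
#' Case-insensitive substrings matched against `INDI_PT`. An editable
#' stand-in for a full preferred-term list.
#' @export
default_indication_patterns <- function() {
  c("breast cancer", "breast neoplasm", "breast carcinoma")
}

#' Build the analysis cohort
#'
#' Applies, in order, the selection filters: female sex; at least one
#' primary-suspect (PS) drug normalizing to a CDK4/6 inhibitor; a single
#' distinct CDK4/6i among the PS rows (two or more is `ambiguous_exposure`);
#' a breast-cancer indication (matched against the PS drug's own INDI rows
#' when linked via `DRUG_SEQ`/`INDI_DRUG_SEQ`, else any indication row on the
#' case); age present and within `[18, 100]` years; `FDA_DT` inside
#' `date_window`. The first failing filter determines the exclusion reason.
#'
#' @param bundle A deduplicated `faers_bundle` (see [dedup_bundle()]).
#' @param lexicon A `drug_lexicon`.
#' @param indication_pts Character vector of case-insensitive substrings
#'   defining the qualifying indication; must be nonempty.
#' @param date_window Integer `c(from, to)` as `YYYYMMDD`.
#' @return List with `cases` (one `data.table` row per retained case:
#'   `primaryid`, `caseid`, `age_years`, `age_group`, `sex`,
#'   `exposure_drug`, covariate flags, `dechal`, `outcome_codes`,
#'   `time_to_onset_days`) and `exclusions` (named counts by reason; reasons
#'   plus retained sum to the input count).
#' @export
build_cohort <- function(bundle, lexicon,
                         indication_pts = default_indication_patterns(),
                         date_window = c(20150101L, 20250331L)) {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (length(indication_pts) == 0)
    stop("indication_pts must be a nonempty set of patterns")
  demo <- data.table::as.data.table(bundle$demo)
  drug <- data.table::as.data.table(bundle$drug)
  n_in <- nrow(demo)

  drug[, canon := normalize_drug_name(DRUGNAME, lexicon)]
  ps <- drug[ROLE_COD == ROLE_PS]
  ps_cdk <- ps[drug_in_class(canon, lexicon, "cdk46i")]
  cdk_per_case <- ps_cdk[, .(n_cdk = data.table::uniqueN(canon),
                             exposure_drug = canon[1L],
                             ps_seq = DRUG_SEQ[1L],
                             dechal = DECHAL[1L]), by = PRIMARYID]

  cases <- demo[, .(PRIMARYID, CASEID, FDA_DT, EVENT_DT, AGE, AGE_COD, SEX)]
  cases <- merge(cases, cdk_per_case, by = "PRIMARYID", all.x = TRUE)
  cases[, age_years := normalize_age(AGE, AGE_COD)]

  # indication: PS-drug-linked INDI rows when present, else any on the case
  indi <- data.table::as.data.table(bundle$indi)
  pat <- paste(sapply(tolower(indication_pts), function(p)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)), collapse = "|")
  indi[, hit := grepl(pat, tolower(INDI_PT))]
  linked <- merge(cases[!is.na(exposure_drug), .(PRIMARYID, ps_seq)],
                  indi, by.x = c("PRIMARYID", "ps_seq"),
                  by.y = c("PRIMARYID", "INDI_DRUG_SEQ"))
  linked_ok <- linked[, .(ok = any(hit), linked = TRUE), by = PRIMARYID]
  any_ok <- indi[, .(ok_any = any(hit)), by = PRIMARYID]
  cases <- merge(cases, linked_ok, by = "PRIMARYID", all.x = TRUE)
  cases <- merge(cases, any_ok, by = "PRIMARYID", all.x = TRUE)
  cases[, indication_ok := data.table::fifelse(
    !is.na(linked), ok, data.table::fifelse(!is.na(ok_any), ok_any, FALSE))]

  # sequential exclusion tally: first failing reason wins
  reason <- rep(NA_character_, nrow(cases))
  fail <- function(cond, label) {
    idx <- which(is.na(reason) & cond)
    reason[idx] <<- label
  }
  fail(is.na(cases$SEX) | cases$SEX != "F", "sex")
  fail(is.na(cases$exposure_drug), "role")
  fail(!is.na(cases$n_cdk) & cases$n_cdk > 1L, "ambiguous_exposure")
  fail(!cases$indication_ok, "indication")
  fail(is.na(cases$age_years) | cases$age_years < 18 | cases$age_years > 100,
       "age")
  fail(is.na(cases$FDA_DT) | cases$FDA_DT < date_window[1] |
         cases$FDA_DT > date_window[2], "date")
  retained <- cases[is.na(reason)]

  cov <- derive_covariates_all(drug[PRIMARYID %in% retained$PRIMARYID], lexicon)
  retained <- merge(retained, cov, by = "PRIMARYID", all.x = TRUE)
  for (col in c("endocrine", "chemotherapy", "other_targeted",
                "immune_checkpoint"))
    retained[is.na(get(col)), (col) := FALSE]

  outc <- data.table::as.data.table(bundle$outc)
  oc <- outc[PRIMARYID %in% retained$PRIMARYID,
             .(outcome_codes = paste(sort(unique(OUTC_COD)), collapse = ",")),
             by = PRIMARYID]
  retained <- merge(retained, oc, by = "PRIMARYID", all.x = TRUE)
  retained[is.na(outcome_codes), outcome_codes := ""]

  # time to onset: EVENT_DT minus earliest THER start of the PS drug, days
  ther <- data.table::as.data.table(bundle$ther)
  st <- merge(retained[, .(PRIMARYID, ps_seq)], ther,
              by.x = c("PRIMARYID", "ps_seq"),
              by.y = c("PRIMARYID", "DSG_DRUG_SEQ"))
  st <- st[!is.na(START_DT)]
  st <- if (nrow(st)) st[, .(start_dt = min(START_DT)), by = PRIMARYID]
        else data.table::data.table(PRIMARYID = integer(),
                                    start_dt = integer())
  retained <- merge(retained, st, by = "PRIMARYID", all.x = TRUE)
  retained[, time_to_onset_days := as.integer(
    ymd_to_date(EVENT_DT) - ymd_to_date(start_dt))]
  retained[!is.na(time_to_onset_days) & time_to_onset_days < 0,
           time_to_onset_days := NA_integer_]

  out <- retained[, .(primaryid = PRIMARYID, caseid = CASEID,
                      age_years, age_group = assign_age_group(age_years),
                      sex = SEX, exposure_drug, endocrine, chemotherapy,
                      other_targeted, immune_checkpoint, dechal,
                      outcome_codes, time_to_onset_days)]
  data.table::setorder(out, primaryid)
  tally <- table(factor(reason, levels = c("sex", "role",
                                           "ambiguous_exposure", "indication",
                                           "age", "date")))
  exclusions <- c(as.list(tally), retained = nrow(out), input = n_in)
  stopifnot(sum(tally) + nrow(out) == n_in)
  list(cases = out, exclusions = exclusions)
}

# vectorized covariate derivation over all cases' co-administered rows
derive_covariates_all <- function(drug, lexicon) {
  co <- drug[ROLE_COD %in% ROLE_COADMIN]
  if (!"canon" %in% names(co))
    co[, canon := normalize_drug_name(DRUGNAME, lexicon)]
  co[, .(endocrine = any(drug_in_class(canon, lexicon, "endocrine")),
         chemotherapy = any(drug_in_class(canon, lexicon, "chemotherapy")),
         other_targeted = any(drug_in_class(canon, lexicon, "other_targeted")),
         immune_checkpoint = any(drug_in_class(canon, lexicon,
                                               "immune_checkpoint"))),
     by = PRIMARYID]
}

#' Derive co-medication covariate flags for one case
#'
#' A flag is set when at least one drug row with a co-administration role
#' (secondary suspect, concomitant, interacting) normalizes into the
#' corresponding lexicon class. Primary-suspect rows never set covariates.
#'
#' @param drug_rows DRUG rows belonging to one case.
#' @param lexicon A `drug_lexicon`.
#' @return Named logical vector `endocrine`, `chemotherapy`,
#'   `other_targeted`, `immune_checkpoint`.
#' @export
derive_covariates <- function(drug_rows, lexicon) {
  drug_rows <- data.table::as.data.table(drug_rows)
  co <- drug_rows[ROLE_COD %in% ROLE_COADMIN]
  canon <- normalize_drug_name(co$DRUGNAME, lexicon)
  c(endocrine = any(drug_in_class(canon, lexicon, "endocrine")),
    chemotherapy = any(drug_in_class(canon, lexicon, "chemotherapy")),
    other_targeted = any(drug_in_class(canon, lexicon, "other_targeted")),
    immune_checkpoint = any(drug_in_class(canon, lexicon, "immune_checkpoint")))
}

#' Descriptive cohort summary
#'
#' Per exposure drug and overall: case count, median/IQR age, age-group
#' counts and percentages, co-medication counts, median/IQR time to onset,
#' dechallenge categories (applied = positive or negative; positive `Y`,
#' negative `N`, not applied `D`, unknown `U` or blank), and outcome
#' categories (death `DE`, hospitalization `HO`, life-threatening `LT`,
#' disability `DS`, other serious `OT`, any serious). Quantiles use linear
#' interpolation (default type 7).
#'
#' @param cases The `cases` table from [build_cohort()].
#' @return Long-format `data.table` with columns `drug`, `metric`, `value`.
#'   An empty cohort yields a zero-row table.
#' @export
summarize_cohort <- function(cases) {
  cases <- data.table::as.data.table(cases)
  if (nrow(cases) == 0)
    return(data.table::data.table(drug = character(), metric = character(),
                                  value = numeric()))
  one <- function(sub, label) {
    n <- nrow(sub)
    q_age <- quantile(sub$age_years, c(0.25, 0.5, 0.75), names = FALSE)
    tto <- sub$time_to_onset_days[!is.na(sub$time_to_onset_days)]
    q_tto <- if (length(tto)) quantile(tto, c(0.25, 0.5, 0.75), names = FALSE)
             else rep(NA_real_, 3)
    grp <- table(factor(sub$age_group, levels = AGE_GROUPS))
    dech <- toupper(ifelse(is.na(sub$dechal), "U", sub$dechal))
    oc <- strsplit(sub$outcome_codes, ",", fixed = TRUE)
    has <- function(code) sum(vapply(oc, function(x) code %in% x, logical(1)))
    any_serious <- sum(vapply(oc, function(x) length(x) > 0, logical(1)))
    vals <- c(n = n,
              age_median = q_age[2], age_q1 = q_age[1], age_q3 = q_age[3],
              setNames(as.numeric(grp), paste0("n_", AGE_GROUPS)),
              setNames(as.numeric(grp) / n * 100, paste0("pct_", AGE_GROUPS)),
              n_endocrine = sum(sub$endocrine),
              n_chemotherapy = sum(sub$chemotherapy),
              n_other_targeted = sum(sub$other_targeted),
              n_immune_checkpoint = sum(sub$immune_checkpoint),
              tto_median = q_tto[2], tto_q1 = q_tto[1], tto_q3 = q_tto[3],
              dechal_applied = sum(dech %in% c("Y", "N")),
              dechal_positive = sum(dech == "Y"),
              dechal_negative = sum(dech == "N"),
              dechal_not_applied = sum(dech == "D"),
              dechal_unknown = sum(!dech %in% c("Y", "N", "D")),
              pct_dechal_unknown = sum(!dech %in% c("Y", "N", "D")) / n * 100,
              outcome_death = has("DE"),
              outcome_hospitalization = has("HO"),
              outcome_life_threatening = has("LT"),
              outcome_disability = has("DS"),
              outcome_other_serious = has("OT"),
              outcome_any_serious = any_serious,
              pct_outcome_death = has("DE") / n * 100)
    data.table::data.table(drug = label, metric = names(vals),
                           value = unname(vals))
  }
  parts <- lapply(sort(unique(cases$exposure_drug)), function(d)
    one(cases[exposure_drug == d], d))
  out <- data.table::rbindlist(c(parts, list(one(cases, "all"))))
  out[]
}
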