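#' Build a 2x2 exposure-by-event contingency table from id sets
#'
#' @param exposed_event_ids Ids of exposed reports with the event.
#' @param exposed_ids Ids of all exposed reports; must be a subset of
#'   `universe_ids`.
#' @param universe_event_ids Ids of all reports with the event (any
#'   exposure).
#' @param universe_ids Ids of all reports in the comparator universe.
#' @return Object of class `contingency`: list with integer cells `a`
#'   (exposed with event), `b` (exposed without), `c` (comparator with),
#'   `d` (comparator without). A degenerate empty comparator (`c = d = 0`)
#'   is allowed here and rejected by [ror_wald()].
#' @export
make_contingency <- function(exposed_event_ids, exposed_ids,
                             universe_event_ids, universe_ids) {
  exposed_ids <- unique(exposed_ids)
  universe_ids <- unique(universe_ids)
  if (length(setdiff(exposed_ids, universe_ids)))
    stop("exposed_ids must be a subset of universe_ids")
  exposed_event <- intersect(unique(exposed_event_ids), exposed_ids)
  universe_event <- intersect(unique(universe_event_ids), universe_ids)
  a <- length(exposed_event)
  b <- length(exposed_ids) - a
  c_ <- length(setdiff(universe_event, exposed_ids))
  d <- length(universe_ids) - length(exposed_ids) - c_
  new_contingency(a, b, c_, d)
}

#' @rdname make_contingency
#' @param a,b,c,d Nonnegative integer cell counts.
#' @export
new_contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be nonnegative integers")
  structure(as.list(cells), class = "contingency")
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a*d)/(b*c)` with
#' `CI = exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any raw cell
#' is zero, the Haldane-Anscombe correction adds 0.5 to all four cells
#' before computation and the result is flagged `corrected`.
#'
#' @param table A `contingency` (or list with `a`,`b`,`c`,`d`).
#' @param alpha Two-sided type-I level for the interval (default 0.05).
#' @return List: `ror`, `ci_low`, `ci_high`, `se_log` (SE of log ROR),
#'   `p_value` (two-sided Wald test of ROR = 1), `corrected`.
#' @export
ror_wald <- function(table, alpha = 0.05) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (a + b == 0 || c_ + d == 0)
    stop("undefined table: an exposure margin is empty")
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  z <- qnorm(1 - alpha / 2)
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  lr <- log(ror)
  list(ror = ror,
       ci_low = exp(lr - z * se),
       ci_high = exp(lr + z * se),
       se_log = se,
       p_value = 2 * pnorm(-abs(lr) / se),
       corrected = corrected)
}

# positive disproportionality: lower CI bound strictly above 1
signal_flag <- function(ci_low) !is.na(ci_low) & ci_low > 1

#' Screen all drug-by-SMQ pairs for disproportionality signals
#'
#' For each exposure drug in the cohort and each SMQ, builds the 2x2 table
#' of exposure against event over the comparator universe and computes the
#' ROR. A pair is a signal when the lower 95% bound exceeds 1 (strictly).
#' Pairs with fewer than `min_case_count` exposed events are reported with
#' status `"insufficient"` and no estimate. A Benjamini-Hochberg adjusted
#' p-value column is included for convenience; the signal rule itself is
#' unadjusted.
#'
#' @param cohort The `cases` table from [build_cohort()] (columns
#'   `primaryid`, `exposure_drug`).
#' @param universe_ids `PRIMARYID`s of all deduplicated reports forming the
#'   comparator universe. With `comparator = "rest_of_database"` (default)
#'   each drug is contrasted with every universe report not in its cohort;
#'   `"within_cohort"` restricts the universe to the cohort itself
#'   (within-indication comparison).
#' @param case_smqs (`PRIMARYID`, `smq_code`) pairs from [map_case_smqs()],
#'   covering the whole universe.
#' @param dict Optional `smq_dictionary` used to attach SMQ names.
#' @param min_case_count Minimum exposed-with-event count to evaluate a pair.
#' @param alpha Two-sided level for the Wald interval.
#' @param comparator Comparator construction (see above).
#' @return `data.table` with one row per drug-SMQ pair: counts, `ror`,
#'   `ci_low`, `ci_high`, `is_signal`, `corrected`, `frequency` (exposed
#'   events / exposed cases), `p_value`, `p_bh`, `status`.
#' @export
screen_signals <- function(cohort, universe_ids, case_smqs, dict = NULL,
                           min_case_count = 3L, alpha = 0.05,
                           comparator = c("rest_of_database",
                                          "within_cohort")) {
  comparator <- match.arg(comparator)
  cohort <- data.table::as.data.table(cohort)
  case_smqs <- data.table::as.data.table(case_smqs)
  if (comparator == "within_cohort") universe_ids <- cohort$primaryid
  universe_ids <- unique(universe_ids)
  n_universe <- length(universe_ids)
  case_smqs <- case_smqs[PRIMARYID %in% universe_ids]
  smq_codes <- sort(unique(case_smqs$smq_code))
  if (!is.null(dict))
    smq_codes <- sort(unique(c(smq_codes, dict$smqs$smq_code)))
  event_totals <- case_smqs[, .N, by = smq_code]

  rows <- list()
  for (dg in sort(unique(cohort$exposure_drug))) {
    exposed <- cohort[exposure_drug == dg]$primaryid
    exposed <- intersect(exposed, universe_ids)
    n_exposed <- length(exposed)
    a_counts <- case_smqs[PRIMARYID %in% exposed, .(a = .N), by = smq_code]
    for (s in smq_codes) {
      a <- a_counts[smq_code == s]$a
      a <- if (length(a)) a else 0L
      total_event <- event_totals[smq_code == s]$N
      total_event <- if (length(total_event)) total_event else 0L
      b <- n_exposed - a
      c_ <- total_event - a
      d_ <- n_universe - n_exposed - c_
      freq <- if (n_exposed > 0) a / n_exposed else NA_real_
      if (a < min_case_count) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          drug = dg, smq_code = s, a = a, b = b, c = c_, d = d_,
          ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          is_signal = FALSE, corrected = NA, frequency = freq,
          p_value = NA_real_, status = "insufficient")
        next
      }
      est <- ror_wald(new_contingency(a, b, c_, d_), alpha = alpha)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        drug = dg, smq_code = s, a = a, b = b, c = c_, d = d_,
        ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
        is_signal = signal_flag(est$ci_low), corrected = est$corrected,
        frequency = freq, p_value = est$p_value, status = "ok")
    }
  }
  out <- data.table::rbindlist(rows)
  out[, p_bh := NA_real_]
  out[status == "ok", p_bh := p.adjust(p_value, method = "BH")]
  if (!is.null(dict))
    out <- merge(out, dict$smqs[, .(smq_code, smq_name)], by = "smq_code",
                 all.x = TRUE, sort = FALSE)
  data.table::setorder(out, drug, smq_code)
  out[]
}

#' Per-drug SMQ reporting frequencies
#'
#' Frequency = flagged cases / cases on the drug. Rows at or below
#' `min_freq` are excluded from the display subset (strict `>`), but the
#' full table is returned with a `display` flag so nothing is lost on
#' export.
#'
#' @param cohort The `cases` table from [build_cohort()].
#' @param case_smqs (`PRIMARYID`, `smq_code`) pairs from [map_case_smqs()].
#' @param min_freq Display threshold as a proportion (default 0.05).
#' @param dict Optional `smq_dictionary` for names.
#' @return `data.table`: `drug`, `smq_code`, `n_cases`, `n_flagged`,
#'   `frequency` (percent), `display`.
#' @export
frequency_table <- function(cohort, case_smqs, min_freq = 0.05, dict = NULL) {
  cohort <- data.table::as.data.table(cohort)
  if (nrow(cohort) == 0) stop("cohort is empty")
  case_smqs <- data.table::as.data.table(case_smqs)
  smq_codes <- sort(unique(case_smqs$smq_code))
  if (!is.null(dict)) smq_codes <- sort(unique(c(smq_codes, dict$smqs$smq_code)))
  drugs <- sort(unique(cohort$exposure_drug))
  grid <- data.table::CJ(drug = drugs, smq_code = smq_codes)
  sizes <- cohort[, .(n_cases = .N), by = .(drug = exposure_drug)]
  flagged <- merge(cohort[, .(PRIMARYID = primaryid, drug = exposure_drug)],
                   case_smqs, by = "PRIMARYID")[
    , .(n_flagged = .N), by = .(drug, smq_code)]
  out <- merge(grid, sizes, by = "drug")
  out <- merge(out, flagged, by = c("drug", "smq_code"), all.x = TRUE)
  out[is.na(n_flagged), n_flagged := 0L]
  out[, frequency := n_flagged / n_cases * 100]
  out[, display := n_flagged / n_cases > min_freq]
  if (!is.null(dict))
    out <- merge(out, dict$smqs[, .(smq_code, smq_name)], by = "smq_code",
                 all.x = TRUE, sort = FALSE)
  data.table::setorder(out, drug, -frequency)
  out[]
}
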