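#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood. Convergence is declared when the
#' maximum absolute score component falls below `tol` or the relative change
#' in log-likelihood falls below `tol`, within `max_iter` iterations.
#' Constant and collinear columns are dropped (recorded in `dropped`)
#' before fitting. Complete or quasi-complete separation — a coefficient
#' exceeding `coef_cap` on the log-odds scale while the gradient has not
#' vanished — yields a result flagged `separation = TRUE` and
#' `converged = FALSE`, never a silent estimate.
#'
#' @param x Numeric design matrix including an intercept column.
#' @param y Binary (0/1 or logical) response.
#' @param tol Convergence tolerance (default `1e-8`).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param coef_cap Separation threshold on |coefficient| (default 15).
#' @return Object of class `logit_fit`: `coefficients`, `vcov`, `table`
#'   (per-term `estimate`, `se`, `aor = exp(estimate)`, Wald `ci_low`,
#'   `ci_high`, `p_value`), `loglik`, `n`, `n_events`, `iterations`,
#'   `converged`, `separation`, `dropped`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L, coef_cap = 15) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))

  # drop rank-deficient columns (constants collinear with the intercept too)
  qx <- qr(x)
  dropped <- character(0)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(x)[-keep]
    x <- x[, sort(keep), drop = FALSE]
  }
  p <- ncol(x)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  separation <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(x, y - mu))
    ll <- bernoulli_loglik(y, eta)
    if (max(abs(score)) < tol ||
        (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol))) {
      converged <- TRUE
      break
    }
    if (any(abs(beta) > coef_cap) && max(abs(score)) > 1e-4) {
      separation <- TRUE
      break
    }
    if (it > max_iter) break
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- qr(x * sw)
    beta <- drop(qr.coef(fit, z * sw))
    ll_old <- ll
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  xtwx <- crossprod(x * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(xtwx)), error = function(e)
    matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vcov))
  zval <- beta / se
  zc <- qnorm(0.975)
  tab <- data.table::data.table(
    term = colnames(x), estimate = beta, se = se, aor = exp(beta),
    ci_low = exp(beta - zc * se), ci_high = exp(beta + zc * se),
    p_value = 2 * pnorm(-abs(zval)))
  structure(list(coefficients = setNames(beta, colnames(x)), vcov = vcov,
                 table = tab, loglik = bernoulli_loglik(y, eta),
                 n = length(y), n_events = sum(y), iterations = it,
                 converged = converged && !separation,
                 separation = separation, dropped = dropped),
            class = "logit_fit")
}

# numerically stable sum of y*eta - log(1 + exp(eta))
bernoulli_loglik <- function(y, eta) {
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, events = %d, iterations = %d, %s\n",
              x$n, x$n_events, x$iterations,
              if (x$separation) "SEPARATION DETECTED"
              else if (x$converged) "converged" else "NOT converged"))
  print(x$table)
  if (length(x$dropped))
    cat("dropped columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# age-group dummy design with lt65 as reference; covariates appended
build_design <- function(cases, covariates = character(0)) {
  g <- factor(cases$age_group, levels = AGE_GROUPS)
  x <- cbind(`(Intercept)` = 1,
             age_65_74 = as.numeric(g == "65_74"),
             age_75_84 = as.numeric(g == "75_84"),
             age_ge85 = as.numeric(g == "ge85"))
  for (cv in covariates)
    x <- cbind(x, as.numeric(cases[[cv]]))
  colnames(x) <- c("(Intercept)", "age_65_74", "age_75_84", "age_ge85",
                   covariates)
  x
}

# strict selection rule: retained iff p < alpha
select_rule <- function(p, alpha = 0.05) !is.na(p) & p < alpha

#' Univariate covariate screen for one outcome
#'
#' Each co-medication covariate is fitted alone against the outcome and
#' retained when its two-sided Wald p-value is strictly below `alpha`. The
#' age-category block (three dummies, reference `lt65`) is tested jointly by
#' likelihood ratio (`age_test = "block"`, default) or term-wise Wald
#' (`"dummy"`, retained if any dummy passes) — and is always selected
#' regardless of its p-value, since age is in every model by design.
#'
#' @param cases Cohort subset (one drug) with `age_group` and covariate
#'   columns.
#' @param outcome Logical/0-1 vector: case flagged for the SMQ under study.
#' @param covariates Covariate column names (default the three co-medication
#'   flags).
#' @param alpha Selection threshold (default 0.05, strict).
#' @param age_test `"block"` or `"dummy"` (see above).
#' @return `data.table`: `term`, `p_value`, `selected`, `test`.
#' @export
univariate_screen <- function(cases, outcome,
                              covariates = c("endocrine", "chemotherapy",
                                             "other_targeted"),
                              alpha = 0.05,
                              age_test = c("block", "dummy")) {
  age_test <- match.arg(age_test)
  cases <- data.table::as.data.table(cases)
  y <- as.numeric(outcome)
  stopifnot(nrow(cases) == length(y))

  rows <- list()
  for (cv in covariates) {
    x <- cbind(`(Intercept)` = 1, as.numeric(cases[[cv]]))
    colnames(x)[2] <- cv
    p <- tryCatch({
      f <- fit_logistic(x, y)
      if (cv %in% f$dropped || !f$converged) NA_real_
      else f$table[term == cv]$p_value
    }, error = function(e) NA_real_)
    rows[[cv]] <- data.table::data.table(
      term = cv, p_value = p, selected = select_rule(p, alpha),
      test = "wald")
  }

  x_age <- build_design(cases)
  p_age <- tryCatch({
    full <- fit_logistic(x_age, y)
    if (age_test == "block") {
      null <- fit_logistic(x_age[, "(Intercept)", drop = FALSE], y)
      df <- 3L - sum(startsWith(full$dropped, "age_"))
      if (df <= 0) NA_real_
      else pchisq(2 * (full$loglik - null$loglik), df = df,
                  lower.tail = FALSE)
    } else {
      min(full$table[startsWith(term, "age_")]$p_value)
    }
  }, error = function(e) NA_real_)
  rows[["age"]] <- data.table::data.table(
    term = "age_group", p_value = p_age, selected = TRUE,
    test = if (age_test == "block") "lrt" else "wald")
  data.table::rbindlist(rows)[]
}

#' Multivariate cascade: adjusted odds ratios per age group
#'
#' For every drug-SMQ pair flagged by the disproportionality screen, the
#' cascade (i) skips the pair when the drug's cohort holds fewer than
#' `min_events` flagged cases — the sparse-data safeguard of at least ten
#' outcome events per modelled variable with six variables; (ii) runs the
#' univariate screen; (iii) fits the multivariate model on the selected
#' covariates plus the age block; and (iv) reports the adjusted odds ratio,
#' 95% CI and p-value of each geriatric age group against the `lt65`
#' reference.
#'
#' @param cohort The `cases` table from [build_cohort()].
#' @param signals Either a [screen_signals()] result (its `is_signal` rows
#'   are used) or a `data.table` of (`drug`, `smq_code`) pairs to model.
#' @param case_smqs (`PRIMARYID`, `smq_code`) pairs from [map_case_smqs()].
#' @param min_events Minimum flagged cases within the drug cohort
#'   (default 60).
#' @param alpha Univariate selection threshold.
#' @param age_test Passed to [univariate_screen()].
#' @param dict Optional `smq_dictionary` for names.
#' @return `data.table` with one row per drug, SMQ and geriatric age group:
#'   `aor`, `ci_low`, `ci_high`, `p_value`, `n_events`, `n`, `status`
#'   (`"ok"`, `"min_events"`, `"not_converged"`, or `"dropped"` when a
#'   stratum is empty), and `covariates_adjusted`.
#' @export
multivariate_cascade <- function(cohort, signals, case_smqs,
                                 min_events = 60L, alpha = 0.05,
                                 age_test = "block", dict = NULL) {
  cohort <- data.table::as.data.table(cohort)
  case_smqs <- data.table::as.data.table(case_smqs)
  signals <- data.table::as.data.table(signals)
  pairs <- if ("is_signal" %in% names(signals))
    signals[is_signal == TRUE, .(drug, smq_code)]
  else unique(signals[, .(drug, smq_code)])

  age_terms <- c(`65_74` = "age_65_74", `75_84` = "age_75_84",
                 ge85 = "age_ge85")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    dg <- pairs$drug[i]
    s <- pairs$smq_code[i]
    sub <- cohort[exposure_drug == dg]
    flagged_ids <- case_smqs[smq_code == s]$PRIMARYID
    y <- as.numeric(sub$primaryid %in% flagged_ids)
    n_ev <- sum(y)
    base <- data.table::data.table(
      drug = dg, smq_code = s, age_group = names(age_terms),
      aor = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, n_events = n_ev, n = nrow(sub))
    if (n_ev < min_events) {
      base[, `:=`(status = "min_events", covariates_adjusted = "")]
      rows[[i]] <- base
      next
    }
    uni <- univariate_screen(sub, y, alpha = alpha, age_test = age_test)
    sel <- uni[selected == TRUE & term != "age_group"]$term
    fit <- fit_logistic(build_design(sub, sel), y)
    fit_status <- if (fit$separation) "separation"
                  else if (!fit$converged) "not_converged" else "ok"
    tab <- fit$table
    for (j in seq_along(age_terms)) {
      trm <- age_terms[j]
      if (trm %in% tab$term) {
        r <- tab[term == trm]
        base[j, `:=`(aor = r$aor, ci_low = r$ci_low, ci_high = r$ci_high,
                     p_value = r$p_value, status = fit_status)]
      } else {
        base[j, status := "dropped"]
      }
    }
    base[, covariates_adjusted := paste(sel, collapse = ",")]
    rows[[i]] <- base
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0)
    return(data.table::data.table(
      drug = character(), smq_code = integer(), age_group = character(),
      aor = numeric(), ci_low = numeric(), ci_high = numeric(),
      p_value = numeric(), n_events = integer(), n = integer(),
      status = character(), covariates_adjusted = character()))
  if (!is.null(dict))
    out <- merge(out, dict$smqs[, .(smq_code, smq_name)], by = "smq_code",
                 all.x = TRUE, sort = FALSE)
  data.table::setorder(out, drug, smq_code, age_group)
  out[]
}
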