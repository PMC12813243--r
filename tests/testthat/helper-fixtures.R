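# Shared fixtures and independent oracles, all built in code at test time.

library(data.table)

# --- deduplication fixture -------------------------------------------------
# 700 unique cases, 300 of them with one planted superseded version
# (mixed cases: earlier FDA_DT, tied FDA_DT with lower PRIMARYID, missing
# FDA_DT). The survivor of case i always has PRIMARYID = 1000*i + 500.
make_dedup_fixture <- function(seed = 123) {
  set.seed(seed)
  n_cases <- 700L
  n_dup <- 300L
  caseid <- seq_len(n_cases)
  fda <- sample(20150101:20250331, n_cases, replace = TRUE)
  survivors <- data.table(CASEID = caseid, FDA_DT = fda,
                          PRIMARYID = 1000L * caseid + 500L)
  dup_case <- sort(sample(n_cases, n_dup))
  kind <- rep_len(c("earlier", "tie", "missing"), n_dup)
  dup_fda <- fda[dup_case] - sample(1:5000, n_dup, replace = TRUE)
  dup_fda[kind == "tie"] <- fda[dup_case][kind == "tie"]
  dup_fda[kind == "missing"] <- NA_integer_
  superseded <- data.table(CASEID = dup_case, FDA_DT = dup_fda,
                           PRIMARYID = 1000L * dup_case +
                             sample(1:499, n_dup, replace = TRUE))
  rows <- rbind(survivors, superseded)
  rows[sample(nrow(rows))]  # shuffled row order
}

# --- minimal hand-built bundle ---------------------------------------------
empty_faers_table <- function(name) {
  schema <- faersage:::FAERS_SCHEMAS[[name]]
  out <- data.table::as.data.table(
    sapply(schema$cols, function(x) character(0), simplify = FALSE))
  for (col in schema$int) out[[col]] <- integer(0)
  out
}

mini_bundle <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL,
                        outc = NULL, indi = NULL) {
  fill <- function(x, name) {
    if (is.null(x)) return(empty_faers_table(name))
    x <- data.table::as.data.table(x)
    tmpl <- empty_faers_table(name)
    for (col in setdiff(names(tmpl), names(x)))
      x[[col]] <- tmpl[[col]][rep(NA_integer_, nrow(x))]
    x[, names(tmpl), with = FALSE]
  }
  structure(list(demo = fill(demo, "DEMO"), drug = fill(drug, "DRUG"),
                 reac = fill(reac, "REAC"), ther = fill(ther, "THER"),
                 outc = fill(outc, "OUTC"), indi = fill(indi, "INDI")),
            class = "faers_bundle")
}

# one fully eligible case skeleton; override fields to trigger exclusions
eligible_case <- function(pid, caseid = pid, sex = "F", age = "66",
                          age_cod = "YR", fda = 20200115L,
                          drugname = "IBRANCE", role = "PS",
                          indi_pt = "Breast cancer") {
  list(demo = data.table(PRIMARYID = pid, CASEID = caseid, FDA_DT = fda,
                         EVENT_DT = 20200101L, AGE = age, AGE_COD = age_cod,
                         SEX = sex),
       drug = data.table(PRIMARYID = pid, CASEID = caseid, DRUG_SEQ = 1L,
                         ROLE_COD = role, DRUGNAME = drugname,
                         DECHAL = "U"),
       reac = data.table(PRIMARYID = pid, CASEID = caseid, PT = "Nausea"),
       indi = data.table(PRIMARYID = pid, CASEID = caseid,
                         INDI_DRUG_SEQ = 1L, INDI_PT = indi_pt))
}

bundle_from_cases <- function(...) {
  cases <- list(...)
  mini_bundle(demo = rbindlist(lapply(cases, `[[`, "demo")),
              drug = rbindlist(lapply(cases, `[[`, "drug")),
              reac = rbindlist(lapply(cases, `[[`, "reac")),
              indi = rbindlist(lapply(cases, `[[`, "indi")))
}

# --- independent logistic-regression oracle --------------------------------
# plain Newton-Raphson on the exact Bernoulli likelihood; shares no code
# with the package's IRLS path
newton_logit <- function(x, y, tol = 1e-12, max_iter = 60L) {
  x <- as.matrix(x)
  beta <- numeric(ncol(x))
  for (i in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(x, y - mu))
    if (max(abs(g)) < tol) break
    h <- crossprod(x, x * (mu * (1 - mu)))
    beta <- beta + solve(h, g)
  }
  beta
}

# --- independent log-space evaluation of the ROR closed form ---------------
ror_oracle <- function(a, b, c, d, alpha = 0.05) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lr <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(exp(-log(a)) + exp(-log(b)) + exp(-log(c)) + exp(-log(d)))
  z <- qnorm(1 - alpha / 2)
  c(ror = exp(lr), ci_low = exp(lr - z * se), ci_high = exp(lr + z * se))
}
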