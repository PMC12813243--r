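#' Deduplicate DEMO per FDA guidance
#'
#' For identical `CASEID`s the most recent report by `FDA_DT` is retained;
#' when both `CASEID` and `FDA_DT` coincide, the report with the higher
#' `PRIMARYID` is kept. A missing `FDA_DT` sorts lowest, so an undated
#' version is always superseded by a dated one. The result is sorted by
#' `CASEID`, making the operation independent of input row order.
#'
#' @param demo DEMO table with columns `CASEID`, `FDA_DT`, `PRIMARYID`.
#' @return The surviving rows (one per `CASEID`), with attributes `n_kept`
#'   and `n_dropped`.
#' @export
deduplicate <- function(demo) {
  demo <- data.table::as.data.table(demo)
  need <- c("CASEID", "FDA_DT", "PRIMARYID")
  missing_cols <- setdiff(need, names(demo))
  if (length(missing_cols))
    stop("DEMO is missing key column(s): ", paste(missing_cols, collapse = ", "))
  n_in <- nrow(demo)
  ord <- order(demo$CASEID, demo$FDA_DT, demo$PRIMARYID, na.last = FALSE)
  sorted <- demo[ord]
  keep <- sorted[, .I[.N], by = CASEID]$V1
  out <- sorted[keep]
  data.table::setorder(out, CASEID)
  data.table::setattr(out, "n_kept", nrow(out))
  data.table::setattr(out, "n_dropped", n_in - nrow(out))
  out[]
}

#' Restrict a bundle to surviving report versions
#'
#' After [deduplicate()] the remaining tables (DRUG, REAC, THER, OUTC, INDI)
#' must be filtered to the surviving `PRIMARYID`s for the bundle to stay
#' internally consistent.
#'
#' @param bundle A `faers_bundle`.
#' @param primaryids Integer vector of surviving `PRIMARYID`s, or `NULL` to
#'   deduplicate `bundle$demo` first.
#' @return A `faers_bundle` containing only the surviving versions.
#' @export
dedup_bundle <- function(bundle, primaryids = NULL) {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (is.null(primaryids)) {
    demo <- deduplicate(bundle$demo)
    primaryids <- demo$PRIMARYID
  } else {
    demo <- bundle$demo[PRIMARYID %in% primaryids]
    data.table::setorder(demo, CASEID)
  }
  out <- lapply(bundle[c("drug", "reac", "ther", "outc", "indi")],
                function(tab) tab[PRIMARYID %in% primaryids])
  structure(c(list(demo = demo), out), class = "faers_bundle")
}
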