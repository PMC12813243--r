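#' Standardised MedDRA Query (SMQ) dictionaries
#'
#' An SMQ is a curated grouping of MedDRA Preferred Terms (PTs) representing a
#' clinical condition. SMQs may be hierarchical: a composite SMQ contains
#' sub-SMQs, and its effective term set is the union of its own terms and all
#' descendants' terms. Each term carries a `narrow` or `broad` scope within its
#' SMQ.
#'
#' A dictionary is represented as a list with two `data.table`s:
#' \describe{
#'   \item{smqs}{columns `smq_code` (integer), `smq_name`, `parent_code`
#'     (integer, `NA` for top-level SMQs), `status` ("A" active).}
#'   \item{terms}{columns `smq_code`, `pt_code` (integer), `pt_name`,
#'     `scope` ("narrow" or "broad") — each SMQ's *own* terms.}
#' }
#' After [expand_smq_hierarchy()] the list additionally carries
#' `effective_terms`, the rolled-up per-SMQ term sets used for mapping.
#'
#' The official MedDRA dictionary is licensed and never redistributed; the
#' package ships a small fictitious dictionary in the same tabular layout for
#' testing ([toy_smq_path()]), and [load_smq_dictionary()] reads any file pair
#' in that layout, including ones exported from a licensed MedDRA
#' installation.
#'
#' @name smq_dictionary
NULL

#' Path to the packaged toy SMQ dictionary
#'
#' @return Named character vector with elements `definitions` and `terms`.
#' @export
toy_smq_path <- function() {
  c(definitions = system.file("extdata", "smq_definitions.tsv",
                              package = "faersage", mustWork = TRUE),
    terms = system.file("extdata", "smq_terms.tsv",
                        package = "faersage", mustWork = TRUE))
}

#' Load an SMQ dictionary from tab-separated definition and term files
#'
#' @param definitions_path TSV with columns `smq_code`, `smq_name`,
#'   `parent_code`, `status`. Empty `parent_code` means top level.
#' @param terms_path TSV with columns `smq_code`, `pt_code`, `pt_name`,
#'   `scope`.
#' @return An object of class `smq_dictionary` (not yet hierarchy-expanded).
#' @export
load_smq_dictionary <- function(definitions_path = NULL, terms_path = NULL) {
  if (is.null(definitions_path)) {
    p <- toy_smq_path()
    definitions_path <- p[["definitions"]]
    terms_path <- p[["terms"]]
  }
  smqs <- data.table::fread(definitions_path, sep = "\t",
                            colClasses = list(character = "smq_name"),
                            na.strings = "")
  terms <- data.table::fread(terms_path, sep = "\t", na.strings = "")
  smqs[, smq_code := as.integer(smq_code)]
  smqs[, parent_code := as.integer(parent_code)]
  terms[, smq_code := as.integer(smq_code)]
  terms[, pt_code := as.integer(pt_code)]
  new_smq_dictionary(smqs, terms)
}

#' Construct and validate an SMQ dictionary from tables
#'
#' @param smqs,terms See [smq_dictionary] for the required columns.
#' @return An `smq_dictionary` object.
#' @export
new_smq_dictionary <- function(smqs, terms) {
  smqs <- data.table::as.data.table(smqs)
  terms <- data.table::as.data.table(terms)
  need_s <- c("smq_code", "smq_name", "parent_code", "status")
  need_t <- c("smq_code", "pt_code", "pt_name", "scope")
  if (!all(need_s %in% names(smqs)))
    stop("SMQ definition table must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_t %in% names(terms)))
    stop("SMQ term table must have columns: ", paste(need_t, collapse = ", "))
  if (anyDuplicated(smqs$smq_code))
    stop("duplicate smq_code in dictionary")
  unknown_parent <- setdiff(smqs$parent_code[!is.na(smqs$parent_code)],
                            smqs$smq_code)
  if (length(unknown_parent))
    stop("parent_code not defined: ", paste(unknown_parent, collapse = ", "))
  if (!all(terms$scope %in% c("narrow", "broad")))
    stop("term scope must be 'narrow' or 'broad'")
  if (anyDuplicated(terms[, .(smq_code, pt_code)]))
    stop("a pt_code may carry only one scope within an SMQ")
  orphan <- setdiff(terms$smq_code, smqs$smq_code)
  if (length(orphan))
    stop("terms reference undefined smq_code: ", paste(orphan, collapse = ", "))
  assert_acyclic(smqs)
  structure(list(smqs = smqs[order(smq_code)],
                 terms = terms[order(smq_code, pt_code)]),
            class = "smq_dictionary")
}

# topological elimination; any remainder is a cycle
assert_acyclic <- function(smqs) {
  remaining <- smqs[, .(smq_code, parent_code)]
  repeat {
    leaves <- setdiff(remaining$smq_code, remaining$parent_code)
    if (!length(leaves)) break
    remaining <- remaining[!smq_code %in% leaves]
  }
  if (nrow(remaining))
    stop("cyclic SMQ hierarchy involving codes: ",
         paste(sort(remaining$smq_code), collapse = ", "))
  invisible(TRUE)
}

#' Expand the SMQ hierarchy into effective term sets
#'
#' Each SMQ's effective term set becomes the union of its own terms and those
#' of all its descendants; the scope recorded for the child term is preserved
#' on roll-up. A PT contributed by several descendants with conflicting scopes
#' keeps the narrow scope (narrow evidence dominates).
#'
#' @param dict An `smq_dictionary`.
#' @return The dictionary with an `effective_terms` table added.
#' @export
expand_smq_hierarchy <- function(dict) {
  stopifnot(inherits(dict, "smq_dictionary"))
  smqs <- dict$smqs
  eff <- data.table::copy(dict$terms)
  # propagate child terms upward one level at a time until fixed point
  repeat {
    child <- smqs[!is.na(parent_code), .(smq_code, parent_code)]
    if (!nrow(child)) break
    up <- merge(eff, child, by = "smq_code")[
      , .(smq_code = parent_code, pt_code, pt_name, scope)]
    merged <- unique(rbind(eff, up))
    # narrow dominates when a PT reaches an SMQ by several paths
    merged <- merged[order(smq_code, pt_code, scope)]  # "broad" < "narrow"
    merged <- merged[, .SD[.N], by = .(smq_code, pt_code)]
    data.table::setcolorder(merged, c("smq_code", "pt_code", "pt_name", "scope"))
    if (nrow(merged) == nrow(eff) &&
        isTRUE(all.equal(merged$scope, eff[order(smq_code, pt_code)]$scope))) {
      eff <- merged
      break
    }
    eff <- merged
  }
  dict$effective_terms <- eff[order(smq_code, pt_code)]
  dict
}

#' Map each case's reaction terms to SMQs
#'
#' A case is flagged for an SMQ if at least one of its reported PTs falls in
#' the SMQ's effective term set under the scope policy; the flag is recorded
#' once per case per SMQ regardless of how many PTs match.
#'
#' @param reac REAC table with columns `PRIMARYID` and `PT` (PT names).
#' @param dict A hierarchy-expanded `smq_dictionary`.
#' @param scope_policy `"narrow_broad"` (full term set, default) or
#'   `"narrow"` (narrow-scope terms only).
#' @return `data.table` of unique (`PRIMARYID`, `smq_code`) pairs, with an
#'   attribute `unmapped` listing PT names absent from the dictionary.
#' @export
map_case_smqs <- function(reac, dict, scope_policy = c("narrow_broad", "narrow")) {
  scope_policy <- match.arg(scope_policy)
  if (is.null(dict$effective_terms))
    dict <- expand_smq_hierarchy(dict)
  eff <- dict$effective_terms
  if (scope_policy == "narrow") eff <- eff[scope == "narrow"]
  reac <- data.table::as.data.table(reac)
  lut <- eff[, .(smq_code, key = toupper(pt_name))]
  rx <- reac[, .(PRIMARYID, key = toupper(PT))]
  hits <- merge(rx, lut, by = "key", allow.cartesian = TRUE)
  out <- unique(hits[, .(PRIMARYID, smq_code)])
  data.table::setorder(out, PRIMARYID, smq_code)
  unmapped <- sort(setdiff(unique(rx$key),
                           unique(toupper(dict$effective_terms$pt_name))))
  data.table::setattr(out, "unmapped", unmapped)
  out[]
}

#' Deterministic synthetic SMQ dictionary
#'
#' Builds a flat (hierarchy-free) dictionary of fictitious SMQs for
#' simulation studies, with deterministic codes and term names. Roughly 60%
#' of each SMQ's terms are narrow scope, the rest broad.
#'
#' @param n_smqs Number of SMQs.
#' @param terms_per_smq Own terms per SMQ.
#' @return An `smq_dictionary`.
#' @export
synthetic_smq_dictionary <- function(n_smqs = 8L, terms_per_smq = 5L) {
  stopifnot(n_smqs >= 1L, terms_per_smq >= 1L)
  smqs <- data.table::data.table(
    smq_code = 91000000L + seq_len(n_smqs),
    smq_name = sprintf("Synthetic syndrome %02d (SMQ)", seq_len(n_smqs)),
    parent_code = NA_integer_,
    status = "A")
  grid <- data.table::CJ(i = seq_len(n_smqs), j = seq_len(terms_per_smq))
  n_narrow <- max(1L, ceiling(0.6 * terms_per_smq))
  terms <- grid[, .(
    smq_code = 91000000L + i,
    pt_code = 95000000L + i * 100L + j,
    pt_name = sprintf("Synthetic reaction %02d-%02d", i, j),
    scope = ifelse(j <= n_narrow, "narrow", "broad"))]
  new_smq_dictionary(smqs, terms)
}

#' @export
print.smq_dictionary <- function(x, ...) {
  cat("SMQ dictionary:", nrow(x$smqs), "SMQs,", nrow(x$terms), "own terms")
  if (!is.null(x$effective_terms))
    cat(",", nrow(x$effective_terms), "effective terms (expanded)")
  cat("\n")
  invisible(x)
}
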