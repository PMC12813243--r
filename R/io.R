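#' FAERS quarterly-file schemas
#'
#' Column names and types for the six supported dollar-delimited ASCII tables.
#' @keywords internal
FAERS_SCHEMAS <- list(
  DEMO = list(cols = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "AGE",
                       "AGE_COD", "SEX"),
              int = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT")),
  DRUG = list(cols = c("PRIMARYID", "CASEID", "DRUG_SEQ", "ROLE_COD",
                       "DRUGNAME", "DECHAL"),
              int = c("PRIMARYID", "CASEID", "DRUG_SEQ")),
  REAC = list(cols = c("PRIMARYID", "CASEID", "PT"),
              int = c("PRIMARYID", "CASEID")),
  THER = list(cols = c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT"),
              int = c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT")),
  OUTC = list(cols = c("PRIMARYID", "CASEID", "OUTC_COD"),
              int = c("PRIMARYID", "CASEID")),
  INDI = list(cols = c("PRIMARYID", "CASEID", "INDI_DRUG_SEQ", "INDI_PT"),
              int = c("PRIMARYID", "CASEID", "INDI_DRUG_SEQ"))
)

#' Read one FAERS-style dollar-delimited ASCII table
#'
#' Parses the FAERS quarterly-file dialect: `$`-separated fields, one header
#' row, blank fields meaning missing. Windows and Unix line endings parse
#' identically. Rows whose `PRIMARYID` does not parse as an integer are
#' counted as malformed and retained (attribute `n_malformed`); with
#' `strict = TRUE` they raise an error instead.
#'
#' @param path File path.
#' @param table_name One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`,
#'   `"INDI"`.
#' @param strict Raise on malformed rows instead of retaining them.
#' @return A `data.table` with the schema's columns typed (ids and dates
#'   integer, the rest character).
#' @export
read_faers_table <- function(path, table_name, strict = FALSE) {
  table_name <- toupper(table_name)
  schema <- FAERS_SCHEMAS[[table_name]]
  if (is.null(schema))
    stop("unknown FAERS table: ", table_name)
  if (!file.exists(path)) stop("cannot read file: ", path)
  dt <- data.table::fread(path, sep = "$", header = TRUE, quote = "",
                          colClasses = "character", na.strings = "",
                          showProgress = FALSE)
  missing_cols <- setdiff(schema$cols, names(dt))
  if (length(missing_cols))
    stop(table_name, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- dt[, schema$cols, with = FALSE]
  pid <- suppressWarnings(as.integer(dt$PRIMARYID))
  n_malformed <- sum(is.na(pid) & !is.na(dt$PRIMARYID)) + sum(is.na(dt$PRIMARYID))
  if (n_malformed > 0) {
    msg <- sprintf("%s: %d malformed row(s) (unparseable PRIMARYID)",
                   table_name, n_malformed)
    if (strict) stop(msg)
    message(msg)
  }
  for (col in schema$int)
    data.table::set(dt, j = col, value = suppressWarnings(as.integer(dt[[col]])))
  data.table::setattr(dt, "n_malformed", n_malformed)
  data.table::setattr(dt, "faers_table", table_name)
  dt[]
}

#' Write a FAERS-style bundle as dollar-delimited ASCII files
#'
#' @param bundle A `faers_bundle` (see [generate_bundle()]).
#' @param dir Output directory (created if needed). Files are named
#'   `DEMO.txt`, `DRUG.txt`, ... Missing values are written as empty fields.
#' @return `dir`, invisibly.
#' @export
write_faers_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(FAERS_SCHEMAS)) {
    data.table::fwrite(bundle[[tolower(nm)]], file.path(dir, paste0(nm, ".txt")),
                       sep = "$", quote = FALSE, na = "", eol = "\n")
  }
  invisible(dir)
}

#' Read a directory of FAERS-style ASCII tables into a bundle
#'
#' @param dir Directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `THER.txt`, `OUTC.txt`, `INDI.txt`.
#' @param strict Passed to [read_faers_table()].
#' @return A `faers_bundle`.
#' @export
read_faers_bundle <- function(dir, strict = FALSE) {
  tabs <- lapply(names(FAERS_SCHEMAS), function(nm)
    read_faers_table(file.path(dir, paste0(nm, ".txt")), nm, strict = strict))
  names(tabs) <- tolower(names(FAERS_SCHEMAS))
  structure(tabs, class = "faers_bundle")
}

#' Normalize reported ages to years
#'
#' FAERS reports age as a value plus a unit code. Conversion factors:
#' `YR` x1, `DEC` x10, `MON` /12, `WK` /52.1775, `DY` /365.25, `HR` /8766.
#' Unparseable values, unknown codes, and negative results yield `NA` —
#' exclusion of missing ages is an analysis-level decision, not a parse
#' failure.
#'
#' @param age_value Character (or numeric) vector of reported ages.
#' @param age_cod Character vector of unit codes, recycled if length 1.
#' @return Numeric vector of ages in years (`NA` where undetermined).
#' @export
normalize_age <- function(age_value, age_cod) {
  v <- suppressWarnings(as.numeric(age_value))
  if (length(age_cod) == 1L) age_cod <- rep(age_cod, length(v))
  factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
               DY = 1 / 365.25, HR = 1 / 8766)
  f <- factors[toupper(trimws(age_cod))]
  out <- unname(v * f)
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

# ---------------------------------------------------------------------------
# Drug lexicon: canonical ingredient names, brand/salt synonyms, class lists

#' Load a drug lexicon
#'
#' The lexicon maps free-text `DRUGNAME` values to canonical ingredient names
#' and assigns each ingredient to a therapy class. The packaged default covers
#' the three CDK4/6 inhibitors plus representative endocrine, chemotherapy,
#' targeted-therapy, and immune-checkpoint agents; it is an editable
#' stand-in for a full antineoplastic (ATC L01) ingredient list and can be
#' replaced by any file in the same layout.
#'
#' @param path TSV with columns `canonical`, `synonym`, `class`; `NULL` uses
#'   the packaged file.
#' @return An object of class `drug_lexicon`: list with `table` (the raw
#'   rows), `synonyms` (named character map, uppercase token -> canonical)
#'   and `classes` (named list of canonical-name vectors).
#' @export
load_drug_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "drug_lexicon.tsv", package = "faersage",
                        mustWork = TRUE)
  tab <- data.table::fread(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("canonical", "synonym", "class") %in% names(tab)))
  syn <- c(setNames(tab$canonical, toupper(tab$synonym)),
           setNames(tab$canonical, toupper(tab$canonical)))
  if (anyDuplicated(names(syn))) {
    chk <- tapply(syn, names(syn), function(x) length(unique(x)))
    if (any(chk > 1))
      stop("synonym maps to more than one canonical name: ",
           paste(names(chk)[chk > 1], collapse = ", "))
    syn <- syn[!duplicated(names(syn))]
  }
  classes <- split(unique(tab[, .(canonical, class)])$canonical,
                   unique(tab[, .(canonical, class)])$class)
  if (!setequal(classes$cdk46i %||% character(), CDK46I))
    warning("lexicon cdk46i class is not {palbociclib, ribociclib, abemaciclib}")
  structure(list(table = tab, synonyms = syn, classes = classes),
            class = "drug_lexicon")
}

## Salt/formulation tokens dropped from DRUGNAME before lookup (FAERS
## free-text practice).
DRUGNAME_STOP_TOKENS <- c(
  "HCL", "HYDROCHLORIDE", "SUCCINATE", "MESYLATE", "MALEATE", "TARTRATE",
  "SODIUM", "CITRATE", "PHOSPHATE", "ACETATE", "BESYLATE", "FUMARATE",
  "TABLET", "TABLETS", "CAPSULE", "CAPSULES", "INJECTION", "MG", "ORAL")

#' Normalize a free-text drug name to a canonical ingredient
#'
#' Matching is insensitive to case, punctuation, and surrounding whitespace;
#' salt and formulation tokens are stripped before lookup. Unmapped names
#' return `NA` so that the verbatim input remains available for audit.
#'
#' @param drugname Character vector of free-text drug names.
#' @param lexicon A `drug_lexicon`.
#' @return Character vector of canonical names (`NA` where unmapped).
#' @export
normalize_drug_name <- function(drugname, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  key <- toupper(drugname)
  key <- gsub("[^A-Z0-9 ]+", " ", key)
  key <- vapply(strsplit(trimws(key), "[ ]+"), function(tok) {
    tok <- tok[!tok %in% DRUGNAME_STOP_TOKENS & tok != "" &
                 !grepl("^[0-9.]+$", tok)]
    paste(tok, collapse = " ")
  }, character(1))
  unname(lexicon$synonyms[key])
}

#' Membership of canonical drug names in a lexicon class
#'
#' @param canonical Character vector of canonical names (`NA` allowed).
#' @param lexicon A `drug_lexicon`.
#' @param class_name One of the class labels in the lexicon (e.g.
#'   `"endocrine"`, `"chemotherapy"`, `"other_targeted"`, `"cdk46i"`,
#'   `"immune_checkpoint"`).
#' @return Logical vector.
#' @export
drug_in_class <- function(canonical, lexicon, class_name) {
  members <- lexicon$classes[[class_name]]
  if (is.null(members)) stop("unknown lexicon class: ", class_name)
  !is.na(canonical) & canonical %in% members
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("Drug lexicon:", length(unique(x$table$canonical)), "ingredients,",
      nrow(x$table), "synonym rows, classes:",
      paste(names(x$classes), collapse = ", "), "\n")
  invisible(x)
}
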