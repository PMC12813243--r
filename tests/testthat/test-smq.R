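toy <- expand_smq_hierarchy(load_smq_dictionary())

test_that("the packaged toy dictionary loads and validates", {
  expect_s3_class(toy, "smq_dictionary")
  expect_equal(nrow(toy$smqs), 12)
  expect_equal(sum(!is.na(toy$smqs$parent_code)), 3)
  expect_true(all(toy$terms$scope %in% c("narrow", "broad")))
})

test_that("malformed dictionaries are rejected", {
  smqs <- data.table::data.table(smq_code = c(1L, 2L), smq_name = c("A", "B"),
                                 parent_code = c(2L, 1L), status = "A")
  terms <- data.table::data.table(smq_code = 1L, pt_code = 1L,
                                  pt_name = "x", scope = "narrow")
  expect_error(new_smq_dictionary(smqs, terms), "cyclic")

  dup <- data.table::data.table(smq_code = c(1L, 1L), smq_name = c("A", "B"),
                                parent_code = NA_integer_, status = "A")
  expect_error(new_smq_dictionary(dup, terms), "duplicate smq_code")

  one <- data.table::data.table(smq_code = 1L, smq_name = "A",
                                parent_code = NA_integer_, status = "A")
  two_scopes <- data.table::data.table(smq_code = 1L, pt_code = c(7L, 7L),
                                       pt_name = "x",
                                       scope = c("narrow", "broad"))
  expect_error(new_smq_dictionary(one, two_scopes), "one scope")
  expect_error(new_smq_dictionary(one, data.table::data.table(
    smq_code = 9L, pt_code = 1L, pt_name = "x", scope = "narrow")),
    "undefined smq_code")
})

test_that("a PT may carry different scopes in different SMQs", {
  smqs <- data.table::data.table(smq_code = 1:2, smq_name = c("A", "B"),
                                 parent_code = NA_integer_, status = "A")
  terms <- data.table::data.table(smq_code = 1:2, pt_code = 7L,
                                  pt_name = "Shared term",
                                  scope = c("narrow", "broad"))
  d <- expand_smq_hierarchy(new_smq_dictionary(smqs, terms))
  expect_equal(d$effective_terms[smq_code == 1]$scope, "narrow")
  expect_equal(d$effective_terms[smq_code == 2]$scope, "broad")
})

test_that("hierarchy expansion unions descendants and preserves child scope", {
  # parent with no own terms inherits the child's single term
  smqs <- data.table::data.table(smq_code = 1:2, smq_name = c("P", "C"),
                                 parent_code = c(NA, 1L), status = "A")
  terms <- data.table::data.table(smq_code = 2L, pt_code = 1L,
                                  pt_name = "pt1", scope = "broad")
  d <- expand_smq_hierarchy(new_smq_dictionary(smqs, terms))
  expect_equal(d$effective_terms[smq_code == 1]$pt_name, "pt1")
  expect_equal(d$effective_terms[smq_code == 1]$scope, "broad")

  # three-level chain with disjoint term sets of sizes 2, 3, 4
  smqs3 <- data.table::data.table(smq_code = 1:3, smq_name = c("R", "M", "L"),
                                  parent_code = c(NA, 1L, 2L), status = "A")
  terms3 <- data.table::data.table(
    smq_code = rep(1:3, c(2, 3, 4)), pt_code = 1:9,
    pt_name = paste0("pt", 1:9), scope = "narrow")
  d3 <- expand_smq_hierarchy(new_smq_dictionary(smqs3, terms3))
  expect_equal(nrow(d3$effective_terms[smq_code == 1]), 9)
  expect_equal(nrow(d3$effective_terms[smq_code == 2]), 7)
  # leaf SMQ: effective set equals own set
  expect_equal(d3$effective_terms[smq_code == 3]$pt_code, 6:9)
})

test_that("case mapping flags once per SMQ and respects scope policy", {
  reac <- data.table::data.table(
    PRIMARYID = c(1L, 1L, 1L, 2L, 3L),
    CASEID = c(1L, 1L, 1L, 2L, 3L),
    PT = c("Diarrhoea", "Diarrhoea haemorrhagic", "diarrhoea",
           "Frequent bowel movements",  # broad-scope term
           "Totally novel reaction"))
  m <- map_case_smqs(reac, toy)
  # three matching PTs in one SMQ flag the case once
  expect_equal(nrow(m[PRIMARYID == 1 & smq_code == 20000002]), 1)
  # child flag implies the composite parent flag
  expect_true(nrow(m[PRIMARYID == 1 & smq_code == 20000001]) == 1)
  # broad-only PT flags under narrow_broad but not narrow policy
  expect_true(20000002 %in% m[PRIMARYID == 2]$smq_code)
  mn <- map_case_smqs(reac, toy, scope_policy = "narrow")
  expect_false(20000002 %in% mn[PRIMARYID == 2]$smq_code)
  # unknown PT logged, not an error
  expect_true("TOTALLY NOVEL REACTION" %in% attr(m, "unmapped"))
  expect_false(3L %in% m$PRIMARYID)
})

test_that("widening scope never removes a flag; ancestors always follow children", {
  b <- generate_bundle(synthetic_config(
    n_cases = 2000, seed = 31, smq_dictionary = load_smq_dictionary()))
  wide <- map_case_smqs(b$reac, toy, "narrow_broad")
  narrow <- map_case_smqs(b$reac, toy, "narrow")
  key <- function(x) paste(x$PRIMARYID, x$smq_code)
  expect_true(all(key(narrow) %in% key(wide)))
  child_parent <- toy$smqs[!is.na(parent_code), .(smq_code, parent_code)]
  for (i in seq_len(nrow(child_parent))) {
    flagged_child <- wide[smq_code == child_parent$smq_code[i]]$PRIMARYID
    flagged_parent <- wide[smq_code == child_parent$parent_code[i]]$PRIMARYID
    expect_true(all(flagged_child %in% flagged_parent))
  }
})
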