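tabs <- fixture_tables()

test_that("recode rules load, validate and reject duplicates", {
  expect_s3_class(tabs$rules, "recode_rules")
  expect_equal(tabs$rules$gm_pattern, "S2203")

  empty <- write_tsv(data.frame(gm_pattern = character(),
                                cm_target = character(), note = character()))
  expect_equal(nrow(load_recode_rules(empty)), 0L)

  dup <- write_tsv(data.frame(gm_pattern = c("S2203", "S2203"),
                              cm_target = c("S2205", "S2206"), note = ""))
  expect_error(load_recode_rules(dup), "duplicate")

  missing_col <- write_tsv(data.frame(gm_pattern = "S2203", note = ""))
  expect_error(load_recode_rules(missing_col), "cm_target")
})

test_that("apply_recode substitutes the longest matching prefix and keeps the tail", {
  expect_equal(format(apply_recode("S22.03", tabs$rules)), "S22.05")
  expect_equal(format(apply_recode("S06.5", tabs$rules)), "S06.5")  # pass-through
  expect_equal(format(apply_recode("S22.030", tabs$rules)), "S22.050")
  expect_equal(attr(apply_recode("S22.03", tabs$rules), "rule_fired"), "S2203")

  # longest-prefix tie-breaking against a brute-force matcher
  rules <- load_recode_rules(write_tsv(data.frame(
    gm_pattern = c("S220", "S2203", "S42"),
    cm_target = c("S221", "S2205", "S43"), note = "")))
  set.seed(7)
  for (sig in c("S2203", "S22030", "S2201", "S220", "S4211", "S065",
                paste0("S", sprintf("%02d", sample(0:99, 20)), sample(0:9, 20, TRUE)))) {
    raw <- paste0(substr(sig, 1, 3), ".", substring(sig, 4))
    raw <- sub("\\.$", "", raw)
    got <- gsub(".", "", format(apply_recode(raw, rules)), fixed = TRUE)
    expect_equal(got, oracle_recode(sig, rules), info = sig)
  }
})

test_that("collect_details separates detail codes and tags interpretations", {
  res <- collect_details(c("S06.5", "S06.7-!"), tabs$details)
  expect_length(res$injuries, 1L)
  expect_equal(format(res$injuries[[1]]), "S06.5")
  expect_equal(nrow(res$annotations), 1L)
  # S06.7 matches no 5-character prefix -> unknown; the specific S06.74! does
  expect_equal(res$annotations$interpretation, "unknown")

  res4 <- collect_details(c("S06.5", "S06.74!"), tabs$details)
  expect_equal(res4$annotations$interpretation, "loc_gt24h_no_return")

  none <- collect_details(c("S22.03"), tabs$details)
  expect_length(none$injuries, 1L)
  expect_equal(nrow(none$annotations), 0L)

  empty <- collect_details(character(), tabs$details)
  expect_length(empty$injuries, 0L)
  expect_equal(nrow(empty$annotations), 0L)
})

test_that("to_cm chains recode, policy lookup and normalisation", {
  expect_equal(format(to_cm("S06.5", NULL, tabs$rules, tabs$policies)),
               "S06.5X0A")
  ann <- collect_details(c("S06.5", "S06.74!"), tabs$details)$annotations
  cm <- to_cm("S06.5", ann, tabs$rules, tabs$policies)
  expect_equal(format(cm), "S06.5X6A")
  expect_match(attr(cm, "rules_fired"), "loc_gt24h_no_return")

  expect_equal(format(to_cm("S22.03", NULL, tabs$rules, tabs$policies)),
               "S22.05XA")

  # unreviewed stem falls back to the placeholder with a warning
  expect_warning(cm2 <- to_cm("S99.9", NULL, tabs$rules, tabs$policies),
                 "policy")
  expect_equal(format(cm2), "S99.9XXA")

  expect_error(to_cm("S06.74!", NULL, tabs$rules, tabs$policies), "detail")
})

test_that("convert_cohort conserves rows, channels errors and stays deterministic", {
  records <- data.frame(
    patient_id = rep(c("A", "B"), each = 3),
    icd_code = c("S06.5", "S22.03", "S52.5", "S36.1", "S20.2", "S02.2"))
  res <- convert_cohort(records)
  expect_equal(nrow(res$conversions), 6L)
  expect_equal(nrow(res$errors), 0L)
  # deterministic: identical inputs give identical outputs
  expect_identical(res$conversions, convert_cohort(records)$conversions)

  bad <- rbind(records, data.frame(patient_id = "C", icd_code = "NOTACODE"))
  res2 <- convert_cohort(bad)
  expect_equal(nrow(res2$conversions), 6L)
  expect_equal(nrow(res2$errors), 1L)
  expect_equal(res2$errors$patient_id, "C")

  # encounter default propagates to every emitted code
  resD <- convert_cohort(records, encounter_default = "D")
  expect_true(all(grepl("D$", resD$conversions$cm_code)))
})

test_that("codes outside S00-T88 pass through tagged, with a warning", {
  records <- data.frame(patient_id = "A", icd_code = c("Z00.0", "S06.5"))
  expect_warning(res <- convert_cohort(records), "S00-T88")
  expect_equal(nrow(res$conversions), 2L)
  row <- res$conversions[res$conversions$gm_code == "Z00.0", ]
  expect_equal(row$rules_fired, "unmapped_chapter")
})

test_that("with empty rules and placeholder policies to_cm is pure padding", {
  empty_rules <- load_recode_rules(write_tsv(data.frame(
    gm_pattern = character(), cm_target = character(), note = character())))
  placeholder <- load_seventh_policies(write_tsv(data.frame(
    cm_subcategory = c("S065", "S2203"), condition = "", value = "X")))
  expect_equal(format(to_cm("S06.5", NULL, empty_rules, placeholder)),
               "S06.5XXA")
  expect_equal(format(to_cm("S22.03", NULL, empty_rules, placeholder)),
               "S22.03XA")
})

test_that("seventh-character policy tables validate their invariants", {
  expect_error(load_seventh_policies(write_tsv(data.frame(
    cm_subcategory = "S065", condition = "tag", value = "6"))),
    "fallback")
  expect_error(load_seventh_policies(write_tsv(data.frame(
    cm_subcategory = c("S065", "S065"), condition = "", value = c("0", "1")))),
    "duplicate")
  expect_error(load_seventh_policies(write_tsv(data.frame(
    cm_subcategory = "S065", condition = "", value = "XX"))),
    "single")
})
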