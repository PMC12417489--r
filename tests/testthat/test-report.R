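test_that("parse_report assigns text between canonical headers", {
  r <- parse_report("IMPRESSION: Abnormal EEG.\nMEDICATIONS: Keppra.")
  expect_equal(r$sections$impression, "Abnormal EEG.")
  expect_equal(r$sections$medications, "Keppra.")

  # empty input: all sections empty
  r0 <- parse_report("")
  expect_true(all(!nzchar(unlist(r0$sections))))

  # headerless text is all preamble
  rp <- parse_report("free text with no headers at all")
  expect_equal(rp$sections$preamble, "free text with no headers at all")

  # duplicated header: contents concatenated in order (split-scan oracle)
  rd <- parse_report("EVENTS: first part.\nIMPRESSION: ok.\nEVENTS: second part.")
  expect_equal(rd$sections$events, "first part. second part.")

  # aliases and case-insensitivity
  ra <- parse_report("description: posterior alpha.\nHistory: none relevant.")
  expect_equal(ra$sections$description_of_the_record, "posterior alpha.")
  expect_equal(ra$sections$clinical_history, "none relevant.")
})

test_that("parse/render round-trip is the identity on section contents", {
  set.seed(42)
  keys <- names(report_sections())
  for (i in 1:20) {
    filled <- sample(keys, sample(1:8, 1))
    secs <- stats::setNames(
      as.list(paste0("text ", seq_along(filled), " about ",
                     sample(letters, length(filled), TRUE))), filled)
    rep0 <- new_clinical_report(secs)
    rep1 <- parse_report(render_report(rep0))
    expect_identical(rep1$sections, rep0$sections)
  }
})

test_that("select_sections joins non-empty sections in canonical order", {
  r <- new_clinical_report(list(impression = "Abnormal EEG.",
                                medications = "Keppra.",
                                clinical_history = "Seizures."))
  expect_equal(select_sections(r, "impression"), "Abnormal EEG.")
  # request order does not override canonical order
  expect_equal(select_sections(r, c("impression", "clinical_history")),
               "Seizures.\n\nAbnormal EEG.")
  expect_equal(select_sections(r, "all"),
               "Seizures.\n\nKeppra.\n\nAbnormal EEG.")
  expect_equal(select_sections(r, "findings"), "")
  expect_error(select_sections(r, "no_such_section"), "unknown")
})

test_that("derive_labels implements the four task rules", {
  meta <- list(age = 50, gender = "M", pathological = TRUE)
  lab <- derive_labels(meta, "IMPRESSION: ok")
  expect_false(lab$age_over_50)          # boundary: 50 is not over 50
  expect_true(derive_labels(list(age = 51), NULL)$age_over_50)
  expect_true(lab$pathological)
  expect_equal(lab$gender, "M")

  expect_true(derive_labels(meta, "The patient was started on Dilantin.")$medication)
  expect_true(derive_labels(meta, "MEDICATIONS: KEPPRA 500mg")$medication)
  expect_true(derive_labels(meta, parse_report("MEDICATIONS: depakote"))$medication)
  expect_false(derive_labels(meta, "aspirin only")$medication)

  # missing metadata stays missing
  lab2 <- derive_labels(list(), NULL)
  expect_true(is.na(lab2$pathological))
  expect_true(is.na(lab2$age_over_50))
  expect_true(is.na(lab2$gender))
  expect_true(is.na(lab2$medication))
  expect_error(derive_labels(list(age = -1), NULL), "nonnegative")
})

test_that("build_prompts returns the fixed prompt pairs", {
  expect_equal(build_prompts("pathological"),
               c(A = "This is a normal recording",
                 B = "This is an abnormal recording"))
  expect_equal(build_prompts("age"),
               c(A = "The patient is under 50 years old",
                 B = "The patient is over 50 years old"))
  expect_equal(build_prompts("gender"),
               c(A = "The patient is male", B = "The patient is female"))
  expect_equal(build_prompts("medication"),
               c(A = "No anti-epileptic drugs were prescribed to the patient",
                 B = "Anti-epileptic drugs were prescribed to the patient"))
  expect_error(build_prompts("handedness"), "unknown task")
})

test_that("task_target maps labels to the binary targets", {
  lab <- derive_labels(list(age = 60, gender = "F", pathological = FALSE),
                       "keppra")
  expect_false(task_target(lab, "pathological"))
  expect_true(task_target(lab, "age"))
  expect_true(task_target(lab, "gender"))
  expect_true(task_target(lab, "medication"))
})
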