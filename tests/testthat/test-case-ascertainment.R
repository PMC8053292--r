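test_that("events classify by code prefix, setting and medication class", {
  expect_equal(classify_event("encounter", "G43.909", "outpatient"),
               "migraine_encounter")
  expect_equal(classify_event("encounter", "g43.1", "inpatient"),
               "migraine_encounter")
  expect_equal(classify_event("encounter", "346.90", "outpatient"),
               "migraine_encounter")
  expect_equal(classify_event("encounter", "G43.909", "ed"), "migraine_ed")
  expect_equal(classify_event("encounter", "G43.909", "urgent_care"),
               "migraine_urgent_care")
  expect_equal(classify_event("encounter", "R51", "neurology"),
               "neurology_visit")
  expect_equal(classify_event("prescription", NA, NA, "triptan"),
               "abortive_fill")
  expect_equal(classify_event("prescription", NA, NA, "ergotamine"),
               "abortive_fill")
  expect_equal(classify_event("problem_list", "G43.1", NA),
               "problem_list_migraine")
  # non-matching prefix
  expect_equal(classify_event("encounter", "G44.1", "outpatient"), "other")
  # malformed inputs never raise
  expect_equal(classify_event("encounter", NA, "outpatient"), "other")
  expect_equal(classify_event("encounter", "", "outpatient"), "other")
  expect_equal(classify_event("widget", "???", "??"), "other")
  expect_equal(classify_event("encounter", 346.9, "outpatient"),
               "migraine_encounter")
})

test_that("the score follows the capped component formula", {
  cfg <- mpa_default_config()
  # no events
  r0 <- mpa_score(data.frame(event_type = character(0),
                             code = character(0),
                             care_setting = character(0),
                             medication_class = character(0)))
  expect_equal(r0$score, 0)
  expect_false(r0$is_case)
  # one migraine encounter -> w_enc = 20, a case
  r1 <- mpa_score(ev("encounter", "G43.909", "outpatient"))
  expect_equal(r1$score, 20)
  expect_true(r1$is_case)
  expect_false(r1$severe)
  # components add: 2 encounters + problem list + 1 fill = 40 + 11 + 15
  e <- rbind(ev("encounter", "G43.909", "outpatient"),
             ev("encounter", "346.90", "inpatient"),
             ev("problem_list", "G43.1"),
             ev("prescription", medication_class = "triptan"))
  expect_equal(mpa_score(e)$score, 66)
  # raw score above the cap truncates to 101 and flags severe:
  # 5 encounters + problem list + 1 fill = 100 + 11 + 15 = 126 -> 101
  e2 <- rbind(do.call(rbind, replicate(5, ev("encounter", "G43.909",
                                             "outpatient"), simplify = FALSE)),
              ev("problem_list", "G43.1"),
              ev("prescription", medication_class = "triptan"))
  r2 <- mpa_score(e2)
  expect_equal(r2$score, 101)
  expect_true(r2$severe)
  # encounter cap: 9 encounters score the same as 5
  e9 <- do.call(rbind, replicate(9, ev("encounter", "G43.909", "outpatient"),
                                 simplify = FALSE))
  e5 <- do.call(rbind, replicate(5, ev("encounter", "G43.909", "outpatient"),
                                 simplify = FALSE))
  expect_equal(mpa_score(e9)$score, mpa_score(e5)$score)
})

test_that("score is bounded and monotone under event additions", {
  set.seed(6)
  types <- c("encounter", "prescription", "problem_list", "junk")
  codes <- c("G43.909", "346.1", "G44.1", "", NA, "xyz")
  settings <- c("outpatient", "inpatient", "ed", "urgent_care", "neurology",
                NA)
  meds <- c("triptan", "ergotamine", "statin", NA)
  for (rep in 1:40) {
    n <- sample(0:25, 1)
    e <- data.frame(event_type = sample(types, n, TRUE),
                    code = sample(codes, n, TRUE),
                    care_setting = sample(settings, n, TRUE),
                    medication_class = sample(meds, n, TRUE),
                    stringsAsFactors = FALSE)
    r <- mpa_score(e)
    expect_true(r$score >= 0 && r$score <= 101)
    expect_equal(r$is_case, r$score > 10)
    if (r$severe) expect_true(r$is_case)
    # adding a migraine encounter or fill never decreases the score
    r_enc <- mpa_score(rbind(e, ev("encounter", "G43.909", "outpatient")))
    r_rx <- mpa_score(rbind(e, ev("prescription",
                                  medication_class = "triptan")))
    expect_gte(r_enc$score, r$score)
    expect_gte(r_rx$score, r$score)
  }
})

test_that("severity outcomes are rates over person-years plus dichotomies", {
  case <- mpa_score(ev("encounter", "G43.909", "outpatient"))
  # zero severity events over 2 person-years
  s0 <- severity_outcomes(ev("encounter", "G43.909", "outpatient"), case, 2)
  expect_equal(s0$neurology_visits_per_py, 0)
  expect_equal(s0$migraine_urgent_care_per_py, 0)
  expect_false(s0$any_migraine_ed)
  expect_false(s0$mpa_gt_100)
  # 3 neurology visits over 1.5 person-years -> 2 per person-year
  e <- rbind(ev("encounter", "G43.909", "outpatient"),
             do.call(rbind, replicate(3, ev("encounter", "R51", "neurology"),
                                      simplify = FALSE)))
  s1 <- severity_outcomes(e, case, 1.5)
  expect_equal(s1$neurology_visits_per_py, 2)
  # one ED visit flips the dichotomy regardless of person-years
  e2 <- ev("encounter", "G43.909", "ed")
  s2 <- severity_outcomes(e2, mpa_score(e2), 57)
  expect_true(s2$any_migraine_ed)
  # non-case is a precondition error
  non_case <- mpa_score(ev("encounter", "G44.1", "outpatient"))
  expect_error(severity_outcomes(e, non_case, 1), "cases only")
  expect_error(severity_outcomes(e, case, 0), "person_years")
})

test_that("cohort-level ascertainment equals per-patient scoring", {
  r <- tiny_region()
  s <- tiny_sources(r)
  tr <- true_model(intercept = stats::qlogis(0.4), seed = 17)
  co <- generate_cohort(r, s, 150, tr)
  asc <- ascertain_cohort(co$patients, co$events)
  for (i in sample(nrow(co$patients), 25)) {
    pid <- co$patients$patient_id[i]
    e <- co$events[co$events$patient_id == pid, , drop = FALSE]
    res <- mpa_score(e)
    expect_equal(asc$mpa_score[i], res$score)
    expect_equal(asc$is_case[i], res$is_case)
    if (res$is_case) {
      so <- severity_outcomes(e, res, co$patients$person_years[i])
      expect_equal(asc$neurology_visits_per_py[i], so$neurology_visits_per_py)
      expect_equal(asc$triptans_per_py[i], so$triptans_per_py)
      expect_equal(asc$any_migraine_ed[i], so$any_migraine_ed)
      expect_equal(asc$mpa_gt_100[i], so$mpa_gt_100)
    }
  }
})
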