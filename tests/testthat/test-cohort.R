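cen <- as.Date("2018-06-28")

test_that("census_spec validates its parameters", {
  expect_error(census_spec("not-a-date"), "date")
  expect_error(census_spec(cen, window_days = 0), "window_days")
  expect_error(census_spec(cen, min_references_v2 = 1), "min_references_v2")
  sp <- census_spec(cen)
  expect_equal(sp$window_days, 183L)
  expect_equal(sp$form_validity_days, 183L)
  expect_equal(sp$algorithm_version, "v2")
})

test_that("active caseload uses closed intervals with open ends ongoing", {
  ep <- episodes_dt(c("A", "B", "C", "D"),
                    start_date = c(cen - 10, cen - 100, cen + 1, cen - 100),
                    end_date = c(cen + 10, cen - 1, NA, NA))
  expect_equal(active_caseload(ep, cen), c("A", "D"))
  # boundary day: episode ending exactly on the census still counts
  ep2 <- episodes_dt("E", cen - 30, cen)
  expect_equal(active_caseload(ep2, cen), "E")
  expect_equal(active_caseload(ep2, cen + 1), character())
})

test_that("dementia index takes the earliest qualifying event from any source", {
  ev <- events_dt(rep("A", 3),
                  date = c("2018-01-10", "2018-01-05", "2018-07-01"),
                  event_class = "diagnosis", detail = "F00-F03",
                  source = c("structured", "text", "structured"))
  s <- manual_stream(ev)
  expect_equal(dementia_index(s, "A", cen), as.Date("2018-01-05"))
  # only post-census events: absent
  ev2 <- events_dt("B", "2018-07-01", "diagnosis", "F00-F03")
  expect_true(is.na(dementia_index(manual_stream(ev2), "B", cen)))
  expect_true(is.na(dementia_index(s, "NOBODY", cen)))
})

test_that("v1 admits any single in-window reference, closed boundaries", {
  spec <- census_spec(cen, algorithm_version = "v1")
  ev <- events_dt("A", format(cen - 183), "medication", "risperidone",
                  kind = "mention", source = "text")
  r <- recent_use_v1(manual_stream(ev), "A", spec)
  expect_true(r$flag)
  expect_equal(nrow(r$evidence), 1L)
  # one day earlier falls out of the window
  ev2 <- events_dt("A", format(cen - 184), "medication", "risperidone",
                   kind = "mention", source = "text")
  expect_false(recent_use_v1(manual_stream(ev2), "A", spec)$flag)
  # a lone stop reference still counts as v1 evidence
  ev3 <- events_dt("A", format(cen - 10), "medication", "risperidone",
                   kind = "stop", source = "text")
  expect_true(recent_use_v1(manual_stream(ev3), "A", spec)$flag)
})

test_that("v2 applies the reference-count and stop filters", {
  spec <- census_spec(cen, algorithm_version = "v2")
  one <- events_dt("A", format(cen - 10), "medication", "risperidone",
                   kind = "mention", source = "text")
  r1 <- recent_use_v2(manual_stream(one), "A", spec)
  expect_false(r1$flag)
  expect_equal(r1$reason, "single_reference")

  same_drug_stopped <- events_dt(
    rep("A", 3), format(cen - c(30, 20, 10)), "medication", "risperidone",
    kind = c("mention", "mention", "stop"), source = "text")
  r2 <- recent_use_v2(manual_stream(same_drug_stopped), "A", spec)
  expect_false(r2$flag)
  expect_equal(r2$reason, "stopped")

  # drug A stopped, drug B clean: included via drug B (pooled count 4)
  two_drugs <- events_dt(
    rep("A", 4), format(cen - c(40, 30, 20, 10)), "medication",
    c("quetiapine", "quetiapine", "risperidone", "risperidone"),
    kind = c("mention", "stop", "mention", "mention"), source = "text")
  r3 <- recent_use_v2(manual_stream(two_drugs), "A", spec)
  expect_true(r3$flag)
  expect_equal(nrow(r3$evidence), 4L)

  expect_equal(recent_use_v2(manual_stream(one[0]), "A", spec)$reason,
               "no_recent_use")
})

test_that("per-drug rule-1 scope is available as the alternative reading", {
  spec_pd <- census_spec(cen, algorithm_version = "v2", rule1_scope = "per_drug")
  # one reference each of two drugs: pooled reading passes rule 1,
  # per-drug reading does not
  ev <- events_dt(rep("A", 2), format(cen - c(20, 10)), "medication",
                  c("risperidone", "quetiapine"), kind = "mention",
                  source = "text")
  s <- manual_stream(ev)
  expect_true(recent_use_v2(s, "A", census_spec(cen))$flag)
  r <- recent_use_v2(s, "A", spec_pd)
  expect_false(r$flag)
  expect_equal(r$reason, "single_reference")
})

test_that("sensitivity exclusions follow the ever/after rules in order", {
  spec <- census_spec(cen, sensitivity_mode = TRUE)
  mk_member <- function(pid, idx = "2018-01-01") {
    data.table::data.table(patient_id = pid, census_date = cen, included = TRUE,
                           exclusion_reason = "none",
                           dementia_index_date = as.Date(idx),
                           n_references_in_window = 2L)
  }
  # F20 years before the dementia index: still excluded ("ever")
  ev_psy <- events_dt(c("A", "A"), c("2015-03-01", "2018-01-01"), "diagnosis",
                      c("F20-F29", "F00-F03"))
  m1 <- apply_sensitivity_exclusions(mk_member("A"), manual_stream(ev_psy), spec)
  expect_false(m1$included)
  expect_equal(m1$exclusion_reason, "psychosis_ever")

  # other-F after the index: excluded
  ev_other <- events_dt(c("B", "B"), c("2018-01-01", "2018-03-01"), "diagnosis",
                        c("F00-F03", "other-F"))
  m2 <- apply_sensitivity_exclusions(mk_member("B"), manual_stream(ev_other), spec)
  expect_equal(m2$exclusion_reason, "other_dx_after_index")

  # other-F before the index only: retained; same-day is not "after"
  ev_before <- events_dt(c("C", "C"), c("2017-06-01", "2018-01-01"), "diagnosis",
                         c("other-F", "F00-F03"))
  expect_true(apply_sensitivity_exclusions(mk_member("C"),
                                           manual_stream(ev_before), spec)$included)
  ev_same <- events_dt(c("D", "D"), c("2018-01-01", "2018-01-01"), "diagnosis",
                       c("other-F", "F00-F03"))
  expect_true(apply_sensitivity_exclusions(mk_member("D"),
                                           manual_stream(ev_same), spec)$included)

  # psychosis rule outranks the other-dx rule
  ev_both <- events_dt(c("E", "E", "E"),
                       c("2015-01-01", "2018-01-01", "2018-03-01"), "diagnosis",
                       c("F20-F29", "F00-F03", "other-F"))
  m3 <- apply_sensitivity_exclusions(mk_member("E"), manual_stream(ev_both), spec)
  expect_equal(m3$exclusion_reason, "psychosis_ever")
})

test_that("build_cohort records the first failing rule per patient", {
  ev <- data.table::rbindlist(list(
    events_dt(c("ACT", "ACT", "ACT"), c("2018-01-01", "2018-05-01", "2018-05-02"),
              c("diagnosis", "medication", "medication"),
              c("F00-F03", "risperidone", "risperidone"),
              kind = c(NA, "mention", "mention"),
              source = c("structured", "text", "text")),
    events_dt("INACT", "2018-01-01", "diagnosis", "F00-F03"),
    events_dt("NODEM", "2018-05-01", "medication", "risperidone",
              kind = "mention", source = "text")
  ))
  ep <- episodes_dt(c("ACT", "NODEM"), "2017-01-01")
  s <- manual_stream(ev, episodes = ep)
  cohort <- build_cohort(s, ep, census_spec(cen))
  expect_equal(cohort[patient_id == "ACT", included], TRUE)
  expect_equal(cohort[patient_id == "INACT", exclusion_reason], "not_active")
  expect_equal(cohort[patient_id == "NODEM", exclusion_reason], "no_dementia")
  expect_equal(cohort[patient_id == "ACT", n_references_in_window], 2L)
  # every evaluated patient appears exactly once, sorted
  expect_equal(cohort$patient_id, sort(cohort$patient_id))
  expect_equal(anyDuplicated(cohort$patient_id), 0L)
})

test_that("cohort membership equals the brute-force oracle on a 50-patient fixture", {
  b <- generate_bundle(small_cfg(n_patients = 50, seed = 41))
  s <- bundle_event_stream(b)
  for (census in as.Date(c("2017-12-28", "2018-06-28", "2019-01-28"))) {
    for (ver in c("v1", "v2")) {
      for (sens in c(FALSE, TRUE)) {
        spec <- census_spec(census, algorithm_version = ver,
                            sensitivity_mode = sens)
        got <- build_cohort(s, b$episodes, spec)
        want <- oracle_cohort(s$events, b$episodes, spec)
        expect_equal(got$patient_id, want$patient_id)
        expect_equal(got$included, want$included,
                     label = sprintf("%s %s sens=%s", census, ver, sens))
        expect_equal(got$exclusion_reason, want$exclusion_reason,
                     label = sprintf("reasons %s %s sens=%s", census, ver, sens))
      }
    }
  }
})

test_that("v2 cohorts are subsets of v1; sensitivity shrinks them further", {
  b <- generate_bundle(small_cfg(n_patients = 80, seed = 43))
  s <- bundle_event_stream(b)
  for (census in as.list(monthly_censuses("2017-10", "2019-01")[c(1, 8, 16)])) {
    inc <- function(ver, sens) {
      build_cohort(s, b$episodes,
                   census_spec(census, algorithm_version = ver,
                               sensitivity_mode = sens))[included == TRUE,
                                                         patient_id]
    }
    v1 <- inc("v1", FALSE); v2 <- inc("v2", FALSE); vs <- inc("v2", TRUE)
    expect_true(all(v2 %in% v1))
    expect_true(all(vs %in% v2))
  }
})

test_that("cohort membership is invariant under a global time translation", {
  b <- generate_bundle(small_cfg(n_patients = 40, seed = 47))
  s <- bundle_event_stream(b)
  spec <- census_spec(cen)
  base <- build_cohort(s, b$episodes, spec)
  offset <- 37L
  s2 <- s
  s2$events <- data.table::copy(s$events)[, date := date + offset]
  ep2 <- data.table::copy(b$episodes)[, `:=`(start_date = start_date + offset,
                                             end_date = end_date + offset)]
  shifted <- build_cohort(s2, ep2, census_spec(cen + offset))
  expect_equal(shifted$included, base$included)
  expect_equal(shifted$exclusion_reason, base$exclusion_reason)
})
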