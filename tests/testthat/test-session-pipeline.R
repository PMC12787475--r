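mini_plan <- function() {
  training_plan(data.frame(
    label = c("stand_a", "stand_b"), phase = c(1L, 2L),
    cycles = "8", executions = 1L, block_duration_s = c(3, 3),
    n_blocks = 1L, gender = "both"))
}

neutral_recording_for <- function(label, phase, gender, subject, fs = 60,
                                  dur = 3) {
  sp <- sequence_spec(label, phase, duration_s = dur)
  generate_sequence(sp, sample_rate_hz = fs, noise_sd_deg = 0,
                    gender = gender, subject_id = subject, seed = 1)$recording
}

test_that("plan bookkeeping reproduces the printed programme totals", {
  plan <- default_training_plan()
  expect_identical(total_duration(plan, "male"), 1358)
  expect_identical(total_duration(plan, "female"), 1410)
  expect_identical(total_duration(plan[0, ], "male"), 0)
  expect_identical(nrow(plan_for_gender(plan, "male")), 16L)
  expect_identical(nrow(plan_for_gender(plan, "female")), 19L)
})

test_that("a neutral session sits entirely in the negligible band", {
  plan <- mini_plan()
  recs <- list(neutral_recording_for("stand_a", 1, "female", "F01"),
               neutral_recording_for("stand_b", 2, "female", "F01"))
  res <- run_session(recs, plan)
  expect_equal(res$session_histogram$mean_reba, 1)
  expect_equal(unname(res$risk_bands$session["negligible"]), 1)
  expect_identical(res$total_frames, sum(vapply(recs, `[[`, 0L, "n_frames")))
})

test_that("the pipeline recovers the generator's ground-truth mean score under noise", {
  plan <- default_training_plan()
  out <- generate_session(plan, "female", seed = 42, sample_rate_hz = 40,
                          time_scale = 0.05, noise_sd_deg = 0.5)
  recs <- lapply(out, `[[`, "recording")
  res <- run_session(recs, plan)
  truth_final <- unlist(lapply(out, function(x) x$truth$reba$scores$final))
  expect_equal(res$session_histogram$mean_reba, mean(truth_final),
               tolerance = 0.05 / mean(truth_final))
})

test_that("unmapped labels and mixed sample rates are refused", {
  plan <- mini_plan()
  rec <- neutral_recording_for("nonesuch", 1, "female", "F01")
  expect_error(run_session(list(rec), plan), "nonesuch")
  recs <- list(neutral_recording_for("stand_a", 1, "female", "F01", fs = 60),
               neutral_recording_for("stand_b", 2, "female", "F01", fs = 50))
  expect_error(run_session(recs, plan), "sample rates")
})

test_that("frame counts are conserved through every aggregation level", {
  plan <- default_training_plan()
  out <- generate_session(plan, "male", seed = 3, sample_rate_hz = 20,
                          time_scale = 0.02)
  res <- run_session(lapply(out, `[[`, "recording"), plan)
  expect_equal(res$session_histogram$total_frames,
               sum(res$per_recording$n_frames))
  expect_equal(sum(vapply(res$phase_histograms, `[[`, 0, "total_frames")),
               res$total_frames)
  expect_equal(sum(vapply(res$sequence_histograms, `[[`, 0, "total_frames")),
               res$total_frames)
  ## every histogram still sums to one
  for (h in c(res$phase_histograms, list(res$session_histogram))) {
    expect_equal(sum(h$rel_freq), 1, tolerance = 1e-9)
  }
})

test_that("a two-gender study produces the full comparison battery", {
  plan <- default_training_plan()
  study <- generate_study(plan, n_female = 3, n_male = 3, seed = 5,
                          sample_rate_hz = 20, time_scale = 0.02)
  res <- run_session(study$recordings, plan)
  cmp <- res$comparisons
  expect_s3_class(cmp$gender_overall, "comparison_result")
  expect_named(cmp$gender_per_phase, c("phase1", "phase2", "phase3"))
  expect_s3_class(cmp$phase_kw_reba, "comparison_result")
  expect_identical(nrow(cmp$phase_pairwise_reba), 3L)
  expect_length(cmp$gender_per_score, 12L)
  expect_true(is.logical(cmp$normality_gate))
})

test_that("under identical generator settings the gender test stays null-calibrated", {
  plan <- mini_plan()
  ps <- vapply(1:100, function(r) {
    study <- generate_study(plan, n_female = 5, n_male = 5,
                            seed = 9000 + r, sample_rate_hz = 15,
                            time_scale = 0.4, noise_sd_deg = 0.5,
                            subject_sd_deg = 2)
    ## give the neutral micro-sessions some posture so scores vary
    res <- run_session(study$recordings, plan)
    cmp <- res$comparisons$gender_overall
    if (is.null(cmp)) NA_real_ else cmp$p_value
  }, 0)
  expect_gte(mean(ps >= 0.05, na.rm = TRUE), 0.90)
})

test_that("reports round-trip and are byte-stable", {
  plan <- default_training_plan()
  study <- generate_study(plan, n_female = 2, n_male = 2, seed = 8,
                          sample_rate_hz = 20, time_scale = 0.02)
  res <- run_session(study$recordings, plan)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  files <- render_report(res, out1)
  expect_true(all(file.exists(files)))
  hist_back <- utils::read.csv(file.path(out1, "session_histogram.csv"))
  expect_equal(hist_back$rel_freq, unname(res$session_histogram$rel_freq))
  bands_back <- utils::read.csv(file.path(out1, "risk_bands.csv"))
  expect_equal(bands_back$rel_freq[bands_back$source == "session"],
               unname(unclass(res$risk_bands$session)))
  render_report(res, out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("stable report file", f))
  }
  ## a single-subject result has no comparisons and says so
  solo <- run_session(list(neutral_recording_for("stand_a", 1, "male", "M01")),
                      mini_plan())
  out3 <- withr::local_tempdir()
  render_report(solo, out3)
  expect_true(any(grepl("no comparisons",
                        readLines(file.path(out3, "report.md")))))
})
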