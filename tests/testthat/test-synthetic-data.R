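test_that("noiseless calibration sweeps are exact template mixtures", {
  neuro <- neurochem_params(noise_sd = 0)
  cal <- generate_calibration_set(neuro, n_samples = 16,
                                  conc_grid = c(0, 1, 2, 3), seed = 1)
  expect_equal(nrow(cal$sweeps), length(cal$labels_da))
  expect_true(all(cal$labels_da >= 0 & cal$labels_sert >= 0))

  i <- which(cal$labels_da == 1 & cal$labels_sert == 0)[1]
  expect_equal(cal$sweeps[i, ], neuro$template_da, tolerance = 1e-12)

  j <- which(cal$labels_da == 2 & cal$labels_sert == 3)[1]
  expect_equal(cal$sweeps[j, ],
               2 * neuro$template_da + 3 * neuro$template_sert,
               tolerance = 1e-12)
})

test_that("calibration labels cycle the full factorial with uniform marginals", {
  cal <- generate_calibration_set(neurochem_params(), n_samples = 500,
                                  conc_grid = c(0, 0.5, 1, 2), seed = 1)
  for (lab in list(cal$labels_da, cal$labels_sert)) {
    counts <- table(lab)
    expect_length(counts, 4)
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
  expect_error(generate_calibration_set(neurochem_params(), 10, numeric(0)),
               "non-empty")
  expect_error(generate_calibration_set(neurochem_params(), 10, c(-1, 1)),
               "non-negative")
})

test_that("collinear analyte templates are rejected", {
  tpl <- sin(seq(0, pi, length.out = 24))
  expect_error(neurochem_params(template_da = tpl, template_sert = 2 * tpl),
               "collinear")
})

test_that("default session has 300 trials on a symmetric grid containing both anchors", {
  s <- quick_session(seed = 3)
  expect_s3_class(s, "session_recording")
  expect_equal(nrow(s$trials), 300)

  counts <- table(s$trials$duration_s)
  levels <- as.numeric(names(counts))
  expect_equal(min(levels), 0.5)
  expect_equal(max(levels), 1.1)
  expect_length(levels, 7)
  # symmetric allocation about the 0.8 s midpoint
  expect_equal(as.integer(counts), rev(as.integer(counts)))
  expect_equal(mean(s$trials$duration_s), 0.8)
  # timestamps uniform at 10 Hz, all epochs inside the recording
  expect_equal(unique(round(diff(s$timestamps), 10)), 0.1)
  expect_true(all(s$trials$onset_s + 1.1 <= max(s$timestamps)))
})

test_that("identical seeds reproduce sessions bit-identically", {
  a <- generate_session(task_config(n_trials = 40), seed = 7)
  b <- generate_session(task_config(n_trials = 40), seed = 7)
  c <- generate_session(task_config(n_trials = 40), seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$trials$response, c$trials$response))
  # behaviour draws are unaffected by skipping the sweep matrix
  d <- generate_session(task_config(n_trials = 40), seed = 7,
                        include_sweeps = FALSE)
  expect_identical(a$trials, d$trials)
  expect_identical(a$truth_da, d$truth_da)
})

test_that("an unbiased observer is at chance on midpoint probes", {
  # pool the 0.8 s probes (the generative bisection point) over sessions
  long <- unlist(lapply(1:7, function(i) {
    tr <- quick_session(seed = 400 + i)$trials
    tr$response[abs(tr$duration_s - 0.8) < 1e-9] == "long"
  }))
  expect_gt(length(long), 250)
  expect_lt(abs(mean(long) - 0.5), 3 * sqrt(0.25 / length(long)))
})

test_that("phasic coupling raises transient amplitude on short-response trials", {
  obs <- observer_params(phasic_coupling = 0.05)
  wins <- vapply(1:100, function(i) {
    tr <- quick_session(seed = 500 + i, observer = obs)$trials
    mean(tr$truth_phasic_amp[tr$response == "short"]) >
      mean(tr$truth_phasic_amp[tr$response == "long"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("with zero couplings behaviour is independent of neurochemistry", {
  covered <- vapply(1:100, function(i) {
    tr <- quick_session(seed = 1500 + i)$trials
    fit <- stats::glm(I(response == "long") ~ scale(duration_s) +
                        scale(truth_phasic_amp),
                      data = tr, family = stats::binomial())
    ci <- suppressMessages(stats::confint.default(fit))[3, ]
    ci[1] < 0 && ci[2] > 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("sessions too short for the trial count are rejected", {
  expect_error(generate_session(task_config(n_trials = 300, iti_mean = 1.2),
                                seed = 1, include_sweeps = FALSE),
               "too short")
})

test_that("trial tables round-trip through delimited text", {
  s <- quick_session(seed = 11, task = task_config(n_trials = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(s$trials, path)
  tr <- read_trial_table(path)
  expect_equal(tr$onset_s, s$trials$onset_s, tolerance = 1e-9)
  expect_identical(tr$response, s$trials$response)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset_s,duration_s,response", "1,0.5,maybe"), bad)
  expect_error(read_trial_table(bad), "invalid response")
})

test_that("session recordings round-trip through text + JSON sidecar", {
  s <- generate_session(task_config(n_trials = 12), seed = 5)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  r <- read_session(dir)
  expect_equal(r$sweeps, s$sweeps, tolerance = 1e-6)
  expect_equal(r$truth_da, s$truth_da, tolerance = 1e-9)
  expect_identical(r$trials$response, s$trials$response)
  expect_equal(r$task$sample_rate, s$task$sample_rate)
  expect_equal(r$neuro$template_da, s$neuro$template_da, tolerance = 1e-9)
})

test_that("trial allocation distributes remainders symmetrically", {
  # 300 over 7: remainder 6 goes to the three outermost pairs
  expect_identical(neurochron:::allocate_levels(300, 7),
                   c(43L, 43L, 43L, 42L, 43L, 43L, 43L))
  # odd remainder: middle level first
  expect_identical(neurochron:::allocate_levels(22, 7),
                   c(3L, 3L, 3L, 4L, 3L, 3L, 3L))
  for (n in c(14, 25, 300, 301)) {
    expect_equal(sum(neurochron:::allocate_levels(n, 7)), n)
  }
})
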