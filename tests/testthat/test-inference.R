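get_beta <- function(fit, term) {
  fit$coefficients$beta[fit$coefficients$term == term]
}
get_se <- function(fit, term) {
  fit$coefficients$se[fit$coefficients$term == term]
}

test_that("tercile partitions are balanced, stable and rank-based", {
  set.seed(41)
  part <- partition_terciles(rnorm(300))
  expect_equal(as.integer(table(part)), c(100L, 100L, 100L))

  # documented tie/rounding rule: larger groups at the low end
  p5 <- partition_terciles(1:5)
  expect_identical(as.character(p5),
                   c("low", "low", "medium", "medium", "high"))

  # label invariance under strictly monotone transforms (the stored
  # boundaries are in data units and differ, by design)
  x <- rnorm(100)
  expect_identical(as.character(partition_terciles(x)),
                   as.character(partition_terciles(exp(x))))

  # sizes always sum to n, differ by at most one within participant
  for (n in c(3, 7, 50, 299, 300)) {
    sz <- as.integer(table(partition_terciles(rnorm(n))))
    expect_equal(sum(sz), n)
    expect_lte(diff(range(sz)), 1)
  }

  # all-equal summaries: stable split with a warning
  expect_warning(pe <- partition_terciles(rep(1, 9)), "all summaries equal")
  expect_equal(as.integer(table(pe)), c(3L, 3L, 3L))
  expect_error(partition_terciles(1:2), ">= 3")

  # within-participant computation
  pp <- partition_terciles(c(1:6, 601:606), rep(1:2, each = 6))
  expect_equal(as.integer(table(pp[1:6])), c(2L, 2L, 2L))
  expect_equal(as.integer(table(pp[7:12])), c(2L, 2L, 2L))
})

test_that("single-participant logistic model equals a direct glm fit", {
  s <- quick_session(seed = 42)
  summ <- window_mean(extract_epochs(truth_series(s), s$trials))
  fit <- fit_trial_logistic(s$trials, summ)
  expect_false(fit$mixed)

  d <- data.frame(long = as.integer(s$trials$response == "long"),
                  zd = as.numeric(scale(s$trials$duration_s)),
                  zs = as.numeric(scale(as.numeric(summ))))
  ref <- stats::glm(long ~ zd + zs, data = d, family = stats::binomial())
  expect_equal(unname(coef(fit)), unname(stats::coef(ref)),
               tolerance = 1e-8)
})

test_that("unit rescaling of the dopamine summary leaves betas unchanged", {
  s <- quick_session(seed = 43,
                     observer = observer_params(phasic_coupling = 0.05))
  summ <- as.numeric(window_mean(extract_epochs(truth_series(s), s$trials)))
  a <- fit_trial_logistic(s$trials, summ)
  b <- fit_trial_logistic(s$trials, summ * 1000)   # uM -> nM
  expect_equal(a$coefficients$beta, b$coefficients$beta, tolerance = 1e-8)

  # mixed path: two participants
  s2 <- quick_session(seed = 44,
                      observer = observer_params(phasic_coupling = 0.05))
  tr <- rbind(s$trials, s2$trials)
  sm2 <- c(summ, as.numeric(window_mean(extract_epochs(truth_series(s2),
                                                       s2$trials))))
  pid <- rep(1:2, each = 300)
  am <- fit_trial_logistic(tr, sm2, pid)
  bm <- fit_trial_logistic(tr, sm2 * 1000, pid)
  expect_equal(am$coefficients$beta, bm$coefficients$beta,
               tolerance = 1e-6)
})

test_that("phasic coupling drives the dopamine beta negative", {
  obs <- observer_params(phasic_coupling = 0.05)
  betas <- vapply(1:25, function(i) {
    s <- quick_session(seed = 4500 + i, observer = obs)
    summ <- window_mean(extract_epochs(truth_series(s), s$trials))
    get_beta(fit_trial_logistic(s$trials, summ), "z_summary")
  }, numeric(1))
  expect_gte(mean(betas < 0), 0.9)
})

test_that("without coupling the dopamine beta CI covers zero", {
  covered <- vapply(1:25, function(i) {
    s <- quick_session(seed = 4600 + i)
    summ <- window_mean(extract_epochs(truth_series(s), s$trials))
    fit <- fit_trial_logistic(s$trials, summ)
    b <- get_beta(fit, "z_summary"); se <- get_se(fit, "z_summary")
    b - 1.96 * se < 0 && b + 1.96 * se > 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("reversing tercile labels flips the tercile beta exactly", {
  s <- quick_session(seed = 46,
                     observer = observer_params(phasic_coupling = 0.05))
  summ <- window_mean(extract_epochs(truth_series(s), s$trials))
  part <- partition_terciles(summ)
  rev_part <- factor(c(low = "high", medium = "medium",
                       high = "low")[as.character(part)],
                     levels = c("low", "medium", "high"), ordered = TRUE)
  a <- fit_tercile_model(s$trials, part)
  b <- fit_tercile_model(s$trials, rev_part)
  expect_equal(get_beta(a, "tercile"), -get_beta(b, "tercile"),
               tolerance = 1e-6)
})

test_that("random terciles carry no effect; injected coupling shifts PFs", {
  null_cover <- vapply(1:25, function(i) {
    s <- quick_session(seed = 4700 + i)
    set.seed(i)
    part <- partition_terciles(rnorm(300))
    fit <- fit_tercile_model(s$trials, part)
    b <- get_beta(fit, "tercile"); se <- get_se(fit, "tercile")
    b - 1.96 * se < 0 && b + 1.96 * se > 0
  }, logical(1))
  expect_gte(mean(null_cover), 0.9)

  obs <- observer_params(phasic_coupling = 0.05)
  res <- vapply(1:15, function(i) {
    s <- quick_session(seed = 4800 + i, observer = obs)
    summ <- window_mean(extract_epochs(truth_series(s), s$trials))
    part <- partition_terciles(summ)
    beta <- get_beta(fit_tercile_model(s$trials, part), "tercile")
    fits <- suppressWarnings(indices_by_group(s$trials, part))
    # underestimation on the P(long) axis: BP rises low -> high tercile
    c(beta < 0, coef(fits$high)[["bp"]] > coef(fits$low)[["bp"]])
  }, logical(2))
  expect_gte(mean(res[1, ]), 0.8)
  expect_gte(mean(res[2, ]), 0.8)
})

test_that("tonic coupling drives the precision beta positive", {
  obs <- observer_params(tonic_coupling = 0.4)
  betas <- vapply(1:20, function(i) {
    ss <- lapply(1:2, function(j) quick_session(seed = 9000 * i + j,
                                                observer = obs))
    tw <- lapply(ss, function(s) {
      tonic_window_indices(truth_series(s), s$trials)
    })
    fit <- suppressWarnings(fit_tonic_outcome(
      unlist(lapply(tw, `[[`, "tonic")),
      do.call(c, lapply(tw, `[[`, "fits")),
      rep(1:2, vapply(tw, function(x) length(x$tonic), integer(1)))))
    get_beta(fit, "z_tonic")
  }, numeric(1))
  expect_gte(mean(betas > 0), 0.9)
})

test_that("phasic-only coupling leaves tonic accuracy at the null", {
  obs <- observer_params(phasic_coupling = 0.05)
  covered <- vapply(1:100, function(i) {
    ss <- lapply(1:2, function(j) quick_session(seed = 9100 * i + j,
                                                observer = obs))
    tw <- lapply(ss, function(s) {
      tonic_window_indices(truth_series(s), s$trials)
    })
    fit <- suppressWarnings(fit_tonic_outcome(
      unlist(lapply(tw, `[[`, "tonic")),
      do.call(c, lapply(tw, `[[`, "fits")),
      rep(1:2, vapply(tw, function(x) length(x$tonic), integer(1))),
      outcome = "accuracy"))
    b <- get_beta(fit, "z_tonic"); se <- get_se(fit, "z_tonic")
    # t-reference interval: a dozen windows is too few for the normal one
    crit <- stats::qt(0.975, fit$n_obs - 2)
    b - crit * se < 0 && b + crit * se > 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("precision beta keeps its sign across tonic window lengths", {
  obs <- observer_params(tonic_coupling = 0.4)
  ss <- lapply(1:2, function(j) quick_session(seed = 9200 + j,
                                              observer = obs))
  signs <- vapply(c(120, 240, 360), function(L) {
    tw <- lapply(ss, function(s) {
      tonic_window_indices(truth_series(s), s$trials, window_length = L)
    })
    fit <- suppressWarnings(fit_tonic_outcome(
      unlist(lapply(tw, `[[`, "tonic")),
      do.call(c, lapply(tw, `[[`, "fits")),
      rep(1:2, vapply(tw, function(x) length(x$tonic), integer(1)))))
    sign(get_beta(fit, "z_tonic"))
  }, numeric(1))
  expect_equal(signs, rep(signs[1], 3))
})

test_that("degenerate tonic-outcome inputs are rejected", {
  s <- quick_session(seed = 48, task = task_config(n_trials = 60))
  tw <- tonic_window_indices(truth_series(s), s$trials,
                             window_length = 120)
  expect_gte(length(tw$tonic), 2)
  # constant tonic predictor
  expect_error(fit_tonic_outcome(rep(1, length(tw$tonic)), tw$fits),
               "zero variance")
  # participant with a single window
  expect_error(fit_tonic_outcome(tw$tonic[1], tw$fits[1]), "< 2 tonic")
  # non-converged window fits are dropped with a warning
  bad <- tw$fits
  bad[[1]]$converged <- FALSE
  expect_warning(fit_tonic_outcome(c(tw$tonic, 9), c(bad, tw$fits[1]),
                                   rep(1, length(tw$tonic) + 1)),
                 "non-converged")
})
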