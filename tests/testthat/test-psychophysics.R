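# Expand a per-level count table into a trial-level data frame.
counts_to_trials <- function(durations, n, k) {
  data.frame(
    duration_s = rep(durations, n),
    response = unlist(Map(function(ki, ni) {
      c(rep("long", ki), rep("short", ni - ki))
    }, k, n)))
}

test_that("maximum-likelihood fit matches an exhaustive grid search", {
  durations <- seq(0.5, 1.1, by = 0.1)
  n <- c(43, 43, 43, 42, 43, 43, 43)
  k <- c(1, 5, 13, 22, 35, 40, 42)
  fit <- fit_pf(counts_to_trials(durations, n, k))

  # oracle: exhaustive 1 ms x 1 ms grid over the optimiser's box
  bp_grid <- seq(0.4, 1.2, by = 0.001)
  sg_grid <- seq(0.001, 0.6, by = 0.001)
  best <- -Inf
  for (sg in sg_grid) {
    p <- stats::pnorm(outer(durations, bp_grid, "-") / sg)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- colSums(k * log(p) + (n - k) * log(1 - p))
    best <- max(best, max(ll))
  }
  expect_equal(fit$logLik, best, tolerance = 1e-4)
  expect_gte(fit$logLik, best - 1e-4)
})

test_that("fitted PF evaluates to exactly 0.5 at its bisection point", {
  s <- quick_session(seed = 21)
  fit <- fit_pf(s$trials)
  expect_equal(unname(predict(fit, coef(fit)[["bp"]])), 0.5,
               tolerance = 1e-15)
})

test_that("bisection point and Weber fraction are recovered across sessions", {
  fits <- lapply(1:100, function(i) fit_pf(quick_session(seed = 2000 + i)$trials))
  bp <- vapply(fits, function(f) coef(f)[["bp"]], numeric(1))
  weber <- vapply(fits, function(f) f$weber, numeric(1))
  expect_lt(stats::median(abs(bp - 0.8)), 0.02)
  expect_lt(stats::median(abs(weber - 0.1)), 0.02)
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
})

test_that("derived indices respect their defining identities", {
  fit <- fit_pf(quick_session(seed = 22)$trials)
  expect_equal(fit$jnd, 0.6745 * coef(fit)[["sigma"]])
  expect_equal(fit$weber, fit$jnd / coef(fit)[["bp"]])
  # 25-75% span: PF crosses .25 and .75 exactly jnd either side of bp
  expect_equal(unname(predict(fit, coef(fit)[["bp"]] + fit$jnd)), 0.75,
               tolerance = 1e-4)
  # fitted PF is non-decreasing in duration
  p <- predict(fit, seq(0.3, 1.3, by = 0.01))
  expect_true(all(diff(p) >= 0))
})

test_that("50/50 trials at the fitted bisection point leave the fit unchanged", {
  s <- quick_session(seed = 23)
  fit <- fit_pf(s$trials)
  bp <- coef(fit)[["bp"]]
  extra <- data.frame(duration_s = rep(bp, 50),
                      response = rep(c("long", "short"), 25))
  fit2 <- fit_pf(rbind(s$trials[, c("duration_s", "response")], extra))
  expect_equal(coef(fit2)[["bp"]], bp, tolerance = 1e-5)
  expect_equal(coef(fit2)[["sigma"]], coef(fit)[["sigma"]], tolerance = 1e-5)
})

test_that("degenerate response patterns are flagged or rejected", {
  d <- data.frame(duration_s = rep(seq(0.5, 1.1, 0.1), each = 20))
  d$response <- ifelse(d$duration_s > 0.8, "long", "short")
  expect_warning(fit <- fit_pf(d), "separable")
  expect_false(fit$converged)
  expect_equal(coef(fit)[["sigma"]], 0.001, tolerance = 1e-6)

  one <- data.frame(duration_s = seq(0.5, 1.1, 0.1),
                    response = "long")
  expect_error(fit_pf(one), "both response categories")
  expect_error(fit_pf(data.frame(duration_s = rep(0.8, 10),
                                 response = rep(c("long", "short"), 5))),
               "distinct durations")
})

test_that("a free lapse parameter is estimated within bounds", {
  obs <- observer_params(lapse = 0.1)
  s <- quick_session(seed = 24, observer = obs)
  fit0 <- fit_pf(s$trials)
  fit1 <- fit_pf(s$trials, fix_lapse = NULL)
  expect_gte(coef(fit1)[["lapse"]], 0)
  expect_lte(coef(fit1)[["lapse"]], 0.5)
  expect_gte(fit1$logLik, fit0$logLik - 1e-9)
})

test_that("identical data under different labels give identical fits", {
  s <- quick_session(seed = 25, task = task_config(n_trials = 90))
  d3 <- rbind(s$trials, s$trials, s$trials)
  lab <- rep(c("a", "b", "c"), each = 90)
  fits <- indices_by_group(d3, lab)
  expect_named(fits, c("a", "b", "c"))
  expect_equal(coef(fits$a), coef(fits$b))
  expect_equal(coef(fits$b), coef(fits$c))
})

test_that("an injected bisection shift is recovered across terciles", {
  shifted <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    d <- rep(seq(0.5, 1.1, 0.1), times = 43)[1:300]
    terc <- sample(rep(c("low", "medium", "high"), each = 100))
    bp_g <- ifelse(terc == "high", 0.75, 0.8)   # leftward shift when high
    p <- stats::pnorm((d - bp_g) / 0.12)
    tr <- data.frame(duration_s = d,
                     response = ifelse(runif(300) < p, "long", "short"))
    fits <- indices_by_group(tr, factor(terc,
                                        levels = c("low", "medium", "high")))
    coef(fits$high)[["bp"]] < coef(fits$low)[["bp"]]
  }, logical(1))
  expect_gte(mean(shifted), 0.9)
})

test_that("equal partitions produce equal-sized group fits", {
  s <- quick_session(seed = 26)
  set.seed(1)
  part <- partition_terciles(rnorm(300))
  fits <- indices_by_group(s$trials, part)
  expect_length(fits, 3)
  expect_equal(vapply(fits, function(f) f$n_trials, numeric(1)),
               c(low = 100, medium = 100, high = 100))
  expect_false(any(vapply(fits, function(f) attr(f, "low_n"), logical(1))))
  # small groups are fitted but flagged
  d30 <- counts_to_trials(c(0.5, 0.8, 1.1), c(10, 10, 10), c(1, 5, 9))
  small <- indices_by_group(d30, rep(c("x", "y"), 15))
  expect_true(all(vapply(small, function(f) attr(f, "low_n"), logical(1))))
})

test_that("pf_fit methods are coherent", {
  s <- quick_session(seed = 27)
  fit <- fit_pf(s$trials)
  expect_output(print(fit), "Weber")
  expect_output(print(summary(fit)), "standard errors")
  expect_equal(attr(logLik(fit), "df"), 2)
  expect_identical(dim(vcov(fit)), c(2L, 2L))
  expect_true(all(is.finite(residuals(fit))))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(7L, 3L))
  expect_true(all(sim >= 0))
})
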