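#' Train the concentration decoder
#'
#' Fits one elastic-net regression per analyte (dopamine, serotonin) on a
#' calibration set, with a single hyperparameter pair shared across the
#' two analytes.  The pair (`l1_ratio`, `lambda`) is selected by k-fold
#' cross-validation, minimising the summed mean held-out MSE of the two
#' analytes; features are standardised using training-fold statistics
#' only.  The final model is refit on the full calibration set at the
#' selected pair.
#'
#' The penalty follows the `glmnet` gaussian convention
#' (objective \eqn{\frac{1}{2n}\|y - X\beta\|^2 +
#' \lambda[\frac{1-\alpha}{2}\|\beta\|_2^2 + \alpha\|\beta\|_1]} on
#' unit-variance response scale), so at `l1_ratio = 0` the coefficients
#' solve the ridge system \eqn{(X'X + n\lambda/\mathrm{sd}(y)\,I)^{-1}X'y}
#' on centred standardised features.
#'
#' @param cal A [generate_calibration_set()] result, or any list with
#'   `sweeps`, `labels_da`, `labels_sert`.
#' @param l1_grid Candidate elastic-net mixing ratios in `[0, 1]`.
#' @param lambda_grid Candidate penalty strengths (default: logarithmic
#'   over six decades).
#' @param n_folds Number of CV folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return An object of class `decoder_model` with per-analyte
#'   coefficient vectors and intercepts, the selected hyperparameters,
#'   standardisation constants, the CV MSE surface, and held-out R² per
#'   analyte (`cv_r2_da`, `cv_r2_sert`).
#' @seealso [decode()], [write_decoder()]
#' @export
fit_decoder <- function(cal,
                        l1_grid = c(0.1, 0.5, 0.9),
                        lambda_grid = 10^seq(1, -5, length.out = 13),
                        n_folds = 10, seed = 1) {
  X <- as.matrix(cal$sweeps)
  y <- cbind(da = cal$labels_da, sert = cal$labels_sert)
  n <- nrow(X)
  if (length(cal$labels_da) != n || length(cal$labels_sert) != n) {
    stopf("sweep and label row counts differ")
  }
  if (n_folds < 2) stopf("n_folds must be >= 2")
  if (n < n_folds) stopf("fewer samples (%d) than folds (%d)", n, n_folds)
  if (!length(l1_grid) || !length(lambda_grid)) {
    stopf("hyperparameter grids must be non-empty")
  }

  keep <- which(apply(X, 2, stats::sd) > 0)
  if (length(keep) < ncol(X)) {
    warnf("dropping %d all-constant feature(s)", ncol(X) - length(keep))
  }
  if (!length(keep)) stopf("all features are constant")
  X <- X[, keep, drop = FALSE]

  lam <- sort(lambda_grid, decreasing = TRUE)
  folds <- with_seed(substream(seed, 21), {
    sample(rep_len(seq_len(n_folds), n))
  })

  cv_mse <- array(0, dim = c(length(l1_grid), length(lam), 2),
                  dimnames = list(NULL, NULL, c("da", "sert")))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sc <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sc[sc == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sc, "/")
    Xva <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sc, "/")
    for (a in seq_along(l1_grid)) {
      for (an in c("da", "sert")) {
        fit <- glmnet::glmnet(Xtr, y[tr, an], alpha = l1_grid[a],
                              lambda = lam, standardize = FALSE,
                              family = "gaussian")
        pred <- stats::predict(fit, newx = Xva, s = lam)
        err <- (pred - y[!tr, an])^2
        cv_mse[a, , an] <- cv_mse[a, , an] + colMeans(err) / n_folds
      }
    }
  }
  total <- matrix(cv_mse[, , "da"] + cv_mse[, , "sert"],
                  length(l1_grid), length(lam))
  best <- which(total == min(total), arr.ind = TRUE)[1, , drop = TRUE]
  alpha_sel <- l1_grid[best[1]]
  lambda_sel <- lam[best[2]]

  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  final <- lapply(c(da = "da", sert = "sert"), function(an) {
    fit <- glmnet::glmnet(Xs, y[, an], alpha = alpha_sel,
                          lambda = lambda_sel, standardize = FALSE,
                          family = "gaussian",
                          thresh = 1e-14, maxit = 1e7)
    b <- as.numeric(stats::coef(fit))
    # store the intercept at the raw-feature origin so that a zero sweep
    # decodes exactly to the intercept
    list(intercept = b[1] - sum(mu / sc * b[-1]), coef = b[-1])
  })

  cv_r2 <- vapply(c(da = "da", sert = "sert"), function(an) {
    1 - cv_mse[best[1], best[2], an] / stats::var(y[, an])
  }, numeric(1))

  structure(
    list(coef_da = final$da$coef, coef_sert = final$sert$coef,
         intercept_da = final$da$intercept,
         intercept_sert = final$sert$intercept,
         l1_ratio = alpha_sel, penalty_lambda = lambda_sel,
         feature_means = mu, feature_scales = sc,
         feature_index = keep,
         cv_mse = cv_mse, cv_r2_da = unname(cv_r2["da"]),
         cv_r2_sert = unname(cv_r2["sert"]),
         n_folds = as.integer(n_folds), seed = as.integer(seed)),
    class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "Elastic-net decoder: %d features, l1_ratio %.3g, lambda %.3g\n  held-out R2: DA %.4f, 5-HT %.4f\n",
    length(x$coef_da), x$l1_ratio, x$penalty_lambda,
    x$cv_r2_da, x$cv_r2_sert))
  invisible(x)
}

#' Decode concentration series from sweeps
#'
#' Applies a fitted decoder to a sweep matrix: per timepoint and analyte,
#' estimate = intercept + scale-standardised sweep · coefficients (the
#' intercept is stored at the raw-feature origin, so an all-zero sweep
#' decodes exactly to the intercept).  The map is affine; estimates may
#' be negative (downstream analyses use relative changes) and are never
#' clipped.
#'
#' @param model A [fit_decoder()] result.
#' @param rec A `session_recording`, or a numeric sweep matrix
#'   (timepoints x features).  Matrices are paired with timestamps at the
#'   decoder's native 10 Hz unless `timestamps` is given.
#' @param timestamps Optional timestamps (s) when `rec` is a bare matrix.
#' @return An object of class `concentration_series`: `timestamps`,
#'   `da`, `sert` (µM estimates).
#' @export
decode <- function(model, rec, timestamps = NULL) {
  stopifnot(inherits(model, "decoder_model"))
  if (inherits(rec, "session_recording")) {
    if (is.null(rec$sweeps)) stopf("session has no sweep matrix to decode")
    sweeps <- rec$sweeps
    timestamps <- rec$timestamps
  } else {
    sweeps <- as.matrix(rec)
    if (is.null(timestamps)) timestamps <- (seq_len(nrow(sweeps)) - 1) / 10
  }
  if (max(model$feature_index) > ncol(sweeps)) {
    stopf("sweep feature dimension (%d) does not match decoder (needs %d)",
          ncol(sweeps), max(model$feature_index))
  }
  sweeps <- sweeps[, model$feature_index, drop = FALSE]
  bad <- which(!stats::complete.cases(sweeps) |
                 rowSums(!is.finite(sweeps)) > 0)
  if (length(bad)) {
    stopf("non-finite features at timepoint(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  Xs <- sweep(sweeps, 2, model$feature_scales, "/")
  concentration_series(
    timestamps = timestamps,
    da = as.numeric(model$intercept_da + Xs %*% model$coef_da),
    sert = as.numeric(model$intercept_sert + Xs %*% model$coef_sert))
}

#' Construct a concentration series
#'
#' Container for decoded (or ground-truth) dopamine and serotonin
#' estimates over time, sampled uniformly.
#'
#' @param timestamps Seconds, uniformly spaced.
#' @param da,sert µM estimates, same length as `timestamps`.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(timestamps, da, sert) {
  if (length(da) != length(timestamps) ||
      length(sert) != length(timestamps)) {
    stopf("timestamps, da and sert must have equal length")
  }
  if (length(timestamps) > 1) {
    dt <- diff(timestamps)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt) + 1e-12) {
      stopf("timestamps must be strictly increasing and uniform")
    }
  }
  structure(list(timestamps = timestamps, da = da, sert = sert),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series: %d timepoints over %.1f s; DA %.3g+/-%.3g uM\n",
              length(x$timestamps), diff(range(x$timestamps)),
              mean(x$da), stats::sd(x$da)))
  invisible(x)
}

#' Serialise a decoder model to JSON
#'
#' Stores coefficients, intercepts, hyperparameters and standardisation
#' constants; `read_decoder` restores an equivalent `decoder_model`
#' (without the CV surface).
#'
#' @param model A `decoder_model`.
#' @param path JSON file path.
#' @return `write_decoder` returns `path` invisibly; `read_decoder`
#'   returns a `decoder_model`.
#' @export
write_decoder <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  keep <- c("coef_da", "coef_sert", "intercept_da", "intercept_sert",
            "l1_ratio", "penalty_lambda", "feature_means",
            "feature_scales", "feature_index", "cv_r2_da", "cv_r2_sert",
            "n_folds", "seed")
  jsonlite::write_json(unclass(model)[keep], path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "decoder_model")
}
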