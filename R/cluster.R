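# Cluster-based permutation contrast of response-conditioned epochs.

# Coerce labels to logical "positive class": TRUE/1/second factor level.
labels_to_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[2])
  if (is.character(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) > 2) stopf("labels must be binary")
    return(labels == lev[length(lev)])
  }
  if (!all(labels %in% c(0, 1))) stopf("numeric labels must be 0/1")
  labels == 1
}

welch_z_series <- function(E, g) {
  # Welch t per column between rows with g TRUE (positive) and FALSE,
  # converted to a signed standard-normal deviate.
  n1 <- sum(g); n0 <- sum(!g)
  E1 <- E[g, , drop = FALSE]; E0 <- E[!g, , drop = FALSE]
  m1 <- colMeans(E1); m0 <- colMeans(E0)
  v1 <- (colSums(E1^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(E0^2) - n0 * m0^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- numeric(length(m1))
  df <- rep(1, length(m1))
  pos <- se2 > 0
  t[pos] <- (m1[pos] - m0[pos]) / sqrt(se2[pos])
  df[pos] <- se2[pos]^2 /
    (v1[pos]^2 / (n1^2 * (n1 - 1)) + v0[pos]^2 / (n0^2 * (n0 - 1)))
  # zero pooled variance: equal means -> t = 0; unequal -> +/-Inf
  t[!pos] <- sign(m1[!pos] - m0[!pos]) * Inf
  t[!pos][m1[!pos] == m0[!pos]] <- 0
  t_to_z(t, df)
}

#' Per-timepoint group statistic for event-locked epochs
#'
#' For each participant, computes a Welch t statistic per epoch timepoint
#' contrasting the two label groups across trials, converts it to a
#' signed standard-normal deviate via the probit transform of its tail
#' probability, and combines participants by Stouffer's method with
#' equal weights.  Participants with only one label present are excluded
#' with a message.
#'
#' @param epochs An [extract_epochs()] result, or a numeric matrix
#'   (trials x timepoints).
#' @param labels Binary label per trial (logical, 0/1, or 2-level
#'   factor/character; the contrast is positive class minus the other).
#' @param participants Participant id per trial (a single id is the
#'   degenerate one-participant case).
#' @param analyte Epoch analyte when `epochs` is an `epoch_set`.
#' @return Numeric z series, one value per epoch timepoint, with the
#'   number of contributing participants as attribute `n_participants`.
#' @export
timepoint_statistic <- function(epochs, labels, participants = NULL,
                                analyte = c("da", "sert")) {
  analyte <- match.arg(analyte)
  E <- if (inherits(epochs, "epoch_set")) epochs[[analyte]] else
    as.matrix(epochs)
  if (is.null(participants)) participants <- rep(1L, nrow(E))
  if (length(labels) != nrow(E) || length(participants) != nrow(E)) {
    stopf("labels and participants must have one entry per epoch row")
  }
  g <- labels_to_logical(labels)
  z_by_p <- list()
  for (p in unique(participants)) {
    rows <- participants == p
    if (length(unique(g[rows])) < 2 || sum(g[rows]) < 2 ||
        sum(!g[rows]) < 2) {
      message(sprintf(
        "participant %s excluded: needs >= 2 trials of each label", p))
      next
    }
    z_by_p[[length(z_by_p) + 1]] <- welch_z_series(E[rows, , drop = FALSE],
                                                   g[rows])
  }
  if (!length(z_by_p)) stopf("no participant has both labels")
  z <- Reduce(`+`, z_by_p) / sqrt(length(z_by_p))
  attr(z, "n_participants") <- length(z_by_p)
  z
}

find_clusters <- function(z, thr) {
  supra <- abs(z) > thr
  if (!any(supra)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(
    start = starts[keep], end = ends[keep],
    mass = vapply(which(keep), function(i) {
      sum(abs(z[starts[i]:ends[i]]))
    }, numeric(1)))
}

#' Cluster-based permutation test of event-locked epochs
#'
#' Tests for contiguous epochs of label-dependent signal while
#' controlling family-wise error over timepoints.  Observed clusters are
#' maximal runs of timepoints with |z| above the two-sided
#' cluster-forming threshold \eqn{\Phi^{-1}(1-\alpha/2)}; the cluster
#' statistic is the mass (sum of |z| in the run).  The null distribution
#' of the maximum cluster mass is built by permuting labels within
#' participant; each cluster's p-value is
#' \eqn{(1 + \#\{null \ge mass\})/(1 + n_{perm})}.
#'
#' @inheritParams timepoint_statistic
#' @param n_perm Number of permutations (>= 100).
#' @param cluster_alpha Two-sided cluster-forming alpha (default 0.05).
#' @param seed Seed for the permutation draw.
#' @return An object of class `cluster_result`: `stat_series`,
#'   `epoch_times` (when available), `clusters` (data frame with
#'   `t_start`, `t_end`, `mass`, `p_value`), `null_masses`, `n_perm`,
#'   `cluster_alpha`, `seed`.
#' @export
cluster_permutation_test <- function(epochs, labels, participants = NULL,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     seed = 1, analyte = c("da", "sert")) {
  analyte <- match.arg(analyte)
  E <- if (inherits(epochs, "epoch_set")) epochs[[analyte]] else
    as.matrix(epochs)
  times <- if (inherits(epochs, "epoch_set")) epochs$epoch_times else
    seq_len(ncol(E))
  if (is.null(participants)) participants <- rep(1L, nrow(E))
  if (n_perm < 100) stopf("n_perm must be >= 100")
  g <- labels_to_logical(labels)
  if (length(unique(g)) < 2) stopf("all labels are identical")

  z_obs <- timepoint_statistic(E, g, participants)
  thr <- stats::qnorm(1 - cluster_alpha / 2)
  cl <- find_clusters(z_obs, thr)

  by_p <- split(seq_len(nrow(E)), participants)
  null_masses <- with_seed(substream(seed, 31), {
    vapply(seq_len(n_perm), function(i) {
      gp <- g
      for (rows in by_p) gp[rows] <- gp[rows][sample.int(length(rows))]
      zp <- suppressMessages(tryCatch(
        timepoint_statistic(E, gp, participants),
        error = function(e) NULL))
      if (is.null(zp)) return(0)
      cp <- find_clusters(zp, thr)
      if (nrow(cp)) max(cp$mass) else 0
    }, numeric(1))
  })

  clusters <- data.frame(
    t_start = times[cl$start], t_end = times[cl$end],
    mass = cl$mass,
    p_value = vapply(cl$mass, function(m) {
      (1 + sum(null_masses >= m)) / (1 + n_perm)
    }, numeric(1)))

  structure(
    list(stat_series = as.numeric(z_obs), epoch_times = times,
         clusters = clusters, null_masses = null_masses,
         n_perm = as.integer(n_perm), cluster_alpha = cluster_alpha,
         seed = as.integer(seed), analyte = analyte),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test (%s, %d permutations, alpha %.3g):\n",
    x$analyte, x$n_perm, x$cluster_alpha))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.3f-%.3f s, mass %.2f, p = %.4f\n", i,
                  x$clusters$t_start[i], x$clusters$t_end[i],
                  x$clusters$mass[i], x$clusters$p_value[i]))
    }
  }
  invisible(x)
}
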