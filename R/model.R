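#' Expected divergence under the haploid neutral epimutation model
#'
#' For a haploid two-state (unmethylated/methylated) chain with per-mitosis
#' gain rate `alpha` and loss rate `beta`, two lineages separated from their
#' common ancestor by `t_i` and `t_j` mitoses are in different states with
#' probability
#' \deqn{D = \sum_s P(s)\,[p_s(t_i) + p_s(t_j) - 2\,p_s(t_i)\,p_s(t_j)]}
#' where \eqn{p_s(t) = \pi + (s - \pi)c^t}, \eqn{\pi = \alpha/(\alpha+\beta)},
#' \eqn{c = 1-\alpha-\beta}, and the ancestor is methylated (`s = 1`) with
#' probability `p0` at the pedigree root. When the two lineages split at an
#' internal ancestor `t_anc` mitoses below the root, the ancestor state
#' probability is propagated: \eqn{p_a = \pi + (p_0-\pi)c^{t_{anc}}}. At
#' `p0 = pi` the expression collapses to
#' \eqn{D = 2\pi(1-\pi)(1 - c^{t_i + t_j})}.
#'
#' @param alpha,beta gain/loss rates per unit per mitosis
#'   (`0 < alpha + beta < 1`)
#' @param p0 probability the root ancestor is methylated
#' @param t_i,t_j mitoses from the common ancestor to each lineage
#'   (vectorised; real values allowed via the continuous extension)
#' @param t_anc mitoses from the pedigree root to the common ancestor
#' @return expected per-unit divergence in `[0, 1]`
#' @export
expected_divergence <- function(alpha, beta, p0, t_i, t_j, t_anc = 0) {
  if (alpha + beta <= 0 || alpha + beta >= 1 || alpha < 0 || beta < 0)
    stopf("need 0 < alpha + beta < 1 with alpha, beta >= 0")
  assert_prob(p0, "p0")
  pi_ <- alpha / (alpha + beta)
  c_ <- 1 - alpha - beta
  p_a <- pi_ + (p0 - pi_) * c_^t_anc
  p_m_i <- pi_ + (1 - pi_) * c_^t_i
  p_m_j <- pi_ + (1 - pi_) * c_^t_j
  p_u_i <- pi_ * (1 - c_^t_i)
  p_u_j <- pi_ * (1 - c_^t_j)
  disc <- function(pi, pj) pi + pj - 2 * pi * pj
  p_a * disc(p_m_i, p_m_j) + (1 - p_a) * disc(p_u_i, p_u_j)
}

#' Brute-force expected divergence via transition-matrix powers
#'
#' Independent oracle for [expected_divergence()]: enumerates the two-state
#' chain with repeated one-step matrix multiplication (integer times only).
#'
#' @inheritParams expected_divergence
#' @return expected per-unit divergence
#' @export
brute_force_divergence <- function(alpha, beta, p0, t_i, t_j, t_anc = 0) {
  Pa <- brute_force_transition(alpha, beta, t_anc)
  Pi <- brute_force_transition(alpha, beta, t_i)
  Pj <- brute_force_transition(alpha, beta, t_j)
  anc <- c(1 - p0, p0) %*% Pa  # state distribution at the split
  sum(vapply(1:2, function(s)
    anc[s] * (Pi[s, 1] * Pj[s, 2] + Pi[s, 2] * Pj[s, 1]), numeric(1)))
}

neutral_residuals <- function(par, points, weights = NULL) {
  D <- expected_divergence(par[["alpha"]], par[["beta"]], par[["p0"]],
                           points$t_i, points$t_j, points$t_anc)
  r <- points$d - par[["D0"]] - D
  if (is.null(weights)) sum(r^2) else sum(weights * r^2)
}

#' Fit the haploid neutral epimutation accumulation model
#'
#' Minimises the residual sum of squares of observed pairwise divergences
#' against [expected_divergence()] plus a baseline `D0` absorbing technical
#' (replicate-level) divergence. Optimisation is bounded local search
#' (`nlminb` on log10 rates) from `n_starts` random starts: rates
#' log-uniform on `[1e-9, 1e-2]`, `p0` uniform on `[0, 1]`, `D0` uniform on
#' `[0, max d]`; deterministic given `seed`. Ties are broken by lowest RSS,
#' then lowest alpha. Estimates within tolerance of the box bounds are
#' flagged as boundary-pinned.
#'
#' Divergence data alone cannot orient the two states: the objective is
#' exactly invariant under the global relabeling
#' `(alpha, beta, p0) -> (beta, alpha, 1 - p0)` (and under `pi -> 1 - pi`
#' in the equilibrium-pinned mode). The lowest-alpha tie-break therefore
#' selects the gain-slower-than-loss orientation, the correct one for a
#' genome whose methylated fraction sits below one half, as in
#' heterochromatic fungal methylomes. Pin `p0` from the observed ancestral
#' methylated fraction when that assumption is in doubt.
#'
#' @param points a `divergence_points` data.frame (columns `d`, `t_i`,
#'   `t_j`, `t_anc`; `NA` divergences are dropped)
#' @param n_starts number of random starts (study default 100)
#' @param seed integer seed for the starts
#' @param p0_equilibrium pin `p0 = alpha/(alpha+beta)` (collapses the time
#'   dependence to `t_i + t_j`)
#' @param fix_D0 pin the baseline to this value (e.g. 0) instead of fitting
#' @param weights optional non-negative per-point weights (used by the
#'   cluster bootstrap)
#' @return object of class `epimutation_fit` with elements alpha, beta, p0,
#'   D0, rss, n, k, model = "neutral", boundary_pinned, convergence
#' @export
fit_neutral <- function(points, n_starts = 100L, seed = 1L,
                        p0_equilibrium = FALSE, fix_D0 = NULL,
                        weights = NULL) {
  pts <- prepare_points(points, weights)
  points <- pts$points; weights <- pts$weights
  if (nrow(points) < 4L || length(unique(points$delta_t)) < 3L)
    stopf("need >= 4 points with >= 3 distinct delta_t values")
  maxd <- max(points$d)

  lo <- c(la = -9, lb = -9, p0 = 0, D0 = 0)
  hi <- c(la = log10(0.45), lb = log10(0.45), p0 = 1, D0 = max(maxd, 1e-6))
  obj <- function(th) {
    par <- c(alpha = 10^th[[1]], beta = 10^th[[2]],
             p0 = if (p0_equilibrium) 10^th[[1]] / (10^th[[1]] + 10^th[[2]])
                  else th[[3]],
             D0 = if (is.null(fix_D0)) th[[4]] else fix_D0)
    neutral_residuals(par, points, weights)
  }
  starts <- with_seed(derive_seed(seed, 7L), {
    cbind(la = runif(n_starts, -9, -2), lb = runif(n_starts, -9, -2),
          p0 = runif(n_starts), D0 = runif(n_starts, 0, maxd))
  })
  best <- NULL
  n_fail <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      nlminb(starts[s, ], obj, lower = lo, upper = hi,
             control = list(iter.max = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) { n_fail <- n_fail + 1L; next }
    # near-ties (including the exact mirror-mode symmetry, see Details)
    # resolve to the lowest gain rate
    tol <- max(1e-12, 1e-8 * max(abs(fit$objective),
                                 abs(best$objective %||% 0)))
    if (is.null(best) || fit$objective < best$objective - tol ||
        (abs(fit$objective - best$objective) <= tol &&
         fit$par[[1]] < best$par[[1]]))
      best <- fit
  }
  if (is.null(best)) stopf("optimizer failed on all %d starts", n_starts)

  alpha <- 10^best$par[[1]]; beta <- 10^best$par[[2]]
  p0 <- if (p0_equilibrium) alpha / (alpha + beta) else best$par[[3]]
  D0 <- if (is.null(fix_D0)) best$par[[4]] else fix_D0
  k <- 4L - p0_equilibrium - !is.null(fix_D0)
  pinned <- c(alpha = abs(best$par[[1]] - lo[["la"]]) < 1e-3 ||
                abs(best$par[[1]] - hi[["la"]]) < 1e-3,
              beta = abs(best$par[[2]] - lo[["lb"]]) < 1e-3 ||
                abs(best$par[[2]] - hi[["lb"]]) < 1e-3)
  if (any(pinned))
    warnf("rate estimate at optimisation boundary (%s); fit may be degenerate",
          paste(names(pinned)[pinned], collapse = ", "))
  structure(list(alpha = alpha, beta = beta, p0 = p0, D0 = D0,
                 rss = best$objective, n = nrow(points), k = k,
                 model = "neutral", boundary_pinned = pinned,
                 convergence = best$convergence, n_failed_starts = n_fail,
                 points = points, weights = weights),
            class = "epimutation_fit")
}

prepare_points <- function(points, weights = NULL) {
  stopifnot(all(c("d", "t_i", "t_j") %in% names(points)))
  if (is.null(points$t_anc)) points$t_anc <- 0
  if (is.null(points$delta_t)) points$delta_t <- points$t_i + points$t_j
  drop <- is.na(points$d)
  if (any(drop)) {
    warnf("dropping %d points with undefined divergence", sum(drop))
    points <- points[!drop, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[!drop]
  }
  list(points = points, weights = weights)
}

#' Fit the null model of no epimutation accumulation
#'
#' Divergence is a constant (its weighted mean), independent of the number
#' of mitoses separating a pair.
#'
#' @inheritParams fit_neutral
#' @return an `epimutation_fit` with model = "null" (`k = 1`)
#' @export
fit_null <- function(points, weights = NULL) {
  pts <- prepare_points(points, weights)
  points <- pts$points; weights <- pts$weights
  w <- weights %||% rep(1, nrow(points))
  mu <- sum(w * points$d) / sum(w)
  structure(list(alpha = NA_real_, beta = NA_real_, p0 = NA_real_, D0 = mu,
                 rss = sum(w * (points$d - mu)^2), n = nrow(points), k = 1L,
                 model = "null", points = points, weights = weights),
            class = "epimutation_fit")
}

#' Fit a phenomenological logistic growth curve to divergence
#'
#' `d(delta_t) = K / (1 + exp(-r (delta_t - t_m)))`, fitted by bounded
#' least squares from multiple random starts. The logistic cannot yield
#' epimutation rates; it only tests whether divergence grows with time.
#'
#' @inheritParams fit_neutral
#' @return object of class `logistic_fit` with K, r, t_m, rss, n, k
#' @export
fit_logistic <- function(points, n_starts = 100L, seed = 1L) {
  pts <- prepare_points(points)
  points <- pts$points
  if (nrow(points) < 4L || length(unique(points$delta_t)) < 3L)
    stopf("logistic fit under-determined: need >= 4 points with >= 3 distinct delta_t")
  dt <- points$delta_t; d <- points$d
  maxd <- max(d); maxt <- max(dt)
  obj <- function(th) {
    pred <- th[[1]] / (1 + exp(-th[[2]] * (dt - th[[3]])))
    sum((d - pred)^2)
  }
  lo <- c(K = 1e-8, r = 1e-8, tm = 0)
  hi <- c(K = 2 * max(maxd, 1e-6), r = 1, tm = 2 * max(maxt, 1))
  starts <- with_seed(derive_seed(seed, 8L), {
    cbind(K = runif(n_starts, 0, max(maxd, 1e-6)),
          r = 10^runif(n_starts, -6, -1),
          tm = runif(n_starts, 0, maxt))
  })
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(nlminb(starts[s, ], obj, lower = lo, upper = hi,
                           control = list(iter.max = 500)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stopf("logistic optimizer failed on all starts")
  structure(list(K = best$par[[1]], r = best$par[[2]], t_m = best$par[[3]],
                 rss = best$objective, n = nrow(points), k = 3L,
                 model = "logistic", points = points),
            class = c("logistic_fit", "epimutation_fit"))
}

#' @export
print.epimutation_fit <- function(x, ...) {
  cat(sprintf("%s model fit on %d pairs, RSS %.4g\n", x$model, x$n, x$rss))
  if (x$model == "neutral")
    cat(sprintf("  alpha %.3g  beta %.3g  p0 %.3f  D0 %.4g  (beta/alpha %.2f, equilibrium %.1f%%)\n",
                x$alpha, x$beta, x$p0, x$D0, x$beta / x$alpha,
                100 * x$alpha / (x$alpha + x$beta)))
  if (x$model == "null") cat(sprintf("  constant divergence %.4g\n", x$D0))
  if (x$model == "logistic")
    cat(sprintf("  K %.4g  r %.3g  t_m %.1f\n", x$K, x$r, x$t_m))
  if (!is.null(x$ci)) {
    cat("  bootstrap 95% intervals:\n")
    for (p in rownames(x$ci))
      cat(sprintf("    %-6s [%.3g, %.3g]\n", p, x$ci[p, 1], x$ci[p, 2]))
  }
  invisible(x)
}

#' F-test comparison of nested least-squares fits
#'
#' `F = [(RSS_0 - RSS_1)/(k_1 - k_0)] / [RSS_1/(n - k_1)]` with p from the
#' F distribution on `(k_1 - k_0, n - k_1)` degrees of freedom. Under
#' Gaussian residuals this is equivalent to a likelihood-ratio test.
#'
#' @param fit_null_,fit_alt `epimutation_fit` objects fitted on the same
#'   points, with the null nested in the alternative (fewer parameters)
#' @return object of class `model_comparison`: models, rss_0, rss_1, df,
#'   statistic, p_value
#' @export
compare_models <- function(fit_null_, fit_alt) {
  if (fit_null_$k >= fit_alt$k)
    stopf("models not nested: null must have fewer parameters")
  if (fit_null_$n != fit_alt$n)
    stopf("fits use different numbers of points")
  n <- fit_alt$n; k0 <- fit_null_$k; k1 <- fit_alt$k
  if (n <= k1) stopf("not enough points for the F test")
  Fstat <- max(0, (fit_null_$rss - fit_alt$rss) / (k1 - k0) /
                 (fit_alt$rss / (n - k1)))
  p <- pf(Fstat, k1 - k0, n - k1, lower.tail = FALSE)
  structure(list(models = c(fit_null_$model, fit_alt$model),
                 rss_0 = fit_null_$rss, rss_1 = fit_alt$rss,
                 df = c(k1 - k0, n - k1), statistic = Fstat, p_value = p),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: F(%d, %d) = %.3f, p = %.3g\n",
              x$models[1], x$models[2], x$df[1], x$df[2], x$statistic,
              x$p_value))
  invisible(x)
}

#' Cluster bootstrap confidence intervals for epimutation rates
#'
#' MA lines are resampled with replacement (the line is the independent
#' unit; pairs within a pedigree share lineage and are not independent).
#' Each replicate reweights the pair set by the product of the drawn lines'
#' multiplicities (pairs touching the ancestor use the drawn line's
#' multiplicity; ancestor-ancestor pairs keep weight 1) and refits the
#' model, warm-started at the point estimate. Percentile 2.5/97.5 intervals
#' are attached to the fit.
#'
#' @param fit an `epimutation_fit` from [fit_neutral()]
#' @param n_boot number of bootstrap replicates (study default 1000)
#' @param seed integer seed
#' @param n_starts random starts per refit (in addition to the warm start)
#' @return the fit, augmented with `ci` (matrix with rows alpha, beta, p0,
#'   D0, ratio, equilibrium) and `boot` (replicate estimates)
#' @export
bootstrap_rates <- function(fit, n_boot = 1000L, seed = 1L, n_starts = 10L) {
  stopifnot(is(fit, "epimutation_fit"), fit$model == "neutral")
  points <- fit$points
  if (!all(c("line_i", "line_j") %in% names(points)))
    stopf("points must carry line_i/line_j for the cluster bootstrap")
  lines <- setdiff(unique(c(points$line_i, points$line_j)), "ancestor")
  if (length(lines) < 4L) stopf("cluster bootstrap needs >= 4 MA lines")

  boot <- with_seed(derive_seed(seed, 9L), {
    res <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("alpha", "beta", "p0", "D0")))
    for (b in seq_len(n_boot)) {
      draw <- table(sample(lines, replace = TRUE))
      mult <- setNames(rep(0, length(lines)), lines)
      mult[names(draw)] <- as.numeric(draw)
      wi <- ifelse(points$line_i == "ancestor", 1, mult[points$line_i])
      wj <- ifelse(points$line_j == "ancestor", 1, mult[points$line_j])
      w <- ifelse(points$line_i == points$line_j |
                    points$line_i == "ancestor" |
                    points$line_j == "ancestor",
                  pmax(wi, wj), wi * wj)
      if (sum(w > 0) < 4L) next
      rf <- tryCatch(
        refit_weighted(fit, points, w, n_starts,
                       derive_seed(seed, 10L + b %% 1000L)),
        error = function(e) NULL)
      if (!is.null(rf)) {
        # the divergence objective is invariant under global state
        # relabeling (alpha, beta, p0) <-> (beta, alpha, 1 - p0); align
        # each replicate with the point estimate's mode
        d_same <- abs(log(rf$alpha / fit$alpha)) +
          abs(log(rf$beta / fit$beta))
        d_swap <- abs(log(rf$beta / fit$alpha)) +
          abs(log(rf$alpha / fit$beta))
        if (d_swap < d_same)
          rf <- list(alpha = rf$beta, beta = rf$alpha, p0 = 1 - rf$p0,
                     D0 = rf$D0)
        res[b, ] <- c(rf$alpha, rf$beta, rf$p0, rf$D0)
      }
    }
    res
  })
  ok <- stats::complete.cases(boot)
  if (sum(ok) < 2L) stopf("bootstrap refits failed")
  est <- c(alpha = fit$alpha, beta = fit$beta, p0 = fit$p0, D0 = fit$D0)
  derived <- cbind(ratio = boot[, "beta"] / boot[, "alpha"],
                   equilibrium = boot[, "alpha"] /
                     (boot[, "alpha"] + boot[, "beta"]))
  allb <- cbind(boot, derived)[ok, , drop = FALSE]
  ci <- t(apply(allb, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  fit$ci <- ci
  fit$boot <- allb
  fit$n_boot_ok <- sum(ok)
  fit
}

refit_weighted <- function(fit, points, w, n_starts, seed) {
  keep <- w > 0
  sub <- points[keep, , drop = FALSE]
  wv <- w[keep]
  # warm start at the point estimate plus random starts
  lo <- c(la = -9, lb = -9, p0 = 0, D0 = 0)
  maxd <- max(sub$d)
  hi <- c(la = log10(0.45), lb = log10(0.45), p0 = 1, D0 = max(maxd, 1e-6))
  obj <- function(th) {
    neutral_residuals(c(alpha = 10^th[[1]], beta = 10^th[[2]],
                        p0 = th[[3]], D0 = th[[4]]), sub, wv)
  }
  starts <- rbind(c(log10(fit$alpha), log10(fit$beta), fit$p0,
                    min(fit$D0, hi[["D0"]])),
                  with_seed(seed, cbind(runif(n_starts, -9, -2),
                                        runif(n_starts, -9, -2),
                                        runif(n_starts),
                                        runif(n_starts, 0, maxd))))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    f <- tryCatch(nlminb(starts[s, ], obj, lower = lo, upper = hi,
                         control = list(iter.max = 500)),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$objective)) next
    if (is.null(best) || f$objective < best$objective) best <- f
  }
  if (is.null(best)) stopf("weighted refit failed")
  list(alpha = 10^best$par[[1]], beta = 10^best$par[[2]],
       p0 = best$par[[3]], D0 = best$par[[4]])
}

#' Equilibrium methylated fraction
#'
#' Under the gain/loss chain the methylated fraction converges to
#' `pi = alpha / (alpha + beta)` regardless of the starting state.
#'
#' @param alpha,beta gain/loss rates (`alpha + beta > 0`)
#' @return list with `fraction` (in `[0, 1]`) and `percent` (rounded to the
#'   nearest integer, for display)
#' @export
equilibrium_fraction <- function(alpha, beta) {
  if (alpha + beta <= 0) stopf("equilibrium undefined: alpha + beta must be > 0")
  if (alpha < 0 || beta < 0) stopf("rates must be non-negative")
  f <- alpha / (alpha + beta)
  list(fraction = f, percent = round(100 * f))
}

#' Loss/gain rate ratio beta/alpha
#' @param alpha,beta gain/loss rates (`alpha > 0`)
#' @param digits decimals for the reported value (2, matching convention)
#' @return `beta/alpha` rounded to `digits`
#' @export
rate_ratio <- function(alpha, beta, digits = 2) {
  if (alpha <= 0) stopf("rate ratio undefined for alpha <= 0")
  round(beta / alpha, digits)
}
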