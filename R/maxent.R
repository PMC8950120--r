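#' Modulation weights of a constrained ensemble
#'
#' The maximal-constrained-entropy ensemble closest (in relative entropy) to
#' the metastatistics under an imposed CV average is an exponential tilt of
#' the frame probabilities: P_g proportional to Ptilde_g * exp(-lambda xi_g).
#' Weights are accumulated in the log domain (max-shifted), so no overflow
#' occurs for |lambda xi| up to ~700.
#'
#' @param meta a [meta_ensemble].
#' @param lam the Lagrange multiplier lambda (inverse-CV units).
#' @return Per-frame probabilities summing to 1.
#' @export
modulation_weights <- function(meta, lam) {
  lw <- log(frame_probs(meta)) - lam * meta$frames$cv
  m <- max(lw)
  w <- exp(lw - m)
  w / sum(w)
}

#' log of the tilted partition function ln Z_lambda
#' @noRd
log_z_lambda <- function(meta, lam) {
  logsumexp(log(frame_probs(meta)) - lam * meta$frames$cv)
}

#' Modulated (constrained) ensemble average
#'
#' <B>_lambda = sum_g P_g(lambda) B_g, the average of any configurational
#' quantity under the tilted ensemble.
#'
#' @param meta a [meta_ensemble].
#' @param lam lambda.
#' @param observable observable name in the schema, "cv", or a per-frame
#'   numeric vector.
#' @return Scalar average.
#' @export
constrained_average <- function(meta, lam, observable) {
  b <- get_observable(meta, observable)
  sum(modulation_weights(meta, lam) * b)
}

#' @noRd
tilted_mean_var <- function(meta, lam) {
  w <- modulation_weights(meta, lam)
  xi <- meta$frames$cv
  m <- sum(w * xi)
  list(mean = m, var = sum(w * (xi - m)^2))
}

#' Solve for the Lagrange multiplier of an imposed CV average
#'
#' Finds lambda such that the tilted ensemble average of the CV equals the
#' target s, by Levenberg-Marquardt minimization of
#' chi^2 = (<xi>_lambda - s)^2 / sigma^2 (sigma^2 = 1 by convention) with the
#' analytic derivative d<xi>/dlambda = -Var_lambda(xi). Convergence is
#' declared when the relative chi^2 change between iterations falls below
#' `tol`. If the LM step stalls, a bracketed monotone root search on
#' <xi>_lambda - s is used as fallback (valid because the map is strictly
#' decreasing).
#'
#' @param meta a [meta_ensemble].
#' @param s target imposed average; must lie strictly inside the sampled CV
#'   range.
#' @param tol relative chi^2 change declaring convergence (default 1e-4).
#' @param max_iter iteration cap.
#' @param sigma2 variance in the chi^2 denominator (default 1).
#' @return An object of class `constraint_solution` with elements `s`, `lam`,
#'   `logZ`, `entropy` (the maximal cross-entropy, <= 0), `chi2`,
#'   `iterations`, `converged`, `lam_error` (NA until set by
#'   [lambda_error()]).
#' @export
solve_lambda <- function(meta, s, tol = 1e-4, max_iter = 100L, sigma2 = 1) {
  xi <- meta$frames$cv
  lo <- min(xi); hi <- max(xi)
  if (s <= lo || s >= hi)
    stopf("constraint unreachable: s = %g outside sampled CV range (%g, %g)", s, lo, hi)
  v0 <- tilted_mean_var(meta, 0)
  if (v0$var <= 0) stopf("degenerate ensemble: CV variance is zero")
  resid_fn <- function(p) (tilted_mean_var(meta, p)$mean - s) / sqrt(sigma2)
  jac_fn <- function(p) {
    v <- tilted_mean_var(meta, p)$var
    if (v <= 0) stopf("degenerate ensemble: zero CV variance at lambda = %g", p)
    matrix(-v / sqrt(sigma2), 1, 1)
  }
  fit <- minpack.lm::nls.lm(par = 0, fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = tol, maxiter = max_iter))
  lam <- unname(fit$par)
  iterations <- fit$niter
  resid <- tilted_mean_var(meta, lam)$mean - s
  stalled <- !(fit$info %in% 1:4) || !is.finite(resid) ||
    abs(resid) > 1e-8 * max(1, abs(s))
  if (stalled) {
    # monotone fallback: expand a bracket on <xi>_lam - s, then root-find
    g <- function(l) tilted_mean_var(meta, l)$mean - s
    span <- 1
    while (g(-span) < 0 && span < 1e8) span <- span * 2
    lo_b <- -span
    span <- 1
    while (g(span) > 0 && span < 1e8) span <- span * 2
    root <- stats::uniroot(g, c(lo_b, span), tol = 1e-12)
    lam <- root$root
    iterations <- iterations + root$iter
    resid <- g(lam)
  }
  chi2 <- resid^2 / sigma2
  converged <- is.finite(resid) && abs(resid) <= 1e-6 * max(1, abs(s))
  logZ <- log_z_lambda(meta, lam)
  entropy <- logZ + lam * s
  structure(list(s = s, lam = lam, logZ = logZ, entropy = entropy,
                 chi2 = chi2, iterations = iterations,
                 lam_error = NA_real_, converged = converged),
            class = "constraint_solution")
}

#' @export
print.constraint_solution <- function(x, ...) {
  cat(sprintf("constraint <xi> = %g: lambda = %.6g, Sc = %.6g, chi2 = %.3g (%s, %d iter)\n",
              x$s, x$lam, x$entropy, x$chi2,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Propagated error on lambda
#'
#' The sensitivity of the imposed average to lambda is
#' ds/dlambda = -Var_lambda(xi); an uncertainty on the target average maps to
#' lambda as s_error / |ds/dlambda|. The error diverges where the variance
#' underflows (sharply peaked modulated ensembles) and is flagged infinite.
#'
#' @param meta a [meta_ensemble].
#' @param sol a converged `constraint_solution`.
#' @param s_error uncertainty on the imposed average.
#' @return The propagated uncertainty on lambda (possibly `Inf`).
#' @export
lambda_error <- function(meta, sol, s_error) {
  if (!inherits(sol, "constraint_solution") || !sol$converged)
    stopf("lambda_error requires a converged constraint_solution")
  if (s_error == 0) return(0)
  v <- tilted_mean_var(meta, sol$lam)$var
  if (v <= .Machine$double.xmin) return(Inf)
  abs(s_error) / v
}

#' Free-energy profile over a grid of imposed CV averages
#'
#' F(s) = <H>_lambda(s) - T kB Sc(s), with H an enthalpy-like observable and
#' Sc the maximal cross-entropy of the constraint, then shifted so that
#' F(reference_s) = 0. This is the informational free energy of modulating
#' the metastatistics, not the potential of mean force of standard
#' metadynamics.
#'
#' @param meta a [meta_ensemble].
#' @param cfg a [run_config] (grid, temperature, kB, reference_s).
#' @param enthalpy_key observable name used as H (kcal/mol), or a per-frame
#'   numeric vector.
#' @param blocking optional [blocking_scheme]; when given, per-point errors
#'   on <H> are estimated by block analysis at the solved lambda.
#' @return An object of class `fes_profile`: data.frame `grid` with columns
#'   s, lambda, Sc, mean_H, F, F_err plus the per-point solutions.
#' @export
free_energy_profile <- function(meta, cfg, enthalpy_key = "H", blocking = NULL) {
  H <- get_observable(meta, enthalpy_key)
  grid <- sort(unique(c(cfg$cv_grid, cfg$reference_s)))
  xi_rng <- range(meta$frames$cv)
  bad <- grid[grid <= xi_rng[1] | grid >= xi_rng[2]]
  if (length(bad))
    stopf("unreachable grid point(s) outside sampled CV range (%g, %g): %s",
          xi_rng[1], xi_rng[2], paste(bad, collapse = ", "))
  sols <- lapply(grid, function(s) solve_lambda(meta, s))
  mean_H <- vapply(seq_along(grid), function(i)
    constrained_average(meta, sols[[i]]$lam, H), numeric(1))
  Sc <- vapply(sols, `[[`, numeric(1), "entropy")
  lam <- vapply(sols, `[[`, numeric(1), "lam")
  Fv <- mean_H - cfg$temperature * cfg$kB * Sc
  ref <- which(abs(grid - cfg$reference_s) < 1e-9)[1]
  Fv <- Fv - Fv[ref]
  err <- rep(NA_real_, length(grid))
  if (!is.null(blocking))
    err <- vapply(seq_along(grid), function(i)
      block_error(meta, blocking, sols[[i]]$lam, H), numeric(1))
  keep <- grid %in% cfg$cv_grid | seq_along(grid) == ref
  out <- data.frame(s = grid, lambda = lam, Sc = Sc, mean_H = mean_H,
                    F = Fv, F_err = err)[keep, ]
  structure(list(grid = out, temperature = cfg$temperature,
                 reference_s = cfg$reference_s,
                 enthalpy_key = if (is.character(enthalpy_key)) enthalpy_key else "<vector>",
                 per_point = sols[keep]),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf("free-energy profile, T = %g K, F(%g) = 0:\n",
              x$temperature, x$reference_s))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Stride-offset blocking scheme
#'
#' Block b (b = 1..n_blocks) is the strided subsample starting at frame
#' offset b: indices b, b + stride, b + 2 stride, ... With
#' n_blocks == stride the blocks partition the trajectory.
#'
#' @param n_blocks number of blocks (default 100).
#' @param block_size frames per block (default 9000).
#' @param stride subsampling stride (default 100).
#' @return An object of class `blocking_scheme`.
#' @export
blocking_scheme <- function(n_blocks = 100L, block_size = 9000L, stride = 100L) {
  if (n_blocks > stride)
    stopf("n_blocks (%d) must be <= stride (%d): offsets beyond the stride reuse frames",
          n_blocks, stride)
  structure(list(n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 stride = as.integer(stride)),
            class = "blocking_scheme")
}

#' Block error of a constrained average
#'
#' Computes the constrained average of the observable at fixed lambda within
#' each stride-offset block, and returns the root-mean-square deviation of
#' the block averages about their mean (the spread across blocks). The
#' standard error of the pooled mean (spread / sqrt(n_blocks)) is available
#' via `method = "sem"`.
#'
#' @param meta a [meta_ensemble].
#' @param scheme a [blocking_scheme].
#' @param lam lambda at which block averages are computed.
#' @param observable observable name or per-frame vector.
#' @param method "sd" (default; RMS deviation across blocks) or "sem".
#' @return Scalar error estimate.
#' @export
block_error <- function(meta, scheme, lam, observable, method = c("sd", "sem")) {
  method <- match.arg(method)
  b <- get_observable(meta, observable)
  n <- nrow(meta$frames)
  need <- scheme$n_blocks + (scheme$block_size - 1L) * scheme$stride
  if (n < need)
    stopf("trajectory too short for blocking: %d frames, need >= %d", n, need)
  lw_all <- log(meta$weights) - lam * meta$frames$cv
  avgs <- vapply(seq_len(scheme$n_blocks), function(off) {
    idx <- off + scheme$stride * (seq_len(scheme$block_size) - 1L)
    lw <- lw_all[idx]
    w <- exp(lw - max(lw))
    sum(w * b[idx]) / sum(w)
  }, numeric(1))
  dev <- sqrt(mean((avgs - mean(avgs))^2))
  if (method == "sem") dev / sqrt(scheme$n_blocks) else dev
}

#' Constrained energy-component differences between two imposed states
#'
#' For each named component U, Delta U = <U>_lambda(s_lo) - <U>_lambda(s_hi):
#' the change upon moving the imposed average from the reference (s_hi,
#' folded) to the target (s_lo, unfolded). When a reference ensemble is
#' supplied (e.g. the wild type), second-level differences
#' DeltaDelta = Delta - Delta_ref are reported as well.
#'
#' @param meta a [meta_ensemble].
#' @param cfg a [run_config].
#' @param s_hi reference imposed average (default 14).
#' @param s_lo target imposed average (default 4).
#' @param components character vector of observable names.
#' @param reference optional [meta_ensemble] for DeltaDelta.
#' @return data.frame with columns component, delta (and delta_delta).
#' @export
component_differences <- function(meta, cfg, s_hi = 14, s_lo = 4,
                                  components, reference = NULL) {
  miss <- setdiff(components, meta$schema)
  if (length(miss)) stopf("missing component(s): %s", paste(miss, collapse = ", "))
  one <- function(m) {
    if (s_hi == s_lo) return(stats::setNames(rep(0, length(components)), components))
    l_hi <- solve_lambda(m, s_hi)$lam
    l_lo <- solve_lambda(m, s_lo)$lam
    vapply(components, function(cp)
      constrained_average(m, l_lo, cp) - constrained_average(m, l_hi, cp),
      numeric(1))
  }
  d <- one(meta)
  out <- data.frame(component = components, delta = unname(d))
  if (!is.null(reference)) out$delta_delta <- unname(d - one(reference))
  out
}
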