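#' Analytic 1-D toy models for the sampler
#'
#' The collective variable is the coordinate itself. Supported potentials:
#' `harmonic` (params: k, kcal/mol/A^2), `double_well`
#' (params: h barrier scale, tilt linear asymmetry:
#' U = h (x^2 - 1)^2 + tilt x, kcal/mol) and `poly` (params: coef, ascending
#' polynomial coefficients).
#'
#' @param potential one of "harmonic", "double_well", "poly".
#' @param params named list of potential parameters.
#' @param temperature K.
#' @param friction gamma*m in 1/ps (mobility = 1/friction); the overdamped
#'   limit is simulated, so only this product matters.
#' @param timestep ps, > 0.
#' @return An object of class `toy_model` with `U` and `dU` functions.
#' @export
toy_model <- function(potential = c("double_well", "harmonic", "poly"),
                      params = list(), temperature = 300, friction = 1,
                      timestep = 0.005) {
  potential <- match.arg(potential)
  if (timestep <= 0) stopf("timestep must be > 0")
  if (friction <= 0) stopf("friction must be > 0")
  p <- params
  fns <- switch(potential,
    harmonic = {
      k <- p$k %||% 5
      list(U = function(x) 0.5 * k * x^2, dU = function(x) k * x)
    },
    double_well = {
      h <- p$h %||% 5; tilt <- p$tilt %||% 1
      list(U = function(x) h * (x^2 - 1)^2 + tilt * x,
           dU = function(x) 4 * h * x * (x^2 - 1) + tilt)
    },
    poly = {
      cf <- p$coef
      if (is.null(cf)) stopf("poly potential needs params$coef")
      dcf <- cf[-1] * seq_along(cf[-1])
      list(U = function(x) drop(outer(x, seq_along(cf) - 1, "^") %*% cf),
           dU = function(x) drop(outer(x, seq_along(dcf) - 1, "^") %*% dcf))
    })
  structure(list(potential = potential, params = p, U = fns$U, dU = fns$dU,
                 temperature = temperature, friction = friction,
                 timestep = timestep),
            class = "toy_model")
}

#' Staging schedule for the toy walkers
#'
#' Ordered stages of (duration in steps, bias deposition on/off, altruistic
#' alpha and w applied at the stage start, deposition interval). The final
#' stage must have deposition off: it is the fixed-bias collection stage that
#' provides the metastatistics.
#'
#' @param stages data.frame with columns duration, bias_on, alpha, w,
#'   deposit_every.
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(stages) {
  req <- c("duration", "bias_on", "alpha", "w", "deposit_every")
  miss <- setdiff(req, names(stages))
  if (length(miss)) stopf("schedule lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(stages$duration < 0)) stopf("stage durations must be >= 0")
  if (stages$bias_on[nrow(stages)])
    stopf("final stage must have deposition off (fixed-bias collection)")
  structure(list(stages = stages), class = "stage_schedule")
}

#' Default schedule: equilibrate, five altruistic biased stages, collection
#'
#' Mirrors the staging proportions of altruistic multi-walker runs:
#' unbiased equilibration, four biased stages with alpha stepping through
#' 0, 0.25, 0.5, 0.75 at w = 1, a long biased stage at alpha = 1, w = 0.5,
#' and a final fixed-bias collection stage.
#'
#' @param scale multiplies every stage duration (default 1 gives 168,000
#'   steps total, enough for the deposited bias to fill a ~6 kcal/mol well).
#' @param deposit_every deposition interval in steps (default 200).
#' @return A [stage_schedule].
#' @export
default_schedule <- function(scale = 1, deposit_every = 200L) {
  st <- data.frame(
    duration = as.integer(round(scale * c(32000, 8000, 8000, 8000, 8000, 32000, 40000))),
    bias_on = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    alpha = c(0, 0, 0.25, 0.5, 0.75, 1, 0),
    w = c(1, 1, 1, 1, 1, 0.5, 1),
    deposit_every = deposit_every)
  stage_schedule(st)
}

#' Run multiple-walker biased Langevin dynamics on a toy model
#'
#' Overdamped Euler-Maruyama updates
#' x <- x - dU_total/dx * dt/friction + sqrt(2 kB T dt / friction) * eta,
#' with U_total the model potential plus each walker's current bias
#' (including any wall). Each walker owns an independent, reproducible noise
#' stream derived from `seed`. Gaussians of the given height/width are
#' deposited on each walker's own bias at its current position; at every
#' stage boundary the altruistic combination with that stage's (alpha, w) is
#' applied. Frames are recorded only during the final (fixed-bias) stage,
#' with the toy potential energy stored as observable "H".
#'
#' @param model a [toy_model].
#' @param n_walkers number of replicas (default 8).
#' @param schedule a [stage_schedule] (default [default_schedule()]).
#' @param seed integer seed.
#' @param x0 starting positions (recycled; default alternating -1, 1).
#' @param height,width deposited gaussian height (kcal/mol) and width (CV).
#' @param wall optional wall list as in [bias_potential()].
#' @param sample_every record a frame every this many steps in the final
#'   stage (default 10).
#' @param bound abort if |x| exceeds this (divergence guard, default 50).
#' @return List with `meta` (a [meta_ensemble]) and `biases` (per-walker
#'   [bias_potential] objects as of the collection stage).
#' @export
run_walkers <- function(model, n_walkers = 8L, schedule = default_schedule(),
                        seed = 1L, x0 = NULL, height = 0.12, width = 0.15,
                        wall = NULL, sample_every = 10L, bound = 50) {
  if (n_walkers < 1) stopf("need at least one walker")
  st <- schedule$stages
  dt <- model$timestep
  mob <- 1 / model$friction
  kT <- KB_KCAL * model$temperature
  sig <- sqrt(2 * kT * dt * mob)
  if (is.null(x0)) x0 <- rep_len(c(-1, 1), n_walkers)
  x <- rep_len(x0, n_walkers)
  total_steps <- sum(st$duration)
  # per-walker reproducible noise streams
  noise <- matrix(0, total_steps, n_walkers)
  for (i in seq_len(n_walkers)) {
    set.seed(seed + i - 1L)
    noise[, i] <- stats::rnorm(total_steps)
  }
  # bias bookkeeping: shared center list, per-walker height matrix (exact
  # altruistic mixing without blowup), plus a value/derivative grid for the
  # dynamics
  glo <- -3; ghi <- 3; gh <- 0.01
  gx <- seq(glo, ghi, by = gh)
  Vg <- matrix(0, length(gx), n_walkers)   # bias value on grid, per walker
  Dg <- matrix(0, length(gx), n_walkers)   # bias derivative on grid
  centers <- numeric(0)
  Hmat <- NULL  # heights: rows = centers, cols = walkers
  gauss_add <- function(c0) {
    v <- height * exp(-(gx - c0)^2 / (2 * width^2))
    list(v = v, d = -v * (gx - c0) / width^2)
  }
  wall_force <- function(xx) {
    if (is.null(wall)) return(0)
    act <- if ((wall$side %||% "below") == "below") xx < wall$xi0 else xx > wall$xi0
    f <- numeric(length(xx))
    f[act] <- wall$k * (xx[act] - wall$xi0)
    f
  }
  interp_d <- function(xx) {
    ii <- pmin(pmax(floor((xx - glo) / gh) + 1L, 1L), length(gx) - 1L)
    t <- (xx - gx[ii]) / gh
    col <- seq_len(n_walkers)
    Dg[cbind(ii, col)] * (1 - t) + Dg[cbind(ii + 1L, col)] * t
  }
  rec_x <- rec_w <- rec_t <- NULL
  step_global <- 0L
  for (sg in seq_len(nrow(st))) {
    if (st$alpha[sg] > 0 && length(centers)) {
      # altruistic mixing at stage start
      a <- st$alpha[sg]; ww <- st$w[sg]
      mean_h <- rowMeans(Hmat)
      Hmat <- (1 - a) * Hmat + a * ww * matrix(mean_h, nrow(Hmat), n_walkers)
      Vg <- (1 - a) * Vg + a * ww * matrix(rowMeans(Vg), nrow(Vg), n_walkers)
      Dg <- (1 - a) * Dg + a * ww * matrix(rowMeans(Dg), nrow(Dg), n_walkers)
    }
    collecting <- !st$bias_on[sg] && sg == nrow(st)
    if (collecting) {
      n_rec <- st$duration[sg] %/% sample_every
      rec_x <- matrix(NA_real_, n_rec, n_walkers)
      rec_t <- numeric(n_rec)
      ri <- 0L
    }
    for (k in seq_len(st$duration[sg])) {
      step_global <- step_global + 1L
      force <- -model$dU(x) - interp_d(x) - wall_force(x)
      x <- x + force * dt * mob + sig * noise[step_global, ]
      if (any(abs(x) > bound))
        stopf("divergent trajectory (|x| > %g) at step %d: reduce the timestep",
              bound, step_global)
      if (st$bias_on[sg] && k %% st$deposit_every[sg] == 0L) {
        for (i in seq_len(n_walkers)) {
          ga <- gauss_add(x[i])
          Vg[, i] <- Vg[, i] + ga$v
          Dg[, i] <- Dg[, i] + ga$d
        }
        centers <- c(centers, x)
        add <- matrix(0, n_walkers, n_walkers)
        diag(add) <- height
        Hmat <- if (is.null(Hmat)) add else rbind(Hmat, add)
      }
      if (collecting && k %% sample_every == 0L) {
        ri <- ri + 1L
        rec_x[ri, ] <- x
        rec_t[ri] <- step_global * dt
      }
    }
  }
  biases <- lapply(seq_len(n_walkers), function(i) {
    if (!length(centers)) return(bias_potential(wall = wall))
    keep <- Hmat[, i] != 0
    bias_potential(centers[keep], Hmat[keep, i], width, wall = wall)
  })
  if (is.null(rec_x) || !nrow(rec_x)) {
    meta <- NULL
  } else {
    frames <- data.frame(
      walker = rep(seq_len(n_walkers), each = nrow(rec_x)),
      time = rep(rec_t, n_walkers),
      cv = as.vector(rec_x))
    frames$H <- model$U(frames$cv)
    meta <- meta_ensemble(frames,
                          provenance = sprintf("toy %s, %d walkers, seed %d",
                                               model$potential, n_walkers, seed))
  }
  list(meta = meta, biases = biases)
}

#' Analytic Boltzmann reference for a toy model
#'
#' Normalized Boltzmann probability p(s) and potential of mean force
#' F(s) = -kB T ln p(s) (shifted to min 0) on the grid, by trapezoid
#' quadrature of exp(-U/kB T) over a range generously covering the grid.
#'
#' @param model a [toy_model].
#' @param s_grid evaluation points.
#' @param lim integration half-range (default covers the grid plus 2).
#' @param n_quad quadrature points (default 20001).
#' @return data.frame with s, p (density), F (kcal/mol).
#' @export
analytic_reference <- function(model, s_grid, lim = NULL, n_quad = 20001L) {
  kT <- KB_KCAL * model$temperature
  if (is.null(lim)) lim <- max(abs(s_grid)) + 2
  xq <- seq(-lim, lim, length.out = n_quad)
  Uq <- model$U(xq)
  if (any(!is.finite(Uq))) stopf("potential not finite on the quadrature range")
  if (min(Uq) < min(model$U(s_grid)) - 1e3)
    stopf("potential appears unbounded below on the quadrature range")
  lw <- -(Uq - min(Uq)) / kT
  Z <- sum(exp(lw)) * (xq[2] - xq[1])
  p <- exp(-(model$U(s_grid) - min(Uq)) / kT) / Z
  Fv <- model$U(s_grid) - min(model$U(s_grid))
  data.frame(s = s_grid, p = p, F = Fv)
}

#' Exact-quadrature constrained-entropy profile for a toy metastatistics
#'
#' Independent oracle for the end-to-end pipeline: treats the continuous
#' density ptilde(x) proportional to exp(-(U + V)/kB T) as the
#' metastatistics, solves the tilt lambda for each imposed average by
#' root-finding on the quadrature grid, and evaluates
#' F(s) = <U>_lambda - T kB Sc(s) exactly (up to quadrature error).
#'
#' @param model a [toy_model].
#' @param bias a [bias_potential] (the fixed collection-stage bias).
#' @param s_grid imposed averages.
#' @param reference_s zero point of the profile.
#' @param lim,n_quad quadrature range and size.
#' @return data.frame with s, lambda, Sc, mean_H, F.
#' @export
constrained_profile_reference <- function(model, bias, s_grid, reference_s,
                                          lim = 2.5, n_quad = 8001L) {
  kT <- KB_KCAL * model$temperature
  xq <- seq(-lim, lim, length.out = n_quad)
  Uq <- model$U(xq)
  Vq <- bias_value(bias, xq)
  lw0 <- -(Uq + Vq) / kT
  lw0 <- lw0 - logsumexp(lw0)
  one <- function(s) {
    g <- function(l) {
      lw <- lw0 - l * xq
      w <- exp(lw - max(lw)); w <- w / sum(w)
      sum(w * xq) - s
    }
    span <- 1
    while (g(-span) < 0 && span < 1e7) span <- span * 2
    lo <- -span; span <- 1
    while (g(span) > 0 && span < 1e7) span <- span * 2
    l <- stats::uniroot(g, c(lo, span), tol = 1e-12)$root
    lw <- lw0 - l * xq
    logZ <- logsumexp(lw)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    c(lambda = l, Sc = logZ + l * s, mean_H = sum(w * Uq))
  }
  res <- t(vapply(c(s_grid, reference_s), one, numeric(3)))
  Fv <- res[, "mean_H"] - model$temperature * KB_KCAL * res[, "Sc"]
  Fv <- Fv - Fv[length(Fv)]
  data.frame(s = s_grid, lambda = res[seq_along(s_grid), "lambda"],
             Sc = res[seq_along(s_grid), "Sc"],
             mean_H = res[seq_along(s_grid), "mean_H"],
             F = Fv[seq_along(s_grid)])
}
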