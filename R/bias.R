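#' Metadynamics bias potentials
#'
#' A gaussian-sum bias V(xi) = sum_k h_k exp(-(xi - c_k)^2 / (2 w_k^2)), with
#' an optional one-sided harmonic wall U_w = k/2 (xi - xi0)^2 active beyond
#' the threshold, and an optional smoothed form (quartic fit with tangent
#' linear tails) attached by [smooth_bias()]. The gaussian width is the
#' standard-deviation parameter.
#'
#' @param centers CV positions of the deposited gaussians (may be empty).
#' @param heights kcal/mol, recycled (default 1: unit height).
#' @param widths CV units, recycled, > 0 (default 1: unit width).
#' @param wall optional list(k, xi0, side) with side "below" or "above";
#'   k in kcal/mol per CV^2.
#' @return An object of class `bias_potential`.
#' @export
bias_potential <- function(centers = numeric(), heights = 1, widths = 1,
                           wall = NULL) {
  n <- length(centers)
  heights <- rep_len(heights, max(n, 1))[seq_len(n)]
  widths <- rep_len(widths, max(n, 1))[seq_len(n)]
  if (n && any(widths <= 0)) stopf("gaussian widths must be > 0")
  if (!is.null(wall)) {
    if (!all(c("k", "xi0") %in% names(wall))) stopf("wall needs elements k and xi0")
    wall$side <- wall$side %||% "below"
    if (!wall$side %in% c("below", "above")) stopf("wall side must be 'below' or 'above'")
  }
  structure(list(centers = as.numeric(centers), heights = as.numeric(heights),
                 widths = as.numeric(widths), wall = wall, smooth = NULL),
            class = "bias_potential")
}

#' @export
print.bias_potential <- function(x, ...) {
  cat(sprintf("bias_potential: %d gaussians%s%s\n", length(x$centers),
              if (!is.null(x$wall)) sprintf(", wall k=%g at xi0=%g (%s)",
                                            x$wall$k, x$wall$xi0, x$wall$side) else "",
              if (!is.null(x$smooth)) ", smoothed" else ""))
  invisible(x)
}

#' Add deposited gaussians to a bias
#' @param bias a [bias_potential].
#' @param centers,heights,widths gaussians to append.
#' @return The updated bias. Deposition is additive and order-independent.
#' @export
deposit_gaussians <- function(bias, centers, heights = 1, widths = 1) {
  out <- bias_potential(c(bias$centers, centers),
                        c(bias$heights, rep_len(heights, length(centers))),
                        c(bias$widths, rep_len(widths, length(centers))),
                        wall = bias$wall)
  out$smooth <- NULL  # stale after new depositions
  out
}

#' Evaluate a bias potential
#'
#' Raw mode sums the gaussians plus the wall term; smooth mode evaluates the
#' fitted quartic inside the fit range and the tangent linear tails outside
#' (no wall: the tails replace it).
#'
#' @param bias a [bias_potential].
#' @param xi CV value(s).
#' @param use_smooth evaluate the smoothed form (requires [smooth_bias()]).
#' @return kcal/mol value(s).
#' @export
bias_value <- function(bias, xi, use_smooth = FALSE) {
  if (use_smooth) {
    sm <- bias$smooth
    if (is.null(sm)) stopf("smoothed form requested but the bias has not been fitted")
    v <- numeric(length(xi))
    inside <- xi >= sm$fit_lo & xi <= sm$fit_hi
    v[inside] <- drop(outer(xi[inside], 0:4, "^") %*% sm$coef)
    low <- xi < sm$fit_lo
    v[low] <- sm$tail_lo[1] + sm$tail_lo[2] * xi[low]
    highs <- xi > sm$fit_hi
    v[highs] <- sm$tail_hi[1] + sm$tail_hi[2] * xi[highs]
    return(v)
  }
  v <- numeric(length(xi))
  if (length(bias$centers)) {
    d <- outer(xi, bias$centers, "-")
    g <- exp(-sweep(d^2, 2, 2 * bias$widths^2, "/"))
    v <- drop(g %*% bias$heights)
  }
  if (!is.null(bias$wall)) {
    w <- bias$wall
    active <- if (w$side == "below") xi < w$xi0 else xi > w$xi0
    v[active] <- v[active] + w$k / 2 * (xi[active] - w$xi0)^2
  }
  v
}

#' Fit the quartic smoothed form of a bias
#'
#' Least-squares fit of a fourth-order polynomial to the raw gaussian sum
#' sampled at `n_points` equally spaced points across [fit_lo, fit_hi];
#' outside the range the bias continues as the tangent lines at the
#' boundaries, so value and slope are continuous there. The wall term is not
#' part of the fit (the linear tails take its confining role).
#'
#' @param bias a [bias_potential].
#' @param fit_lo,fit_hi fit range (default 1.5 and 15.5).
#' @param n_points number of sample points, >= 5 (default 15).
#' @return The bias with a `smooth` element attached.
#' @export
smooth_bias <- function(bias, fit_lo = 1.5, fit_hi = 15.5, n_points = 15L) {
  if (fit_hi <= fit_lo) stopf("fit_hi must exceed fit_lo")
  if (n_points < 5) stopf("need at least 5 points to determine a quartic")
  x <- seq(fit_lo, fit_hi, length.out = n_points)
  wall_save <- bias$wall
  bias_nw <- bias; bias_nw$wall <- NULL
  y <- bias_value(bias_nw, x)
  X <- outer(x, 0:4, "^")
  coef <- qr.solve(X, y)  # least squares via QR
  pval <- function(t) drop(outer(t, 0:4, "^") %*% coef)
  pder <- function(t) drop(outer(t, 0:3, "^") %*% (coef[2:5] * (1:4)))
  sm <- list(coef = coef, fit_lo = fit_lo, fit_hi = fit_hi,
             tail_lo = c(pval(fit_lo) - pder(fit_lo) * fit_lo, pder(fit_lo)),
             tail_hi = c(pval(fit_hi) - pder(fit_hi) * fit_hi, pder(fit_hi)))
  out <- bias
  out$wall <- wall_save
  out$smooth <- sm
  out
}

#' Altruistic combination of walker biases
#'
#' Each walker's accumulated bias is replaced by a linear combination with
#' the walker-averaged bias: V_i' = (1 - alpha) V_i + alpha w Vbar, with
#' Vbar the plain mean over walkers. alpha = 0 is the identity; w = 1
#' preserves the total (and mean) bias for any alpha.
#'
#' @param biases non-empty list of [bias_potential] objects.
#' @param alpha mixing fraction in 0..1.
#' @param w shrink factor applied to the shared mean, <= 1.
#' @return List of combined [bias_potential] objects (same length).
#' @export
altruistic_combine <- function(biases, alpha, w) {
  if (!length(biases)) stopf("empty bias list")
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  if (alpha == 0) return(biases)
  all_centers <- unlist(lapply(biases, `[[`, "centers"))
  all_heights <- unlist(lapply(biases, `[[`, "heights"))
  all_widths <- unlist(lapply(biases, `[[`, "widths"))
  n <- length(biases)
  lapply(biases, function(b) {
    out <- bias_potential(c(b$centers, all_centers),
                          c((1 - alpha) * b$heights, alpha * w * all_heights / n),
                          c(b$widths, all_widths),
                          wall = b$wall)
    out
  })
}

#' Standard metadynamics free-energy estimate from the bias
#'
#' F(s) - F(s0) = -(V_G(s) - V_G(s0)): in the flat-histogram limit the
#' deposited bias mirrors the underlying free energy.
#'
#' @param bias a [bias_potential].
#' @param s CV value(s).
#' @param s0 reference CV value.
#' @param use_smooth evaluate through the smoothed form.
#' @return kcal/mol value(s).
#' @export
fes_from_bias <- function(bias, s, s0, use_smooth = FALSE) {
  -(bias_value(bias, s, use_smooth) - bias_value(bias, s0, use_smooth))
}

#' Write / read a bias potential
#'
#' Gaussians as a commented TSV (center, height, width); wall and smooth
#' parameters in a JSON sidecar `<path>.json`.
#'
#' @param bias a [bias_potential].
#' @param path TSV path.
#' @export
write_bias <- function(bias, path) {
  con <- file(path, "w")
  writeLines(c("# maxentfes bias potential: center (CV), height (kcal/mol), width (CV)",
               "center\theight\twidth"), con)
  if (length(bias$centers))
    utils::write.table(data.frame(bias$centers, bias$heights, bias$widths),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  close(con)
  side <- list(wall = bias$wall, smooth = bias$smooth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bias
#' @return `read_bias` returns the [bias_potential].
#' @export
read_bias <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path, simplifyVector = TRUE)
          else list()
  b <- bias_potential(df$center, df$height, df$width, wall = side$wall)
  if (!is.null(side$smooth) && length(side$smooth)) {
    sm <- side$smooth
    sm$coef <- as.numeric(sm$coef)
    sm$tail_lo <- as.numeric(sm$tail_lo); sm$tail_hi <- as.numeric(sm$tail_hi)
    b$smooth <- sm
  }
  b
}
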