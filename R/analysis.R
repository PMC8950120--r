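#' Optimal superposition and RMSD (Kabsch)
#'
#' Pairs atoms between the two structures by (residue number, atom name)
#' over the requested selection, centres both sets (geometric or
#' mass-weighted centre), finds the optimal rotation by singular value
#' decomposition with reflection correction, and reports
#' RMSD = sqrt(sum_i m_i |q_i - q_i0|^2 / sum_i m_i) (m_i = 1 unless
#' mass-weighted: backbone heavy atoms have near-equal masses, so the
#' unweighted convention matches standard tools).
#'
#' @param mobile,reference [mol_structure] objects.
#' @param resno_range inclusive residue range c(lo, hi); NULL uses all
#'   shared residues.
#' @param atom_names atom-name selection (default backbone N, CA, C, O).
#' @param mass_weighted logical (default FALSE).
#' @return An object of class `superposition`: `rmsd` (Angstrom),
#'   `rotation` (3x3, det +1), `translation`, `n_atoms`, `mass_weighted`.
#' @export
superpose_rmsd <- function(mobile, reference, resno_range = NULL,
                           atom_names = c("N", "CA", "C", "O"),
                           mass_weighted = FALSE) {
  pick <- function(s) {
    a <- s$atoms
    keep <- a$name %in% atom_names & !a$is_h
    if (!is.null(resno_range))
      keep <- keep & a$resno >= resno_range[1] & a$resno <= resno_range[2]
    a[keep, , drop = FALSE]
  }
  am <- pick(mobile); ar <- pick(reference)
  km <- paste(am$resno, am$name); kr <- paste(ar$resno, ar$name)
  common <- intersect(km, kr)
  unpaired <- c(setdiff(km, kr), setdiff(kr, km))
  if (length(unpaired))
    stopf("selections do not map 1:1; unpaired atoms: %s",
          paste(utils::head(unpaired, 5), collapse = "; "))
  if (length(common) < 3) stopf("need at least 3 paired atoms")
  X <- as.matrix(am[match(common, km), c("x", "y", "z")])
  Y <- as.matrix(ar[match(common, kr), c("x", "y", "z")])
  m <- if (mass_weighted) am$mass[match(common, km)] else rep(1, length(common))
  wm <- m / sum(m)
  cx <- colSums(X * wm); cy <- colSums(Y * wm)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc * wm) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Xr <- Xc %*% t(R)
  rmsd <- sqrt(sum(wm * rowSums((Xr - Yc)^2)))
  structure(list(rmsd = rmsd, rotation = R, translation = cy - drop(R %*% cx),
                 n_atoms = length(common), mass_weighted = mass_weighted),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: RMSD = %.3f A (%s)\n",
              x$n_atoms, x$rmsd,
              if (x$mass_weighted) "mass-weighted" else "unweighted"))
  invisible(x)
}

#' Inter-helix axis angle
#'
#' The angle between the unit vectors along CA(94)->CA(112) (helix 1) and
#' CA(184)->CA(191) (helix 2), in [0, 180] degrees. Any four CA anchors can
#' be supplied.
#'
#' @param structure a [mol_structure].
#' @param helix1,helix2 length-2 residue-number vectors (start, end) of the
#'   two direction vectors.
#' @return Angle in degrees.
#' @export
helix_axis_angle <- function(structure, helix1 = c(94, 112), helix2 = c(184, 191)) {
  ca <- function(res) {
    row <- find_atom(structure, res, "CA")
    c(row$x, row$y, row$z)
  }
  v1 <- ca(helix1[2]) - ca(helix1[1])
  v2 <- ca(helix2[2]) - ca(helix2[1])
  u1 <- v1 / sqrt(sum(v1^2)); u2 <- v2 / sqrt(sum(v2^2))
  acos(pmin(pmax(sum(u1 * u2), -1), 1)) * 180 / pi
}

#' Distance between two selected atoms
#'
#' @param structure a [mol_structure].
#' @param sel_a,sel_b selector lists with `resno`, `name` and optional
#'   `chain`.
#' @return Euclidean distance, Angstrom.
#' @export
atom_distance <- function(structure, sel_a, sel_b) {
  g <- function(sel) {
    row <- find_atom(structure, sel$resno, sel$name, sel$chain %||% NULL)
    c(row$x, row$y, row$z)
  }
  sqrt(sum((g(sel_a) - g(sel_b))^2))
}

#' Reweighted histogram of an observable
#'
#' Histogram of the observable with the modulation weights at the given
#' lambda as frame weights -- the machinery behind folded-vs-unfolded
#' (imposed CV 14 vs 4) observable distributions.
#'
#' @param meta a [meta_ensemble].
#' @param lam lambda (0 gives the plain metastatistics histogram).
#' @param observable name or per-frame vector.
#' @param breaks strictly increasing bin edges covering all values.
#' @param s optional imposed average recorded with the result.
#' @return An object of class `reweighted_histogram`: `bin_edges`,
#'   `probabilities` (sum 1), `lam`, `s`, `observable`.
#' @export
reweighted_histogram <- function(meta, lam, observable, breaks, s = NA_real_) {
  if (length(breaks) < 2) stopf("need at least two bin edges")
  if (is.unsorted(breaks, strictly = TRUE)) stopf("bin edges must be strictly increasing")
  b <- get_observable(meta, observable)
  if (any(b < breaks[1] | b > breaks[length(breaks)]))
    stopf("observable values outside the bin range [%g, %g]",
          breaks[1], breaks[length(breaks)])
  w <- modulation_weights(meta, lam)
  bin <- findInterval(b, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- vapply(seq_len(length(breaks) - 1), function(k) sum(w[bin == k]), numeric(1))
  structure(list(observable = if (is.character(observable)) observable else "<vector>",
                 bin_edges = breaks, probabilities = p, lam = lam, s = s),
            class = "reweighted_histogram")
}

#' Relative SASA columns of an ensemble
#'
#' Divides each frame's group SASA by the maximum of that column over the
#' whole metastatistics, giving per-frame values in (0, 1] that are
#' comparable across atom groups of different sizes.
#'
#' @param meta a [meta_ensemble].
#' @param columns observable column names holding group SASA values.
#' @return data.frame of relative values (same column names).
#' @export
relative_sasa <- function(meta, columns) {
  out <- lapply(columns, function(cn) {
    v <- get_observable(meta, cn)
    mx <- max(v)
    if (mx <= 0) stopf("group '%s' has all-zero SASA", cn)
    v / mx
  })
  stats::setNames(as.data.frame(out), columns)
}

#' Synthetic ideal alpha-helix backbone
#'
#' Builds an n-residue poly-alanine backbone (N, CA, C, O, CB) on an ideal
#' alpha-helical wheel (rise 1.5 A per residue, 100 degrees per turn, CA
#' radius 2.3 A), for tests and SASA cross-checks. This is a synthetic
#' construct, not a deposited structure.
#'
#' @param n_res number of residues.
#' @param chain chain id.
#' @return A [mol_structure].
#' @export
build_helix <- function(n_res, chain = "A") {
  rise <- 1.5; twist <- 100 * pi / 180
  mk <- function(i, r, dphi, dz) {
    phi <- (i - 1) * twist + dphi
    c(r * cos(phi), r * sin(phi), (i - 1) * rise + dz)
  }
  rows <- lapply(seq_len(n_res), function(i) {
    pos <- rbind(N = mk(i, 1.6, -0.45, -0.9),
                 CA = mk(i, 2.3, 0, 0),
                 C = mk(i, 1.7, 0.45, 1.0),
                 O = mk(i, 2.0, 0.9, 1.3),
                 CB = mk(i, 3.3, -0.1, -0.2))
    data.frame(name = rownames(pos), resname = "ALA", resno = i, chain = chain,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               element = c("N", "C", "C", "O", "C"), stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$occupancy <- 1
  rownames(at) <- NULL
  mol_structure(at, source = sprintf("synthetic %d-residue helix", n_res))
}
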