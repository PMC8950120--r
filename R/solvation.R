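#' Solvation parameters
#'
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param sphere_points number of test points per atom sphere (default 122),
#'   placed on a deterministic golden-spiral covering, >= 12.
#' @param sigma_table data.frame (element, sigma) of nonpolar surface
#'   coefficients, kcal/(mol A^2); positive for hydrophobic, negative for
#'   hydrophilic groups. NULL loads the shipped defaults.
#' @param radii_table data.frame (element, radius), Angstrom; NULL loads the
#'   shipped defaults.
#' @return An object of class `solvation_params`.
#' @export
solvation_params <- function(probe_radius = 1.4, sphere_points = 122L,
                             sigma_table = NULL, radii_table = NULL) {
  if (probe_radius < 0) stopf("probe radius must be >= 0")
  if (sphere_points < 12) stopf("need at least 12 sphere points")
  if (is.null(sigma_table)) sigma_table <- read_param_table("sasa_sigma.tsv")
  if (is.null(radii_table)) radii_table <- read_param_table("atom_radii.tsv")
  structure(list(probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points),
                 sigma_table = sigma_table, radii_table = radii_table),
            class = "solvation_params")
}

#' Deterministic golden-spiral covering of the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_covering <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * k * (1 + sqrt(5)) / 2
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley style)
#'
#' For each heavy atom, test points on the sphere of radius R + probe are
#' checked against every neighbouring heavy-atom sphere; the exposed
#' fraction times 4 pi (R + probe)^2 is the atom's SASA. Hydrogens have zero
#' radius (their surface is subsumed in the parent heavy atom), contribute
#' zero area and do not occlude. The point set is fixed in the lab frame,
#' so rigid-motion invariance holds to quadrature error (~1% at 122 points).
#'
#' @param structure a [mol_structure]; radii are taken from its `radius`
#'   column if assigned, else from the params table.
#' @param params a [solvation_params].
#' @return List with `per_atom` (Angstrom^2 per atom, 0 for hydrogens) and
#'   `total`.
#' @export
sasa <- function(structure, params = solvation_params()) {
  a <- structure$atoms
  r <- a$radius
  if (all(is.na(r))) {
    tab <- params$radii_table
    r <- tab$radius[match(toupper(a$element), toupper(tab$element))]
  }
  r[a$is_h] <- 0
  if (any(is.na(r)))
    stopf("no radius for atom type(s): %s",
          paste(unique(a$element[is.na(r)]), collapse = ", "))
  heavy <- which(!a$is_h & r > 0)
  pts <- sphere_covering(params$sphere_points)
  rp <- params$probe_radius
  xyz <- cbind(a$x, a$y, a$z)
  per_atom <- numeric(nrow(a))
  if (length(heavy)) {
    hx <- xyz[heavy, , drop = FALSE]
    hr <- r[heavy]
    # pairwise neighbour lists among heavy atoms
    d2 <- as.matrix(stats::dist(hx))^2
    for (ii in seq_along(heavy)) {
      Ri <- hr[ii] + rp
      cutoff <- (Ri + hr + rp)^2
      nb <- which(d2[ii, ] < cutoff & seq_along(heavy) != ii)
      if (!length(nb)) {
        per_atom[heavy[ii]] <- 4 * pi * Ri^2
        next
      }
      p <- sweep(pts * Ri, 2, hx[ii, ], "+")     # test points, lab frame
      exposed <- rep(TRUE, nrow(p))
      for (jj in nb) {
        if (!any(exposed)) break
        Rj2 <- (hr[jj] + rp)^2
        dd <- (p[exposed, 1] - hx[jj, 1])^2 + (p[exposed, 2] - hx[jj, 2])^2 +
              (p[exposed, 3] - hx[jj, 3])^2
        exposed[exposed] <- dd > Rj2
      }
      per_atom[heavy[ii]] <- 4 * pi * Ri^2 * sum(exposed) / nrow(p)
    }
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Nonpolar (surface) solvation energy
#'
#' U_np = sum_i sigma_i SASA_i with element-keyed sigma coefficients.
#'
#' @param areas per-atom areas (Angstrom^2), as returned by [sasa()].
#' @param structure the [mol_structure] the areas belong to.
#' @param params a [solvation_params].
#' @return kcal/mol.
#' @export
nonpolar_solvation <- function(areas, structure, params = solvation_params()) {
  if (is.list(areas)) areas <- areas$per_atom
  a <- structure$atoms
  tab <- params$sigma_table
  sig <- tab$sigma[match(toupper(a$element), toupper(tab$element))]
  sig[a$is_h] <- 0
  if (any(is.na(sig) & areas > 0))
    stopf("no sigma coefficient for atom type(s): %s",
          paste(unique(a$element[is.na(sig) & areas > 0]), collapse = ", "))
  sig[is.na(sig)] <- 0
  sum(sig * areas)
}

#' Poisson-Boltzmann grid
#'
#' @param dims lattice dimensions (default 100^3).
#' @param spacing lattice spacing, Angstrom (default 0.875).
#' @param eps_solute,eps_solvent relative permittivities (defaults 1 and 80).
#' @param ionic_strength 1:1 salt, mol/L (default 0.1; 0 disables screening).
#' @param padding minimum solute-boundary clearance, Angstrom (default 10).
#' @return An object of class `pb_grid`.
#' @export
pb_grid <- function(dims = c(100L, 100L, 100L), spacing = 0.875,
                    eps_solute = 1, eps_solvent = 80,
                    ionic_strength = 0.1, padding = 10) {
  if (spacing <= 0) stopf("spacing must be > 0")
  if (length(dims) == 1) dims <- rep(dims, 3)
  structure(list(dims = as.integer(dims), spacing = spacing,
                 eps_solute = eps_solute, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, padding = padding),
            class = "pb_grid")
}

# inverse Debye length squared (A^-2): kappa^2 = 8 pi e_c I_num / (eps kT)
#' @noRd
kappa2_debye <- function(ionic_strength, eps_solvent, temperature = 300) {
  n_num <- ionic_strength * 6.02214076e-4   # ions/A^3 per mol/L
  8 * pi * COULOMB_KCAL * n_num / (eps_solvent * (KB_KCAL * temperature))
}

#' Polar solvation energy by finite-difference linearized Poisson-Boltzmann
#'
#' Solves the linearized PB equation on a 7-point stencil with per-edge
#' dielectric (harmonic mean weighted by the exact inside-fraction of each
#' lattice edge: eps_solute inside the atomic spheres, eps_solvent with
#' Debye screening elsewhere), Dirichlet boundary values from the
#' Debye-screened Coulomb sum, and a Jacobi-preconditioned
#' conjugate-gradient solver. The Coulomb singularity is split off
#' analytically (phi = phi_coul/eps_solute + psi) and only the smooth
#' reaction field psi is solved on the lattice, which removes the grid
#' self-energy without a matched reference solve:
#' U_pol = 1/2 sum_i q_i psi(r_i).
#'
#' @param structure a [mol_structure] with radii and charges assigned
#'   (see [assign_parameters()]).
#' @param grid a [pb_grid].
#' @param temperature K (enters the Debye length).
#' @param tol relative-residual convergence target (default 1e-6).
#' @param max_iter CG iteration cap.
#' @return List with `energy` (kcal/mol), `iterations`, `residual`.
#' @export
solve_pb <- function(structure, grid, temperature = 300,
                     tol = 1e-6, max_iter = 2000L) {
  a <- structure$atoms
  if (all(is.na(a$charge))) stopf("charges not assigned; run assign_parameters()")
  q <- a$charge
  q[is.na(q)] <- 0
  keep <- which(q != 0 | (!a$is_h & !is.na(a$radius) & a$radius > 0))
  if (!length(keep)) return(list(energy = 0, iterations = 0L, residual = 0))
  xyz <- cbind(a$x, a$y, a$z)
  rad <- a$radius
  rad[is.na(rad) | a$is_h] <- 0
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  h <- grid$spacing
  ctr <- colMeans(xyz[keep, , drop = FALSE])
  # solute centred on the lattice, with the origin snapped so the centre
  # falls on a node (single buried charges then sit on-node, which is the
  # most accurate placement)
  org <- ctr - h * (c(nx, ny, nz) - 1) / 2
  fidx <- (ctr - org) / h
  org <- org + (fidx - round(fidx)) * h
  X <- xyz[keep, , drop = FALSE]
  box_hi <- org + h * (c(nx, ny, nz) - 1)
  clearance <- min(sweep(X, 2, org) - rad[keep],
                   sweep(-X, 2, box_hi, "+") - rad[keep])
  if (clearance < grid$padding)
    stopf("solute touches the boundary: clearance %.1f A < padding %.1f A",
          clearance, grid$padding)
  gx <- org[1] + h * (seq_len(nx) - 1)
  gy <- org[2] + h * (seq_len(ny) - 1)
  gz <- org[3] + h * (seq_len(nz) - 1)
  charged <- which(q != 0)
  solute <- keep[rad[keep] > 0]

  if (!length(charged)) return(list(energy = 0, iterations = 0L, residual = 0))
  eps_in <- grid$eps_solute; eps_out <- grid$eps_solvent
  kap2 <- kappa2_debye(grid$ionic_strength, eps_out, temperature)
  kap <- sqrt(kap2)

  # logical array: lattice points (xs, ys, zs) inside any solute sphere;
  # bounding-box subsetting keeps this O(atoms * (r/h)^3)
  mask_from_spheres <- function(xs, ys, zs) {
    m <- array(FALSE, c(length(xs), length(ys), length(zs)))
    for (s in solute) {
      r2 <- rad[s]^2
      i <- which(abs(xs - xyz[s, 1]) <= rad[s])
      j <- which(abs(ys - xyz[s, 2]) <= rad[s])
      k <- which(abs(zs - xyz[s, 3]) <= rad[s])
      if (!length(i) || !length(j) || !length(k)) next
      d2 <- outer(outer((xs[i] - xyz[s, 1])^2, (ys[j] - xyz[s, 2])^2, "+"),
                  (zs[k] - xyz[s, 3])^2, "+")
      m[i, j, k] <- m[i, j, k] | (d2 <= r2)
    }
    m
  }
  # inside fraction of each lattice edge along `axis`: exact chord overlap
  # per sphere, combined over spheres by the maximum (exact for edges cut by
  # a single sphere, which dominate the cavity boundary)
  edge_fraction <- function(axis) {
    dims <- c(nx, ny, nz); dims[axis] <- dims[axis] - 1L
    f <- array(0, dims)
    gA <- list(gx, gy, gz)[[axis]]
    perp <- setdiff(1:3, axis)
    gP1 <- list(gx, gy, gz)[[perp[1]]]
    gP2 <- list(gx, gy, gz)[[perp[2]]]
    gE <- gA[seq_len(dims[axis])]   # edge start coordinates
    for (s in solute) {
      cA <- xyz[s, axis]; c1 <- xyz[s, perp[1]]; c2 <- xyz[s, perp[2]]
      j <- which(abs(gP1 - c1) <= rad[s]); k <- which(abs(gP2 - c2) <= rad[s])
      i <- which(gE + h >= cA - rad[s] & gE <= cA + rad[s])
      if (!length(i) || !length(j) || !length(k)) next
      p2 <- outer((gP1[j] - c1)^2, (gP2[k] - c2)^2, "+")
      half <- sqrt(pmax(rad[s]^2 - p2, 0))
      for (ii1 in i) {
        x0 <- gE[ii1]; x1 <- x0 + h
        ov <- pmax(pmin(cA + half, x1) - pmax(cA - half, x0), 0) / h
        ov[half == 0] <- 0
        idx <- switch(axis,
                      cbind(ii1, rep(j, times = length(k)), rep(k, each = length(j))),
                      cbind(rep(j, times = length(k)), ii1, rep(k, each = length(j))),
                      cbind(rep(j, times = length(k)), rep(k, each = length(j)), ii1))
        f[idx] <- pmax(f[idx], as.vector(ov))
      }
    }
    f
  }
  # face dielectric: harmonic mean along the connecting edge
  face_eps <- function(axis) {
    f <- edge_fraction(axis)
    1 / (f / eps_in + (1 - f) / eps_out)
  }
  node_outside <- !mask_from_spheres(gx, gy, gz)

  ii <- 2:(nx - 1); jj <- 2:(ny - 1); kk <- 2:(nz - 1)
  interior <- array(FALSE, c(nx, ny, nz)); interior[ii, jj, kk] <- TRUE
  make_apply <- function(ex, ey, ez, screen) {
    diagc <- array(0, c(nx, ny, nz))
    diagc[ii, jj, kk] <-
      ex[ii, jj, kk] + ex[ii - 1, jj, kk] +
      ey[ii, jj, kk] + ey[ii, jj - 1, kk] +
      ez[ii, jj, kk] + ez[ii, jj, kk - 1] +
      if (is.null(screen)) 0 else screen[ii, jj, kk]
    list(diag = diagc, apply = function(p) {
      ap <- array(0, c(nx, ny, nz))
      ap[ii, jj, kk] <- diagc[ii, jj, kk] * p[ii, jj, kk] -
        ex[ii, jj, kk] * p[ii + 1, jj, kk] - ex[ii - 1, jj, kk] * p[ii - 1, jj, kk] -
        ey[ii, jj, kk] * p[ii, jj + 1, kk] - ey[ii, jj - 1, kk] * p[ii, jj - 1, kk] -
        ez[ii, jj, kk] * p[ii, jj, kk + 1] - ez[ii, jj, kk - 1] * p[ii, jj, kk - 1]
      ap
    })
  }
  ex <- face_eps(1); ey <- face_eps(2); ez <- face_eps(3)
  screen <- array(0, c(nx, ny, nz))
  if (kap2 > 0) screen[node_outside] <- eps_out * kap2 * h^2
  A <- make_apply(ex, ey, ez, screen)
  A0 <- make_apply(array(eps_in, c(nx - 1, ny, nz)),
                   array(eps_in, c(nx, ny - 1, nz)),
                   array(eps_in, c(nx, ny, nz - 1)), NULL)

  # singularity splitting: phi = phi_coul(eps_in) + psi; psi (the reaction
  # field) is smooth at the charges, so coarse grids stay accurate.
  rr2 <- function(s) outer(outer((gx - xyz[s, 1])^2, (gy - xyz[s, 2])^2, "+"),
                           (gz - xyz[s, 3])^2, "+")
  phic <- array(0, c(nx, ny, nz))
  psib <- array(0, c(nx, ny, nz))
  for (s in charged) {
    r <- sqrt(pmax(rr2(s), (h / 2)^2))
    phic <- phic + COULOMB_KCAL * q[s] / (eps_in * r)
    psib <- psib + COULOMB_KCAL * q[s] *
      (exp(-kap * r) / eps_out - 1 / eps_in) / r
  }
  rhs <- -(A$apply(phic) - A0$apply(phic))
  bnd <- array(0, c(nx, ny, nz))
  bnd[!interior] <- psib[!interior]
  rhs <- rhs - A$apply(bnd)
  rhs[!interior] <- 0

  # Jacobi-preconditioned conjugate gradients on the interior
  psi <- array(0, c(nx, ny, nz))
  r <- rhs
  Minv <- array(0, c(nx, ny, nz))
  Minv[interior] <- 1 / A$diag[interior]
  zv <- Minv * r
  p <- zv
  rz <- sum(r * zv)
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0) return(list(energy = 0, iterations = 0L, residual = 0))
  iter <- 0L
  res <- Inf
  repeat {
    iter <- iter + 1L
    Ap <- A$apply(p); Ap[!interior] <- 0
    alpha <- rz / sum(p * Ap)
    psi <- psi + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res < tol || iter >= max_iter) break
    zv <- Minv * r
    rz_new <- sum(r * zv)
    p <- zv + (rz_new / rz) * p
    rz <- rz_new
  }
  if (res >= tol)
    stopf("PB solver did not converge: relative residual %.2e after %d iterations",
          res, iter)
  psi[!interior] <- psib[!interior]

  interp_psi <- vapply(charged, function(s) {
    fx <- (xyz[s, 1] - org[1]) / h; fy <- (xyz[s, 2] - org[2]) / h
    fz <- (xyz[s, 3] - org[3]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    v <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wgt <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
             (if (dk) tz else 1 - tz)
      v <- v + wgt * psi[i0 + di + 1, j0 + dj + 1, k0 + dk + 1]
    }
    v
  }, numeric(1))
  e <- 0.5 * sum(q[charged] * interp_psi)
  list(energy = e, iterations = iter, residual = res)
}

#' MM/PBSA-style mean-field energy of a configuration
#'
#' Ubar = U_intra + U_np + U_pol: the intramolecular force-field terms are
#' supplied externally (they are not computed here), the nonpolar term is
#' the sigma-weighted SASA and the polar term the linearized-PB solvation
#' energy. The result can stand in for the enthalpy in
#' [free_energy_profile()].
#'
#' @param structure a [mol_structure] with radii/charges assigned.
#' @param intra_components named numeric vector of intramolecular energies
#'   (kcal/mol), e.g. c(str=, bend=, tors=, vdw=, el=).
#' @param params a [solvation_params].
#' @param grid a [pb_grid].
#' @return List with `total` and the component map.
#' @export
mean_field_energy <- function(structure, intra_components,
                              params = solvation_params(), grid = pb_grid()) {
  if (is.null(names(intra_components)) || !length(intra_components))
    stopf("intra_components must be a named numeric vector (may be zeros)")
  ar <- sasa(structure, params)
  np <- nonpolar_solvation(ar, structure, params)
  pol <- solve_pb(structure, grid)$energy
  comps <- c(as.list(intra_components), list(solv_np = np, solv_pol = pol))
  list(total = sum(unlist(comps)), components = comps)
}
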