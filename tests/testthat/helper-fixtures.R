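# shared fixtures, all built in code

two_state_meta <- function(B = c(0, 10)) {
  meta_ensemble(data.frame(cv = c(0, 1), B = B))
}

random_meta <- function(n, seed) {
  set.seed(seed)
  meta_ensemble(data.frame(cv = runif(n, 0, 16),
                           B = rnorm(n),
                           U_el = rnorm(n, -50, 5)),
                weights = sample(1:3, n, replace = TRUE))
}

# direct enumeration of the tilted-ensemble formulas (independent oracle:
# plain sums, no log-domain tricks)
maxent_enum <- function(meta, lam) {
  p <- meta$weights / sum(meta$weights)
  xi <- meta$frames$cv
  w <- p * exp(-lam * xi)
  Z <- sum(w)
  P <- w / Z
  list(Z = Z, P = P,
       mean_xi = sum(P * xi),
       Sc = -sum(P * log(P / p)),
       avg = function(b) sum(P * b))
}

# minimal synthetic PDB text
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.722   6.803  -4.199  1.00  0.00           C",
    "TER", "END")
  writeLines(lines, path)
  path
}

# single Born ion as a structure
born_ion <- function(q = 1, radius = 2, pos = c(0, 0, 0)) {
  s <- mol_structure(data.frame(serial = 1L, name = "NA", resname = "ION",
                                resno = 1L, chain = "A",
                                x = pos[1], y = pos[2], z = pos[3],
                                element = "NA", stringsAsFactors = FALSE))
  s$atoms$radius <- radius
  s$atoms$charge <- q
  s
}

born_energy <- function(q = 1, radius = 2, eps = 80) {
  -332.0636 * q^2 / (2 * radius) * (1 - 1 / eps)
}

# random rigid motion applied to a structure
rigid_move <- function(structure, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- rnorm(3, sd = 5)
  out <- structure
  xyz <- as.matrix(out$atoms[, c("x", "y", "z")]) %*% t(R)
  out$atoms$x <- xyz[, 1] + tr[1]
  out$atoms$y <- xyz[, 2] + tr[2]
  out$atoms$z <- xyz[, 3] + tr[3]
  out
}

bio3d_example <- function(name) system.file("examples", name, package = "bio3d")

# pooled mean bias of a multi-walker run
mean_bias_of <- function(run) {
  mb <- bias_potential()
  for (b in run$biases)
    mb <- deposit_gaussians(mb, b$centers, b$heights, b$widths)
  mb$heights <- mb$heights / length(run$biases)
  mb
}
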