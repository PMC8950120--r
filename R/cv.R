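#' Rational switching function for coordination numbers
#'
#' s(r) = (1 - x^6) / (1 - x^8) with x = r/d0: a smooth count that is 1 at
#' contact, 3/4 exactly at r = d0 (the n/m limit of the removable
#' singularity) and decays as x^-2 at long range. Strictly decreasing in r.
#'
#' @param r distance(s), Angstrom, >= 0.
#' @param d0 reference distance, Angstrom, > 0.
#' @return Dimensionless value(s) in (0, 1].
#' @export
switching_function <- function(r, d0) {
  if (d0 <= 0) stopf("d0 must be > 0")
  if (any(r < 0)) stopf("distances must be >= 0")
  x <- r / d0
  out <- numeric(length(x))
  near <- abs(x - 1) < 1e-6
  # analytic limit at x -> 1 is n/m = 6/8
  out[near] <- 0.75
  x6 <- x[!near]^6
  out[!near] <- (1 - x6) / (1 - x6 * x[!near]^2)
  out
}

#' Atom-pair lists for coordination-number CVs
#'
#' @param resno_i,resno_j residue numbers (author numbering) of the first and
#'   second atom of each pair.
#' @param name_i,name_j atom names (recycled; e.g. "N" and "O").
#' @param d0 switching reference distance, Angstrom.
#' @param label CV label (e.g. "beta_1-4").
#' @param chain optional chain id applied to every selector.
#' @return An object of class `atom_pairs`.
#' @export
atom_pairs <- function(resno_i, resno_j, name_i = "N", name_j = "O",
                       d0 = 3.5, label = "", chain = NA_character_) {
  if (d0 <= 0) stopf("d0 must be > 0")
  pairs <- data.frame(resno_i = resno_i, name_i = rep_len(name_i, length(resno_i)),
                      resno_j = resno_j, name_j = rep_len(name_j, length(resno_i)),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, d0 = d0, label = label, chain = chain),
            class = "atom_pairs")
}

#' Coordination-number collective variable
#'
#' Sums the switching function over the listed atom pairs:
#' S_a = sum_ij (1 - x_ij^6)/(1 - x_ij^8), x_ij = |r_i - r_j| / d0.
#'
#' @param structure a [mol_structure].
#' @param pairs an [atom_pairs] list.
#' @return An object of class `cv_value`: total `value`, per-pair
#'   contributions `per_pair`, and the `label`.
#' @export
coordination_number <- function(structure, pairs) {
  p <- pairs$pairs
  ai <- lapply(seq_len(nrow(p)), function(k)
    find_atom(structure, p$resno_i[k], p$name_i[k], pairs$chain))
  aj <- lapply(seq_len(nrow(p)), function(k)
    find_atom(structure, p$resno_j[k], p$name_j[k], pairs$chain))
  xi <- do.call(rbind, lapply(ai, function(a) c(a$x, a$y, a$z)))
  xj <- do.call(rbind, lapply(aj, function(a) c(a$x, a$y, a$z)))
  d <- sqrt(rowSums((xi - xj)^2))
  s <- switching_function(d, pairs$d0)
  structure(list(label = pairs$label, value = sum(s),
                 per_pair = data.frame(p, distance = d, s = s)),
            class = "cv_value")
}

#' @export
print.cv_value <- function(x, ...) {
  cat(sprintf("CV %s = %.4f over %d pairs\n", x$label, x$value, nrow(x$per_pair)))
  invisible(x)
}

# Backbone N/O hydrogen-bond pairs of the frataxin 90-210 fold.
# beta_1-4: the 1-4 beta-sheet network (the collective variable); alpha_1 and
# alpha_2: the i -> i-4 helical hydrogen bonds of the two helices.
.fxn_beta_resno <- list(
  i = c(124, 124, 126, 126, 134, 134, 132, 132, 144, 144, 146, 146, 158, 158, 156, 156, 154, 154),
  j = c(135, 135, 133, 133, 143, 143, 145, 145, 157, 157, 155, 155, 162, 162, 164, 164, 166, 166),
  ni = rep(c("N", "O"), 9), nj = rep(c("O", "N"), 9))
.fxn_alpha1_resno <- list(i = 96:114, j = 92:110, ni = "N", nj = "O")
.fxn_alpha2_resno <- list(i = 186:193, j = 182:189, ni = "N", nj = "O")

.fxn_variants <- c("WT", "D104G", "A107V", "F109L", "Y123S",
                   "S161I", "W173C", "S181F", "S202F")

#' Frataxin coordination-number pair lists
#'
#' Returns the three hydrogen-bond pair lists of the frataxin 90-210 fold:
#' `beta_1-4` (18 N/O pairs across the four-strand beta-sheet; the collective
#' variable), `alpha_1` (19 pairs, helix 92-114) and `alpha_2` (8 pairs,
#' helix 182-193), all with d0 = 3.5 Angstrom. Selectors are backbone N/O
#' atoms, so they are identical for the wild type and every supported
#' single-point variant; the variant argument is validated against the
#' studied set.
#'
#' @param variant "WT" or one of D104G, A107V, F109L, Y123S, S161I, W173C,
#'   S181F, S202F.
#' @param d0 switching reference distance (A).
#' @param chain optional chain id for all selectors.
#' @return Named list of three [atom_pairs]: `beta_1-4`, `alpha_1`, `alpha_2`.
#' @export
fxn_pairlists <- function(variant = "WT", d0 = 3.5, chain = NA_character_) {
  if (!variant %in% .fxn_variants)
    stopf("unknown variant '%s' (supported: %s)", variant,
          paste(.fxn_variants, collapse = ", "))
  b <- .fxn_beta_resno
  list(
    "beta_1-4" = atom_pairs(b$i, b$j, b$ni, b$nj, d0 = d0, label = "beta_1-4", chain = chain),
    "alpha_1" = atom_pairs(.fxn_alpha1_resno$i, .fxn_alpha1_resno$j,
                           d0 = d0, label = "alpha_1", chain = chain),
    "alpha_2" = atom_pairs(.fxn_alpha2_resno$i, .fxn_alpha2_resno$j,
                           d0 = d0, label = "alpha_2", chain = chain))
}

#' Salt-bridge coordination score
#'
#' Enumerates every acidic-center x basic-center pair -- acidic: CG of Asp,
#' CD of Glu, and the terminal carboxyl C (C of the last residue in the
#' structure); basic: NZ of Lys, both NH1/NH2 of Arg, and the terminal
#' amine N (N of the first residue) -- and sums the switching function at
#' d0 = 4 Angstrom. His is not counted as charged.
#'
#' @param structure a [mol_structure].
#' @param d0 reference distance, default 4 A.
#' @param include_termini count the terminal charged groups (default TRUE).
#' @return A `cv_value` labelled "SSB"; value 0 when no charged groups exist.
#' @export
salt_bridge_score <- function(structure, d0 = 4.0, include_termini = TRUE) {
  a <- structure$atoms
  acid <- a[(a$resname == "ASP" & a$name == "CG") |
            (a$resname == "GLU" & a$name == "CD"), , drop = FALSE]
  base <- a[(a$resname == "LYS" & a$name == "NZ") |
            (a$resname == "ARG" & a$name %in% c("NH1", "NH2")), , drop = FALSE]
  if (include_termini) {
    first <- min(a$resno); last <- max(a$resno)
    nt <- a[a$resno == first & a$name == "N", , drop = FALSE]
    ct <- a[a$resno == last & a$name == "C", , drop = FALSE]
    acid <- rbind(acid, ct)
    base <- rbind(base, nt)
  }
  if (!nrow(acid) || !nrow(base))
    return(structure(list(label = "SSB", value = 0,
                          per_pair = data.frame()), class = "cv_value"))
  dx <- outer(acid$x, base$x, "-")
  dy <- outer(acid$y, base$y, "-")
  dz <- outer(acid$z, base$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  s <- matrix(switching_function(as.vector(d), d0), nrow = nrow(acid))
  per <- data.frame(
    acid = rep(paste(acid$resname, acid$resno, acid$name), times = nrow(base)),
    base = rep(paste(base$resname, base$resno, base$name), each = nrow(acid)),
    distance = as.vector(d), s = as.vector(s), stringsAsFactors = FALSE)
  structure(list(label = "SSB", value = sum(s), per_pair = per),
            class = "cv_value")
}
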