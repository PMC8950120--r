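#' Molecular structures
#'
#' A `mol_structure` holds one model of a molecule as an ordered atom table
#' with positions in Angstrom, PDB author residue numbering (1-based,
#' inclusive ranges throughout) and, once assigned, per-atom radii (Angstrom,
#' 0 for hydrogens), masses (amu) and partial charges (elementary charges).
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resno`,
#'   `chain`, `x`, `y`, `z`, `element`. Optional: `occupancy`, `mass`,
#'   `radius`, `charge`.
#' @param model integer model index the atoms came from.
#' @param source free-text identifier (e.g. a PDB code or file name).
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, model = 1L, source = "") {
  req <- c("serial", "name", "resname", "resno", "chain", "x", "y", "z", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stopf("atom table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stopf("non-finite atom coordinates")
  atoms$is_h <- toupper(atoms$element) == "H"
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate (chain, residue, atom name) records: %s",
          paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  structure(list(atoms = atoms, model = as.integer(model), source = source),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure '%s' (model %d): %d atoms, %d residues, chains %s\n",
              x$source, x$model, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# standard atomic masses; element symbols upper-case
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
                     "NA" = 22.990, CL = 35.45, MG = 24.305, K = 39.098, CA = 40.078)

#' @noRd
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011   # fall back to carbon for exotic types
  unname(m)
}

#' Guess the element from a PDB atom name
#' @noRd
element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  # strip leading digits (e.g. "1HB"), then first letter; two-letter ions rare here
  nm <- sub("^[0-9]+", "", nm)
  el <- substr(nm, 1, 1)
  el[nm %in% c("SE", "FE", "ZN", "MG", "CL", "NA", "BR")] <- nm[nm %in% c("SE", "FE", "ZN", "MG", "CL", "NA", "BR")]
  el
}

#' Read one model/chain of a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), resolves alternate locations
#' to the highest-occupancy conformer (ties: first encountered), retains
#' hydrogens (flagged via the `is_h` column) and returns the requested model
#' and chain as a [mol_structure].
#'
#' @param path PDB file path.
#' @param model 1-based model index (NMR entries have several).
#' @param chain optional single-character chain id; default keeps all chains.
#' @param keep_hetatm keep HETATM records (default FALSE: protein atoms only).
#' @return A [mol_structure].
#' @export
read_structure <- function(path, model = 1L, chain = NULL, keep_hetatm = FALSE) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stopf("no ATOM records in %s", path)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1L || model > n_models)
    stopf("model %d not present in %s (available: 1..%d)", model, path, n_models)
  # coordinates of the requested model
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else pdb$xyz
  idx <- at$eleno  # bio3d keeps xyz for all atoms incl. HETATM in file order
  all_at <- pdb$atom
  ord <- match(rownames(at), rownames(all_at))
  at$x <- xyz[3 * (ord - 1) + 1]
  at$y <- xyz[3 * (ord - 1) + 2]
  at$z <- xyz[3 * (ord - 1) + 3]
  if (!is.null(chain)) {
    chains <- unique(all_at$chain[all_at$type == "ATOM"])
    if (!chain %in% at$chain)
      stopf("chain '%s' not present in %s (present: %s)", chain, path,
            paste(chains, collapse = ", "))
    at <- at[at$chain == chain, , drop = FALSE]
  }
  # altLoc: keep highest occupancy per (chain, resno, insert, name); ties first
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    i <- which(key == k)
    best <- i[which.max(occ[i])]
    keep[setdiff(i, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  elesy <- at$elesy
  no_el <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[no_el] <- element_from_name(at$elety[no_el])
  atoms <- data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
                      resno = at$resno, chain = at$chain,
                      x = at$x, y = at$y, z = at$z,
                      element = toupper(trimws(elesy)),
                      occupancy = occ[keep], stringsAsFactors = FALSE)
  mol_structure(atoms, model = model, source = basename(path))
}

#' Write a structure as a minimal PDB file
#'
#' Emits ATOM records (coordinates to 3 decimals, the precision the format
#' fixes), a TER and END. Round-tripping through [read_structure()] is
#' idempotent on the atom table.
#'
#' @param structure a [mol_structure].
#' @param path output file.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), a$name)
  lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial %% 100000, name4, a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, a$occupancy %||% 1, 0, a$element)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Select a residue range (inclusive, author numbering)
#'
#' @param structure a [mol_structure].
#' @param lo,hi inclusive residue-number bounds.
#' @param chain optional chain restriction.
#' @return A [mol_structure] with the subset of atoms.
#' @export
select_residues <- function(structure, lo, hi, chain = NULL) {
  a <- structure$atoms
  keep <- a$resno >= lo & a$resno <= hi
  if (!is.null(chain)) keep <- keep & a$chain == chain
  if (!any(keep)) stopf("no atoms in residue range [%d, %d]", lo, hi)
  out <- structure
  out$atoms <- a[keep, , drop = FALSE]
  out
}

#' Locate one atom by selector
#'
#' @param structure a [mol_structure].
#' @param resno residue number (author numbering).
#' @param name atom name (e.g. "CA").
#' @param chain optional chain id.
#' @return Single row of the atom table.
#' @export
find_atom <- function(structure, resno, name, chain = NULL) {
  a <- structure$atoms
  hit <- a$resno == resno & a$name == name
  if (!is.null(chain) && !is.na(chain)) hit <- hit & a$chain == chain
  i <- which(hit)
  if (!length(i))
    stopf("atom (%s resno %s, name %s) not found in %s",
          chain %||% "*", resno, name, structure$source)
  a[i[1], , drop = FALSE]
}

#' Assign van der Waals radii and sigma/charge parameters
#'
#' Radii (Angstrom) and nonpolar surface coefficients sigma (kcal/(mol A^2))
#' come from editable element-keyed tables shipped in `inst/extdata`;
#' hydrogens get radius 0 (their surface is subsumed by the heavy atom they
#' ride on). Partial charges default to a formal-charge table for ionizable
#' side-chain groups (carboxylate oxygens -0.5 e, Lys NZ +1 e, Arg NH1/NH2
#' +0.5 e) and 0 elsewhere.
#'
#' @param structure a [mol_structure].
#' @param radii_table optional data.frame (element, radius) overriding the
#'   shipped defaults.
#' @param charge_table optional data.frame (resname, name, charge).
#' @return The structure with `radius` and `charge` columns filled.
#' @export
assign_parameters <- function(structure, radii_table = NULL, charge_table = NULL) {
  if (is.null(radii_table)) radii_table <- read_param_table("atom_radii.tsv")
  if (is.null(charge_table)) charge_table <- read_param_table("formal_charges.tsv")
  a <- structure$atoms
  r <- radii_table$radius[match(toupper(a$element), toupper(radii_table$element))]
  unknown <- is.na(r) & !a$is_h
  if (any(unknown))
    stopf("no radius for element(s): %s", paste(unique(a$element[unknown]), collapse = ", "))
  r[a$is_h] <- 0
  a$radius <- r
  key <- paste(a$resname, a$name)
  tkey <- paste(charge_table$resname, charge_table$name)
  q <- charge_table$charge[match(key, tkey)]
  q[is.na(q)] <- 0
  a$charge <- q
  out <- structure
  out$atoms <- a
  out
}

#' @noRd
read_param_table <- function(fname) {
  path <- system.file("extdata", fname, package = "maxentfes")
  if (!nzchar(path)) stopf("parameter table %s not found in package", fname)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Extend a chain C-terminally with all-trans backbone residues
#'
#' Builds missing C-terminal residues with ideal bond geometry and
#' phi = psi = omega = 180 degrees (fully extended), continuing from the last
#' residue present. Built atoms are flagged in a `built` column so analyses
#' can report whether constructed coordinates were used.
#'
#' @param structure a [mol_structure]; must end in a complete backbone
#'   (N, CA, C) residue.
#' @param resnames character vector of 3-letter codes to append, in order.
#' @return The extended [mol_structure].
#' @export
extend_backbone <- function(structure, resnames) {
  a <- structure$atoms
  last <- max(a$resno)
  chain <- a$chain[which.max(a$resno)]
  take <- function(res, nm) {
    row <- find_atom(structure, res, nm, chain)
    c(row$x, row$y, row$z)
  }
  # ideal geometry (Engh-Huber-like): C-N 1.33, N-CA 1.46, CA-C 1.52 A
  p_n  <- take(last, "N"); p_ca <- take(last, "CA"); p_c <- take(last, "C")
  a$built <- FALSE
  serial <- max(a$serial)
  place <- function(p1, p2, p3, length, angle) {
    # position p4 with bond p3-p4 of given length, angle p2-p3-p4, dihedral
    # p1-p2-p3-p4 = 180 degrees (trans)
    b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
    b0 <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    n <- b0 - sum(b0 * b1) * b1
    n <- n / sqrt(sum(n^2))
    ang <- angle * pi / 180
    p3 + length * (-cos(ang) * b1 + sin(ang) * (-n))
  }
  for (k in seq_along(resnames)) {
    res <- last + k
    n_new  <- place(p_n, p_ca, p_c, 1.33, 116.2)
    ca_new <- place(p_ca, p_c, n_new, 1.46, 121.7)
    c_new  <- place(p_c, n_new, ca_new, 1.52, 111.0)
    o_new  <- place(n_new, ca_new, c_new, 1.23, 120.5)
    add <- data.frame(serial = serial + seq_len(4), name = c("N", "CA", "C", "O"),
                      resname = resnames[k], resno = res, chain = chain,
                      x = c(n_new[1], ca_new[1], c_new[1], o_new[1]),
                      y = c(n_new[2], ca_new[2], c_new[2], o_new[2]),
                      z = c(n_new[3], ca_new[3], c_new[3], o_new[3]),
                      element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
    for (cn in setdiff(names(a), names(add))) add[[cn]] <- NA
    add$is_h <- FALSE
    add$mass <- element_mass(add$element)
    add$built <- TRUE
    if (!is.null(a$occupancy)) add$occupancy <- 1
    a <- rbind(a, add[names(a)])
    serial <- serial + 4
    p_n <- n_new; p_ca <- ca_new; p_c <- c_new
  }
  out <- structure
  out$atoms <- a
  out
}
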