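# Molecular geometries, XYZ I/O and deterministic benchmark fixtures.

ELEMENTS <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
              F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
              S = 16, Cl = 17, Ar = 18)

#' Create a molecule
#'
#' A molecule is a set of nuclei with Cartesian coordinates (stored in bohr),
#' a total charge and a spin multiplicity.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z.
#' @param charge integer total charge.
#' @param multiplicity integer spin multiplicity (2S+1).
#' @param label free-text name used in error messages and reports.
#' @param unit `"angstrom"` (default) or `"bohr"` for the input coordinates.
#' @return an object of class `molecule`.
#' @export
molecule <- function(elements, coords, charge = 0L, multiplicity = 1L,
                     label = "molecule", unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  elements <- canonical_element(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(elements) || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching 'elements'")
  if (length(elements) < 1) stop("molecule needs at least one atom")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (unit == "angstrom") coords <- coords / BOHR_ANGSTROM
  if (nrow(coords) > 1) {
    dmin <- min(dist(coords)) * BOHR_ANGSTROM
    if (dmin < 0.1)
      stop(sprintf("atoms closer than 0.1 Angstrom (%.4f) in '%s'", dmin, label))
  }
  nelec <- sum(ELEMENTS[elements]) - charge
  if (nelec < 1) stop("molecule has no electrons")
  # parity: n_unpaired = multiplicity - 1 must match electron count parity
  if ((nelec %% 2L) != ((multiplicity - 1L) %% 2L))
    stop(sprintf("electron count %d inconsistent with multiplicity %d",
                 nelec, multiplicity))
  structure(list(elements = elements, coords = coords,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity), label = label),
            class = "molecule")
}

canonical_element <- function(x) {
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
  bad <- setdiff(x, names(ELEMENTS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  x
}

#' @export
#' @method print molecule
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, charge %d, multiplicity %d, %d electrons>\n",
              x$label, length(x$elements), x$charge, x$multiplicity,
              n_electrons(x)))
  invisible(x)
}

#' Number of electrons in a molecule
#' @param mol a `molecule`.
#' @return integer electron count.
#' @export
n_electrons <- function(mol) {
  as.integer(sum(ELEMENTS[mol$elements]) - mol$charge)
}

nuclear_charges <- function(mol) unname(ELEMENTS[mol$elements])

#' Read a molecule from a standard XYZ file
#'
#' Standard dialect: atom-count line, comment line, then `element x y z`
#' rows in Angstrom.  Charge and multiplicity may be given in the comment
#' line as `charge=<c> mult=<m>` (defaults 0 and 1).
#'
#' @param path file path.
#' @param label optional label (defaults to the file name).
#' @return a `molecule`.
#' @export
load_xyz <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("XYZ parse error: fewer than two lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("XYZ parse error in count line (line 1): ", sQuote(lines[1]))
  if (length(lines) < n + 2)
    stop(sprintf("XYZ parse error: count line says %d atoms but only %d rows present",
                 n, max(0L, length(lines) - 2L)))
  comment <- lines[2]
  charge <- 0L; mult <- 1L
  mc <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(mc) == 2) charge <- as.integer(mc[2])
  mm <- regmatches(comment, regexec("mult=([0-9]+)", comment))[[1]]
  if (length(mm) == 2) mult <- as.integer(mm[2])
  els <- character(n); xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("XYZ parse error: atom row %d (line %d) has %d fields",
                   i, i + 2, length(tok)))
    els[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v))
      stop(sprintf("XYZ coordinate parse failure at atom row %d (line %d)", i, i + 2))
    xyz[i, ] <- v
  }
  molecule(els, xyz, charge = charge, multiplicity = mult, label = label,
           unit = "angstrom")
}

#' Write a molecule to a standard XYZ file
#'
#' Coordinates are printed in Angstrom with 10 decimal places; element
#' symbols in canonical capitalisation.
#'
#' @param mol a `molecule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path) {
  xyz <- mol$coords * BOHR_ANGSTROM
  lines <- c(sprintf("%d", length(mol$elements)),
             sprintf("%s charge=%d mult=%d", mol$label, mol$charge,
                     mol$multiplicity),
             sprintf("%-2s %18.10f %18.10f %18.10f", mol$elements,
                     xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Pair two monomers with their basis sets
#'
#' Monomer-centered bases only: each monomer is described exclusively in its
#' own atomic-orbital basis (no ghost functions, no dimer-centered set).
#'
#' @param monomer_a,monomer_b `molecule` objects.
#' @param basis_a,basis_b basis-set names (e.g. `"6-31g"`, `"cc-pvdz"`).
#' @return an object of class `dimer_system`.
#' @export
dimer_system <- function(monomer_a, monomer_b, basis_a, basis_b = basis_a) {
  stopifnot(inherits(monomer_a, "molecule"), inherits(monomer_b, "molecule"))
  dmin <- min_cross_distance(monomer_a, monomer_b)
  if (dmin <= 0.5)
    stop(sprintf("monomers not geometrically disjoint (min A-B distance %.3f Angstrom)",
                 dmin))
  structure(list(monomer_a = monomer_a, monomer_b = monomer_b,
                 basis_a = basis_a, basis_b = basis_b),
            class = "dimer_system")
}

min_cross_distance <- function(a, b) {
  d <- outer(seq_len(nrow(a$coords)), seq_len(nrow(b$coords)),
             Vectorize(function(i, j) sqrt(sum((a$coords[i, ] - b$coords[j, ])^2))))
  min(d) * BOHR_ANGSTROM
}

#' @export
#' @method print dimer_system
print.dimer_system <- function(x, ...) {
  cat(sprintf("<dimer: A='%s' (%s), B='%s' (%s), min A-B distance %.3f Angstrom>\n",
              x$monomer_a$label, x$basis_a, x$monomer_b$label, x$basis_b,
              min_cross_distance(x$monomer_a, x$monomer_b)))
  invisible(x)
}

# ------------------------------------------------------------------ fixtures

#' Hydrogen-bonded water dimer with a symmetrically stretched monomer
#'
#' Fixed, fully documented textbook geometry.  The hydrogen-bond donor sits
#' at the equilibrium monomer geometry (r_OH = 0.9572 Angstrom, HOH angle
#' 104.52 degrees) and donates a collinear O-H...O hydrogen bond along the x
#' axis with a fixed O-O distance of 2.91 Angstrom.  The acceptor monomer's
#' two O-H bonds are both set to `r_oh_donor` with the bond angle and
#' orientation held fixed; its hydrogens point away from the donor (bisector
#' along -x, in the xz plane), so the intermonomer separation is fixed for
#' every stretch and the donor coordinates are bitwise independent of
#' `r_oh_donor`.
#'
#' @param r_oh_donor O-H bond length of the stretched monomer in Angstrom
#'   (0.5 to 3.0).
#' @param basis basis-set name applied to both monomers.
#' @return a `dimer_system`; monomer A is the stretched water, monomer B the
#'   equilibrium (donor) water.
#' @export
make_water_dimer <- function(r_oh_donor = 0.9572, basis = "6-31g") {
  if (r_oh_donor < 0.5 || r_oh_donor > 3.0)
    stop("r_oh_donor out of range [0.5, 3.0] Angstrom")
  r_eq <- 0.9572; ang <- 104.52 * pi / 180; d_oo <- 2.91
  half <- ang / 2
  stretched <- molecule(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(-r_oh_donor * cos(half), 0,  r_oh_donor * sin(half)),
          c(-r_oh_donor * cos(half), 0, -r_oh_donor * sin(half))),
    label = "water acceptor (stretched)")
  donor <- molecule(
    c("O", "H", "H"),
    rbind(c(d_oo, 0, 0),
          c(d_oo - r_eq, 0, 0),
          c(d_oo - r_eq * cos(ang), r_eq * sin(ang), 0)),
    label = "water donor")
  dimer_system(stretched, donor, basis, basis)
}

benzene_template <- function() {
  r_cc <- 1.397; r_ch <- 1.084
  k <- 0:5; th <- k * pi / 3
  carbons <- cbind(r_cc * cos(th), r_cc * sin(th), 0)
  hydrogens <- cbind((r_cc + r_ch) * cos(th), (r_cc + r_ch) * sin(th), 0)
  list(C = carbons, H = hydrogens)
}

#' T-shaped benzene / p-benzyne dimer
#'
#' Benzene at a standard D6h geometry (r_CC = 1.397, r_CH = 1.084 Angstrom)
#' in the xy plane centered at the origin; p-benzyne is obtained from the
#' same ring by deleting the two para hydrogens (those on the +x and -x
#' carbons), rotated into the xz plane (perpendicular ring planes) and
#' translated so the ring centroids are exactly `R` apart along z.  The
#' dehydrogenated para axis lies along x.  p-Benzyne is a low-spin singlet
#' biradical, consistent with its active-space treatment.
#'
#' @param R centroid-to-centroid distance in Angstrom (>= 3).
#' @param basis basis-set name applied to both monomers.
#' @return a `dimer_system`; monomer A is p-benzyne, monomer B is benzene.
#' @export
make_benzene_pbenzyne_tshape <- function(R = 4.45, basis = "cc-pvdz") {
  if (R < 3.0) stop("R out of range (must be >= 3.0 Angstrom)")
  tpl <- benzene_template()
  benzene <- molecule(rep(c("C", "H"), each = 6), rbind(tpl$C, tpl$H),
                      label = "benzene")
  keepH <- c(2, 3, 5, 6)  # drop para hydrogens on ring positions 1 and 4
  pb_xy <- rbind(tpl$C, tpl$H[keepH, ])
  # rotate ring plane xy -> xz (y -> z), then translate centroid to (0, 0, R)
  pb <- cbind(pb_xy[, 1], 0 * pb_xy[, 2], pb_xy[, 2] + R)
  pbenzyne <- molecule(rep(c("C", "H"), c(6, 4)), pb,
                       label = "p-benzyne", multiplicity = 1L)
  dimer_system(pbenzyne, benzene, basis, basis)
}

#' Tiny two-monomer test systems
#'
#' Either two collinear H2 molecules (bond length 0.7414 Angstrom) with
#' centers of mass separated by `R` along z, or two He atoms separated by
#' `R`.
#'
#' @param kind `"h2h2"` or `"hehe"`.
#' @param R center-to-center separation in Angstrom (> 0.5).
#' @param basis basis-set name applied to both monomers.
#' @return a `dimer_system`.
#' @export
make_toy_dimer <- function(kind = c("h2h2", "hehe"), R = 5, basis = "sto-3g") {
  kind <- match.arg(kind)
  if (R <= 0.5) stop("R out of range (must exceed 0.5 Angstrom)")
  if (kind == "hehe") {
    a <- molecule("He", matrix(c(0, 0, 0), 1), label = "He (A)")
    b <- molecule("He", matrix(c(0, 0, R), 1), label = "He (B)")
  } else {
    r <- 0.7414
    a <- molecule(c("H", "H"), rbind(c(0, 0, -r / 2), c(0, 0, r / 2)),
                  label = "H2 (A)")
    b <- molecule(c("H", "H"), rbind(c(0, 0, R - r / 2), c(0, 0, R + r / 2)),
                  label = "H2 (B)")
  }
  dimer_system(a, b, basis, basis)
}

#' Rigidly translate a molecule
#' @param mol a `molecule`.
#' @param shift length-3 numeric, displacement in Angstrom.
#' @return the translated `molecule`.
#' @export
translate_molecule <- function(mol, shift) {
  mol$coords <- sweep(mol$coords, 2, shift / BOHR_ANGSTROM, "+")
  mol
}
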