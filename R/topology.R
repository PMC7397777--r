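# Residue topology: heavy-atom composition, ideal internal coordinates
# (Z-matrix over a spanning tree rooted at the backbone), chemical bonds,
# named torsion variables (phi/psi/chi*), and scoring atom classes.
#
# Atom classes:
#   hC     hydrophobic carbon (no N/O/S neighbour)
#   pC     polar carbon (bonded to N/O/S)
#   don    hydrogen-bond donor heteroatom
#   acc    hydrogen-bond acceptor heteroatom
#   donacc both donor and acceptor (hydroxyls)
#   oth    neither (sulfur, proline backbone N)

# one side-chain Z-matrix row: atom placed at distance r from `par`, angle
# theta against `ang`, dihedral (tor, ang, par, atom) = value of torsion
# variable `tvar` plus offset `toff` (tvar == "" means a fixed dihedral).
.sc <- function(name, el, par, ang, tor, r, theta, tvar, toff, class) {
  data.frame(name = name, el = el, par = par, ang = ang, tor = tor,
             r = r, theta = theta, tvar = tvar, toff = toff, class = class,
             stringsAsFactors = FALSE)
}

.sc_tab <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(data.frame(name = character(), el = character(), par = character(),
                      ang = character(), tor = character(), r = numeric(),
                      theta = numeric(), tvar = character(), toff = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Ideal backbone geometry (Engh-Huber-like values).
.bb_geom <- list(
  n_c    = 1.329,  # C(i-1)-N
  n_ca   = 1.458,
  ca_c   = 1.525,
  c_o    = 1.231,
  c_oxt  = 1.250,
  ang_c_n_ca  = 121.7,  # CA(i)-N(i)-C(i-1)
  ang_ca_c_n  = 116.2,  # N(i+1)-C(i)-CA(i)
  ang_n_ca_c  = 111.2,
  ang_ca_c_o  = 120.8,
  ang_ca_c_oxt = 117.0,
  cb_r = 1.530, cb_theta = 110.5, cb_impr = 122.8  # dihedral(C,N,CA,CB)
)

.aa_sidechains <- list(
  A = .sc_tab(),  # CB added generically
  G = .sc_tab(),
  S = .sc_tab(.sc("OG",  "O", "CB", "CA", "N", 1.417, 110.8, "chi1", 0, "donacc")),
  C = .sc_tab(.sc("SG",  "S", "CB", "CA", "N", 1.808, 114.4, "chi1", 0, "oth")),
  T = .sc_tab(.sc("OG1", "O", "CB", "CA", "N", 1.433, 109.6, "chi1", 0, "donacc"),
              .sc("CG2", "C", "CB", "CA", "N", 1.521, 110.5, "chi1", -120, "hC")),
  V = .sc_tab(.sc("CG1", "C", "CB", "CA", "N", 1.521, 110.5, "chi1", 0, "hC"),
              .sc("CG2", "C", "CB", "CA", "N", 1.521, 110.5, "chi1", 122, "hC")),
  L = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.530, 116.3, "chi1", 0, "hC"),
              .sc("CD1", "C", "CG", "CB", "CA", 1.521, 110.7, "chi2", 0, "hC"),
              .sc("CD2", "C", "CG", "CB", "CA", 1.521, 110.7, "chi2", 122, "hC")),
  I = .sc_tab(.sc("CG1", "C", "CB", "CA", "N", 1.530, 110.4, "chi1", 0, "hC"),
              .sc("CG2", "C", "CB", "CA", "N", 1.521, 110.5, "chi1", -122, "hC"),
              .sc("CD1", "C", "CG1", "CB", "CA", 1.513, 113.8, "chi2", 0, "hC")),
  M = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.520, 114.1, "chi1", 0, "pC"),
              .sc("SD",  "S", "CG", "CB", "CA", 1.803, 112.7, "chi2", 0, "oth"),
              .sc("CE",  "C", "SD", "CG", "CB", 1.791, 100.9, "chi3", 0, "pC")),
  D = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.516, 112.6, "chi1", 0, "pC"),
              .sc("OD1", "O", "CG", "CB", "CA", 1.249, 118.4, "chi2", 0, "acc"),
              .sc("OD2", "O", "CG", "CB", "CA", 1.249, 118.4, "chi2", 180, "acc")),
  N = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.516, 112.6, "chi1", 0, "pC"),
              .sc("OD1", "O", "CG", "CB", "CA", 1.231, 120.8, "chi2", 0, "acc"),
              .sc("ND2", "N", "CG", "CB", "CA", 1.328, 116.4, "chi2", 180, "don")),
  E = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.520, 114.1, "chi1", 0, "hC"),
              .sc("CD",  "C", "CG", "CB", "CA", 1.516, 112.6, "chi2", 0, "pC"),
              .sc("OE1", "O", "CD", "CG", "CB", 1.249, 118.4, "chi3", 0, "acc"),
              .sc("OE2", "O", "CD", "CG", "CB", 1.249, 118.4, "chi3", 180, "acc")),
  Q = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.520, 114.1, "chi1", 0, "hC"),
              .sc("CD",  "C", "CG", "CB", "CA", 1.516, 112.6, "chi2", 0, "pC"),
              .sc("OE1", "O", "CD", "CG", "CB", 1.231, 120.8, "chi3", 0, "acc"),
              .sc("NE2", "N", "CD", "CG", "CB", 1.328, 116.4, "chi3", 180, "don")),
  K = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.520, 114.1, "chi1", 0, "hC"),
              .sc("CD",  "C", "CG", "CB", "CA", 1.520, 111.3, "chi2", 0, "hC"),
              .sc("CE",  "C", "CD", "CG", "CB", 1.520, 111.3, "chi3", 0, "pC"),
              .sc("NZ",  "N", "CE", "CD", "CG", 1.489, 111.9, "chi4", 0, "don")),
  R = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.520, 114.1, "chi1", 0, "hC"),
              .sc("CD",  "C", "CG", "CB", "CA", 1.520, 111.3, "chi2", 0, "pC"),
              .sc("NE",  "N", "CD", "CG", "CB", 1.461, 112.0, "chi3", 0, "don"),
              .sc("CZ",  "C", "NE", "CD", "CG", 1.329, 124.2, "chi4", 0, "pC"),
              .sc("NH1", "N", "CZ", "NE", "CD", 1.326, 120.0, "", 0, "don"),
              .sc("NH2", "N", "CZ", "NE", "CD", 1.326, 120.0, "", 180, "don")),
  H = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.497, 113.7, "chi1", 0, "pC"),
              .sc("ND1", "N", "CG", "CB", "CA", 1.371, 122.7, "chi2", 0, "don"),
              .sc("CD2", "C", "CG", "CB", "CA", 1.356, 129.7, "chi2", 180, "pC"),
              .sc("CE1", "C", "ND1", "CG", "CB", 1.319, 109.0, "", 180, "pC"),
              .sc("NE2", "N", "CD2", "CG", "CB", 1.374, 107.2, "", 180, "acc")),
  F = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.502, 113.8, "chi1", 0, "hC"),
              .sc("CD1", "C", "CG", "CB", "CA", 1.390, 120.0, "chi2", 0, "hC"),
              .sc("CD2", "C", "CG", "CB", "CA", 1.390, 120.0, "chi2", 180, "hC"),
              .sc("CE1", "C", "CD1", "CG", "CB", 1.390, 120.0, "", 180, "hC"),
              .sc("CE2", "C", "CD2", "CG", "CB", 1.390, 120.0, "", 180, "hC"),
              .sc("CZ",  "C", "CE1", "CD1", "CG", 1.390, 120.0, "", 0, "hC")),
  Y = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.502, 113.8, "chi1", 0, "hC"),
              .sc("CD1", "C", "CG", "CB", "CA", 1.390, 120.0, "chi2", 0, "hC"),
              .sc("CD2", "C", "CG", "CB", "CA", 1.390, 120.0, "chi2", 180, "hC"),
              .sc("CE1", "C", "CD1", "CG", "CB", 1.390, 120.0, "", 180, "hC"),
              .sc("CE2", "C", "CD2", "CG", "CB", 1.390, 120.0, "", 180, "hC"),
              .sc("CZ",  "C", "CE1", "CD1", "CG", 1.390, 120.0, "", 0, "pC"),
              .sc("OH",  "O", "CZ", "CE1", "CD1", 1.376, 119.9, "", 180, "donacc")),
  W = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.498, 113.6, "chi1", 0, "hC"),
              .sc("CD1", "C", "CG", "CB", "CA", 1.365, 126.9, "chi2", 0, "pC"),
              .sc("CD2", "C", "CG", "CB", "CA", 1.433, 126.6, "chi2", 180, "hC"),
              .sc("NE1", "N", "CD1", "CG", "CB", 1.374, 110.2, "", 180, "don"),
              .sc("CE2", "C", "CD2", "CG", "CB", 1.409, 107.2, "", 180, "pC"),
              .sc("CE3", "C", "CD2", "CG", "CB", 1.398, 133.9, "", 0, "hC"),
              .sc("CZ2", "C", "CE2", "CD2", "CG", 1.394, 122.4, "", 180, "hC"),
              .sc("CZ3", "C", "CE3", "CD2", "CG", 1.382, 118.6, "", 180, "hC"),
              .sc("CH2", "C", "CZ2", "CE2", "CD2", 1.368, 117.5, "", 180, "hC")),
  # proline ring: near-planar fixed pucker chosen so the (untracked) CD-N
  # closure bond comes out at ~1.47 A in the extended build
  P = .sc_tab(.sc("CG",  "C", "CB", "CA", "N", 1.492, 104.5, "", -5, "hC"),
              .sc("CD",  "C", "CG", "CB", "CA", 1.503, 106.1, "", -10, "pC"))
)

# Ring-closure bonds: chemical bonds not on the Z-matrix spanning tree.
# They enter the chemical bond graph (atom classification, clash exclusion)
# but not the kinematic tree, so ring-internal dihedrals stay fixed.
.aa_closures <- list(
  F = list(c("CE2", "CZ")),
  Y = list(c("CE2", "CZ")),
  H = list(c("CE1", "NE2")),
  W = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  P = list(c("CD", "N"))
)

.aa_names3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa_codes1 <- structure(names(.aa_names3), names = .aa_names3)
.std_resids <- unname(.aa_names3)

#' Heavy-atom topology of one amino-acid residue
#'
#' Returns the package's ideal heavy-atom topology for a standard residue:
#' atom names and elements, scoring atom classes, the internal-coordinate
#' spanning tree used to construct ideal geometry, chemical bonds
#' (tree bonds plus ring-closure bonds), and the torsion variables
#' (\code{chi1}..\code{chi4}) the side chain exposes.
#'
#' @param aa One-letter residue code (one of the 20 standard residues).
#' @param terminal Logical; if \code{TRUE} the C-terminal carboxylate
#'   oxygen \code{OXT} is included.
#' @return A list with elements \code{atoms} (data frame: \code{name},
#'   \code{el}, \code{class}), \code{zmat} (side-chain internal-coordinate
#'   rows), \code{bonds} (two-column matrix of atom names, including ring
#'   closures), and \code{chis} (character vector of rotatable side-chain
#'   torsion variables).
#' @export
residueTopology <- function(aa, terminal = FALSE) {
  aa <- toupper(aa)
  if (nchar(aa) == 3) aa <- unname(.aa_codes1[aa])
  if (is.na(aa) || !aa %in% names(.aa_sidechains))
    stop("unknown residue code: ", aa)
  bb <- data.frame(
    name = c("N", "CA", "C", "O"),
    el = c("N", "C", "C", "O"),
    class = c(if (aa == "P") "oth" else "don", "pC", "pC", "acc"),
    stringsAsFactors = FALSE)
  sc <- .aa_sidechains[[aa]]
  atoms <- bb
  bonds <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (aa != "G") {
    cb_class <- if (aa %in% c("S", "C", "T")) "pC" else "hC"  # CB next to O/S
    atoms <- rbind(atoms, data.frame(name = "CB", el = "C", class = cb_class))
    bonds <- rbind(bonds, c("CA", "CB"))
  }
  if (nrow(sc) > 0) {
    atoms <- rbind(atoms, data.frame(name = sc$name, el = sc$el, class = sc$class))
    bonds <- rbind(bonds, cbind(sc$par, sc$name))
  }
  for (cl in .aa_closures[[aa]]) bonds <- rbind(bonds, cl)
  if (terminal) {
    atoms <- rbind(atoms, data.frame(name = "OXT", el = "O", class = "acc"))
    bonds <- rbind(bonds, c("C", "OXT"))
  }
  chis <- unique(sc$tvar[nzchar(sc$tvar)])
  dimnames(bonds) <- NULL
  list(aa = aa, aa3 = unname(.aa_names3[aa]), atoms = atoms,
       zmat = sc, bonds = bonds, chis = chis)
}

#' Heavy-atom count of a peptide sequence under the ideal topology
#'
#' @param sequence One-letter amino-acid string.
#' @param terminal Include the C-terminal \code{OXT} oxygen.
#' @return Integer atom count.
#' @export
heavyAtomCount <- function(sequence, terminal = TRUE) {
  aas <- strsplit(toupper(sequence), "")[[1]]
  n <- sum(vapply(aas, function(a) nrow(residueTopology(a)$atoms), 1L))
  if (terminal) n + 1L else n
}

.check_sequence <- function(sequence, allow_any_length = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("peptide sequence must be a non-empty character scalar")
  sequence <- toupper(sequence)
  aas <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aas, names(.aa_sidechains))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  if (!allow_any_length && !(length(aas) >= 8 && length(aas) <= 11))
    stop("peptide length ", length(aas),
         " outside the class I range 8-11; use allow_any_length = TRUE to override")
  sequence
}
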