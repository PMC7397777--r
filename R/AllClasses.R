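#' @include geometry.R topology.R
NULL

#' @import methods
NULL

#' Full-atom peptide conformation with a torsion tree
#'
#' Heavy-atom model of a short peptide.  Cartesian coordinates are the ground
#' truth; named rotatable dihedrals (phi/psi/chi and the terminal carboxylate
#' rotation) are edited by rigid rotation of the distal atom set about the
#' bond axis, which leaves every bond length and bond angle untouched.
#'
#' @slot sequence One-letter amino-acid string.
#' @slot atoms Data frame with one row per heavy atom: \code{name} (PDB atom
#'   name), \code{el} (element), \code{resno} (1-based residue index),
#'   \code{class} (scoring atom class: \code{hC}, \code{pC}, \code{don},
#'   \code{acc}, \code{donacc}, \code{oth}).
#' @slot coords Numeric matrix (atoms x 3), Angstrom.
#' @slot torsions Data frame of named dihedrals: \code{id}, \code{type},
#'   \code{resno}, defining atom rows \code{a,b,c,d} (rotation axis is the
#'   b--c bond), and \code{rotatable}.
#' @slot moving List (parallel to \code{torsions} rows) of integer vectors:
#'   the atoms distal to each rotation axis.
#' @slot idealBonds Data frame (\code{i}, \code{j}, \code{r}): spanning-tree
#'   bonds with their ideal lengths.
#' @slot idealAngles Data frame (\code{i}, \code{j}, \code{k}, \code{theta}):
#'   bonded angles with ideal values (vertex \code{j}).
#' @slot chemBonds Integer matrix (2 columns): the full chemical bond graph,
#'   including ring closures and inter-residue peptide bonds.
#' @export
setClass("PeptideConformation", representation(
  sequence = "character",
  atoms = "data.frame",
  coords = "matrix",
  torsions = "data.frame",
  moving = "list",
  idealBonds = "data.frame",
  idealAngles = "data.frame",
  chemBonds = "matrix"
))

setValidity("PeptideConformation", function(object) {
  msg <- character()
  if (nrow(object@coords) != nrow(object@atoms))
    msg <- c(msg, "coords and atoms row counts differ")
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (nrow(object@torsions) != length(object@moving))
    msg <- c(msg, "torsions and moving lengths differ")
  if (length(msg)) msg else TRUE
})

#' Rigid class I HLA receptor model
#'
#' The receptor is a rigid heavy-atom set together with a rectangular
#' binding-site box, a groove axis (unit vector pointing from the A-pocket
#' anchor site toward the F-pocket anchor site), and reference backbone
#' coordinates for the two terminal anchor residues.
#'
#' @slot id Receptor identifier (e.g. allele name or fixture id).
#' @slot atoms Data frame: \code{name}, \code{el}, \code{resno}, \code{class}.
#' @slot coords Numeric matrix (atoms x 3), Angstrom.
#' @slot boxCenter,boxDims Numeric length-3: binding-site box, Angstrom.
#' @slot grooveAxis Unit 3-vector, A-pocket to F-pocket.
#' @slot anchorSites List with elements \code{n} and \code{c}: 3 x 3 matrices
#'   (rows N, CA, C) of reference backbone coordinates for the first- and
#'   last-residue anchors.
#' @export
setClass("Receptor", representation(
  id = "character",
  atoms = "data.frame",
  coords = "matrix",
  boxCenter = "numeric",
  boxDims = "numeric",
  grooveAxis = "numeric",
  anchorSites = "list"
))

setValidity("Receptor", function(object) {
  msg <- character()
  if (nrow(object@coords) != nrow(object@atoms))
    msg <- c(msg, "coords and atoms row counts differ")
  if (abs(.vnorm(object@grooveAxis) - 1) > 1e-6)
    msg <- c(msg, "grooveAxis must have unit norm")
  if (!all(c("n", "c") %in% names(object@anchorSites)))
    msg <- c(msg, "anchorSites must have elements 'n' and 'c'")
  else {
    lo <- object@boxCenter - object@boxDims / 2
    hi <- object@boxCenter + object@boxDims / 2
    for (s in object@anchorSites[c("n", "c")]) {
      if (!all(t(s) >= lo - 1e-9 & t(s) <= hi + 1e-9))
        msg <- c(msg, "anchor sites must lie inside the box")
    }
  }
  if (length(msg)) msg else TRUE
})

#' One peptide binding mode
#'
#' A single full-atom pose of a peptide in the receptor frame, with the
#' energies assigned to it so far (one per scoring function) and sampling
#' provenance (round, replicate, seed).
#'
#' @slot peptide A \linkS4class{PeptideConformation} in absolute coordinates.
#' @slot scores Named numeric: energies in kcal/mol keyed by scoring-function
#'   id; empty until an explicit scoring call.
#' @slot provenance List: \code{round}, \code{replicate}, \code{seed}.
#' @export
setClass("BindingMode", representation(
  peptide = "PeptideConformation",
  scores = "numeric",
  provenance = "list"
))

setValidity("BindingMode", function(object) {
  if (!all(is.finite(object@peptide@coords))) "peptide coordinates must be finite"
  else TRUE
})

#' Ordered ensemble of binding modes for one peptide-receptor pair
#'
#' @slot pairId Character: peptide sequence + receptor id.
#' @slot modes List of \linkS4class{BindingMode} objects, all sharing one
#'   peptide sequence.
#' @export
setClass("Ensemble", representation(
  pairId = "character",
  modes = "list"
))

setValidity("Ensemble", function(object) {
  if (length(object@modes)) {
    seqs <- vapply(object@modes, function(m) m@peptide@sequence, "")
    if (length(unique(seqs)) > 1) return("all modes must share one sequence")
  }
  TRUE
})

#' Anchor template for ensemble generation
#'
#' Backbone coordinates onto which the first and last peptide residues are
#' anchored before loop closure.
#'
#' @slot nTerm,cTerm 3 x 3 matrices (rows N, CA, C), Angstrom.
#' @slot sourceId Template identifier.
#' @slot tolerance Allowed deviation at the anchors, Angstrom.
#' @export
setClass("AnchorTemplate", representation(
  nTerm = "matrix",
  cTerm = "matrix",
  sourceId = "character",
  tolerance = "numeric"
))

setValidity("AnchorTemplate", function(object) {
  msg <- character()
  if (!all(dim(object@nTerm) == c(3, 3))) msg <- c(msg, "nTerm must be 3x3")
  if (!all(dim(object@cTerm) == c(3, 3))) msg <- c(msg, "cTerm must be 3x3")
  if (object@tolerance <= 0) msg <- c(msg, "tolerance must be positive")
  if (length(msg)) msg else TRUE
})
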