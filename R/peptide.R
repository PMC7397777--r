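#' @include topology.R geometry.R AllClasses.R
NULL

# Peptide construction and internal-coordinate kinematics.
#
# A peptide is built once from ideal residue topology (NeRF chain growth);
# afterwards Cartesian coordinates are the ground truth and dihedral edits
# are rigid rotations of the distal atom set about the bond axis, so bonded
# geometry is preserved to machine precision no matter how many edits are
# applied.

# Improper dihedral(C, N, CA, CB) fixing the L-configuration at CA.
.cb_improper <- 122.8

# Assemble the full topology of a peptide: atom table, Z-matrix reference
# arrays, torsion-variable table, moving sets, ideal bond/angle tables and
# the chemical bond graph.  Coordinates are NOT set here.
.peptide_topology <- function(sequence) {
  aas <- strsplit(sequence, "")[[1]]
  L <- length(aas)
  g <- .bb_geom

  name <- character(); el <- character(); resno <- integer(); class <- character()
  par <- integer(); angr <- integer(); torr <- integer()
  rr <- numeric(); th <- numeric(); tvar <- character(); toff <- numeric()
  closure <- matrix(integer(), 0, 2)

  idx <- vector("list", L)
  add_atom <- function(nm, e, rn, cl, p, a, t, r, theta, tv, off) {
    name <<- c(name, nm); el <<- c(el, e); resno <<- c(resno, rn)
    class <<- c(class, cl)
    par <<- c(par, p); angr <<- c(angr, a); torr <<- c(torr, t)
    rr <<- c(rr, r); th <<- c(th, theta); tvar <<- c(tvar, tv); toff <<- c(toff, off)
    k <- length(name)
    idx[[rn]][[nm]] <<- k
    k
  }

  for (i in seq_len(L)) {
    aa <- aas[i]
    topo <- residueTopology(aa)
    bbclass <- topo$atoms$class[match(c("N", "CA", "C", "O"), topo$atoms$name)]
    if (i == 1) {
      add_atom("N", "N", 1, bbclass[1], 0L, 0L, 0L, NA, NA, "", NA)
      add_atom("CA", "C", 1, bbclass[2], idx[[1]]$N, 0L, 0L, g$n_ca, NA, "", NA)
      add_atom("C", "C", 1, bbclass[3], idx[[1]]$CA, idx[[1]]$N, 0L,
               g$ca_c, g$ang_n_ca_c, "", NA)
    } else {
      p <- idx[[i - 1]]
      add_atom("N", "N", i, bbclass[1], p$C, p$CA, p$N,
               g$n_c, g$ang_ca_c_n, sprintf("psi:%d", i - 1), 0)
      ni <- idx[[i]]$N
      add_atom("CA", "C", i, bbclass[2], ni, p$C, p$CA,
               g$n_ca, g$ang_c_n_ca, "", 180)  # omega fixed trans
      add_atom("C", "C", i, bbclass[3], idx[[i]]$CA, ni, p$C,
               g$ca_c, g$ang_n_ca_c, sprintf("phi:%d", i), 0)
    }
    add_atom("O", "O", i, bbclass[4], idx[[i]]$C, idx[[i]]$CA, idx[[i]]$N,
             g$c_o, g$ang_ca_c_o, sprintf("psi:%d", i), 180)
    if (aa != "G") {
      cbcl <- topo$atoms$class[topo$atoms$name == "CB"]
      add_atom("CB", "C", i, cbcl, idx[[i]]$CA, idx[[i]]$N, idx[[i]]$C,
               g$cb_r, g$cb_theta, "", .cb_improper)
    }
    zm <- topo$zmat
    if (nrow(zm)) {
      for (j in seq_len(nrow(zm))) {
        tv <- if (nzchar(zm$tvar[j])) sprintf("%s:%d", zm$tvar[j], i) else ""
        add_atom(zm$name[j], zm$el[j], i, zm$class[j],
                 idx[[i]][[zm$par[j]]], idx[[i]][[zm$ang[j]]],
                 idx[[i]][[zm$tor[j]]], zm$r[j], zm$theta[j], tv, zm$toff[j])
      }
    }
    for (cl in .aa_closures[[aa]])
      closure <- rbind(closure, c(idx[[i]][[cl[1]]], idx[[i]][[cl[2]]]))
    if (i == L) {
      add_atom("OXT", "O", i, "acc", idx[[i]]$C, idx[[i]]$CA, idx[[i]]$N,
               g$c_oxt, g$ang_ca_c_oxt, sprintf("psi:%d", i), 0)
    }
  }

  n_atoms <- length(name)
  atoms <- data.frame(name = name, el = el, resno = resno, class = class,
                      stringsAsFactors = FALSE)

  # descendants of each atom in the spanning tree
  anc <- vector("list", n_atoms)
  for (k in seq_len(n_atoms)) {
    anc[[k]] <- if (par[k] == 0L) integer() else c(par[k], anc[[par[k]]])
  }

  # torsion-variable table: the defining atom of variable v is the atom with
  # tvar == v and zero offset; quadruple (torref, angref, parent, atom)
  defin <- which(nzchar(tvar) & toff == 0)
  vids <- tvar[defin]
  keep <- !duplicated(vids)
  defin <- defin[keep]; vids <- vids[keep]
  tt <- data.frame(
    id = vids,
    type = sub(":.*", "", vids),
    resno = as.integer(sub(".*:", "", vids)),
    a = torr[defin], b = angr[defin], c = par[defin], d = defin,
    rotatable = TRUE,
    stringsAsFactors = FALSE)
  ord <- order(tt$resno, match(tt$type, c("phi", "psi", "chi1", "chi2",
                                          "chi3", "chi4")))
  tt <- tt[ord, , drop = FALSE]
  rownames(tt) <- NULL
  moving <- lapply(tt$c, function(cc) {
    which(vapply(anc, function(a) cc %in% a, TRUE))
  })

  tree_edges <- cbind(par[par != 0L], which(par != 0L))
  chem <- rbind(tree_edges, closure)
  ib <- data.frame(i = tree_edges[, 1], j = tree_edges[, 2],
                   r = rr[par != 0L])
  hasang <- which(angr != 0L)
  ia <- data.frame(i = hasang, j = par[hasang], k = angr[hasang],
                   theta = th[hasang])

  list(atoms = atoms, par = par, angr = angr, torr = torr, r = rr,
       theta = th, tvar = tvar, toff = toff, torsions = tt, moving = moving,
       idealBonds = ib, idealAngles = ia, chemBonds = chem)
}

# Forward-kinematics construction of coordinates from the topology and a
# named torsion-variable value vector (degrees).
.peptide_build_coords <- function(topo, values) {
  g <- .bb_geom
  n <- nrow(topo$atoms)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$n_ca, 0, 0)
  thc <- g$ang_n_ca_c * .deg2rad
  xyz[3, ] <- xyz[2, ] + g$ca_c * c(-cos(thc), sin(thc), 0)
  for (k in seq_len(n)) {
    if (k <= 3) next
    tau <- topo$toff[k]
    if (nzchar(topo$tvar[k])) tau <- tau + values[[topo$tvar[k]]]
    xyz[k, ] <- .nerf_place(xyz[topo$torr[k], ], xyz[topo$angr[k], ],
                            xyz[topo$par[k], ], topo$r[k], topo$theta[k], tau)
  }
  xyz
}

.new_peptide <- function(sequence, topo, coords) {
  new("PeptideConformation", sequence = sequence, atoms = topo$atoms,
      coords = coords, torsions = topo$torsions, moving = topo$moving,
      idealBonds = topo$idealBonds, idealAngles = topo$idealAngles,
      chemBonds = topo$chemBonds)
}

#' Build an ideal-geometry extended peptide from sequence
#'
#' Constructs a full heavy-atom conformation with ideal bond lengths and
#' angles, backbone fully extended (phi = psi = 180 degrees, trans omega) and
#' every side chain in the anti (180 degree) rotamer.  The torsion tree of
#' named rotatable dihedrals (phi/psi/chi plus the terminal carboxylate
#' rotation) is populated.
#'
#' @param sequence One-letter amino-acid string (standard residues). Lengths
#'   outside 8-11 are rejected unless \code{allow_any_length}.
#' @param allow_any_length Logical override for the class I length check.
#' @return A \linkS4class{PeptideConformation}.
#' @examples
#' pep <- buildExtendedPeptide("QFKDNVILL")
#' nrow(atomTable(pep))
#' @export
buildExtendedPeptide <- function(sequence, allow_any_length = FALSE) {
  sequence <- .check_sequence(sequence, allow_any_length)
  topo <- .peptide_topology(sequence)
  vals <- lapply(topo$torsions$id, function(v) 180)
  names(vals) <- topo$torsions$id
  xyz <- .peptide_build_coords(topo, vals)
  .new_peptide(sequence, topo, xyz)
}

#' Build a peptide conformation from explicit heavy-atom coordinates
#'
#' Maps coordinates (e.g. read from a PDB chain) onto the package's residue
#' topology by residue index and atom name.  A missing C-terminal \code{OXT}
#' is rebuilt at ideal geometry; any other missing atom is an error.  The
#' resulting conformation keeps the input geometry as-is (it is not
#' idealized); dihedral edits still preserve whatever bonded geometry the
#' input had.
#'
#' @param sequence One-letter amino-acid string matching the coordinates.
#' @param df Data frame with columns \code{resno}, \code{name}, \code{x},
#'   \code{y}, \code{z} (one row per heavy atom).
#' @param allow_any_length Logical override for the class I length check.
#' @return A \linkS4class{PeptideConformation}.
#' @export
peptideFromCoords <- function(sequence, df, allow_any_length = FALSE) {
  sequence <- .check_sequence(sequence, allow_any_length)
  topo <- .peptide_topology(sequence)
  key_in <- paste(df$resno, df$name)
  key_topo <- paste(topo$atoms$resno, topo$atoms$name)
  m <- match(key_topo, key_in)
  xyz <- cbind(df$x[m], df$y[m], df$z[m])
  missing <- which(is.na(m))
  oxt_row <- which(topo$atoms$name == "OXT")
  if (length(setdiff(missing, oxt_row)))
    stop("missing heavy atoms: ",
         paste(key_topo[setdiff(missing, oxt_row)], collapse = ", "))
  if (oxt_row %in% missing) {
    L <- max(topo$atoms$resno)
    ids <- function(nm) which(topo$atoms$resno == L & topo$atoms$name == nm)
    psi_o <- dihedralAngle(xyz[ids("N"), ], xyz[ids("CA"), ],
                           xyz[ids("C"), ], xyz[ids("O"), ])
    xyz[oxt_row, ] <- .nerf_place(xyz[ids("N"), ], xyz[ids("CA"), ],
                                  xyz[ids("C"), ], .bb_geom$c_oxt,
                                  .bb_geom$ang_ca_c_oxt, psi_o + 180)
  }
  .new_peptide(sequence, topo, xyz)
}

#' List the named dihedrals of a peptide
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @param rotatable_only Return only rotatable dihedrals.
#' @return Character vector of dihedral identifiers such as \code{"phi:3"}.
#' @export
listDihedrals <- function(peptide, rotatable_only = TRUE) {
  tt <- peptide@torsions
  if (rotatable_only) tt <- tt[tt$rotatable, , drop = FALSE]
  tt$id
}

.torsion_row <- function(peptide, dihedral_id) {
  k <- match(dihedral_id, peptide@torsions$id)
  if (is.na(k)) stop("unknown dihedral id: ", dihedral_id)
  k
}

#' Read a named dihedral (degrees)
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @param dihedral_id Identifier from \code{\link{listDihedrals}}.
#' @return Angle in degrees in (-180, 180].
#' @export
getDihedral <- function(peptide, dihedral_id) {
  k <- .torsion_row(peptide, dihedral_id)
  tt <- peptide@torsions
  x <- peptide@coords
  dihedralAngle(x[tt$a[k], ], x[tt$b[k], ], x[tt$c[k], ], x[tt$d[k], ])
}

#' Set a named dihedral (degrees)
#'
#' Rotates the atoms distal to the dihedral's bond axis rigidly; no bond
#' length or bond angle changes.
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @param dihedral_id Identifier from \code{\link{listDihedrals}}.
#' @param angle Target angle, degrees.
#' @return The modified \linkS4class{PeptideConformation}.
#' @export
setDihedral <- function(peptide, dihedral_id, angle) {
  k <- .torsion_row(peptide, dihedral_id)
  tt <- peptide@torsions
  x <- peptide@coords
  cur <- dihedralAngle(x[tt$a[k], ], x[tt$b[k], ], x[tt$c[k], ], x[tt$d[k], ])
  delta <- angle - cur
  if (delta == 0) return(peptide)
  b <- x[tt$b[k], ]; cc <- x[tt$c[k], ]
  u <- .unit(b - cc)  # rotating distal atoms about c->b advances the dihedral
  mv <- peptide@moving[[k]]
  x[mv, ] <- .rotate_about_axis(x[mv, , drop = FALSE], cc, u, delta)
  peptide@coords <- x
  peptide
}

# set several dihedrals at once (named vector), cheaper than repeated calls
.set_dihedrals <- function(peptide, values) {
  for (nm in names(values)) peptide <- setDihedral(peptide, nm, values[[nm]])
  peptide
}

#' Verify bonded geometry against the ideal residue topology
#'
#' Recomputes every spanning-tree bond length and bonded angle from the
#' coordinates and compares with the ideal values recorded at construction.
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @return List with \code{max_bond_dev} (Angstrom), \code{max_angle_dev}
#'   (degrees), and the underlying deviation vectors.
#' @export
checkGeometry <- function(peptide) {
  x <- peptide@coords
  ib <- peptide@idealBonds
  d <- sqrt(rowSums((x[ib$i, , drop = FALSE] - x[ib$j, , drop = FALSE])^2))
  bond_dev <- d - ib$r
  ia <- peptide@idealAngles
  ang <- vapply(seq_len(nrow(ia)), function(k) {
    bondAngle(x[ia$i[k], ], x[ia$j[k], ], x[ia$k[k], ])
  }, 1)
  ang_dev <- ang - ia$theta
  list(max_bond_dev = max(abs(bond_dev)), max_angle_dev = max(abs(ang_dev)),
       bond_dev = bond_dev, angle_dev = ang_dev)
}

#' All-heavy-atom RMSD between two conformations of the same peptide
#'
#' Computed in the frame the coordinates are expressed in -- no additional
#' superposition is applied.  For cross-receptor comparisons, superpose the
#' receptors first (\code{\link{superposeReceptors}}).
#'
#' @param a,b \linkS4class{PeptideConformation} objects with identical
#'   sequences.
#' @return RMSD in Angstrom.
#' @export
heavyAtomRMSD <- function(a, b) {
  if (is(a, "BindingMode")) a <- a@peptide
  if (is(b, "BindingMode")) b <- b@peptide
  if (a@sequence != b@sequence)
    stop("sequence mismatch: ", a@sequence, " vs ", b@sequence)
  sqrt(mean(rowSums((a@coords - b@coords)^2)))
}

#' Apply a rigid transform to a peptide
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @param R 3 x 3 rotation matrix.
#' @param t Length-3 translation.
#' @return The transformed conformation.
#' @export
transformPeptide <- function(peptide, R = diag(3), t = c(0, 0, 0)) {
  peptide@coords <- .apply_rigid(peptide@coords, R, t)
  peptide
}
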