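#' @include peptide.R AllGenerics.R
NULL

# PDB input/output.  Reading is backed by bio3d::read.pdb after a
# fixed-column validation pass (so malformed coordinate fields are reported
# with their line number); writing serializes the package's own containers
# with standard fixed-column ATOM records, using MODEL/ENDMDL blocks for
# ensembles.

.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  coord_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  for (ln in coord_lines) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      field <- substr(lines[ln], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(field))))
        stop("malformed coordinate field at line ", ln, ": '", field, "'")
    }
  }
  invisible(lines)
}

#' Read a PDB file and label receptor/peptide chains
#'
#' Parses fixed-column ATOM/HETATM records, drops waters and non-standard
#' HETATM groups, and assigns chain roles: a chain whose residue count falls
#' in \code{peptide_range} is labeled the peptide, all others the receptor.
#'
#' @param path PDB file path.
#' @param peptide_range Length-2 integer: residue-count window used to
#'   auto-detect the peptide chain (default 8-11).
#' @param require_peptide Error if no chain of peptide length is present.
#' @return A list of class \code{"pdbComplex"}: \code{atoms} (data frame with
#'   \code{name}, \code{el}, \code{resid}, \code{chain}, \code{resno},
#'   \code{x}, \code{y}, \code{z}), \code{peptide_chain} (chain id or
#'   \code{NA}), \code{receptor_chains}.
#' @export
readPDB <- function(path, peptide_range = c(8L, 11L), require_peptide = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  drop <- (a$type == "HETATM" & !(a$resid %in% .std_resids)) |
    a$resid %in% c("HOH", "WAT")
  a <- a[!drop & a$elesy != "H", , drop = FALSE]
  el <- a$elesy
  el[is.na(el) | !nzchar(el)] <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  atoms <- data.frame(name = a$elety, el = el, resid = a$resid,
                      chain = a$chain, resno = a$resno,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  chains <- unique(atoms$chain)
  nres <- vapply(chains, function(ch)
    length(unique(atoms$resno[atoms$chain == ch])), 1L)
  pep <- chains[nres >= peptide_range[1] & nres <= peptide_range[2]]
  pep_chain <- if (length(pep)) pep[1] else NA_character_
  if (require_peptide && is.na(pep_chain))
    stop("role assignment: no chain with ", peptide_range[1], "-",
         peptide_range[2], " residues found for the peptide role")
  structure(list(atoms = atoms, peptide_chain = pep_chain,
                 receptor_chains = setdiff(chains, pep_chain), path = path),
            class = "pdbComplex")
}

#' @export
print.pdbComplex <- function(x, ...) {
  cat("pdbComplex:", nrow(x$atoms), "atoms;",
      "receptor chains:", paste(x$receptor_chains, collapse = ","),
      "; peptide chain:", x$peptide_chain, "\n")
  invisible(x)
}

#' Extract the peptide chain of a parsed complex as a PeptideConformation
#'
#' @param struct A \code{pdbComplex} from \code{\link{readPDB}}.
#' @return A \linkS4class{PeptideConformation} with the as-read geometry.
#' @export
complexPeptide <- function(struct) {
  if (is.na(struct$peptide_chain)) stop("structure has no peptide chain")
  a <- struct$atoms[struct$atoms$chain == struct$peptide_chain, , drop = FALSE]
  resnos <- sort(unique(a$resno))
  res3 <- vapply(resnos, function(r) a$resid[a$resno == r][1], "")
  seq1 <- paste(.aa_codes1[res3], collapse = "")
  if (grepl("NA", seq1, fixed = TRUE)) stop("non-standard peptide residue")
  a$resno <- match(a$resno, resnos)  # renumber 1..L
  peptideFromCoords(seq1, a, allow_any_length = TRUE)
}

.fmt_atom <- function(serial, name, resid, chain, resno, xyz, el) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resid, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0, el)
}

.peptide_pdb_lines <- function(peptide, chain = "C", serial0 = 0L) {
  at <- peptide@atoms
  res3 <- .aa_names3[strsplit(peptide@sequence, "")[[1]]]
  vapply(seq_len(nrow(at)), function(k) {
    .fmt_atom(serial0 + k, at$name[k], res3[at$resno[k]], chain, at$resno[k],
              peptide@coords[k, ], at$el[k])
  }, "")
}

.receptor_pdb_lines <- function(receptor, chain = "A", serial0 = 0L) {
  at <- receptor@atoms
  resid <- if ("resid" %in% names(at)) at$resid else rep("UNK", nrow(at))
  vapply(seq_len(nrow(at)), function(k) {
    .fmt_atom(serial0 + k, at$name[k], resid[k], chain, at$resno[k],
              receptor@coords[k, ], at$el[k])
  }, "")
}

#' Write structures to a PDB file
#'
#' Writes a \linkS4class{PeptideConformation} (chain C), a
#' \linkS4class{Receptor} (chain A), a receptor--peptide complex (both), or
#' an \linkS4class{Ensemble} (one MODEL block per binding mode).
#'
#' @param x Object to write.
#' @param path Output file path.
#' @param receptor Optional \linkS4class{Receptor} written alongside
#'   a peptide or ensemble.
#' @return Invisibly, the path.
#' @export
setGeneric("writePDB", function(x, path, receptor = NULL)
  standardGeneric("writePDB"))

#' @rdname writePDB
setMethod("writePDB", "PeptideConformation", function(x, path, receptor = NULL) {
  lines <- character()
  n0 <- 0L
  if (!is.null(receptor)) {
    lines <- c(lines, .receptor_pdb_lines(receptor), "TER")
    n0 <- nrow(receptor@atoms)
  }
  lines <- c(lines, .peptide_pdb_lines(x, serial0 = n0), "TER", "END")
  writeLines(lines, path)
  invisible(path)
})

#' @rdname writePDB
setMethod("writePDB", "Receptor", function(x, path, receptor = NULL) {
  writeLines(c(.receptor_pdb_lines(x), "TER", "END"), path)
  invisible(path)
})

#' @rdname writePDB
setMethod("writePDB", "BindingMode", function(x, path, receptor = NULL) {
  writePDB(x@peptide, path, receptor = receptor)
})

#' @rdname writePDB
setMethod("writePDB", "Ensemble", function(x, path, receptor = NULL) {
  lines <- character()
  if (!is.null(receptor)) lines <- c(lines, .receptor_pdb_lines(receptor), "TER")
  for (i in seq_along(x@modes)) {
    lines <- c(lines, sprintf("MODEL %8d", i),
               .peptide_pdb_lines(x@modes[[i]]@peptide), "TER", "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
})

#' Read a multi-model peptide ensemble written by \code{writePDB}
#'
#' @param path PDB file with MODEL/ENDMDL blocks of one peptide chain.
#' @param receptor_id Receptor id recorded in the rebuilt ensemble's pair id.
#' @return An \linkS4class{Ensemble} (modes carry no scores).
#' @export
readEnsemblePDB <- function(path, receptor_id = "pdb") {
  lines <- .validate_pdb_lines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) stop("no MODEL records in ", path)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  mode_list <- lapply(seq_along(starts), function(i) {
    writeLines(c(lines[(starts[i] + 1):(ends[i] - 1)], "END"), tmp)
    st <- readPDB(tmp, require_peptide = TRUE)
    new("BindingMode", peptide = complexPeptide(st), scores = numeric(),
        provenance = list(round = NA_integer_, replicate = i, seed = NA_integer_))
  })
  seq1 <- mode_list[[1]]@peptide@sequence
  new("Ensemble", pairId = paste0(seq1, "|", receptor_id), modes = mode_list)
}

#' Build a Receptor from a parsed PDB complex
#'
#' Uses the receptor chains as the rigid atom set (classes assigned from the
#' residue topology tables) and derives the binding-site box, groove axis
#' and anchor sites from the bound peptide chain.
#'
#' @param struct A \code{pdbComplex} with both receptor and peptide chains.
#' @param id Receptor identifier (defaults to the file name).
#' @param box_margin Box margin around the bound peptide, Angstrom.
#' @return A \linkS4class{Receptor}.
#' @export
receptorFromStructure <- function(struct, id = NULL,
                                  box_margin = 4) {
  if (is.na(struct$peptide_chain))
    stop("structure has no peptide chain to derive the binding site from")
  pep <- complexPeptide(struct)
  a <- struct$atoms[struct$atoms$chain %in% struct$receptor_chains, ,
                    drop = FALSE]
  a <- assignAtomClasses(a)
  x <- pep@coords; at <- pep@atoms
  L <- max(at$resno)
  lo <- apply(x, 2, min) - box_margin
  hi <- apply(x, 2, max) + box_margin
  site <- function(rn) {
    m <- rbind(x[at$resno == rn & at$name == "N", ],
               x[at$resno == rn & at$name == "CA", ],
               x[at$resno == rn & at$name == "C", ])
    rownames(m) <- c("N", "CA", "C")
    m
  }
  ca1 <- x[at$resno == 1 & at$name == "CA", ]
  caL <- x[at$resno == L & at$name == "CA", ]
  new("Receptor",
      id = if (is.null(id)) basename(struct$path) else id,
      atoms = data.frame(name = a$name, el = a$el, resno = a$resno,
                         resid = a$resid, class = a$class,
                         stringsAsFactors = FALSE),
      coords = cbind(a$x, a$y, a$z),
      boxCenter = (lo + hi) / 2, boxDims = hi - lo,
      grooveAxis = .unit(caL - ca1),
      anchorSites = list(n = site(1), c = site(L)))
}
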