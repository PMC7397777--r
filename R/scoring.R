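#' @include topology.R AllClasses.R AllGenerics.R
NULL

# Empirical pairwise scoring.  Three scoring-function variants are provided:
#
#   vina_class    gauss1 + gauss2 + repulsion + hydrophobic + H-bond linear
#                 terms evaluated on surface distance (published Vina weights)
#   vinardo_class single gauss + repulsion + hydrophobic + H-bond with the
#                 Vinardo weights and shifted radii
#   ad4_class     grid-free direct-sum 12-6 van der Waals with a 12-10
#                 H-bond well (AutoDock4-style free-energy coefficients,
#                 no charge/desolvation model)
#
# All functions sum over receptor-peptide heavy-atom pairs within an 8 A
# interatomic cutoff and add a torsional penalty proportional to the number
# of active rotatable bonds.  Energies in kcal/mol, lower is better.

.class_levels <- c("hC", "pC", "don", "acc", "donacc", "oth")

.score_params <- list(
  vina_class = list(
    form = "vina",
    radii = c(C = 1.9, N = 1.8, O = 1.7, S = 2.0),
    w = c(gauss1 = -0.035579, gauss2 = -0.005156, repulsion = 0.840245,
          hydrophobic = -0.035069, hbond = -0.587439),
    gauss1_width = 0.5, gauss2_offset = 3, gauss2_width = 2,
    hyd_lo = 0.5, hyd_hi = 1.5, hb_lo = -0.7, hb_hi = 0,
    w_tors = 0.05846),
  vinardo_class = list(
    form = "vinardo",
    radii = c(C = 2.0, N = 1.7, O = 1.6, S = 2.0),
    w = c(gauss1 = -0.045, repulsion = 0.8,
          hydrophobic = -0.035, hbond = -0.6),
    gauss1_width = 0.8,
    hyd_lo = 0, hyd_hi = 2.5, hb_lo = -0.6, hb_hi = 0,
    w_tors = 0.05846),
  ad4_class = list(
    form = "ad4",
    radii = c(C = 2.0, N = 1.75, O = 1.6, S = 2.0),  # Rii/2
    eps = c(C = 0.15, N = 0.16, O = 0.20, S = 0.20),
    w_vdw = 0.1662, w_hb = 0.1209,
    hb_R = 2.9, hb_eps = 5.0, r_min = 0.8,
    w_tors = 0.2983)
)

.scoring_fn_ids <- names(.score_params)

#' Scoring-function identifiers
#'
#' @return Character vector of the available scoring-function ids.
#' @export
scoringFunctions <- function() .scoring_fn_ids

.check_fn <- function(fn) {
  if (!fn %in% .scoring_fn_ids)
    stop("unknown scoring function id: ", fn,
         " (use one of ", paste(.scoring_fn_ids, collapse = ", "), ")")
  fn
}

.el_radii <- function(el, radii) {
  r <- radii[el]
  r[is.na(r)] <- mean(radii)
  unname(r)
}

#' Assign scoring atom classes to an atom table
#'
#' Fills the \code{class} column of an atom data frame from the residue
#' topology tables (keyed by residue name + atom name).  Carbons bonded only
#' to carbon/hydrogen are hydrophobic; heteroatom donor/acceptor roles come
#' from the per-residue tables.  Atoms not covered by the tables fall back to
#' an element default (C hydrophobic, N donor, O acceptor, S other).
#'
#' @param atoms Data frame with at least \code{name}, \code{el} and (for
#'   table lookup) \code{resid} columns.
#' @return The data frame with a filled \code{class} column.
#' @export
assignAtomClasses <- function(atoms) {
  if (any(!atoms$el %in% c("C", "N", "O", "S")))
    stop("unknown element(s): ",
         paste(unique(setdiff(atoms$el, c("C", "N", "O", "S"))), collapse = ", "))
  cl <- rep(NA_character_, nrow(atoms))
  if ("resid" %in% names(atoms)) {
    for (res3 in intersect(unique(atoms$resid), .std_resids)) {
      topo <- residueTopology(.aa_codes1[res3], terminal = TRUE)
      sel <- atoms$resid == res3
      m <- match(atoms$name[sel], topo$atoms$name)
      cl[sel] <- topo$atoms$class[m]
    }
  }
  fallback <- c(C = "hC", N = "don", O = "acc", S = "oth")
  cl[is.na(cl)] <- fallback[atoms$el[is.na(cl)]]
  atoms$class <- cl
  atoms
}

# Pairwise interaction terms between two atom sets.  Returns the named term
# vector (without the torsional penalty).  xyz: n x 3; cl: class strings;
# rad: per-atom radii for this scoring function.
.pair_terms <- function(p, axyz, acl, bxyz, bcl, cutoff = 8) {
  D2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), "+") - 2 * axyz %*% t(bxyz)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  sel <- which(D <= cutoff)
  if (!length(sel)) {
    nm <- if (p$form == "ad4") c("vdw", "hbond") else names(p$w)
    return(structure(numeric(length(nm)), names = nm))
  }
  ai <- ((sel - 1) %% nrow(axyz)) + 1
  bi <- ((sel - 1) %/% nrow(axyz)) + 1
  r <- D[sel]
  aclv <- acl[ai]; bclv <- bcl[bi]
  hb_pair <- ((aclv %in% c("don", "donacc")) & (bclv %in% c("acc", "donacc"))) |
    ((aclv %in% c("acc", "donacc")) & (bclv %in% c("don", "donacc")))
  if (p$form %in% c("vina", "vinardo")) {
    d <- r - (attr(acl, "rad")[ai] + attr(bcl, "rad")[bi])
    out <- c()
    out["gauss1"] <- sum(exp(-(d / p$gauss1_width)^2))
    if (p$form == "vina")
      out["gauss2"] <- sum(exp(-((d - p$gauss2_offset) / p$gauss2_width)^2))
    out["repulsion"] <- sum(ifelse(d < 0, d^2, 0))
    hyd <- (aclv == "hC") & (bclv == "hC")
    ramp <- function(x, lo, hi) pmin(1, pmax(0, (hi - x) / (hi - lo)))
    out["hydrophobic"] <- sum(ramp(d[hyd], p$hyd_lo, p$hyd_hi))
    out["hbond"] <- sum(ramp(d[hb_pair], p$hb_lo, p$hb_hi))
    w <- p$w[intersect(names(p$w), names(out))]
    out <- out[names(w)] * w
    return(out)
  }
  # ad4 form
  rr <- pmax(r, p$r_min)
  Rij <- attr(acl, "rad")[ai] + attr(bcl, "rad")[bi]
  epsij <- sqrt(attr(acl, "eps")[ai] * attr(bcl, "eps")[bi])
  q6 <- (Rij / rr)^6
  vdw_all <- epsij * (q6^2 - 2 * q6)
  qh <- (p$hb_R / rr)^2
  hb_all <- p$hb_eps * (5 * qh^6 - 6 * qh^5)
  c(vdw = p$w_vdw * sum(vdw_all[!hb_pair]),
    hbond = p$w_hb * sum(hb_all[hb_pair]))
}

# attach per-atom radii (and ad4 epsilons) to a class vector for a function
.score_ctx <- function(atoms, fn) {
  p <- .score_params[[fn]]
  cl <- atoms$class
  attr(cl, "rad") <- .el_radii(atoms$el, p$radii)
  if (p$form == "ad4") attr(cl, "eps") <- .el_radii(atoms$el, p$eps)
  cl
}

.n_rotatable <- function(peptide) sum(peptide@torsions$rotatable)

.in_inflated_box <- function(xyz, receptor, margin = 5) {
  lo <- receptor@boxCenter - receptor@boxDims / 2 - margin
  hi <- receptor@boxCenter + receptor@boxDims / 2 + margin
  all(sweep(xyz, 2, lo, ">=") & sweep(xyz, 2, hi, "<="))
}

#' Score a binding mode against a receptor
#'
#' Sums distance-dependent pair terms over all receptor-peptide heavy-atom
#' pairs within the 8 Angstrom cutoff, evaluated on surface distance
#' (interatomic distance minus the two van der Waals radii), and adds a
#' torsional penalty proportional to the number of active rotatable bonds.
#' Deterministic for fixed input.
#'
#' @param mode A \linkS4class{BindingMode} or
#'   \linkS4class{PeptideConformation}.
#' @param receptor A \linkS4class{Receptor}; the pose must lie inside the
#'   receptor box inflated by 5 Angstrom.
#' @param fn Scoring-function id (see \code{\link{scoringFunctions}}).
#' @param n_rot Number of active rotatable bonds for the torsional penalty;
#'   defaults to the peptide's full rotatable-dihedral count.
#' @return Named numeric of class \code{"ScoreBreakdown"}: per-term energies
#'   plus \code{total} (kcal/mol); \code{total} equals the sum of the terms.
#' @export
scoreMode <- function(mode, receptor, fn = "vina_class", n_rot = NULL) {
  fn <- .check_fn(fn)
  peptide <- if (is(mode, "BindingMode")) mode@peptide else mode
  if (any(is.na(peptide@atoms$class)))
    stop("atom classes must be assigned before scoring")
  if (!.in_inflated_box(peptide@coords, receptor))
    stop("pose outside the inflated receptor box")
  if (is.null(n_rot)) n_rot <- .n_rotatable(peptide)
  p <- .score_params[[fn]]
  rcl <- .score_ctx(receptor@atoms, fn)
  pcl <- .score_ctx(peptide@atoms, fn)
  terms <- .pair_terms(p, receptor@coords, rcl, peptide@coords, pcl)
  terms["torsion"] <- p$w_tors * n_rot
  out <- c(terms, total = sum(terms))
  class(out) <- "ScoreBreakdown"
  out
}

#' @export
print.ScoreBreakdown <- function(x, ...) {
  cat("ScoreBreakdown (kcal/mol):\n")
  for (nm in names(x)) cat(sprintf("  %-12s %10.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Rescore every mode of an ensemble with one or more scoring functions
#'
#' Geometry is untouched and mode order preserved; each mode gains one score
#' per requested function.
#'
#' @param ensemble An \linkS4class{Ensemble}.
#' @param receptor The \linkS4class{Receptor}.
#' @param fns Character vector of scoring-function ids (non-empty).
#' @return The ensemble with filled score maps.
#' @export
rescoreEnsemble <- function(ensemble, receptor, fns = scoringFunctions()) {
  if (!length(fns)) stop("empty scoring-function list")
  for (fn in fns) .check_fn(fn)
  if (!nModes(ensemble)) stop("empty ensemble")
  ensemble@modes <- lapply(ensemble@modes, function(m) {
    for (fn in fns) {
      br <- scoreMode(m, receptor, fn)
      m@scores[fn] <- unname(br["total"])
    }
    m
  })
  ensemble
}

#' Top-m binding modes under one scoring function
#'
#' Ascending energy (lower is better); ties broken by (round, replicate,
#' seed) provenance order.  Returns \code{min(m, nModes)} modes.
#'
#' @param ensemble A scored \linkS4class{Ensemble}.
#' @param fn Scoring-function id whose scores are used.
#' @param m Number of modes to return (default 5).
#' @return List of \linkS4class{BindingMode} objects, best first.
#' @export
rankTop <- function(ensemble, fn = "vina_class", m = 5) {
  fn <- .check_fn(fn)
  sc <- vapply(ensemble@modes, function(x) {
    if (!fn %in% names(x@scores)) NA_real_ else x@scores[[fn]]
  }, 1)
  if (anyNA(sc)) stop("modes missing scores for ", fn, "; rescore first")
  pv <- function(field) vapply(ensemble@modes, function(x) {
    v <- x@provenance[[field]]
    if (is.null(v) || is.na(v)) Inf else as.numeric(v)
  }, 1)
  ord <- order(sc, pv("round"), pv("replicate"), pv("seed"))
  ensemble@modes[ord[seq_len(min(m, length(ord)))]]
}

#' Tabulate ensemble scores
#'
#' @param ensemble A scored \linkS4class{Ensemble}.
#' @return Data frame: \code{mode_id}, \code{round}, \code{replicate},
#'   one column per scoring function present.
#' @export
scoreTable <- function(ensemble) {
  fns <- unique(unlist(lapply(ensemble@modes, function(m) names(m@scores))))
  rows <- lapply(seq_along(ensemble@modes), function(i) {
    m <- ensemble@modes[[i]]
    out <- data.frame(mode_id = i,
                      round = m@provenance$round %||% NA,
                      replicate = m@provenance$replicate %||% NA)
    for (fn in fns) out[[fn]] <- if (fn %in% names(m@scores)) m@scores[[fn]] else NA
    out
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
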