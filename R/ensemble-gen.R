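#' @include docking.R
NULL

# Anchored ensemble generation: place the peptide termini on template
# anchors, close the backbone loop many times by randomized coordinate
# descent, rebuild side chains from a small rotamer set, locally optimize,
# and optionally iterate with the best mode's termini as the next template.

#' Construct an anchor template
#'
#' @param nTerm,cTerm 3 x 3 matrices (rows N, CA, C) of backbone anchor
#'   coordinates for the first and last peptide residues, Angstrom.
#' @param sourceId Template identifier.
#' @param tolerance Allowed anchor deviation, Angstrom.
#' @return An \linkS4class{AnchorTemplate}.
#' @export
AnchorTemplate <- function(nTerm, cTerm, sourceId = "template",
                           tolerance = 0.3) {
  rownames(nTerm) <- rownames(cTerm) <- c("N", "CA", "C")
  new("AnchorTemplate", nTerm = nTerm, cTerm = cTerm, sourceId = sourceId,
      tolerance = tolerance)
}

#' Anchor template from a receptor's recorded anchor sites
#'
#' @param receptor A \linkS4class{Receptor}.
#' @param tolerance Allowed anchor deviation, Angstrom.
#' @return An \linkS4class{AnchorTemplate}.
#' @export
anchorTemplateFromReceptor <- function(receptor, tolerance = 0.3) {
  AnchorTemplate(receptor@anchorSites$n, receptor@anchorSites$c,
                 sourceId = receptor@id, tolerance = tolerance)
}

#' Anchor template from a peptide pose's own termini
#'
#' @param peptide A \linkS4class{PeptideConformation} or
#'   \linkS4class{BindingMode}.
#' @param tolerance Allowed anchor deviation, Angstrom.
#' @return An \linkS4class{AnchorTemplate}.
#' @export
anchorTemplateFromPeptide <- function(peptide, tolerance = 0.3) {
  if (is(peptide, "BindingMode")) peptide <- peptide@peptide
  x <- peptide@coords; at <- peptide@atoms
  L <- max(at$resno)
  site <- function(rn) rbind(x[at$resno == rn & at$name == "N", ],
                             x[at$resno == rn & at$name == "CA", ],
                             x[at$resno == rn & at$name == "C", ])
  AnchorTemplate(site(1), site(L), sourceId = peptide@sequence,
                 tolerance = tolerance)
}

.backbone_site <- function(peptide, rn) {
  at <- peptide@atoms
  rbind(peptide@coords[at$resno == rn & at$name == "N", ],
        peptide@coords[at$resno == rn & at$name == "CA", ],
        peptide@coords[at$resno == rn & at$name == "C", ])
}

#' Ensemble-generation configuration
#'
#' @param n_backbones Loop-closure samples per round.
#' @param rounds Iterative template rounds.
#' @param closure_tolerance Anchor-gap tolerance, Angstrom.
#' @param seed Integer seed.
#' @param fn Scoring-function id used to pick the best mode.
#' @param minimize Apply the internal torsion-space minimizer to each mode.
#' @param max_iter Coordinate-descent iteration cap per closure sample.
#' @return Validated list of class \code{"EnsembleConfig"}.
#' @export
EnsembleConfig <- function(n_backbones = 100, rounds = 1,
                           closure_tolerance = 0.3, seed = 1,
                           fn = "vina_class", minimize = FALSE,
                           max_iter = 1000) {
  if (n_backbones < 1) stop("n_backbones must be >= 1")
  if (rounds < 1) stop("rounds must be >= 1")
  .check_fn(fn)
  structure(list(n_backbones = as.integer(n_backbones),
                 rounds = as.integer(rounds),
                 closure_tolerance = closure_tolerance,
                 seed = as.integer(seed), fn = fn, minimize = minimize,
                 max_iter = as.integer(max_iter)),
            class = c("EnsembleConfig", "list"))
}

#' Place a peptide onto a template's N-terminal anchor
#'
#' Rigidly superposes the first residue's backbone (N, CA, C) onto the
#' template's N-terminal anchor and registers the C-terminal anchor as the
#' loop-closure target.  Errors if the chain cannot span the anchor-anchor
#' distance.
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @param template An \linkS4class{AnchorTemplate}.
#' @return List of class \code{"AnchoredPeptide"}: \code{peptide} (placed),
#'   \code{template}.
#' @export
placeAnchors <- function(peptide, template) {
  L <- max(peptide@atoms$resno)
  span <- .vnorm(template@cTerm["CA", ] - template@nTerm["CA", ])
  reach <- 3.8 * (L - 1) + 0.5
  if (span > reach)
    stop("anchors ", round(span, 1), " A apart exceed the ", L,
         "-mer maximum span of ", round(reach, 1), " A")
  fit <- kabschFit(.backbone_site(peptide, 1), template@nTerm)
  peptide@coords <- .apply_rigid(peptide@coords, fit$R, fit$t)
  structure(list(peptide = peptide, template = template),
            class = "AnchoredPeptide")
}

.anchor_gap <- function(peptide, template) {
  L <- max(peptide@atoms$resno)
  sqrt(mean(rowSums((.backbone_site(peptide, L) - template@cTerm)^2)))
}

# closed-form optimal angle update for one coordinate-descent step: rotate
# the moving set about the dihedral axis to bring the C-terminal backbone
# atoms closest to their targets
.ccd_delta <- function(peptide, k, target_idx, target_xyz) {
  tt <- peptide@torsions
  x <- peptide@coords
  b <- x[tt$b[k], ]; cc <- x[tt$c[k], ]
  u <- .unit(b - cc)  # setDihedral's rotation axis for +delta
  sa <- 0; sb <- 0
  for (m in seq_along(target_idx)) {
    if (!(target_idx[m] %in% peptide@moving[[k]])) next
    r <- x[target_idx[m], ] - cc; r <- r - sum(r * u) * u
    s <- target_xyz[m, ] - cc; s <- s - sum(s * u) * u
    sa <- sa + sum(r * s)
    sb <- sb + sum(.cross3(u, r) * s)
  }
  if (sa == 0 && sb == 0) return(0)
  atan2(sb, sa) * .rad2deg
}

#' Close the backbone loop onto the C-terminal anchor, many times
#'
#' Randomized coordinate descent on the interior phi/psi dihedrals: starting
#' from a randomized backbone, dihedrals are visited in random order and
#' each set to the closed-form angle minimizing the distance of the last
#' residue's N/CA/C to the template anchor, until the gap falls below the
#' tolerance or the iteration cap is hit (failed samples are dropped with a
#' message).  Bonded geometry is untouched throughout.
#'
#' @param anchored An \code{"AnchoredPeptide"} from \code{\link{placeAnchors}}.
#' @param n Number of closure samples.
#' @param seed Integer seed.
#' @param tolerance Anchor-gap tolerance (RMSD over N/CA/C), Angstrom.
#' @param max_iter Coordinate-descent iteration cap per sample.
#' @return List of closed \linkS4class{PeptideConformation} objects.
#' @export
closeLoops <- function(anchored, n, seed = 1, tolerance = 0.3,
                       max_iter = 1000) {
  if (n < 1) stop("n must be >= 1")
  pep0 <- anchored$peptide
  template <- anchored$template
  at <- pep0@atoms
  L <- max(at$resno)
  target_idx <- c(which(at$resno == L & at$name == "N"),
                  which(at$resno == L & at$name == "CA"),
                  which(at$resno == L & at$name == "C"))
  tt <- pep0@torsions
  dof <- tt$id[tt$rotatable & tt$type %in% c("phi", "psi") &
                 !(tt$type == "phi" & tt$resno == 1)]
  set.seed(seed)
  out <- list()
  dropped <- 0L
  for (j in seq_len(n)) {
   closed_ok <- FALSE
   for (attempt in 1:3) {   # per-sample retries with fresh initialization
    p <- pep0
    if (!(j == 1 && .anchor_gap(p, template) <= tolerance)) {
      # sample 1 starts from the canonical beta backbone (deterministic,
      # comparable across peptides); later samples initialize mostly from
      # the beta basin (bound class I peptides are extended-ish) with a
      # uniform-random minority for breadth
      for (id in dof) {
        k0 <- .torsion_row(p, id)
        is_phi <- p@torsions$type[k0] == "phi"
        init <- if (j == 1 && attempt == 1) {
          if (is_phi) -80 else 90
        } else if (stats::runif(1) < 0.8) {
          if (is_phi) stats::runif(1, -110, -50) else stats::runif(1, 60, 120)
        } else stats::runif(1, -180, 180)
        p <- setDihedral(p, id, init)
      }
      it <- 0L
      stall <- 0L
      g_prev <- .anchor_gap(p, template)
      while (g_prev > tolerance && it < max_iter) {
        id <- dof[sample.int(length(dof), 1)]
        k <- .torsion_row(p, id)
        delta <- .ccd_delta(p, k, target_idx, template@cTerm)
        if (delta != 0)
          p <- setDihedral(p, id, getDihedral(p, id) + delta)
        g <- .anchor_gap(p, template)
        stall <- if (g > g_prev - 1e-4) stall + 1L else 0L
        if (stall >= 15L) {  # escape a locked configuration
          for (id2 in sample(dof, 2))
            p <- setDihedral(p, id2, getDihedral(p, id2) +
                               stats::runif(1, -60, 60))
          stall <- 0L
          g <- .anchor_gap(p, template)
        }
        g_prev <- g
        it <- it + 1L
      }
      if (.anchor_gap(p, template) > tolerance) next
    }
    closed_ok <- TRUE
    break
   }
   if (!closed_ok) {
     dropped <- dropped + 1L
     next
   }
   out[[length(out) + 1]] <- p
  }
  if (dropped > 0)
    message(dropped, " of ", n, " closure samples failed and were dropped")
  if (!length(out))
    stop("loop closure failed for all ", n, " samples")
  out
}

#' Rebuild side chains against the receptor and locally optimize
#'
#' Greedy N-to-C placement from a discrete rotamer set (chi1/chi2 in
#' {-60, 60, 180}, at most 9 rotamers per residue; later chis stay anti),
#' choosing per residue the rotamer minimizing the docking objective
#' (receptor interaction plus intra-peptide clash), followed by a
#' deterministic line-search pass over all side-chain dihedrals.  Backbone
#' and rigid-body degrees of freedom are not touched, so anchor placement is
#' preserved.
#'
#' @param backbone A \linkS4class{PeptideConformation} (full-atom; side
#'   chains are re-posed in place).
#' @param receptor The \linkS4class{Receptor}.
#' @param fn Scoring-function id.
#' @param ctx Optional precomputed energy context.
#' @return A \linkS4class{BindingMode} (unscored; use
#'   \code{\link{rescoreEnsemble}}).
#' @export
rebuildSideChains <- function(backbone, receptor, fn = "vina_class",
                              ctx = NULL, anchor = NULL) {
  if (is.null(ctx)) ctx <- .energy_ctx(receptor, backbone, fn)
  p <- backbone
  tt <- p@torsions
  rc <- .round_ctx(ctx, seq_len(nrow(p@atoms)), .n_rotatable(p))
  rot_vals <- c(-60, 60, 180)
  for (rn in sort(unique(tt$resno[tt$type %in% c("chi1", "chi2")]))) {
    chi1 <- tt$id[tt$resno == rn & tt$type == "chi1" & tt$rotatable]
    chi2 <- tt$id[tt$resno == rn & tt$type == "chi2" & tt$rotatable]
    if (!length(chi1)) next
    combos <- if (length(chi2)) {
      expand.grid(c1 = rot_vals, c2 = rot_vals)
    } else data.frame(c1 = rot_vals)
    best <- NULL; best_e <- Inf
    for (ci in seq_len(nrow(combos))) {
      q <- setDihedral(p, chi1, combos$c1[ci])
      if (length(chi2)) q <- setDihedral(q, chi2, combos$c2[ci])
      e <- .pose_energy(q@coords, rc)
      if (e < best_e) { best_e <- e; best <- q }
    }
    p <- best
  }
  chis <- tt$id[tt$rotatable & grepl("^chi", tt$type)]
  e <- .pose_energy(p@coords, rc)
  if (length(chis)) {
    res <- .polish_chis(p, rc, chis, e)
    p <- res$p; e <- res$e
  }
  if (!is.null(anchor)) {
    # anchor-bounded Monte-Carlo refinement over all rotatable dihedrals:
    # greedy acceptance, moves that break the anchors are rejected
    all_rot <- tt$id[tt$rotatable]
    for (s in seq_len(60)) {
      id <- all_rot[[sample.int(length(all_rot), 1)]]
      cand <- setDihedral(p, id, getDihedral(p, id) + stats::rnorm(1, 0, 25))
      if (.anchor_gap(cand, anchor) > anchor@tolerance) next
      ec <- .pose_energy(cand@coords, rc)
      if (ec < e) { e <- ec; p <- cand }
    }
    # bounded backbone relaxation: line searches over interior phi/psi that
    # keep both anchors within the template tolerance
    bb <- tt$id[tt$rotatable & tt$type %in% c("phi", "psi")]
    for (pass in 1:2) {
      e_in <- e
      for (id in bb) {
        cur <- getDihedral(p, id)
        best_d <- 0
        for (d in c(-20, -8, -3, 3, 8, 20)) {
          cand <- setDihedral(p, id, cur + d)
          if (.anchor_gap(cand, anchor) > anchor@tolerance) next
          ec <- .pose_energy(cand@coords, rc)
          if (ec < e) { e <- ec; best_d <- d }
        }
        if (best_d != 0) p <- setDihedral(p, id, cur + best_d)
      }
      res <- .polish_chis(p, rc, chis, e)
      p <- res$p; e <- res$e
      if (e >= e_in - 1e-9) break
    }
  }
  new("BindingMode", peptide = p, scores = numeric(),
      provenance = list(round = NA_integer_, replicate = NA_integer_,
                        seed = NA_integer_))
}

# line-search polish restricted to side-chain dihedrals
.polish_chis <- function(p, rc, chis, e) {
  for (id in chis) {
    cur <- getDihedral(p, id)
    best_d <- 0
    for (d in c(-20, -10, -5, 5, 10, 20)) {
      cand <- setDihedral(p, id, cur + d)
      ec <- .pose_energy(cand@coords, rc)
      if (ec < e) { e <- ec; best_d <- d }
    }
    if (best_d != 0) p <- setDihedral(p, id, cur + best_d)
  }
  list(p = p, e = e)
}

#' Generate a binding-mode ensemble by anchored sampling
#'
#' Per round: anchor placement, loop closure (\code{n_backbones} samples),
#' side-chain rebuilding with local optimization, scoring with
#' \code{config$fn}.  After each round the best mode's termini become the
#' next round's anchor template and the best mode itself is carried into
#' the next round's ensemble, so the per-round best energy is
#' non-increasing.  Returns the union ensemble across rounds.
#'
#' @param sequence Peptide sequence (character) or a
#'   \linkS4class{PeptideConformation}.
#' @param receptor The \linkS4class{Receptor}.
#' @param template An \linkS4class{AnchorTemplate} for round 1.
#' @param config An \code{\link{EnsembleConfig}}.
#' @return A scored \linkS4class{Ensemble}; attribute \code{"round_best"}
#'   records the per-round best energies.
#' @export
generateEnsemble <- function(sequence, receptor, template,
                             config = EnsembleConfig()) {
  pep <- if (is.character(sequence)) {
    buildExtendedPeptide(sequence, allow_any_length = TRUE)
  } else sequence
  ctx <- .energy_ctx(receptor, pep, config$fn)
  all_modes <- list()
  round_best <- numeric()
  best_mode <- NULL
  for (r in seq_len(config$rounds)) {
    anch <- placeAnchors(pep, template)
    closed <- closeLoops(anch, config$n_backbones,
                         seed = childSeed(config$seed, "close", r),
                         tolerance = config$closure_tolerance,
                         max_iter = config$max_iter)
    modes <- lapply(seq_along(closed), function(i) {
      m <- rebuildSideChains(closed[[i]], receptor, config$fn, ctx = ctx,
                             anchor = template)
      if (isTRUE(config$minimize)) {
        m <- internalMinimizer(m, receptor, config$fn, ctx = ctx,
                               backbone = FALSE)
      }
      m@provenance <- list(round = r, replicate = i,
                           seed = childSeed(config$seed, "close", r))
      m@scores[config$fn] <- unname(scoreMode(m, receptor, config$fn)["total"])
      m
    })
    if (!is.null(best_mode)) {
      prev <- best_mode
      prev@provenance$round <- r
      modes <- c(list(prev), modes)
    }
    sc <- vapply(modes, function(m) m@scores[[config$fn]], 1)
    best_mode <- modes[[which.min(sc)]]
    round_best <- c(round_best, min(sc))
    # the carried-forward previous best (modes[[1]] when r > 1) is already in
    # the union; append only the fresh samples
    all_modes <- c(all_modes, if (r == 1) modes else modes[-1])
    template <- anchorTemplateFromPeptide(best_mode@peptide,
                                          tolerance = template@tolerance)
  }
  ens <- new("Ensemble",
             pairId = paste0(pep@sequence, "|", receptor@id),
             modes = all_modes)
  attr(ens, "round_best") <- round_best
  ens
}

#' Internal torsion-space minimizer
#'
#' Bounded greedy line-search descent of the docking objective over peptide
#' dihedrals (side chains, optionally backbone) -- the package's built-in
#' stand-in behind the pluggable minimizer interface.
#'
#' @param mode A \linkS4class{BindingMode}.
#' @param receptor The \linkS4class{Receptor}.
#' @param fn Scoring-function id.
#' @param ctx Optional precomputed energy context.
#' @param backbone Also relax backbone dihedrals (may move anchors).
#' @return The minimized \linkS4class{BindingMode} (scores cleared).
#' @export
internalMinimizer <- function(mode, receptor, fn = "vina_class", ctx = NULL,
                              backbone = FALSE) {
  p <- mode@peptide
  if (is.null(ctx)) ctx <- .energy_ctx(receptor, p, fn)
  rc <- .round_ctx(ctx, seq_len(nrow(p@atoms)), .n_rotatable(p))
  tt <- p@torsions
  ids <- tt$id[tt$rotatable & (grepl("^chi", tt$type) | backbone)]
  e <- .pose_energy(p@coords, rc)
  for (pass in 1:2) {
    res <- .polish_chis(p, rc, ids, e)
    p <- res$p; e <- res$e
  }
  mode@peptide <- p
  mode@scores <- numeric()
  mode
}

#' Look up an anchor template by allele name
#'
#' Resolves an allele against the local template library with the fallback
#' chain: exact allele entry, then the allele's supertype, then the global
#' default.  The shipped library is a synthetic stand-in (see its
#' \code{README.txt}); templates are expressed in a canonical groove frame
#' with the A-to-F pocket axis along x and the N-terminal CA at the origin.
#'
#' @param allele Allele name (e.g. \code{"SYN-A01"} or
#'   \code{"HLA-A*24:02"}).
#' @param library_dir Template library directory (defaults to the one
#'   shipped with the package).
#' @param tolerance Anchor tolerance of the returned template, Angstrom.
#' @return An \linkS4class{AnchorTemplate}; attribute \code{"resolution"}
#'   records which fallback level matched (allele / supertype / default).
#' @export
lookupTemplate <- function(allele,
                           library_dir = system.file("extdata", "templates",
                                                     package = "pHLAdock"),
                           tolerance = 0.3) {
  alleles <- utils::read.delim(file.path(library_dir, "alleles.tsv"),
                               stringsAsFactors = FALSE)
  tpl_file <- function(id) file.path(library_dir,
                                     sprintf("anchors_%s.tsv", id))
  level <- "default"; id <- "default"
  if (file.exists(tpl_file(allele))) {
    level <- "allele"; id <- allele
  } else if (allele %in% alleles$allele) {
    st <- alleles$supertype[match(allele, alleles$allele)]
    if (file.exists(tpl_file(st))) { level <- "supertype"; id <- st }
  }
  df <- utils::read.delim(tpl_file(id), stringsAsFactors = FALSE)
  site <- function(term) as.matrix(df[df$terminus == term, c("x", "y", "z")])
  out <- AnchorTemplate(site("N"), site("C"),
                        sourceId = paste0(allele, ":", id),
                        tolerance = tolerance)
  attr(out, "resolution") <- level
  out
}
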