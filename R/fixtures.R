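#' @include ensemble-gen.R
NULL

# Synthetic fixtures: toy receptor pockets with a planted ground-truth
# binding mode, and labeled binder/decoy screening sets.
#
# A toy pocket is built around an extended conformation of the planted
# peptide: for each peptide heavy atom, pseudo-atoms of a complementary
# scoring class are placed at a favourable surface distance on the far side
# of the groove axis, forming a sequence-specific cage whose global energy
# minimum is the planted pose.  The pockets are physically simplistic (no
# real HLA geometry); their contract is a known global minimum compatible
# with the scoring module.

.complement_class <- c(hC = "hC", pC = "hC", don = "acc", acc = "don",
                       donacc = "donacc", oth = "hC")
.class_element <- c(hC = "C", pC = "C", don = "N", acc = "O",
                    donacc = "O", oth = "C")

#' Build a toy receptor pocket with a planted binding mode
#'
#' Constructs a rigid pseudo-atom groove complementary to the extended
#' conformation of \code{planted_sequence}, with anchor sites at the planted
#' termini, a groove axis running from the first to the last residue, and a
#' binding-site box enclosing the planted pose.  At construction the planted
#' pose is verified to score strictly below \code{n_probes} random probe
#' poses; on failure the pocket is regenerated with a fresh derived seed (at
#' most 5 attempts).
#'
#' @param planted_sequence Peptide planted in the pocket (default a 9-mer).
#' @param seed Integer seed; the fixture is fully determined by it.
#' @param groove_margin Box margin around the planted pose, Angstrom.
#' @param contact_offset Surface distance at which pocket atoms sit from
#'   their partner peptide atoms, Angstrom.
#' @param n_probes Random poses for the construction-time optimality check.
#' @param allow_any_length Passed to the peptide builder.
#' @return List: \code{receptor} (\linkS4class{Receptor}), \code{truth}
#'   (\linkS4class{BindingMode}, the planted pose), \code{probe_margin}
#'   (smallest probe energy minus planted energy, vina_class pair terms).
#' @export
makeToyPocket <- function(planted_sequence = "RDSVQNKLF", seed = 1,
                          groove_margin = 4, contact_offset = 0,
                          n_probes = 1000, allow_any_length = FALSE) {
  for (attempt in 0:4) {
    s <- childSeed(seed, "pocket", attempt)
    fx <- .build_toy_pocket(planted_sequence, s, groove_margin,
                            contact_offset, allow_any_length)
    chk <- .probe_check(fx, n_probes, childSeed(s, "probe", 1))
    if (chk$ok) {
      fx$probe_margin <- chk$margin
      return(fx)
    }
  }
  stop("failed to construct a pocket with a verified planted minimum ",
       "after 5 attempts")
}

.build_toy_pocket <- function(sequence, seed, groove_margin, contact_offset,
                              allow_any_length) {
  set.seed(seed)
  pep <- buildExtendedPeptide(sequence, allow_any_length = allow_any_length)
  # planted backbone in the beta region (phi -80, psi 90): ~2.9 A of anchor
  # span per residue, as in class I grooves, leaving the loop-closure
  # ensemble room to vary (a fully extended chain would admit essentially
  # one closed conformation)
  L0 <- max(pep@atoms$resno)
  for (i in seq_len(L0)) {
    if (i > 1) pep <- setDihedral(pep, sprintf("phi:%d", i), -80)
    pep <- setDihedral(pep, sprintf("psi:%d", i), 90)
  }
  pep@coords <- sweep(pep@coords, 2, colMeans(pep@coords))
  at <- pep@atoms
  x <- pep@coords
  L <- max(at$resno)
  ca1 <- x[at$resno == 1 & at$name == "CA", ]
  caL <- x[at$resno == L & at$name == "CA", ]
  axis <- .unit(caL - ca1)

  # pocket pseudo-atoms: 2 lateral directions per peptide atom, rotated
  # around the groove axis, on the "walls and floor" side
  vrad <- .score_params$vina_class$radii
  prad <- .el_radii(at$el, vrad)
  rname <- character(); rel <- character(); rclass <- character()
  rxyz <- matrix(0, 0, 3)
  dirs0 <- list(c(0, 0, -1), c(0, 0.8, -0.6), c(0, -0.8, -0.6))
  # anchor residues (two at each terminus) get full three-direction
  # coverage of every side-chain atom, mimicking the dominant A/F pockets
  # that fix the bound register in class I grooves
  dirs_anchor <- dirs0
  anchor_res <- c(1, 2, L - 1, L)
  for (i in seq_len(nrow(at))) {
    cls <- .complement_class[[at$class[i]]]
    el <- .class_element[[cls]]
    rr <- vrad[[el]]
    is_anchor <- at$resno[i] %in% anchor_res
    is_polar <- at$class[i] %in% c("don", "acc", "donacc")
    # polar side-chain atoms get full coverage: matched H-bond networks are
    # what distinguish the right sequence from a size-matched decoy
    nmax <- if (at$name[i] %in% c("N", "CA", "C", "O")) 1
      else if (is_anchor || is_polar) 3 else 2
    placed <- 0
    dirs <- if (is_anchor) dirs_anchor else dirs0
    for (d in sample(seq_along(dirs))) {
      if (placed >= nmax) break
      u <- .unit(dirs[[d]] + stats::rnorm(3, 0, 0.08))
      # H-bond partners sit inside the contact surface (the H-bond well of
      # the scoring functions lives at negative surface distance)
      off <- if (cls %in% c("don", "acc", "donacc")) -0.3 else contact_offset
      pos <- x[i, ] + u * (prad[i] + rr + off)
      dsurf <- sqrt(rowSums(sweep(x[-i, , drop = FALSE], 2, pos)^2)) -
        prad[-i] - rr
      if (min(dsurf) < 0.1) next                          # would clash
      if (nrow(rxyz) && min(sqrt(rowSums(sweep(rxyz, 2, pos)^2))) < 2.0) next
      add_atom <- function(xyz, e2, cl2) {
        rxyz <<- rbind(rxyz, xyz)
        rname <<- c(rname, sprintf("P%d", length(rname) + 1))
        rel <<- c(rel, e2); rclass <<- c(rclass, cl2)
      }
      add_atom(pos, el, cls)
      # backing atom directly behind the contact: emulates solid receptor
      # bulk -- close enough that nothing fits between the two shells
      add_atom(pos + u * 2.4, "C", "oth")
      # neutral lid atom on the opposite side: balances the net force so
      # the planted pose is a stationary point and closes the groove into
      # a tunnel, but carries no hydrophobic/H-bond reward -- flipping the
      # peptide about the groove axis must not reproduce its contacts
      off_m <- 0.8  # lids sit farther out than floor contacts: the
      # groove is top-bottom asymmetric, so mirrored backbones lose badly
      mir <- x[i, ] - u * (prad[i] + vrad[["C"]] + off_m)
      dsurf_m <- sqrt(rowSums(sweep(x[-i, , drop = FALSE], 2, mir)^2)) -
        prad[-i] - vrad[["C"]]
      if (min(dsurf_m) >= 0.1 &&
          min(sqrt(rowSums(sweep(rxyz, 2, mir)^2))) >= 2.0) {
        add_atom(mir, "C", "oth")
        add_atom(mir - u * 2.4, "C", "oth")  # lid backing
      }
      placed <- placed + 1
    }
  }
  # closed groove ends (A/F-pocket walls): cap atoms beyond both termini so
  # that register-shifted or protruding poses clash with the walls
  for (end in list(list(base = ca1, dir = -axis), list(base = caL, dir = axis))) {
    perp1 <- .unit(.cross3(end$dir, c(0, 0, 1)))
    for (off in list(c(0, 0), c(2, 0), c(-2, 0), c(0, -2), c(0, 2))) {
      pos <- end$base + end$dir * 4.2 + perp1 * off[1] + c(0, 0, 1) * off[2]
      dsurf <- sqrt(rowSums(sweep(x, 2, pos)^2)) - prad - vrad[["C"]]
      if (min(dsurf) < 0.1) next
      if (nrow(rxyz) && min(sqrt(rowSums(sweep(rxyz, 2, pos)^2))) < 2.0) next
      rxyz <- rbind(rxyz, pos)
      rname <- c(rname, sprintf("P%d", length(rname) + 1))
      rel <- c(rel, "C"); rclass <- c(rclass, "hC")
    }
  }
  lo <- apply(x, 2, min) - groove_margin
  hi <- apply(x, 2, max) + groove_margin
  # void filler: neutral bulk on a grid through every cavity the contact
  # shells leave open, so the receptor behaves like a solid -- side chains
  # larger than the planted ones have nowhere to go
  grid <- as.matrix(expand.grid(seq(lo[1] + 1, hi[1] - 1, by = 1.8),
                                seq(lo[2] + 1, hi[2] - 1, by = 1.8),
                                seq(lo[3] + 1, hi[3] - 1, by = 1.8)))
  for (gi in seq_len(nrow(grid))) {
    gpt <- grid[gi, ]
    dsurf <- sqrt(rowSums(sweep(x, 2, gpt)^2)) - prad - vrad[["C"]]
    if (min(dsurf) < 0.5 || min(dsurf) > 2.0) next  # thin crust: blocks
    # voids without adding a large nonspecific attraction field
    if (min(sqrt(rowSums(sweep(rxyz, 2, gpt)^2))) < 2.0) next
    rxyz <- rbind(rxyz, gpt)
    rname <- c(rname, sprintf("P%d", length(rname) + 1))
    rel <- c(rel, "C"); rclass <- c(rclass, "oth")
  }
  ratoms <- data.frame(name = rname, el = rel,
                       resno = seq_along(rname), class = rclass,
                       stringsAsFactors = FALSE)
  site <- function(rn) {
    m <- rbind(x[at$resno == rn & at$name == "N", ],
               x[at$resno == rn & at$name == "CA", ],
               x[at$resno == rn & at$name == "C", ])
    rownames(m) <- c("N", "CA", "C")
    m
  }
  receptor <- new("Receptor", id = sprintf("toy-%s-%d", sequence, seed),
                  atoms = ratoms, coords = rxyz,
                  boxCenter = (lo + hi) / 2, boxDims = hi - lo,
                  grooveAxis = axis,
                  anchorSites = list(n = site(1), c = site(L)))
  # the emitted ground truth is the pocket's own energy minimum: relax the
  # construction pose deterministically so the planted mode is exactly the
  # pose an ideal search should return
  ctx <- .energy_ctx(receptor, pep, "vina_class")
  rc <- .round_ctx(ctx, seq_len(nrow(pep@atoms)), .n_rotatable(pep))
  flex <- pep@torsions$id[pep@torsions$rotatable]
  e <- .pose_energy(pep@coords, rc)
  for (soft in c(0.25, 1)) {
    res <- .polish_pose(pep, rc, flex, .pose_energy(pep@coords, rc, soft),
                        soft = soft)
    pep <- res$p
  }
  # anchors/axis/box stay at the construction pose; the relaxed truth moves
  # by well under an Angstrom
  truth <- new("BindingMode", peptide = pep, scores = numeric(),
               provenance = list(round = 0L, replicate = 0L, seed = seed))
  list(receptor = receptor, truth = truth)
}

# planted pose must beat every random probe pose (pair terms, vina_class)
.probe_check <- function(fx, n_probes, seed) {
  set.seed(seed)
  rec <- fx$receptor
  pep <- fx$truth@peptide
  p <- .score_params$vina_class
  rcl <- .score_ctx(rec@atoms, "vina_class")
  pcl <- .score_ctx(pep@atoms, "vina_class")
  e_pair <- function(coords) sum(.pair_terms(p, rec@coords, rcl, coords, pcl))
  e0 <- e_pair(pep@coords)
  lo <- rec@boxCenter - rec@boxDims / 2
  hi <- rec@boxCenter + rec@boxDims / 2
  ids <- listDihedrals(pep)
  margin <- Inf
  for (j in seq_len(n_probes)) {
    q <- pep
    if (j %% 2 == 0) {  # local perturbation, displacement >= 2 A
      shift <- stats::rnorm(3); shift <- shift / sqrt(sum(shift^2))
      shift <- shift * stats::runif(1, 2, 6)
      q@coords <- sweep(q@coords, 2, shift, "+")
      for (id in sample(ids, 3))
        q <- setDihedral(q, id, getDihedral(q, id) + stats::runif(1, -40, 40))
    } else {            # global random pose
      for (id in sample(ids, 5))
        q <- setDihedral(q, id, stats::runif(1, -180, 180))
      R <- .random_rotation()
      cen <- colMeans(q@coords)
      q@coords <- .apply_rigid(q@coords, R, -drop(R %*% cen))
      q@coords <- sweep(q@coords, 2, stats::runif(3, lo, hi), "+")
    }
    ej <- e_pair(q@coords)
    margin <- min(margin, ej - e0)
    if (ej <= e0) return(list(ok = FALSE, margin = margin))
  }
  list(ok = TRUE, margin = margin)
}

.AA20 <- names(.aa_names3)

#' Generate a labeled binder/decoy screening set for one allele motif
#'
#' Binders draw each position from the motif's preferred residues with
#' probability \code{p_motif} (uniform otherwise); decoys are uniform over
#' the 20 residues.  Binder and decoy sets are disjoint.
#'
#' @param motif List of character vectors: preferred residues per position.
#' @param n_binders,n_decoys Set sizes (paper-scale defaults 500/1000; use
#'   \code{scale} to shrink for desk runs).
#' @param scale Multiplier applied to both counts.
#' @param p_motif Probability a binder position is drawn from the motif.
#' @param seed Integer seed.
#' @return Data frame: \code{peptide}, \code{label} (binder/decoy).
#' @export
makeScreeningSet <- function(motif, n_binders = 500, n_decoys = 1000,
                             scale = 1, p_motif = 0.9, seed = 1) {
  set.seed(seed)
  nb <- max(1, round(n_binders * scale))
  nd <- max(1, round(n_decoys * scale))
  draw_binder <- function() {
    paste(vapply(motif, function(pref) {
      if (stats::runif(1) < p_motif) sample(pref, 1) else sample(.AA20, 1)
    }, ""), collapse = "")
  }
  draw_decoy <- function() {
    paste(sample(.AA20, length(motif), replace = TRUE), collapse = "")
  }
  binders <- character(0)
  while (length(binders) < nb)
    binders <- unique(c(binders, draw_binder()))
  binders <- binders[seq_len(nb)]
  decoys <- character(0)
  while (length(decoys) < nd) {
    d <- draw_decoy()
    if (!(d %in% binders)) decoys <- unique(c(decoys, d))
  }
  decoys <- decoys[seq_len(nd)]
  data.frame(peptide = c(binders, decoys),
             label = rep(c("binder", "decoy"), c(nb, nd)),
             stringsAsFactors = FALSE)
}

# planted 9-mers for the synthetic allele panel
# medium-sized residues throughout: larger decoy side chains clash with
# the solid groove, smaller ones lose contacts, so steric fit discriminates
.allele_planted <- c("SYN-A01" = "ALSDTKVNL", "SYN-A02" = "KSVDNLATV",
                     "SYN-A03" = "SLTNDVAKL", "SYN-B01" = "GLNDKAVTS",
                     "SYN-B02" = "TQANSAVDL", "SYN-C01" = "AVLDSNKTI")

#' Synthetic allele panel: pockets, templates and motifs
#'
#' Builds one toy pocket per requested synthetic allele (each with its own
#' planted 9-mer), the matching anchor template, and the sequence motif
#' (preferred residue = the planted residue at each position) used to draw
#' binders.
#'
#' @param alleles Character vector of synthetic allele names (subset of the
#'   built-in panel of 6).
#' @param seed Integer seed.
#' @param n_probes Probe count forwarded to \code{\link{makeToyPocket}}.
#' @return Named list per allele: \code{receptor}, \code{truth},
#'   \code{template}, \code{motif}, \code{planted}.
#' @export
makeAllelePanel <- function(alleles = names(.allele_planted), seed = 1,
                            n_probes = 200) {
  unknown <- setdiff(alleles, names(.allele_planted))
  if (length(unknown))
    stop("unknown synthetic allele(s): ", paste(unknown, collapse = ", "))
  out <- lapply(seq_along(alleles), function(i) {
    al <- alleles[i]
    planted <- .allele_planted[[al]]
    fx <- makeToyPocket(planted, seed = childSeed(seed, "allele", i),
                        n_probes = n_probes)
    fx$receptor@id <- al
    list(receptor = fx$receptor, truth = fx$truth,
         template = anchorTemplateFromReceptor(fx$receptor),
         motif = as.list(strsplit(planted, "")[[1]]),
         planted = planted)
  })
  names(out) <- alleles
  out
}
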