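#' @include scoring.R runtime.R
NULL

# Parallel incremental meta-docking.
#
# A small N-terminal fragment of the peptide (at most k rotatable bonds) is
# docked first from random starts; the n best modes are carried forward,
# grown by one residue per round (newly added bonds become flexible, the
# oldest flexible bonds are frozen at their optimized values so at most k
# are ever simultaneously free), and re-optimized, until the whole peptide
# is reconstructed in the binding site.
#
# The per-run optimizer is a greedy Monte-Carlo perturbation scheme over the
# flexible dihedrals and the rigid-body degrees of freedom, followed by a
# deterministic line-search polish.  Its objective is the receptor-peptide
# interaction energy of the active atoms plus an internal intra-peptide
# clash penalty (steric repulsion between atom pairs four or more bonds
# apart); reported scores from scoreMode() remain pure receptor-peptide.

#' Docking configuration
#'
#' @param k Maximum simultaneously flexible bonds (>= 0).
#' @param n Modes carried per round (>= 1).
#' @param threads Parallel workers; affects wall time only, never results.
#' @param seed Base random seed.
#' @param local_steps Monte-Carlo perturbation steps per optimization run.
#' @param fn Scoring-function id driving the optimization.
#' @param spawn Randomized restarts generated per carried mode and round.
#' @param per_round Residues appended per expansion round.
#' @return Validated list of class \code{"DockingConfig"}.
#' @export
DockingConfig <- function(k = 6, n = 10, threads = 1, seed = 1,
                          local_steps = 50, fn = "vina_class", spawn = 2,
                          per_round = 1) {
  if (k < 0) stop("k must be >= 0")
  if (n < 1) stop("n must be >= 1")
  if (threads < 1) stop("threads must be >= 1")
  if (spawn < 1 || per_round < 1) stop("spawn and per_round must be >= 1")
  .check_fn(fn)
  structure(list(k = as.integer(k), n = as.integer(n),
                 threads = as.integer(threads), seed = as.integer(seed),
                 local_steps = as.integer(local_steps), fn = fn,
                 spawn = as.integer(spawn), per_round = as.integer(per_round)),
            class = c("DockingConfig", "list"))
}

# ---- energy context ---------------------------------------------------------

# shortest bond-graph distances up to `cap` bonds, as an exclusion pair list
.intra_excluded_pairs <- function(peptide, cap = 3L) {
  n <- nrow(peptide@atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(peptide@chemBonds))) {
    i <- peptide@chemBonds[r, 1]; j <- peptide@chemBonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- vector("list", n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    frontier <- s
    for (d in seq_len(cap)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    near <- which(!is.na(dist))
    excl[[s]] <- near[near > s]
  }
  excl
}

# intra pairs more than 5 bonds apart (candidates for the clash penalty);
# closer pairs are bonded-geometry neighbours whose contacts are legitimate
.intra_pairs <- function(peptide) {
  excl <- .intra_excluded_pairs(peptide, cap = 5L)
  n <- nrow(peptide@atoms)
  ii <- integer(); jj <- integer()
  for (i in seq_len(n - 1)) {
    j <- setdiff((i + 1):n, excl[[i]])
    ii <- c(ii, rep(i, length(j))); jj <- c(jj, j)
  }
  cbind(ii, jj)
}

.energy_ctx <- function(receptor, peptide, fn) {
  p <- .score_params[[fn]]
  list(p = p, fn = fn,
       rxyz = receptor@coords,
       rcl = .score_ctx(receptor@atoms, fn),
       pcl = .score_ctx(peptide@atoms, fn),
       prad_clash = .el_radii(peptide@atoms$el, .score_params$vina_class$radii),
       intra = .intra_pairs(peptide),
       box_lo = receptor@boxCenter - receptor@boxDims / 2 - 5,
       box_hi = receptor@boxCenter + receptor@boxDims / 2 + 5)
}

# restrict a context to the active atom subset of one round, precomputing
# per-pair masks and radius sums so the inner-loop energy is cheap
.round_ctx <- function(ctx, active, n_rot) {
  pcl <- ctx$pcl[active]
  attr(pcl, "rad") <- attr(ctx$pcl, "rad")[active]
  if (!is.null(attr(ctx$pcl, "eps")))
    attr(pcl, "eps") <- attr(ctx$pcl, "eps")[active]
  keep <- ctx$intra[, 1] %in% active & ctx$intra[, 2] %in% active
  intra <- ctx$intra[keep, , drop = FALSE]
  rcl <- as.character(ctx$rcl); acl <- as.character(pcl)
  r_dn <- rcl %in% c("don", "donacc"); r_ac <- rcl %in% c("acc", "donacc")
  a_dn <- acl %in% c("don", "donacc"); a_ac <- acl %in% c("acc", "donacc")
  out <- list(p = ctx$p, rxyz = ctx$rxyz, rcl = ctx$rcl, pcl = pcl,
              active = active,
              clash_rad = ctx$prad_clash,
              intra = intra, tors = ctx$p$w_tors * n_rot,
              box_lo = ctx$box_lo, box_hi = ctx$box_hi,
              rr2 = rowSums(ctx$rxyz^2),
              radsum = outer(attr(ctx$rcl, "rad"), attr(pcl, "rad"), "+"),
              hbm = outer(r_dn, a_ac, "&") | outer(r_ac, a_dn, "&"),
              hydm = outer(rcl == "hC", acl == "hC", "&"),
              intra_rs = ctx$prad_clash[intra[, 1]] +
                ctx$prad_clash[intra[, 2]])
  if (ctx$p$form == "ad4") {
    out$epsm <- outer(sqrt(attr(ctx$rcl, "eps")), sqrt(attr(pcl, "eps")))
  }
  out
}

# optimizer objective for full-peptide coords under a round context;
# soft < 1 scales the repulsive terms down (annealing phase of the search)
.pose_energy <- function(coords, rc, soft = 1) {
  axyz <- coords[rc$active, , drop = FALSE]
  if (min(axyz[, 1]) < rc$box_lo[1] || min(axyz[, 2]) < rc$box_lo[2] ||
      min(axyz[, 3]) < rc$box_lo[3] || max(axyz[, 1]) > rc$box_hi[1] ||
      max(axyz[, 2]) > rc$box_hi[2] || max(axyz[, 3]) > rc$box_hi[3])
    return(Inf)
  p <- rc$p
  D2 <- outer(rc$rr2, rowSums(axyz^2), "+") - 2 * (rc$rxyz %*% t(axyz))
  sel <- which(D2 <= 64)
  e_pair <- 0
  if (length(sel)) {
    r <- sqrt(pmax(D2[sel], 0))
    if (p$form %in% c("vina", "vinardo")) {
      d <- r - rc$radsum[sel]
      e_pair <- p$w[["gauss1"]] * sum(exp(-(d / p$gauss1_width)^2))
      if (p$form == "vina")
        e_pair <- e_pair + p$w[["gauss2"]] *
          sum(exp(-((d - p$gauss2_offset) / p$gauss2_width)^2))
      dn <- d[d < 0]
      e_pair <- e_pair + soft * p$w[["repulsion"]] * sum(dn * dn)
      dh <- d[rc$hydm[sel]]
      e_pair <- e_pair + p$w[["hydrophobic"]] *
        sum(pmin(1, pmax(0, (p$hyd_hi - dh) / (p$hyd_hi - p$hyd_lo))))
      db <- d[rc$hbm[sel]]
      e_pair <- e_pair + p$w[["hbond"]] *
        sum(pmin(1, pmax(0, (p$hb_hi - db) / (p$hb_hi - p$hb_lo))))
    } else {
      rr <- pmax(r, p$r_min)
      hb <- rc$hbm[sel]
      q6 <- (rc$radsum[sel][!hb] / rr[!hb])^6
      e_pair <- p$w_vdw * sum(rc$epsm[sel][!hb] * (q6 * q6 - 2 * q6))
      qh <- (p$hb_R / rr[hb])^2
      e_pair <- e_pair + p$w_hb * p$hb_eps * sum(5 * qh^6 - 6 * qh^5)
    }
  }
  clash <- 0
  if (nrow(rc$intra)) {
    dv <- coords[rc$intra[, 1], , drop = FALSE] -
      coords[rc$intra[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dv * dv)) - rc$intra_rs + 0.5
    dn <- d[d < 0]  # 0.5 A buffer: bonded-geometry near-contacts are fine
    clash <- 0.840245 * sum(dn * dn)
  }
  e_pair + soft * clash + rc$tors
}

# ---- fragment bookkeeping ---------------------------------------------------

.active_torsions <- function(peptide, resmax) {
  tt <- peptide@torsions
  resno <- peptide@atoms$resno
  ok <- vapply(seq_len(nrow(tt)), function(r) {
    tt$rotatable[r] &&
      resno[tt$b[r]] <= resmax && resno[tt$c[r]] <= resmax &&
      any(resno[peptide@moving[[r]]] <= resmax)
  }, TRUE)
  tt$id[ok]
}

.fragment_state <- function(peptide, resmax, k, round) {
  active_tors <- .active_torsions(peptide, resmax)
  flexible <- if (k == 0) character() else
    utils::tail(active_tors, k)
  list(resmax = resmax,
       active = which(peptide@atoms$resno <= resmax),
       torsions = active_tors,
       flexible = flexible,
       frozen = setdiff(active_tors, flexible),
       round = round)
}

#' Decompose a peptide into an incremental expansion plan
#'
#' The root fragment is the longest N-terminal run of residues whose
#' rotatable-bond count does not exceed \code{k}; each later round appends
#' \code{per_round} residues until the full peptide is covered.
#'
#' @param peptide A \linkS4class{PeptideConformation}.
#' @param k Maximum simultaneously flexible bonds.
#' @param per_round Residues appended per round.
#' @return Data frame of class \code{"ExpansionPlan"}: \code{round},
#'   \code{resmax} (last residue active in that round), \code{n_torsions}.
#' @export
decomposeLigand <- function(peptide, k = 6, per_round = 1) {
  if (!nrow(peptide@torsions)) stop("torsion tree not populated")
  L <- max(peptide@atoms$resno)
  if (k == 0) message("k = 0: expansion plan degenerates to rigid-body-only rounds")
  root <- 1L
  if (k > 0) {
    for (m in seq_len(L)) {
      if (length(.active_torsions(peptide, m)) <= k) root <- m else break
    }
  }
  resmax <- root
  while (utils::tail(resmax, 1) < L)
    resmax <- c(resmax, min(L, utils::tail(resmax, 1) + per_round))
  plan <- data.frame(round = seq_along(resmax), resmax = resmax,
                     n_torsions = vapply(resmax, function(m)
                       length(.active_torsions(peptide, m)), 1L))
  class(plan) <- c("ExpansionPlan", "data.frame")
  plan
}

#' Expand a fragment state to the next round
#'
#' Newly added bonds become flexible; the oldest previously flexible bonds
#' are frozen at their current (optimized) values so that at most \code{k}
#' bonds stay free.  Frozen values live in the coordinates and are carried
#' over exactly.
#'
#' @param fragment Current fragment state (from \code{\link{expandFragment}}
#'   or internal round setup).
#' @param peptide The full \linkS4class{PeptideConformation}.
#' @param plan Expansion plan from \code{\link{decomposeLigand}}.
#' @param k Maximum simultaneously flexible bonds.
#' @return The next round's fragment state.
#' @export
expandFragment <- function(fragment, peptide, plan, k) {
  if (fragment$round >= nrow(plan))
    stop("expansion requested past the final round")
  .fragment_state(peptide, plan$resmax[fragment$round + 1], k,
                  fragment$round + 1)
}

# ---- sampling and optimization ---------------------------------------------

.random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 360)
  a <- ang * .deg2rad
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Sample random fragment conformations
#'
#' Draws every flexible dihedral independently and uniformly from
#' [-180, 180) and places the fragment with a random rigid-body pose inside
#' the receptor box.  Reproducible given the seed.
#'
#' @param peptide Full \linkS4class{PeptideConformation} (the template
#'   conformation for non-flexible parts).
#' @param fragment Fragment state for the current round.
#' @param receptor The \linkS4class{Receptor} providing the box.
#' @param n Number of conformations (>= 1).
#' @param seed Integer seed.
#' @return List of \code{n} \linkS4class{PeptideConformation} objects.
#' @export
sampleFragment <- function(peptide, fragment, receptor, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  lo <- receptor@boxCenter - receptor@boxDims / 2 + 1
  hi <- receptor@boxCenter + receptor@boxDims / 2 - 1
  lapply(seq_len(n), function(j) {
    p <- peptide
    for (id in fragment$flexible)
      p <- setDihedral(p, id, stats::runif(1, -180, 180))
    R <- .random_rotation()
    target <- stats::runif(3, lo, hi)
    cen <- colMeans(p@coords[fragment$active, , drop = FALSE])
    p@coords <- .apply_rigid(p@coords, R, -drop(R %*% cen))
    p@coords <- sweep(p@coords, 2, target, "+")
    p
  })
}

# one deterministic improvement sweep: per-dihedral line searches plus
# gradient line searches over the rigid-body coordinates
.polish_pose <- function(p, rc, flexible, e, soft = 1, passes = 3) {
  E <- function(q) .pose_energy(q@coords, rc, soft)
  deltas <- c(-120, -60, -30, -10, -4, -1, 1, 4, 10, 30, 60, 120, 180)
  for (pass in seq_len(passes)) {
    e_in <- e
    for (id in flexible) {
      cur <- getDihedral(p, id)
      best_d <- 0
      for (d in deltas) {
        cand <- setDihedral(p, id, cur + d)
        ec <- E(cand)
        if (ec < e) { e <- ec; best_d <- d }
      }
      if (best_d != 0) p <- setDihedral(p, id, cur + best_d)
    }
    res <- .rigid_descent(p, rc, e, soft)
    p <- res$p; e <- res$e
    if (e >= e_in - 1e-9) break  # converged
  }
  list(p = p, e = e)
}

# steepest-descent line searches over translation and rotation
.rigid_descent <- function(p, rc, e, soft = 1, iters = 2) {
  E <- function(xyz) .pose_energy(xyz, rc, soft)
  for (it in seq_len(iters)) {
    e_in <- e
    # translation gradient (central differences)
    g <- vapply(1:3, function(ax) {
      h <- c(0, 0, 0); h[ax] <- 0.05
      (E(sweep(p@coords, 2, h, "+")) - E(sweep(p@coords, 2, h, "-"))) / 0.1
    }, 1)
    if (all(is.finite(g)) && any(g != 0)) {
      u <- -g / sqrt(sum(g^2))
      for (step in c(2, 1, 0.5, 0.25, 0.1)) {
        cand <- sweep(p@coords, 2, u * step, "+")
        ec <- E(cand)
        if (ec < e) { e <- ec; p@coords <- cand; break }
      }
    }
    # rotation line searches about the active-atom centroid
    cen <- colMeans(p@coords[rc$active, , drop = FALSE])
    for (ax in 1:3) {
      u <- c(0, 0, 0); u[ax] <- 1
      for (ang in c(-8, -2, 2, 8)) {
        cand <- .rotate_about_axis(p@coords, cen, u, ang)
        ec <- E(cand)
        if (ec < e) { e <- ec; p@coords <- cand }
      }
    }
    if (e >= e_in - 1e-9) break
  }
  list(p = p, e = e)
}

# one Monte-Carlo phase: Metropolis acceptance at temperature T, tracking
# the best pose seen; proposals mix dihedral and rigid-body moves
.mc_phase <- function(p, rc, flexible, steps, T, soft = 1) {
  E <- function(q) .pose_energy(q@coords, rc, soft)
  e <- E(p)
  best <- p; ebest <- e
  nflex <- length(flexible)
  for (s in seq_len(steps)) {
    u01 <- stats::runif(1)
    if (nflex > 0 && u01 < 0.6) {
      id <- flexible[[sample.int(nflex, 1)]]
      cand <- setDihedral(p, id, getDihedral(p, id) + stats::rnorm(1, 0, 40))
    } else if (u01 < 0.8 || nflex == 0 && u01 < 0.5) {
      shift <- stats::rnorm(3, 0, sample(c(0.5, 2.0), 1))
      cand <- p; cand@coords <- sweep(p@coords, 2, shift, "+")
    } else {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      cen <- colMeans(p@coords[rc$active, , drop = FALSE])
      cand <- p
      cand@coords <- .rotate_about_axis(p@coords, cen, ax,
                                        stats::rnorm(1, 0, sample(c(10, 45), 1)))
    }
    ec <- E(cand)
    if (is.finite(ec) &&
        (ec < e || stats::runif(1) < exp(-(ec - e) / T))) {
      p <- cand; e <- ec
      if (ec < ebest) { best <- cand; ebest <- ec }
    }
  }
  list(p = best, e = ebest)
}

# full per-run optimization: annealed soft phase, then full-energy phase,
# then deterministic polish; never returns a pose worse than the input
.optimize_pose <- function(p, rc, flexible, steps, seed) {
  set.seed(seed)
  e0 <- .pose_energy(p@coords, rc)
  soft_res <- .mc_phase(p, rc, flexible, steps, T = 0.6, soft = 0.25)
  q <- .polish_pose(soft_res$p, rc, flexible,
                    .pose_energy(soft_res$p@coords, rc, 0.25), soft = 0.25,
                    passes = 1)
  hard <- .mc_phase(q$p, rc, flexible, steps, T = 0.15)
  fin <- .polish_pose(hard$p, rc, flexible, hard$e, passes = 2)
  if (fin$e <= e0) fin else list(p = p, e = e0)
}

#' Optimize a set of fragment conformations (one docking round)
#'
#' Each conformation is optimized independently (Monte-Carlo perturbations
#' plus a line-search polish over the flexible dihedrals and rigid-body
#' degrees of freedom).  Run \code{j} uses seed \code{config$seed +
#' run_index0 + j}, so results are bit-identical for any thread count, and
#' the returned objective energy never exceeds the input energy.
#'
#' @param conformations List of \linkS4class{PeptideConformation} starts
#'   sharing one fragment state.
#' @param receptor The \linkS4class{Receptor}.
#' @param fragment Fragment state of this round.
#' @param config A \code{\link{DockingConfig}}.
#' @param run_index0 Offset added to run indices for seeding.
#' @param ctx Optional precomputed energy context.
#' @return List of \linkS4class{BindingMode} objects; each carries the
#'   optimizer objective in \code{provenance$objective}.
#' @export
dockRound <- function(conformations, receptor, fragment, config,
                      run_index0 = 0L, ctx = NULL) {
  if (is.null(ctx)) ctx <- .energy_ctx(receptor, conformations[[1]], config$fn)
  rc <- .round_ctx(ctx, fragment$active, length(fragment$flexible))
  one <- function(j) {
    seed_j <- config$seed + run_index0 + j
    res <- .optimize_pose(conformations[[j]], rc, fragment$flexible,
                          config$local_steps, seed_j)
    new("BindingMode", peptide = res$p, scores = numeric(),
        provenance = list(round = fragment$round, replicate = run_index0 + j,
                          seed = seed_j, objective = res$e))
  }
  idx <- seq_along(conformations)
  if (config$threads > 1) {
    parallel::mclapply(idx, one, mc.cores = config$threads)
  } else {
    lapply(idx, one)
  }
}

.mode_objective <- function(m) m@provenance$objective

# sliding-window refinement: deterministic polish of all active torsions,
# k bonds at a time (never more than k simultaneously flexible), so errors
# frozen in earlier rounds can relax without violating the k-cap
.refine_windows <- function(mode, rc, torsions, k, with_rigid = TRUE) {
  p <- mode@peptide
  e <- .pose_energy(p@coords, rc)
  nt <- length(torsions)
  starts <- if (nt <= k) 1 else unique(c(seq(1, nt - k + 1, by = max(1, k)),
                                         nt - k + 1))
  for (w in starts) {
    win <- torsions[w:min(w + k - 1, nt)]
    res <- .polish_pose(p, rc, win, e, passes = 1)
    p <- res$p; e <- res$e
  }
  if (with_rigid) {
    res <- .rigid_descent(p, rc, e)
    p <- res$p; e <- res$e
  }
  mode@peptide <- p
  mode@provenance$objective <- e
  mode
}

# greedy energy-sorted selection with an RMSD diversity gate over the active
# atoms, so distinct binding registers survive the round-to-round pruning;
# if fewer than n distinct modes exist the remainder fills by energy
.select_diverse <- function(docked, n, active, min_rmsd = 2) {
  ord <- order(vapply(docked, .mode_objective, 1))
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= n) break
    xi <- docked[[i]]@peptide@coords[active, , drop = FALSE]
    ok <- TRUE
    for (j in picked) {
      xj <- docked[[j]]@peptide@coords[active, , drop = FALSE]
      if (sqrt(mean(rowSums((xi - xj)^2))) < min_rmsd) { ok <- FALSE; break }
    }
    if (ok) picked <- c(picked, i)
  }
  if (length(picked) < n)
    picked <- c(picked, setdiff(ord, picked)[seq_len(n - length(picked))])
  docked[picked[!is.na(picked)]]
}

#' Incremental parallel docking of a peptide into a receptor
#'
#' Implements the full meta-docking loop: decompose, sample the root
#' fragment, optimize, select the n best modes, expand by one residue,
#' re-optimize, and repeat until the entire peptide is reconstructed in the
#' binding site.  Deterministic given \code{config$seed}; thread count
#' affects wall time only.
#'
#' @param x Peptide sequence (character) or a
#'   \linkS4class{PeptideConformation}.
#' @param receptor The \linkS4class{Receptor}.
#' @param config A \code{\link{DockingConfig}}.
#' @param keep_history Also return per-round best modes (attribute
#'   \code{"history"}).
#' @return An \linkS4class{Ensemble} of up to \code{config$n} final modes
#'   ordered by optimizer objective (best first).  Modes carry no scores
#'   until \code{\link{rescoreEnsemble}} is called.  The \code{"history"}
#'   attribute records per-round fragment sizes, flexible-bond counts and
#'   best objectives.
#' @examples
#' \donttest{
#' fx <- makeToyPocket(planted_sequence = "ASAGA", seed = 7,
#'                     allow_any_length = TRUE)
#' cfg <- DockingConfig(n = 4, local_steps = 10, seed = 1)
#' ens <- incrementalDock("ASAGA", fx$receptor, cfg)
#' }
#' @export
incrementalDock <- function(x, receptor, config = DockingConfig(),
                            keep_history = FALSE) {
  pep <- if (is.character(x)) {
    buildExtendedPeptide(x, allow_any_length = TRUE)
  } else x
  plan <- decomposeLigand(pep, config$k, config$per_round)
  ctx <- .energy_ctx(receptor, pep, config$fn)
  history <- list()
  run_index0 <- 0L
  carried <- NULL
  fragment <- .fragment_state(pep, plan$resmax[1], config$k, 1L)
  for (r in seq_len(nrow(plan))) {
    if (r > 1) fragment <- .fragment_state(pep, plan$resmax[r], config$k, r)
    if (r == 1) {
      n_rand <- config$n * config$spawn
      starts <- sampleFragment(pep, fragment, receptor, n_rand,
                               childSeed(config$seed, "sample", r))
      # additionally seed starts at the receptor's A-pocket anchor site:
      # class I grooves anchor the peptide N-terminus there, and the
      # receptor records those reference backbone coordinates
      set.seed(childSeed(config$seed, "anchorstart", r))
      bb1 <- function(p) {
        at <- p@atoms
        rbind(p@coords[at$resno == 1 & at$name == "N", ],
              p@coords[at$resno == 1 & at$name == "CA", ],
              p@coords[at$resno == 1 & at$name == "C", ])
      }
      for (j in seq_len(n_rand)) {
        p2 <- pep
        for (id in fragment$flexible)
          p2 <- setDihedral(p2, id, stats::runif(1, -180, 180))
        fit <- kabschFit(bb1(p2), receptor@anchorSites$n)
        p2@coords <- .apply_rigid(p2@coords, fit$R, fit$t)
        p2@coords <- sweep(p2@coords, 2, stats::rnorm(3, 0, 0.4), "+")
        starts[[length(starts) + 1]] <- p2
      }
    } else {
      new_bonds <- setdiff(fragment$flexible,
                           .active_torsions(pep, plan$resmax[r - 1]))
      set.seed(childSeed(config$seed, "respawn", r))
      lo <- receptor@boxCenter - receptor@boxDims / 2 + 1
      hi <- receptor@boxCenter + receptor@boxDims / 2 - 1
      bb1 <- function(p) {
        at <- p@atoms
        rbind(p@coords[at$resno == 1 & at$name == "N", ],
              p@coords[at$resno == 1 & at$name == "CA", ],
              p@coords[at$resno == 1 & at$name == "C", ])
      }
      draw_new <- function(p2) {
        # new backbone bonds start in the beta basin (bound class I
        # peptides are extended-ish); side-chain bonds are uniform
        for (id in new_bonds) {
          ty <- sub(":.*", "", id)
          v <- if (ty == "phi") stats::runif(1, -150, -60)
          else if (ty == "psi") stats::runif(1, 60, 150)
          else stats::runif(1, -180, 180)
          p2 <- setDihedral(p2, id, v)
        }
        p2
      }
      starts <- list()
      for (m in carried) {
        starts[[length(starts) + 1]] <- m@peptide
        if (config$spawn > 1) {
          for (s in seq_len(config$spawn - 1)) {
            p2 <- draw_new(m@peptide)
            if (s == 1) {
              # re-anchored variant: put the N-terminal backbone back on
              # the A-pocket anchor site, so a correctly registered lineage
              # is regrown every round
              fit <- kabschFit(bb1(p2), receptor@anchorSites$n)
              p2@coords <- .apply_rigid(p2@coords, fit$R, fit$t)
              p2@coords <- sweep(p2@coords, 2, stats::rnorm(3, 0, 0.3), "+")
            } else {
              # re-dock the grown fragment from a fresh rigid-body pose:
              # gives wrong-register modes a chance to re-register
              R <- .random_rotation()
              cenp <- colMeans(p2@coords[fragment$active, , drop = FALSE])
              p2@coords <- .apply_rigid(p2@coords, R, -drop(R %*% cenp))
              p2@coords <- sweep(p2@coords, 2, stats::runif(3, lo, hi), "+")
            }
            starts[[length(starts) + 1]] <- p2
          }
        }
      }
    }
    docked <- dockRound(starts, receptor, fragment, config, run_index0, ctx)
    run_index0 <- run_index0 + length(starts)
    carried <- .select_diverse(docked, config$n, fragment$active)
    if (config$k > 0) {
      rc_r <- .round_ctx(ctx, fragment$active, length(fragment$flexible))
      carried <- lapply(carried, .refine_windows, rc = rc_r,
                        torsions = fragment$torsions, k = config$k)
      carried <- carried[order(vapply(carried, .mode_objective, 1))]
    }
    history[[r]] <- list(round = r, resmax = plan$resmax[r],
                         n_flexible = length(fragment$flexible),
                         n_active_torsions = length(fragment$torsions),
                         best_objective = .mode_objective(carried[[1]]),
                         best_modes = if (keep_history) carried else NULL)
  }
  # final refinement: sliding-window Monte-Carlo + line-search sweeps over
  # the finished modes (never more than k bonds simultaneously flexible)
  if (config$k > 0) {
  all_tors <- .active_torsions(pep, max(plan$resmax))
  rc_f <- .round_ctx(ctx, fragment$active, min(config$k, length(all_tors)))
  nt <- length(all_tors)
  win_starts <- if (nt <= config$k) 1 else
    unique(c(seq(1, nt - config$k + 1, by = max(1, config$k %/% 2)),
             nt - config$k + 1))
  n_refine <- min(3L, length(carried))  # full sweeps for the top modes only
  carried <- lapply(seq_along(carried), function(i) {
    m <- carried[[i]]
    if (i > n_refine) return(m)
    p <- m@peptide
    e <- .pose_energy(p@coords, rc_f)
    for (w in win_starts) {
      win <- all_tors[w:min(w + config$k - 1, nt)]
      res <- .optimize_pose(p, rc_f, win, max(10, config$local_steps %/% 2),
                            childSeed(config$seed, "finalref", i * 100 + w))
      p <- res$p; e <- res$e
    }
    m@peptide <- p
    m@provenance$objective <- e
    m
  })
  carried <- carried[order(vapply(carried, .mode_objective, 1))]
  }
  ens <- new("Ensemble",
             pairId = paste0(pep@sequence, "|", receptor@id),
             modes = carried)
  attr(ens, "history") <- history
  ens
}
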