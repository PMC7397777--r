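small_dock_config <- function(seed = 1, ...) {
  DockingConfig(n = 3, spawn = 1, local_steps = 8, seed = seed, ...)
}

test_that("ligand decomposition covers the peptide and respects k", {
  pep <- buildExtendedPeptide("AG", allow_any_length = TRUE)  # 3 backbone bonds
  plan <- decomposeLigand(pep, k = 6)
  expect_equal(nrow(plan), 1)
  expect_equal(plan$resmax, 2)

  pep3 <- buildExtendedPeptide("AAA", allow_any_length = TRUE)
  plan3 <- decomposeLigand(pep3, k = 2)
  # oracle: count torsions per prefix independently from the torsion table
  tt <- torsionTable(pep3)
  at <- atomTable(pep3)
  count_prefix <- function(m) {
    sum(vapply(seq_len(nrow(tt)), function(r) {
      at$resno[tt$b[r]] <= m && at$resno[tt$c[r]] <= m &&
        any(at$resno[pep3@moving[[r]]] <= m)
    }, TRUE))
  }
  root_oracle <- max(which(vapply(1:3, count_prefix, 1L) <= 2), 1)
  expect_equal(plan3$resmax[1], root_oracle)
  expect_equal(max(plan3$resmax), 3)
  expect_true(all(diff(plan3$resmax) > 0))
  expect_message(decomposeLigand(pep3, k = 0), "rigid-body-only")
})

test_that("fragment sampling is seeded, in range, and uniform-ish", {
  fx <- small_fixture()
  pep <- buildExtendedPeptide("RDSVF", allow_any_length = TRUE)
  frag <- pHLAdock:::.fragment_state(pep, 2, 6, 1L)
  s1 <- sampleFragment(pep, frag, fx$receptor, 4, seed = 9)
  s2 <- sampleFragment(pep, frag, fx$receptor, 4, seed = 9)
  for (i in 1:4) expect_identical(s1[[i]]@coords, s2[[i]]@coords)
  one <- sampleFragment(pep, frag, fx$receptor, 1, seed = 5)
  expect_length(one, 1)
  for (id in frag$flexible) {
    a <- getDihedral(one[[1]], id)
    expect_true(a >= -180 && a <= 180)
  }
  expect_error(sampleFragment(pep, frag, fx$receptor, 0), ">= 1")
  # uniformity of dihedral draws (chi-squared over 12 bins, fixed seed)
  many <- sampleFragment(pep, frag, fx$receptor, 400, seed = 31)
  draws <- vapply(many, function(p) getDihedral(p, frag$flexible[1]), 1)
  ct <- table(cut(draws, breaks = seq(-180, 180, by = 30)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("optimization never worsens the objective and has fixed points", {
  fx <- small_fixture()
  pep <- fx$truth@peptide
  frag <- pHLAdock:::.fragment_state(pep, 5, 6, 1L)
  ctx <- pHLAdock:::.energy_ctx(fx$receptor, pep, "vina_class")
  rc <- pHLAdock:::.round_ctx(ctx, frag$active, length(frag$flexible))
  starts <- sampleFragment(pep, frag, fx$receptor, 4, seed = 3)
  cfg <- small_dock_config()
  docked <- dockRound(starts, fx$receptor, frag, cfg, ctx = ctx)
  for (i in seq_along(starts)) {
    e_in <- pHLAdock:::.pose_energy(starts[[i]]@coords, rc)
    expect_lte(docked[[i]]@provenance$objective, e_in)
  }
  # optimize to convergence, then a 0-step re-run must not move the pose
  opt <- pHLAdock:::.optimize_pose(pep, rc, frag$flexible, 30, 77)
  cfg0 <- DockingConfig(n = 1, local_steps = 0, seed = 77)
  re <- dockRound(list(opt$p), fx$receptor, frag, cfg0, ctx = ctx)
  expect_equal(re[[1]]@provenance$objective, opt$e, tolerance = 1e-12)
})

test_that("thread count never changes results", {
  fx <- small_fixture()
  cfgs <- lapply(c(1, 2, 4), function(th)
    small_dock_config(seed = 5, threads = th))
  enss <- lapply(cfgs, function(cfg)
    incrementalDock("RDSVF", fx$receptor, cfg))
  for (i in 2:3) {
    expect_equal(nModes(enss[[1]]), nModes(enss[[i]]))
    for (j in seq_len(nModes(enss[[1]]))) {
      expect_identical(modes(enss[[1]])[[j]]@peptide@coords,
                       modes(enss[[i]])[[j]]@peptide@coords)
      expect_identical(modes(enss[[1]])[[j]]@provenance$objective,
                       modes(enss[[i]])[[j]]@provenance$objective)
    }
  }
})

test_that("incremental docking respects the k-cap and reconstructs fully", {
  fx <- small_fixture()
  for (sd in 1:3) {
    ens <- incrementalDock("RDSVF", fx$receptor,
                           small_dock_config(seed = sd, k = 4))
    h <- attr(ens, "history")
    expect_true(all(vapply(h, function(x) as.numeric(x$n_flexible), 1) <= 4))
    resmax <- vapply(h, function(x) as.numeric(x$resmax), 1)
    expect_true(all(diff(resmax) >= 0))        # monotone reconstruction
    expect_equal(max(resmax), 5)               # full peptide at the end
    for (m in modes(ens))
      expect_equal(nrow(atomTable(m@peptide)),
                   nrow(atomTable(fx$truth@peptide)))
  }
})

test_that("expansion freezes the oldest bonds and carries values exactly", {
  pep <- buildExtendedPeptide("QFKDNVILL")
  plan <- decomposeLigand(pep, k = 6)
  f1 <- pHLAdock:::.fragment_state(pep, plan$resmax[1], 6, 1L)
  f2 <- expandFragment(f1, pep, plan, 6)
  expect_lte(length(f2$flexible), 6)
  expect_gt(length(f2$frozen), 0)
  # frozen set is the oldest part of the active torsions
  expect_identical(f2$frozen,
                   setdiff(f2$torsions, utils::tail(f2$torsions, 6)))
  # a frozen dihedral's value is untouched by later flexible-bond edits
  set.seed(1)
  p2 <- pep
  frozen_id <- f2$frozen[1]
  v0 <- getDihedral(p2, frozen_id)
  for (id in f2$flexible)
    p2 <- setDihedral(p2, id, runif(1, -180, 180))
  expect_lt(abs(ang_diff(getDihedral(p2, frozen_id), v0)), 1e-9)
  flast <- pHLAdock:::.fragment_state(pep, 9, 6, nrow(plan))
  expect_error(expandFragment(flast, pep, plan, 6), "final round")
})

test_that("rigid peptides reduce to rigid-body docking", {
  fx <- small_fixture()
  cfg <- small_dock_config(seed = 2, k = 0)
  suppressMessages({
    ens <- incrementalDock("RDSVF", fx$receptor, cfg)
  })
  h <- attr(ens, "history")
  expect_true(all(vapply(h, function(x) as.numeric(x$n_flexible), 1) == 0))
  # internal conformation unchanged: all dihedrals still at build values
  ref <- buildExtendedPeptide("RDSVF", allow_any_length = TRUE)
  for (id in listDihedrals(ref)) {
    expect_lt(abs(ang_diff(getDihedral(modes(ens)[[1]]@peptide, id),
                           getDihedral(ref, id))), 1e-6)
  }
})

test_that("a start inside the planted basin converges onto the planted pose", {
  fx <- small_fixture()
  pep <- fx$truth@peptide
  ctx <- pHLAdock:::.energy_ctx(fx$receptor, pep, "vina_class")
  frag <- pHLAdock:::.fragment_state(pep, 5, 6, 1L)
  rc <- pHLAdock:::.round_ctx(ctx, frag$active, length(frag$flexible))
  set.seed(21)
  q <- transformPeptide(pep, t = c(0.4, -0.3, 0.2))
  res <- pHLAdock:::.optimize_pose(q, rc, frag$flexible, 40, 55)
  expect_lt(heavyAtomRMSD(res$p, pep), 1.0)
})
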