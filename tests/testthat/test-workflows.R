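mode_at <- function(pep, t = c(0, 0, 0)) {
  new("BindingMode", peptide = transformPeptide(pep, t = t),
      scores = numeric(), provenance = list(round = 1L, replicate = 1L,
                                            seed = 1L))
}

test_that("the reverse-orientation filter keeps exactly the forward modes", {
  fx <- toy_fixture()
  fwd <- fx$truth@peptide
  # reflect the residue order through the box center: same atom cloud shape,
  # opposite first-to-last direction
  rev <- fwd
  rev@coords <- sweep(-sweep(fwd@coords, 2, fx$receptor@boxCenter), 2,
                      fx$receptor@boxCenter, "+")
  ens <- new("Ensemble", pairId = "t", modes = list(
    mode_at(fwd), mode_at(rev), mode_at(fwd, c(1, 0, 0)), mode_at(rev)))
  kept <- filterReverseOrientation(ens, fx$receptor)
  expect_equal(nModes(kept), 2)
  # antisymmetry: exactly one of {mode, reflected mode} passes
  for (p in list(fwd, rev)) {
    e1 <- new("Ensemble", pairId = "t", modes = list(mode_at(p)))
    p2 <- p
    p2@coords <- sweep(-sweep(p@coords, 2, fx$receptor@boxCenter), 2,
                       fx$receptor@boxCenter, "+")
    e2 <- new("Ensemble", pairId = "t", modes = list(mode_at(p2)))
    expect_equal(nModes(filterReverseOrientation(e1, fx$receptor)) +
                   nModes(filterReverseOrientation(e2, fx$receptor)), 1)
  }
})

scored_ens <- function(values, fn = "vina_class") {
  pep <- buildExtendedPeptide("AAA", allow_any_length = TRUE)
  ms <- lapply(seq_along(values), function(i) {
    m <- mode_at(pep)
    m@scores[fn] <- values[i]
    m
  })
  new("Ensemble", pairId = "t", modes = ms)
}

test_that("ensemble binding energy is the median with the even-count rule", {
  expect_equal(ensembleBindingEnergy(scored_ens(c(-7.1, -5.3, -6.2))), -6.2)
  expect_equal(ensembleBindingEnergy(scored_ens(c(-8.0, -6.0))), -7.0)
  set.seed(1)
  v <- rnorm(11)
  expect_equal(ensembleBindingEnergy(scored_ens(v)),
               ensembleBindingEnergy(scored_ens(sample(v))))
  # duplication invariance
  expect_equal(ensembleBindingEnergy(scored_ens(c(v, v))),
               ensembleBindingEnergy(scored_ens(v)))
  expect_error(ensembleBindingEnergy(new("Ensemble", pairId = "e",
                                         modes = list())), "empty")
})

test_that("Pearson correlations hit the textbook formula and the bounds", {
  # constructed: energies exactly linear in log10(nM)
  nM <- c(10, 50, 200, 1000, 5000)
  e_lin <- 2 * log10(nM) - 7
  expect_equal(stats::cor(e_lin, log10(nM)), 1.0)
  expect_equal(stats::cor(-e_lin, log10(nM)), -1.0)
  # oracle on random tables: explicit sum formula
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    n <- length(x)
    r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    expect_equal(stats::cor(x, y), r_oracle, tolerance = 1e-12)
    expect_true(abs(r_oracle) <= 1)
  }
})

test_that("binding prediction returns energies and correlations end to end", {
  fx <- toy_fixture()
  tpl <- anchorTemplateFromReceptor(fx$receptor)
  peps <- data.frame(peptide = c("RDEQSAVLF", "RDEQSAVLV", "KDEQSAVLF"),
                     affinity_nM = c(20, 400, 5000))
  suppressMessages({
    res <- bindingPrediction(peps, fx$receptor, tpl,
                             ens_config = EnsembleConfig(n_backbones = 2,
                                                         seed = 4))
  })
  expect_equal(nrow(res$table), 3)
  expect_true(all(scoringFunctions() %in% names(res$table)))
  expect_true(all(abs(res$correlations) <= 1))
  peps2 <- peps[1:2, ]
  suppressMessages({
    expect_warning(
      res2 <- bindingPrediction(peps2, fx$receptor, tpl,
                                ens_config = EnsembleConfig(n_backbones = 2,
                                                            seed = 4)),
      "fewer than 3")
  })
  expect_null(res2$correlations)
})

test_that("the PWM predictor matches its documented score-to-nM mapping", {
  set.seed(2)
  binders <- replicate(25, paste(sample(c("A", "L", "V"), 9, TRUE),
                                 collapse = ""))
  pred <- trainPWMPredictor(list(X = binders))
  # a residue never seen at any position achieves the matrix minimum -> 50000
  expect_equal(pred$predict(strrep("W", 9), "X"), 50000, tolerance = 1e-9)
  # the per-position argmax sequence achieves the maximum -> 1 nM
  lod <- pred$models$X$lod
  best <- paste(rownames(lod)[apply(lod, 2, which.max)], collapse = "")
  expect_equal(pred$predict(best, "X"), 1, tolerance = 1e-9)
  # identical training sequences: that sequence beats any other same-length
  pred1 <- trainPWMPredictor(list(Y = rep("SLYNTVATL", 20)))
  others <- replicate(20, paste(sample(names(std_heavy_counts), 9, TRUE),
                                collapse = ""))
  nm_self <- pred1$predict("SLYNTVATL", "Y")
  expect_true(all(vapply(others, pred1$predict, 1, allele = "Y") >= nm_self))
  # ranking by predictor equals ranking by an oracle rescan of the counts
  probes <- replicate(30, paste(sample(c("A", "L", "V", "K"), 9, TRUE),
                                collapse = ""))
  oracle_score <- function(s) {
    aa <- strsplit(s, "")[[1]]
    cnt <- sapply(seq_len(9), function(p)
      sum(substr(binders, p, p) == aa[p]))
    sum(log((cnt + 1) / (length(binders) + 20) * 20))
  }
  expect_equal(order(vapply(probes, pred$predict, 1, allele = "X")),
               order(-vapply(probes, oracle_score, 1)))
  expect_error(trainPWMPredictor(list(Z = binders[1:5])), ">= 20")
  expect_error(trainPWMPredictor(list(Z = c(binders, "AAAA"))), "uniform")
})

test_that("virtual screening applies the inclusive prefilter and ranks", {
  fx <- toy_fixture()
  panel <- list(AL1 = list(receptor = fx$receptor,
                           template = anchorTemplateFromReceptor(fx$receptor)))
  fake <- list(predict = function(peptide, allele) {
    c(RDEQSAVLF = 100, KDEQSAVLF = 500, WWWWWWWWW = 600)[[peptide]]
  })
  peps <- data.frame(peptide = c("RDEQSAVLF", "KDEQSAVLF", "WWWWWWWWW"))
  suppressMessages({
    rec <- virtualScreen(peps, panel, fake,
                         config = WorkflowConfig(affinity_threshold_nM = 500),
                         ens_config = EnsembleConfig(n_backbones = 1, seed = 2))
  })
  expect_equal(rec$status, c("ok", "ok", "filtered"))  # 500 is inclusive
  expect_true(is.na(rec$structural_energy[3]))
  expect_false(anyNA(rec$structural_energy[1:2]))
  expect_setequal(rec$rank[1:2], 1:2)
  # missing allele template -> error record, no crash
  rec2 <- virtualScreen(peps, panel, fake, alleles = c("AL1", "MISSING"),
                        config = WorkflowConfig(affinity_threshold_nM = 1),
                        ens_config = EnsembleConfig(n_backbones = 1, seed = 2))
  expect_true(all(rec2$status[rec2$allele == "MISSING"] == "no_template"))
  # empty input -> empty records
  expect_equal(nrow(virtualScreen(peps[0, , drop = FALSE], panel, fake)), 0)
})

test_that("raising the prefilter threshold never shrinks stage 2", {
  fx <- toy_fixture()
  panel <- list(AL1 = list(receptor = fx$receptor,
                           template = anchorTemplateFromReceptor(fx$receptor)))
  set.seed(6)
  binders <- replicate(25, paste(sample(c("R", "D", "E", "Q", "S", "A",
                                          "V", "L", "F"), 9, TRUE),
                                 collapse = ""))
  pred <- trainPWMPredictor(list(AL1 = binders))
  peps <- data.frame(peptide = replicate(12, paste(
    sample(names(std_heavy_counts), 9, TRUE), collapse = "")))
  run <- function(thr) {
    suppressMessages(virtualScreen(
      peps, panel, pred,
      config = WorkflowConfig(affinity_threshold_nM = thr),
      ens_config = EnsembleConfig(n_backbones = 1, seed = 2)))
  }
  r500 <- run(500); r50k <- run(50000)
  pass500 <- r500$peptide[r500$status == "ok"]
  pass50k <- r50k$peptide[r50k$status == "ok"]
  expect_true(all(pass500 %in% pass50k))
  # threshold Inf disables the prefilter entirely
  rInf <- run(Inf)
  expect_true(all(rInf$status == "ok"))
})

test_that("geometry prediction reports top modes, RMSDs and the flag", {
  fx <- small_fixture()
  cfg <- DockingConfig(n = 3, spawn = 1, local_steps = 8, seed = 6)
  suppressMessages({
    rep <- geometryPrediction("RDSVF", fx$receptor, reference = fx$truth,
                              dock_config = cfg,
                              config = WorkflowConfig(top_m = 2))
  })
  expect_true(all(table(rep$table$fn) <= 2))
  expect_setequal(unique(rep$table$fn), scoringFunctions())
  expect_false(anyNA(rep$table$rmsd))
  expect_true(is.finite(rep$min_rmsd))
  expect_identical(rep$near_native, rep$min_rmsd < 2.5)
  # self-reference: a mode contained in the ensemble gives min RMSD 0
  ens <- rep$ensemble
  ref2 <- modes(ens)[[1]]@peptide
  rms <- vapply(modes(ens), function(m) heavyAtomRMSD(m@peptide, ref2), 1)
  expect_equal(min(rms), 0)
})

test_that("enrichment AUROC is 1 for perfectly separated energies", {
  energy <- c(-8, -7.5, -7, -2, -1.5, -1)
  label <- c(rep("binder", 3), rep("decoy", 3))
  expect_equal(enrichmentAUC(energy, label), 1)
  expect_equal(enrichmentAUC(rev(energy), rev(label)), 1)
})
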