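test_that("atom classes follow residue topology and bond structure", {
  pep <- buildExtendedPeptide("ASLYNTVKF")
  at <- atomTable(pep)
  expect_equal(at$class[at$resno == 1 & at$name == "CB"], "hC")   # alanine CB
  pep2 <- buildExtendedPeptide("ASA", allow_any_length = TRUE)
  at2 <- atomTable(pep2)
  expect_equal(at2$class[at2$resno == 2 & at2$name == "OG"], "donacc")
  # oracle: walk the chemical bond graph; a carbon is hydrophobic iff no
  # N/O/S neighbour
  for (sq in c("ASLYNTVKF", "WMHEQRCDGI")) {
    p <- buildExtendedPeptide(sq, allow_any_length = TRUE)
    at <- atomTable(p)
    nb <- vector("list", nrow(at))
    for (r in seq_len(nrow(p@chemBonds))) {
      i <- p@chemBonds[r, 1]; j <- p@chemBonds[r, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
    for (k in which(at$el == "C")) {
      hydrophobic <- !any(at$el[nb[[k]]] %in% c("N", "O", "S"))
      expect_equal(at$class[k] == "hC", hydrophobic,
                   label = paste(sq, at$resno[k], at$name[k]))
    }
  }
})

test_that("assignAtomClasses fills classes and rejects unknown elements", {
  df <- data.frame(name = c("CB", "OG"), el = c("C", "O"),
                   resid = c("SER", "SER"), stringsAsFactors = FALSE)
  out <- assignAtomClasses(df)
  expect_equal(out$class, c("pC", "donacc"))
  expect_error(assignAtomClasses(data.frame(name = "X", el = "Zn",
                                            resid = "ALA")), "element")
})

test_that("pair terms vanish beyond the cutoff, leaving the torsional penalty", {
  pep <- buildExtendedPeptide("QFKDNVILL")
  far <- new("Receptor", id = "far",
             atoms = data.frame(name = "P1", el = "C", resno = 1L,
                                class = "hC", stringsAsFactors = FALSE),
             coords = matrix(c(500, 0, 0), 1, 3),
             boxCenter = c(250, 0, 0), boxDims = c(600, 600, 600),
             grooveAxis = c(1, 0, 0),
             anchorSites = list(n = matrix(249, 3, 3), c = matrix(251, 3, 3)))
  br <- scoreMode(pep, far, "vina_class")
  expect_equal(unname(br["gauss1"]), 0)
  expect_equal(unname(br["repulsion"]), 0)
  w_tors <- pHLAdock:::.score_params$vina_class$w_tors
  n_rot <- sum(torsionTable(pep)$rotatable)
  expect_equal(unname(br["total"]), w_tors * n_rot, tolerance = 1e-12)
})

test_that("a single pair at surface distance zero hits the gauss1 maximum", {
  p <- pHLAdock:::.score_params$vina_class
  acl <- structure("hC", rad = 1.9)
  bcl <- structure("hC", rad = 1.9)
  terms <- pHLAdock:::.pair_terms(p, matrix(c(0, 0, 0), 1, 3), acl,
                                  matrix(c(3.8, 0, 0), 1, 3), bcl)
  expect_equal(unname(terms["gauss1"]), unname(p$w["gauss1"]),
               tolerance = 1e-12)   # exp(0) = 1 times the weight
  expect_equal(unname(terms["repulsion"]), 0)
})

test_that("module totals equal an independent brute-force double loop", {
  fx <- small_fixture()
  for (fn in scoringFunctions()) {
    br <- scoreMode(fx$truth, fx$receptor, fn)
    oracle <- brute_force_pairs(fx$receptor, fx$truth@peptide, fn)
    expect_equal(unname(br["total"] - br["torsion"]), oracle,
                 tolerance = 1e-9, label = fn)
  }
})

test_that("scores are invariant to a rigid motion of the whole complex", {
  fx <- small_fixture()
  ang <- 0.6
  R <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3, 3)
  t <- c(5, -3, 2)
  rec2 <- fx$receptor
  rec2@coords <- pHLAdock:::.apply_rigid(rec2@coords, R, t)
  rec2@boxCenter <- drop(R %*% rec2@boxCenter) + t
  rec2@grooveAxis <- drop(R %*% rec2@grooveAxis)
  rec2@anchorSites <- lapply(rec2@anchorSites, function(s)
    pHLAdock:::.apply_rigid(s, R, t))
  pep2 <- transformPeptide(fx$truth@peptide, R, t)
  for (fn in scoringFunctions()) {
    expect_equal(unname(scoreMode(pep2, rec2, fn)["total"]),
                 unname(scoreMode(fx$truth, fx$receptor, fn)["total"]),
                 tolerance = 1e-9, label = fn)
  }
})

test_that("inserting an atom beyond the cutoff changes nothing", {
  fx <- small_fixture()
  rec2 <- fx$receptor
  rec2@atoms <- rbind(rec2@atoms,
                      data.frame(name = "PX", el = "C",
                                 resno = nrow(rec2@atoms) + 1L, class = "hC"))
  rec2@coords <- rbind(rec2@coords, rec2@boxCenter + c(0, 0, 200))
  rec2@boxDims <- rec2@boxDims + c(0, 0, 500)   # keep the atom "in" the box
  for (fn in scoringFunctions()) {
    expect_identical(unname(scoreMode(fx$truth, rec2, fn)["total"]),
                     unname(scoreMode(fx$truth, fx$receptor, fn)["total"]))
  }
})

test_that("ScoreBreakdown totals equal the sum of their terms", {
  fx <- small_fixture()
  for (fn in scoringFunctions()) {
    br <- scoreMode(fx$truth, fx$receptor, fn)
    expect_equal(unname(br["total"]),
                 sum(br[setdiff(names(br), "total")]), tolerance = 1e-9)
  }
})

test_that("scoring errors on unscorable states", {
  fx <- small_fixture()
  outside <- transformPeptide(fx$truth@peptide, t = c(500, 0, 0))
  expect_error(scoreMode(outside, fx$receptor), "box")
  expect_error(scoreMode(fx$truth, fx$receptor, "autodock_vina"), "unknown")
})

make_scored_ensemble <- function(fx, n = 10) {
  set.seed(99)
  ms <- lapply(seq_len(n), function(i) {
    p <- transformPeptide(fx$truth@peptide,
                          t = runif(3, -1, 1))
    new("BindingMode", peptide = p, scores = numeric(),
        provenance = list(round = 1L, replicate = i, seed = i))
  })
  new("Ensemble", pairId = "test", modes = ms)
}

test_that("rescoring fills one cell per mode and function, deterministically", {
  fx <- small_fixture()
  ens <- make_scored_ensemble(fx)
  scored <- rescoreEnsemble(ens, fx$receptor, scoringFunctions())
  cells <- unlist(lapply(modes(scored), modeScores))
  expect_length(cells, 30)
  scored2 <- rescoreEnsemble(ens, fx$receptor, scoringFunctions())
  expect_identical(lapply(modes(scored), modeScores),
                   lapply(modes(scored2), modeScores))
  # element-wise agreement with direct score() calls
  for (i in c(1, 5, 10)) {
    for (fn in scoringFunctions()) {
      expect_equal(modeScores(modes(scored)[[i]])[[fn]],
                   unname(scoreMode(modes(ens)[[i]], fx$receptor, fn)["total"]))
    }
  }
  # geometry untouched, order preserved
  for (i in seq_len(nModes(ens)))
    expect_identical(modes(scored)[[i]]@peptide@coords,
                     modes(ens)[[i]]@peptide@coords)
  expect_error(rescoreEnsemble(ens, fx$receptor, character()), "empty")
})

test_that("rankTop agrees with an independent sort and clamps m", {
  fx <- small_fixture()
  ens <- rescoreEnsemble(make_scored_ensemble(fx), fx$receptor, "vina_class")
  top <- rankTop(ens, "vina_class", 5)
  expect_length(top, 5)
  e <- vapply(top, function(m) modeScores(m)[["vina_class"]], 1)
  expect_true(all(diff(e) >= 0))
  all_e <- vapply(modes(ens), function(m) modeScores(m)[["vina_class"]], 1)
  expect_equal(e, sort(all_e)[1:5])
  expect_length(rankTop(ens, "vina_class", 50), nModes(ens))
  unscored <- make_scored_ensemble(fx)
  expect_error(rankTop(unscored, "vina_class", 5), "rescore")
})
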