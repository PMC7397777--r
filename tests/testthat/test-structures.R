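test_that("extended peptide construction matches standard residue topology", {
  pep <- buildExtendedPeptide("QFKDNVILL")
  expect_equal(max(atomTable(pep)$resno), 9)
  oracle <- sum(std_heavy_counts[strsplit("QFKDNVILL", "")[[1]]]) + 1  # + OXT
  expect_equal(nrow(atomTable(pep)), unname(oracle))
  for (sq in c("ARNDCQEGHI", "LKMFPSTWYV")) {
    pep2 <- buildExtendedPeptide(sq, allow_any_length = TRUE)
    oracle2 <- sum(std_heavy_counts[strsplit(sq, "")[[1]]]) + 1
    expect_equal(nrow(atomTable(pep2)), unname(oracle2))
    g <- checkGeometry(pep2)
    expect_lt(g$max_bond_dev, 1e-9)
    expect_lt(g$max_angle_dev, 1e-9)
  }
})

test_that("extended build reads back phi/psi of 180 degrees", {
  pep <- buildExtendedPeptide("AAA", allow_any_length = TRUE)
  for (id in listDihedrals(pep)) {
    expect_lt(abs(ang_diff(getDihedral(pep, id), 180)), 1e-6)
  }
})

test_that("sequence validation rejects bad input", {
  expect_error(buildExtendedPeptide(""), "non-empty")
  expect_error(buildExtendedPeptide("AXA", allow_any_length = TRUE),
               "unknown residue")
  expect_error(buildExtendedPeptide("AAA"), "8-11")
})

test_that("set/get dihedral round-trips and is a pure rotation", {
  pep <- buildExtendedPeptide("ATLKSEVNF")
  ids <- listDihedrals(pep)
  for (id in c("phi:3", "psi:5", "chi1:2", "chi1:4")) {
    p2 <- setDihedral(pep, id, 37.5)
    expect_lt(abs(ang_diff(getDihedral(p2, id), 37.5)), 1e-6)
  }
  # identity rotation moves nothing
  cur <- getDihedral(pep, "psi:4")
  p3 <- setDihedral(pep, "psi:4", cur)
  expect_equal(max(abs(p3@coords - pep@coords)), 0)
  expect_error(setDihedral(pep, "chi9:1", 10), "unknown dihedral")
})

test_that("random dihedral edits leave bonded geometry invariant", {
  pep <- buildExtendedPeptide("AWA", allow_any_length = TRUE)
  # oracle: record all spanning-tree bond lengths directly from coordinates
  ib <- pep@idealBonds
  len0 <- sqrt(rowSums((pep@coords[ib$i, ] - pep@coords[ib$j, ])^2))
  set.seed(42)
  ids <- listDihedrals(pep)
  for (k in 1:500) {
    id <- sample(ids, 1)
    pep <- setDihedral(pep, id, runif(1, -180, 180))
  }
  len1 <- sqrt(rowSums((pep@coords[ib$i, ] - pep@coords[ib$j, ])^2))
  expect_lt(max(abs(len1 - len0)), 1e-9)
  expect_lt(checkGeometry(pep)$max_angle_dev, 1e-9)
})

test_that("only atoms distal to a rotated bond move", {
  pep <- buildExtendedPeptide("QFKDNVILL")
  k <- match("chi1:3", pep@torsions$id)
  before <- pep@coords
  p2 <- setDihedral(pep, "chi1:3", getDihedral(pep, "chi1:3") + 55)
  moved <- which(rowSums(abs(p2@coords - before)) > 1e-12)
  expect_setequal(moved, pep@moving[[k]])
})

test_that("heavy-atom RMSD is the plain fixed-frame formula", {
  a <- buildExtendedPeptide("QFKDNVILL")
  expect_equal(heavyAtomRMSD(a, a), 0)
  b <- transformPeptide(a, t = c(3, 4, 0))
  expect_equal(heavyAtomRMSD(a, b), 5.0, tolerance = 1e-12)
  # random pair vs explicit double loop
  set.seed(7)
  cc <- a
  for (id in sample(listDihedrals(cc), 5))
    cc <- setDihedral(cc, id, runif(1, -180, 180))
  s <- 0
  for (i in seq_len(nrow(a@coords)))
    s <- s + sum((a@coords[i, ] - cc@coords[i, ])^2)
  expect_equal(heavyAtomRMSD(a, cc), sqrt(s / nrow(a@coords)),
               tolerance = 1e-12)
  expect_equal(heavyAtomRMSD(a, cc), heavyAtomRMSD(cc, a))
  d <- buildExtendedPeptide("QFKDNVILV")
  expect_error(heavyAtomRMSD(a, d), "mismatch")
})

test_that("RMSD satisfies metric properties on fixed frames", {
  set.seed(11)
  a <- buildExtendedPeptide("SLYNTVATL")
  perturb <- function(p) {
    for (id in sample(listDihedrals(p), 3))
      p <- setDihedral(p, id, runif(1, -180, 180))
    transformPeptide(p, t = rnorm(3))
  }
  b <- perturb(a); c <- perturb(a)
  expect_gte(heavyAtomRMSD(a, b), 0)
  expect_equal(heavyAtomRMSD(a, b), heavyAtomRMSD(b, a))
  expect_lt(heavyAtomRMSD(a, a), 1e-12)
})

test_that("PDB round-trip is the identity on names, numbering, coordinates", {
  fx <- small_fixture()
  f1 <- tempfile(fileext = ".pdb")
  writePDB(fx$truth@peptide, f1, receptor = fx$receptor)
  st1 <- readPDB(f1, peptide_range = c(4L, 11L))
  expect_equal(sort(unname(st1$receptor_chains)), "A")
  expect_equal(unname(st1$peptide_chain), "C")
  pep1 <- complexPeptide(st1)
  f2 <- tempfile(fileext = ".pdb")
  writePDB(pep1, f2, receptor = fx$receptor)
  st2 <- readPDB(f2, peptide_range = c(4L, 11L))
  pep2 <- complexPeptide(st2)
  expect_identical(atomTable(pep1)$name, atomTable(pep2)$name)
  expect_identical(atomTable(pep1)$resno, atomTable(pep2)$resno)
  expect_equal(pep1@coords, pep2@coords, tolerance = 1e-9)  # 3-decimal file
  expect_lt(heavyAtomRMSD(fx$truth@peptide, pep2), 1e-3)
})

test_that("malformed coordinate fields are reported with their line number", {
  fx <- small_fixture()
  f <- tempfile(fileext = ".pdb")
  writePDB(fx$truth@peptide, f)
  lines <- readLines(f)
  substr(lines[3], 33, 38) <- "xx.yyy"
  writeLines(lines, f)
  expect_error(readPDB(f), "line 3")
})

test_that("peptide role assignment errors when required and absent", {
  fx <- small_fixture()  # 5-mer peptide, outside the default 8-11 window
  f <- tempfile(fileext = ".pdb")
  writePDB(fx$truth@peptide, f, receptor = fx$receptor)
  expect_error(readPDB(f, require_peptide = TRUE), "role")
})

test_that("ensembles serialize to multi-model PDB and back", {
  pep <- buildExtendedPeptide("QFKDNVILL")
  m <- function(dx) new("BindingMode", peptide = transformPeptide(pep, t = c(dx, 0, 0)),
                        scores = numeric(), provenance = list(round = 1L,
                                                              replicate = dx,
                                                              seed = 1L))
  ens <- new("Ensemble", pairId = "QFKDNVILL|x", modes = list(m(0), m(2), m(5)))
  f <- tempfile(fileext = ".pdb")
  writePDB(ens, f)
  ens2 <- readEnsemblePDB(f)
  expect_equal(nModes(ens2), 3)
  for (i in 1:3) {
    expect_lt(heavyAtomRMSD(modes(ens)[[i]]@peptide,
                            modes(ens2)[[i]]@peptide), 1e-3)
  }
})

test_that("Kabsch superposition recovers a known rigid transform", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  Q <- P %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  fit <- kabschFit(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$R, R, tolerance = 1e-9)
})
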