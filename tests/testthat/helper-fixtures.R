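# Shared fixtures, built once per test run.  Everything is generated in code
# from fixed seeds; no data files are read.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_fixture <- function() {
  cached("toy", makeToyPocket("RDEQSAVLF", seed = 1, n_probes = 200))
}

small_fixture <- function() {
  cached("small", makeToyPocket("RDSVF", seed = 2, n_probes = 100,
                                allow_any_length = TRUE))
}

# angular difference in degrees, wrapped to [-180, 180)
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}

# independent textbook heavy-atom counts per residue (without terminal OXT)
std_heavy_counts <- c(A = 5, R = 11, N = 8, D = 8, C = 6, Q = 9, E = 9,
                      G = 4, H = 10, I = 8, L = 8, K = 9, M = 8, F = 11,
                      P = 7, S = 6, T = 7, W = 14, Y = 12, V = 7)

# brute-force re-implementation of the pairwise interaction terms, written
# as explicit double loops straight from the functional forms
brute_force_pairs <- function(receptor, peptide, fn) {
  p <- pHLAdock:::.score_params[[fn]]
  rx <- receptor@coords; px <- peptide@coords
  rcl <- receptor@atoms$class; pcl <- peptide@atoms$class
  rrad <- p$radii[receptor@atoms$el]; prad <- p$radii[peptide@atoms$el]
  if (p$form == "ad4") {
    reps <- p$eps[receptor@atoms$el]; peps <- p$eps[peptide@atoms$el]
  }
  is_hb <- function(a, b) {
    (a %in% c("don", "donacc") && b %in% c("acc", "donacc")) ||
      (a %in% c("acc", "donacc") && b %in% c("don", "donacc"))
  }
  total <- 0
  for (i in seq_len(nrow(rx))) {
    for (j in seq_len(nrow(px))) {
      r <- sqrt(sum((rx[i, ] - px[j, ])^2))
      if (r > 8) next
      if (p$form %in% c("vina", "vinardo")) {
        d <- r - rrad[i] - prad[j]
        e <- p$w[["gauss1"]] * exp(-(d / p$gauss1_width)^2)
        if (p$form == "vina")
          e <- e + p$w[["gauss2"]] *
            exp(-((d - p$gauss2_offset) / p$gauss2_width)^2)
        if (d < 0) e <- e + p$w[["repulsion"]] * d^2
        if (rcl[i] == "hC" && pcl[j] == "hC")
          e <- e + p$w[["hydrophobic"]] *
            min(1, max(0, (p$hyd_hi - d) / (p$hyd_hi - p$hyd_lo)))
        if (is_hb(rcl[i], pcl[j]))
          e <- e + p$w[["hbond"]] *
            min(1, max(0, (p$hb_hi - d) / (p$hb_hi - p$hb_lo)))
      } else {
        rr <- max(r, p$r_min)
        Rij <- rrad[i] + prad[j]
        epsij <- sqrt(reps[i] * peps[j])
        if (is_hb(rcl[i], pcl[j])) {
          q <- p$hb_R / rr
          e <- p$w_hb * p$hb_eps * (5 * q^12 - 6 * q^10)
        } else {
          q6 <- (Rij / rr)^6
          e <- p$w_vdw * epsij * (q6^2 - 2 * q6)
        }
      }
      total <- total + e
    }
  }
  unname(total)
}
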