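#' @include ensemble-gen.R docking.R fixtures.R
NULL

# End-to-end workflows: geometry prediction (incremental docking +
# orientation filter + multi-function rescoring), ensemble-based binding
# energy prediction (median of ensemble energies, correlation with measured
# affinities), and two-stage virtual screening (sequence prefilter +
# structural re-ranking).

#' Workflow configuration
#'
#' @param near_native_rmsd All-heavy-atom RMSD threshold below which a pose
#'   counts as near-native, Angstrom (default 2.5).
#' @param affinity_threshold_nM Prefilter cutoff for virtual screening, nM
#'   (default 500; \code{Inf} disables the prefilter).
#' @param top_m Ranking depth reported per scoring function (default 5).
#' @param minimize Apply the internal minimizer to each generated mode.
#' @return Validated list of class \code{"WorkflowConfig"}.
#' @export
WorkflowConfig <- function(near_native_rmsd = 2.5,
                           affinity_threshold_nM = 500, top_m = 5,
                           minimize = FALSE) {
  if (near_native_rmsd <= 0 || affinity_threshold_nM <= 0 || top_m <= 0)
    stop("workflow thresholds must be positive")
  structure(list(near_native_rmsd = near_native_rmsd,
                 affinity_threshold_nM = affinity_threshold_nM,
                 top_m = as.integer(top_m), minimize = minimize),
            class = c("WorkflowConfig", "list"))
}

#' Superpose one receptor onto another (cross-docking frame)
#'
#' Least-squares fit on shared atoms (alpha-carbons when both have them,
#' otherwise all atoms matched by name and residue number).  Apply the
#' returned transform to poses expressed in \code{mov}'s frame to compare
#' them against poses in \code{ref}'s frame.
#'
#' @param ref,mov \linkS4class{Receptor} objects.
#' @return List: \code{R}, \code{t}, \code{rmsd} of the fit.
#' @export
superposeReceptors <- function(ref, mov) {
  key <- function(r) paste(r@atoms$resno, r@atoms$name)
  ca_ref <- ref@atoms$name == "CA"; ca_mov <- mov@atoms$name == "CA"
  if (any(ca_ref) && any(ca_mov)) {
    kr <- key(ref)[ca_ref]; km <- key(mov)[ca_mov]
    shared <- intersect(kr, km)
    P <- mov@coords[ca_mov, , drop = FALSE][match(shared, km), , drop = FALSE]
    Q <- ref@coords[ca_ref, , drop = FALSE][match(shared, kr), , drop = FALSE]
  } else {
    shared <- intersect(key(ref), key(mov))
    P <- mov@coords[match(shared, key(mov)), , drop = FALSE]
    Q <- ref@coords[match(shared, key(ref)), , drop = FALSE]
  }
  if (nrow(P) < 3) stop("fewer than 3 shared atoms to superpose on")
  kabschFit(P, Q)
}

#' Remove modes bound in reverse orientation
#'
#' A mode is kept iff the unit vector from its first-residue CA to its
#' last-residue CA has positive dot product with the receptor's groove axis
#' (A-pocket to F-pocket).  Order is otherwise preserved.
#'
#' @param ensemble An \linkS4class{Ensemble}.
#' @param receptor The \linkS4class{Receptor} defining the groove axis.
#' @return The filtered \linkS4class{Ensemble}.
#' @export
filterReverseOrientation <- function(ensemble, receptor) {
  keep <- vapply(ensemble@modes, function(m) {
    at <- m@peptide@atoms
    L <- max(at$resno)
    ca1 <- m@peptide@coords[at$resno == 1 & at$name == "CA", ]
    caL <- m@peptide@coords[at$resno == L & at$name == "CA", ]
    sum(.unit(caL - ca1) * receptor@grooveAxis) > 0
  }, TRUE)
  ensemble@modes <- ensemble@modes[keep]
  ensemble
}

#' Median ensemble binding energy
#'
#' The binding energy of a peptide is estimated as the median score within
#' its conformation ensemble (even counts: arithmetic mean of the two
#' central values).
#'
#' @param ensemble A scored \linkS4class{Ensemble}.
#' @param fn Scoring-function id whose scores are used.
#' @return Energy in kcal/mol.
#' @export
ensembleBindingEnergy <- function(ensemble, fn = "vina_class") {
  fn <- .check_fn(fn)
  if (!nModes(ensemble)) stop("empty ensemble")
  sc <- vapply(ensemble@modes, function(m) {
    if (!fn %in% names(m@scores)) NA_real_ else m@scores[[fn]]
  }, 1)
  if (anyNA(sc)) stop("modes missing scores for ", fn)
  stats::median(sc)
}

#' Geometry-prediction workflow
#'
#' Runs incremental docking, removes reverse-orientation modes, rescores
#' with all three scoring functions, and reports the top modes per function.
#' When a reference pose is given, per-mode all-heavy-atom RMSDs (receptor
#' frame, no peptide superposition), the minimum-RMSD mode and a near-native
#' flag (min RMSD below \code{config$near_native_rmsd}) are included.
#'
#' @param peptide Sequence or \linkS4class{PeptideConformation}.
#' @param receptor The \linkS4class{Receptor}.
#' @param reference Optional reference pose (\linkS4class{BindingMode} or
#'   \linkS4class{PeptideConformation}) in the receptor frame.
#' @param dock_config A \code{\link{DockingConfig}}.
#' @param config A \code{\link{WorkflowConfig}}.
#' @return List: \code{ensemble} (filtered, fully rescored), \code{table}
#'   (one row per function and rank: \code{fn}, \code{rank}, \code{energy},
#'   \code{rmsd}), \code{min_rmsd}, \code{near_native}.
#' @export
geometryPrediction <- function(peptide, receptor, reference = NULL,
                               dock_config = DockingConfig(),
                               config = WorkflowConfig()) {
  ens <- incrementalDock(peptide, receptor, dock_config)
  ens <- filterReverseOrientation(ens, receptor)
  if (!nModes(ens)) stop("no modes survive the orientation filter")
  ens <- rescoreEnsemble(ens, receptor, scoringFunctions())
  ref_pep <- if (is(reference, "BindingMode")) reference@peptide else reference
  rmsd_of <- function(m) heavyAtomRMSD(m@peptide, ref_pep)
  rows <- list()
  for (fn in scoringFunctions()) {
    top <- rankTop(ens, fn, config$top_m)
    for (i in seq_along(top)) {
      rows[[length(rows) + 1]] <- data.frame(
        fn = fn, rank = i, energy = top[[i]]@scores[[fn]],
        rmsd = if (is.null(ref_pep)) NA_real_ else rmsd_of(top[[i]]))
    }
  }
  tab <- do.call(rbind, rows)
  min_rmsd <- NA_real_; near_native <- NA
  if (!is.null(ref_pep)) {
    all_rmsd <- vapply(ens@modes, rmsd_of, 1)
    min_rmsd <- min(all_rmsd)
    near_native <- min_rmsd < config$near_native_rmsd
  }
  list(ensemble = ens, table = tab, min_rmsd = min_rmsd,
       near_native = near_native)
}

#' Ensemble-based binding-energy prediction with affinity correlation
#'
#' For each peptide, generates an anchored ensemble, rescores it with all
#' three scoring functions, and takes the median ensemble energy per
#' function.  With at least 3 experimental affinities, the Pearson
#' correlation R between each function's energies and log10(affinity nM) is
#' reported.
#'
#' @param peptides Data frame with columns \code{peptide} and (optionally)
#'   \code{affinity_nM}.
#' @param receptor The \linkS4class{Receptor}.
#' @param template An \linkS4class{AnchorTemplate}.
#' @param ens_config An \code{\link{EnsembleConfig}}.
#' @param config A \code{\link{WorkflowConfig}} (its \code{minimize} flag
#'   overrides the ensemble config's).
#' @param minimizer Pluggable minimizer \code{function(mode, receptor, fn)};
#'   defaults to \code{\link{internalMinimizer}}.
#' @return List: \code{table} (peptide, affinity, one energy column per
#'   function), \code{correlations} (named numeric, or NULL with a warning
#'   when fewer than 3 affinities are available).
#' @export
bindingPrediction <- function(peptides, receptor, template,
                              ens_config = EnsembleConfig(),
                              config = WorkflowConfig(),
                              minimizer = internalMinimizer) {
  stopifnot(is.data.frame(peptides), "peptide" %in% names(peptides))
  fns <- scoringFunctions()
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    sq <- peptides$peptide[i]
    cfg <- ens_config
    cfg$seed <- childSeed(ens_config$seed, "bindpred", i)
    ens <- generateEnsemble(sq, receptor, template, cfg)
    if (isTRUE(config$minimize)) {
      ens@modes <- lapply(ens@modes, minimizer, receptor = receptor,
                          fn = cfg$fn)
    }
    ens <- rescoreEnsemble(ens, receptor, fns)
    out <- data.frame(peptide = sq, stringsAsFactors = FALSE)
    for (fn in fns) out[[fn]] <- ensembleBindingEnergy(ens, fn)
    out
  })
  tab <- do.call(rbind, rows)
  if ("affinity_nM" %in% names(peptides))
    tab$affinity_nM <- peptides$affinity_nM
  correlations <- NULL
  if ("affinity_nM" %in% names(peptides)) {
    ok <- is.finite(tab$affinity_nM)
    if (sum(ok) >= 3) {
      correlations <- vapply(fns, function(fn) {
        stats::cor(tab[[fn]][ok], log10(tab$affinity_nM[ok]))
      }, 1)
    } else {
      warning("fewer than 3 peptides with affinities; correlation omitted")
    }
  }
  list(table = tab, correlations = correlations)
}

#' Train the position-weight-matrix affinity predictor
#'
#' Position-specific log-odds over a uniform background with additive
#' pseudocount 1, trained per allele on known binders (at least 20, one
#' length per model).  Scores map monotonically to a pseudo-nM scale:
#' nM = 50000^(1 - s), where s is the score normalized to [0, 1] by the
#' matrix's attainable minimum and maximum.
#'
#' @param binders Named list: per allele, a character vector of binder
#'   sequences of one common length.
#' @return An object of class \code{"PWMPredictor"} with a
#'   \code{predict(peptide, allele)} element returning nM.
#' @export
trainPWMPredictor <- function(binders) {
  models <- lapply(names(binders), function(al) {
    seqs <- toupper(binders[[al]])
    if (length(seqs) < 20)
      stop("allele ", al, ": need >= 20 binders, got ", length(seqs))
    len <- unique(nchar(seqs))
    if (length(len) != 1)
      stop("allele ", al, ": binders must have uniform length")
    mat <- matrix(0, nrow = 20, ncol = len, dimnames = list(.AA20, NULL))
    for (s in seqs) {
      aa <- strsplit(s, "")[[1]]
      for (p in seq_len(len)) mat[aa[p], p] <- mat[aa[p], p] + 1
    }
    lod <- log((mat + 1) / (length(seqs) + 20)) - log(1 / 20)
    list(lod = lod, len = len,
         smin = sum(apply(lod, 2, min)), smax = sum(apply(lod, 2, max)))
  })
  names(models) <- names(binders)
  score1 <- function(model, peptide) {
    aa <- strsplit(toupper(peptide), "")[[1]]
    if (length(aa) != model$len)
      stop("peptide length ", length(aa), " does not match model length ",
           model$len)
    ri <- match(aa, rownames(model$lod))
    if (anyNA(ri)) stop("non-standard residue in peptide ", peptide)
    sum(model$lod[cbind(ri, seq_along(aa))])
  }
  obj <- list(
    models = models,
    score = function(peptide, allele) score1(models[[allele]], peptide),
    predict = function(peptide, allele) {
      model <- models[[allele]]
      if (is.null(model)) stop("no PWM model for allele ", allele)
      s <- (score1(model, peptide) - model$smin) / (model$smax - model$smin)
      50000^(1 - s)
    })
  class(obj) <- "PWMPredictor"
  obj
}

#' @export
print.PWMPredictor <- function(x, ...) {
  cat("PWMPredictor:", length(x$models), "allele model(s):",
      paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage virtual screening
#'
#' Stage 1 keeps (peptide, allele) pairs whose predicted affinity does not
#' exceed \code{config$affinity_threshold_nM} (inclusive; \code{Inf}
#' disables the prefilter).  Stage 2 models each surviving pair with the
#' anchored ensemble generator and records the top-scoring mode's energy.
#' Stage 3 ranks survivors per allele by ascending energy.
#'
#' @param peptides Data frame with column \code{peptide} and optionally
#'   \code{label} (binder/decoy).
#' @param panel Named list per allele with elements \code{receptor} and
#'   \code{template} (see \code{\link{makeAllelePanel}}); alleles missing
#'   from the panel yield error records.
#' @param predictor An affinity predictor with a \code{predict(peptide,
#'   allele)} element (e.g. \code{\link{trainPWMPredictor}}).
#' @param config A \code{\link{WorkflowConfig}}.
#' @param ens_config An \code{\link{EnsembleConfig}} for stage 2.
#' @param alleles Alleles to screen (default: all panel names).
#' @return Data frame of screening records: \code{peptide}, \code{allele},
#'   \code{predicted_affinity_nM}, \code{structural_energy}, \code{label},
#'   \code{rank}, \code{status} (ok / filtered / no_template).
#' @export
virtualScreen <- function(peptides, panel, predictor,
                          config = WorkflowConfig(),
                          ens_config = EnsembleConfig(),
                          alleles = names(panel)) {
  stopifnot(is.data.frame(peptides))
  if (!nrow(peptides)) {
    return(data.frame(peptide = character(), allele = character(),
                      predicted_affinity_nM = numeric(),
                      structural_energy = numeric(), label = character(),
                      rank = integer(), status = character()))
  }
  labels <- if ("label" %in% names(peptides)) peptides$label else
    rep("unknown", nrow(peptides))
  out <- list()
  for (al in alleles) {
    entry <- panel[[al]]
    if (is.null(entry) || is.null(entry$receptor) || is.null(entry$template)) {
      out[[length(out) + 1]] <- data.frame(
        peptide = peptides$peptide, allele = al,
        predicted_affinity_nM = NA_real_, structural_energy = NA_real_,
        label = labels, rank = NA_integer_, status = "no_template",
        stringsAsFactors = FALSE)
      next
    }
    nm <- vapply(peptides$peptide, predictor$predict, 1, allele = al)
    pass <- nm <= config$affinity_threshold_nM
    energy <- rep(NA_real_, nrow(peptides))
    failed <- rep(FALSE, nrow(peptides))
    for (i in which(pass)) {
      cfg <- ens_config
      cfg$seed <- childSeed(ens_config$seed, paste0("screen:", al), i)
      ens <- tryCatch(
        generateEnsemble(peptides$peptide[i], entry$receptor,
                         entry$template, cfg),
        error = function(e) NULL)
      if (is.null(ens)) { failed[i] <- TRUE; next }
      top <- rankTop(ens, cfg$fn, 1)
      energy[i] <- top[[1]]@scores[[cfg$fn]]
    }
    modeled <- pass & !failed
    rank <- rep(NA_integer_, nrow(peptides))
    rank[modeled] <- rank(energy[modeled], ties.method = "first")
    out[[length(out) + 1]] <- data.frame(
      peptide = peptides$peptide, allele = al,
      predicted_affinity_nM = unname(nm), structural_energy = energy,
      label = labels, rank = rank,
      status = ifelse(!pass, "filtered",
                      ifelse(failed, "model_error", "ok")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Binder/decoy enrichment AUROC
#'
#' Area under the ROC curve for separating binders from decoys by
#' structural energy (lower energy ranks higher).
#'
#' @param energy Numeric energies (kcal/mol).
#' @param label Character labels, \code{"binder"} or \code{"decoy"}.
#' @return AUROC in [0, 1].
#' @export
enrichmentAUC <- function(energy, label) {
  ok <- is.finite(energy) & label %in% c("binder", "decoy")
  r <- pROC::roc(response = factor(label[ok], levels = c("decoy", "binder")),
                 predictor = -energy[ok], direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}
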