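#' @include AllClasses.R
NULL

#' Accessors for pHLAdock objects
#'
#' \code{peptideSequence} returns the one-letter sequence;
#' \code{atomCoords} the heavy-atom coordinate matrix; \code{atomTable} the
#' atom annotation data frame; \code{torsionTable} the named-dihedral table;
#' \code{modes} the list of binding modes of an ensemble; \code{modeScores}
#' the named energy vector of a mode; \code{provenance} its sampling
#' provenance.
#'
#' @param x A \linkS4class{PeptideConformation}, \linkS4class{Receptor},
#'   \linkS4class{BindingMode} or \linkS4class{Ensemble}.
#' @param value Replacement value.
#' @return The slot contents (see details above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("atomCoords<-", function(x, value) standardGeneric("atomCoords<-"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("torsionTable", function(x) standardGeneric("torsionTable"))
#' @rdname accessors
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("modeScores", function(x) standardGeneric("modeScores"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

setMethod("peptideSequence", "PeptideConformation", function(x) x@sequence)
setMethod("peptideSequence", "BindingMode", function(x) x@peptide@sequence)
setMethod("peptideSequence", "Ensemble", function(x) {
  if (length(x@modes)) x@modes[[1]]@peptide@sequence else NA_character_
})

setMethod("atomCoords", "PeptideConformation", function(x) x@coords)
setMethod("atomCoords", "Receptor", function(x) x@coords)
setMethod("atomCoords", "BindingMode", function(x) x@peptide@coords)
setMethod("atomCoords<-", "PeptideConformation", function(x, value) {
  x@coords <- value; validObject(x); x
})

setMethod("atomTable", "PeptideConformation", function(x) x@atoms)
setMethod("atomTable", "Receptor", function(x) x@atoms)
setMethod("torsionTable", "PeptideConformation", function(x) x@torsions)
setMethod("modes", "Ensemble", function(x) x@modes)
setMethod("modeScores", "BindingMode", function(x) x@scores)
setMethod("provenance", "BindingMode", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))
setMethod("nModes", "Ensemble", function(x) length(x@modes))

setMethod("show", "PeptideConformation", function(object) {
  cat("PeptideConformation:", object@sequence,
      sprintf("(%d residues, %d heavy atoms, %d rotatable dihedrals)\n",
              nchar(object@sequence), nrow(object@atoms),
              sum(object@torsions$rotatable)))
})

setMethod("show", "Receptor", function(object) {
  cat("Receptor", object@id, sprintf("(%d atoms)\n", nrow(object@atoms)))
  cat("  box center:", paste(sprintf("%.1f", object@boxCenter), collapse = " "),
      " dims:", paste(sprintf("%.1f", object@boxDims), collapse = " "), "\n")
})

setMethod("show", "BindingMode", function(object) {
  cat("BindingMode:", object@peptide@sequence, "\n")
  if (length(object@scores)) {
    cat("  scores:",
        paste(sprintf("%s=%.3f", names(object@scores), object@scores),
              collapse = ", "), "\n")
  } else cat("  scores: <unscored>\n")
  pv <- object@provenance
  if (length(pv))
    cat(sprintf("  provenance: round=%s replicate=%s seed=%s\n",
                pv$round, pv$replicate, pv$seed))
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble", object@pairId, sprintf("(%d modes)\n", length(object@modes)))
})
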