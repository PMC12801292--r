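#' @include AllClasses.R
NULL

#' Accessors for PharmScreen classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))
#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("dockingScore", function(x) standardGeneric("dockingScore"))
#' @rdname accessors
#' @export
setGeneric("conformer", function(x) standardGeneric("conformer"))
#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname accessors
#' @export
setGeneric("interactionKeys", function(x, ...) standardGeneric("interactionKeys"))
#' @rdname accessors
#' @export
setGeneric("keyInteractions", function(x) standardGeneric("keyInteractions"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("receptorAtoms", function(x) standardGeneric("receptorAtoms"))
#' @rdname accessors
#' @export
setGeneric("bindingSite", function(x) standardGeneric("bindingSite"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))
#' @rdname accessors
#' @export
setGeneric("filterStages", function(x) standardGeneric("filterStages"))
#' @rdname accessors
#' @export
setGeneric("removedCompounds", function(x) standardGeneric("removedCompounds"))
#' @rdname accessors
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

setMethod("compoundId", "PoseRecord", function(x) x@compoundId)
setMethod("compoundId", "InteractionProfile", function(x) x@compoundId)
setMethod("structureId", "PoseRecord", function(x) x@structureId)
setMethod("structureId", "InteractionProfile", function(x) x@structureId)
setMethod("structureId", "FrequencyTable", function(x) x@structureId)
setMethod("structureId", "PharmacologicalModel", function(x) x@structureId)
setMethod("structureId", "ReceptorStructure", function(x) x@id)
setMethod("dockingScore", "PoseRecord", function(x) x@dockingScore)
setMethod("conformer", "PoseRecord", function(x) x@conformer)
setMethod("interactions", "InteractionProfile", function(x) x@interactions)
setMethod("keyInteractions", "PharmacologicalModel",
          function(x) x@keyInteractions)
setMethod("receptorAtoms", "ReceptorStructure", function(x) x@atoms)
setMethod("bindingSite", "ReceptorStructure", function(x) x@bindingSite)
setMethod("frequencies", "FrequencyTable", function(x) x@entries)
setMethod("ranking", "ConsensusRanking", function(x) x@ranking)
setMethod("filterStages", "FilterReport", function(x) x@stages)
setMethod("removedCompounds", "FilterReport", function(x) x@removed)
setMethod("fingerprintBits", "FingerprintSet", function(x) x@bits)

setMethod("residues", "ReceptorStructure", function(x) {
  unique(x@atoms[, c("chain", "resno", "resname")])
})

#' @rdname accessors
#' @param ... for `interactionKeys`, `subtype = FALSE` to key at residue
#'   level (default) or `TRUE` to include the subtype in the key.
setMethod("interactionKeys", "InteractionProfile", function(x, subtype = FALSE) {
  df <- x@interactions
  if (!nrow(df)) return(character())
  if (subtype) .interaction_key_sub(df$chain, df$resno, df$kind, df$subtype)
  else .interaction_key(df$chain, df$resno, df$kind)
})

setMethod("interactionKeys", "PharmacologicalModel", function(x, subtype = FALSE) {
  df <- x@keyInteractions
  if (!nrow(df)) return(character())
  if (subtype) .interaction_key_sub(df$chain, df$resno, df$kind, df$subtype)
  else .interaction_key(df$chain, df$resno, df$kind)
})

setMethod("show", "Molecule", function(object) {
  np <- sum(!is.na(object@coords[, 1]))
  cat("Molecule", object@id, "-", length(object@elements), "atoms (",
      sum(object@elements != "H"), "heavy ),", nrow(object@bonds), "bonds,",
      np, "with 3D coordinates\n")
})

setMethod("show", "ReceptorStructure", function(object) {
  r <- residues(object)
  cat("ReceptorStructure", object@id, "-", nrow(r), "residues,",
      nrow(object@atoms), "atoms")
  if (nrow(object@bindingSite))
    cat(";", nrow(object@bindingSite), "binding-site residues")
  cat("\n")
})

setMethod("show", "PoseRecord", function(object) {
  cat(sprintf("PoseRecord %s @ %s (docking score %.3f, %d heavy atoms)\n",
              object@compoundId, object@structureId, object@dockingScore,
              sum(object@conformer@elements != "H")))
})

setMethod("show", "InteractionProfile", function(object) {
  cat(sprintf("InteractionProfile %s @ %s: %d interaction(s)\n",
              object@compoundId, object@structureId,
              nrow(object@interactions)))
  if (nrow(object@interactions)) {
    df <- object@interactions
    cat(paste0("  ", df$resname, df$resno, " ", df$kind, "/", df$subtype,
               sprintf(" %.2f A", df$distance), collapse = "\n"), "\n")
  }
})

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable", object@structureId, "- over", object@nPoses,
      "poses,", nrow(object@entries), "distinct interaction keys\n")
})

setMethod("show", "PharmacologicalModel", function(object) {
  cat(sprintf(
    "PharmacologicalModel %s (HB >= %.2f, HP >= %.2f): %d key interaction(s)\n",
    object@structureId, object@hbThreshold, object@hpThreshold,
    nrow(object@keyInteractions)))
  df <- object@keyInteractions
  if (nrow(df))
    cat(paste0("  ", df$resname, df$resno, " ", df$kind, "/", df$subtype,
               sprintf(" (%.2f)", df$frequency), collapse = "\n"), "\n")
})

setMethod("show", "ConsensusRanking", function(object) {
  cat("ConsensusRanking over", length(object@structureIds), "structures (",
      paste(object@structureIds, collapse = ", "), "),",
      nrow(object@ranking), "compounds\n")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  print(object@stages, row.names = FALSE)
})

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d compounds, radius %d, %d bits\n",
              length(object@ids), object@radius, object@nBits))
})

setMethod("show", "BenchmarkSpec", function(object) {
  cat(sprintf(paste0(
    "BenchmarkSpec: %d structures, %d actives / %d decoys\n",
    "  planted per structure: %d HB + %d HP; p(active)=%.2f p(decoy)=%.2f",
    " p(noise)=%.2f\n  docking scores: N(%.2f, %.2f) actives vs N(%.2f, %.2f)",
    " decoys; seed %d\n"),
    object@nStructures, object@nActives, object@nDecoys,
    object@nPlantedHB, object@nPlantedHP, object@pActive, object@pDecoy,
    object@pNoise, object@activeMean, object@scoreSd, object@decoyMean,
    object@scoreSd, object@seed))
})
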