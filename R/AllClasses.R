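#' @import methods
NULL

#' Molecule: a light atom/bond container with optional 3D coordinates
#'
#' Holds one small molecule as parallel atom vectors plus a bond table.
#' Conformers carry coordinates in Angstrom; 2D/topology-only molecules have
#' an all-`NA` coordinate matrix. Bond order 4 denotes an aromatic bond
#' (SDF V2000 convention).
#'
#' @slot id character(1) compound identifier.
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric matrix (n x 3), Angstrom; rows may be all-NA.
#' @slot bonds integer matrix (m x 3): atom index 1, atom index 2, order.
#' @slot charges integer formal charges, one per atom.
#' @slot meta list of record-level metadata (SDF data fields, SMILES, ...).
#' @exportClass Molecule
setClass("Molecule", representation(
  id = "character",
  elements = "character",
  coords = "matrix",
  bonds = "matrix",
  charges = "integer",
  meta = "list"
))

.valid_elements <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U")

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (!all(object@elements %in% .valid_elements))
    msg <- c(msg, paste("unknown element symbol(s):",
                        paste(setdiff(object@elements, .valid_elements),
                              collapse = ", ")))
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n)
    msg <- c(msg, "coords must be a numeric n x 3 matrix")
  else {
    present <- !is.na(object@coords[, 1])
    if (any(present) && !all(is.finite(object@coords[present, ])))
      msg <- c(msg, "present coordinates must be finite")
  }
  if (length(object@charges) != n)
    msg <- c(msg, "charges must have one entry per atom")
  b <- object@bonds
  if (nrow(b) > 0) {
    if (ncol(b) != 3L) msg <- c(msg, "bonds must have 3 columns")
    else if (any(b[, 1:2] < 1L | b[, 1:2] > n))
      msg <- c(msg, "bond atom indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' ReceptorStructure: residue/atom model of a protein binding site
#'
#' Atom-level protein model read from PDB (waters and heteroatoms stripped),
#' with an optional binding-site residue subset used to restrict interaction
#' detection.
#'
#' @slot id character(1), e.g. a PDB code.
#' @slot atoms data.frame with columns chain, resno, resname, atom, elem,
#'   x, y, z (coordinates in Angstrom).
#' @slot bindingSite data.frame with columns chain, resno; zero rows means
#'   the whole structure is the site.
#' @exportClass ReceptorStructure
setClass("ReceptorStructure", representation(
  id = "character",
  atoms = "data.frame",
  bindingSite = "data.frame"
))

setValidity("ReceptorStructure", function(object) {
  need <- c("chain", "resno", "resname", "atom", "elem", "x", "y", "z")
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "atom coordinates must be finite")
    if (nrow(object@bindingSite)) {
      have <- unique(paste(object@atoms$chain, object@atoms$resno))
      want <- paste(object@bindingSite$chain, object@bindingSite$resno)
      if (!all(want %in% have))
        msg <- c(msg, "binding-site residues absent from atom records")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PoseRecord: one docked conformer of one compound in one structure
#'
#' @slot compoundId character(1).
#' @slot structureId character(1) receptor structure the pose was docked into.
#' @slot conformer a [Molecule-class] with mandatory coordinates.
#' @slot dockingScore numeric(1); more negative means a better engine score.
#' @exportClass PoseRecord
setClass("PoseRecord", representation(
  compoundId = "character",
  structureId = "character",
  conformer = "Molecule",
  dockingScore = "numeric"
))

setValidity("PoseRecord", function(object) {
  msg <- character()
  if (!is.finite(object@dockingScore))
    msg <- c(msg, "dockingScore must be finite")
  conf <- object@conformer
  heavy <- conf@elements != "H"
  if (!any(heavy & !is.na(conf@coords[, 1])))
    msg <- c(msg, "conformer needs >= 1 heavy atom with coordinates")
  if (length(msg)) msg else TRUE
})

#' InteractionProfile: the typed residue contacts one pose makes
#'
#' Interactions are deduplicated at the (chain, residue, kind) level: a
#' residue contacted by both alkyl and pi-stacking hydrophobic interactions
#' in the same pose appears once with subtype `"mixed"`.
#'
#' @slot compoundId,structureId character(1).
#' @slot interactions data.frame with columns chain, resno, resname, kind
#'   (`"HB"` or `"HP"`), subtype (HB: `"donor"`/`"acceptor"`/`"both"`, the
#'   ligand's role; HP: `"alkyl"`/`"pi"`/`"mixed"`), distance (Angstrom) and
#'   angle (degrees, `NA` where not applicable).
#' @exportClass InteractionProfile
setClass("InteractionProfile", representation(
  compoundId = "character",
  structureId = "character",
  interactions = "data.frame"
))

setValidity("InteractionProfile", function(object) {
  df <- object@interactions
  msg <- character()
  need <- c("chain", "resno", "resname", "kind", "subtype", "distance", "angle")
  if (!all(need %in% names(df)))
    return(paste("interactions must have columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$kind %in% c("HB", "HP"))) msg <- c(msg, "kind must be HB or HP")
    okhb <- df$kind != "HB" | df$subtype %in% c("donor", "acceptor", "both")
    okhp <- df$kind != "HP" | df$subtype %in% c("alkyl", "pi", "mixed")
    if (!all(okhb & okhp)) msg <- c(msg, "subtype inconsistent with kind")
    if (!all(df$distance > 0)) msg <- c(msg, "distances must be positive")
    ang <- df$angle[!is.na(df$angle)]
    if (length(ang) && !all(ang >= 0 & ang <= 180))
      msg <- c(msg, "angles must lie in [0, 180]")
    key <- .interaction_key(df$chain, df$resno, df$kind)
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (residue, kind) keys")
  }
  if (length(msg)) msg else TRUE
})

#' FrequencyTable: per-structure interaction frequencies over a pose set
#'
#' @slot structureId character(1).
#' @slot nPoses integer(1), the number M of profiles aggregated.
#' @slot entries data.frame with columns chain, resno, resname, kind,
#'   subtype, count, frequency (= count / M).
#' @exportClass FrequencyTable
setClass("FrequencyTable", representation(
  structureId = "character",
  nPoses = "integer",
  entries = "data.frame"
))

setValidity("FrequencyTable", function(object) {
  df <- object@entries
  msg <- character()
  if (object@nPoses < 1L) msg <- c(msg, "nPoses must be >= 1")
  if (nrow(df)) {
    if (!all(df$frequency >= 0 & df$frequency <= 1))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (max(abs(df$frequency - df$count / object@nPoses)) > 1e-12)
      msg <- c(msg, "frequency must equal count / nPoses")
  }
  if (length(msg)) msg else TRUE
})

#' PharmacologicalModel: key interactions of one receptor structure
#'
#' Interactions retained because they were formed by at least the threshold
#' fraction of top-ranked known actives: hydrogen bonds at `hbThreshold`
#' (default 0.50) and hydrophobic contacts at `hpThreshold` (default 0.80).
#'
#' @slot structureId character(1).
#' @slot hbThreshold,hpThreshold numeric(1) in (0, 1]; inclusive bounds.
#' @slot keyInteractions data.frame with columns chain, resno, resname,
#'   kind, subtype, frequency.
#' @slot provenance list: nPoses, compoundIds, thresholds, and any warnings.
#' @exportClass PharmacologicalModel
setClass("PharmacologicalModel", representation(
  structureId = "character",
  hbThreshold = "numeric",
  hpThreshold = "numeric",
  keyInteractions = "data.frame",
  provenance = "list"
))

setValidity("PharmacologicalModel", function(object) {
  msg <- character()
  for (th in c(object@hbThreshold, object@hpThreshold))
    if (!(th > 0 && th <= 1)) msg <- c(msg, "thresholds must lie in (0, 1]")
  df <- object@keyInteractions
  if (nrow(df)) {
    ok <- ifelse(df$kind == "HB", df$frequency >= object@hbThreshold - 1e-12,
                 df$frequency >= object@hpThreshold - 1e-12)
    if (!all(ok)) msg <- c(msg, "key interaction below its class threshold")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusRanking: rank sums of compounds across receptor structures
#'
#' @slot structureIds character vector (length >= 2) of structures combined.
#' @slot ranking data.frame: compound_id, one `rank_<structure>` column per
#'   structure, consensus_score (integer rank sum; lower is better) and
#'   final_rank.
#' @exportClass ConsensusRanking
setClass("ConsensusRanking", representation(
  structureIds = "character",
  ranking = "data.frame"
))

setValidity("ConsensusRanking", function(object) {
  msg <- character()
  if (length(object@structureIds) < 2L)
    msg <- c(msg, "need >= 2 structures")
  df <- object@ranking
  rk <- paste0("rank_", object@structureIds)
  if (!all(c("compound_id", rk, "consensus_score", "final_rank") %in% names(df)))
    msg <- c(msg, "ranking table missing required columns")
  else if (nrow(df)) {
    if (max(abs(df$consensus_score -
                rowSums(as.matrix(df[, rk, drop = FALSE])))) > 0)
      msg <- c(msg, "consensus_score must equal the exact rank sum")
    if (!identical(sort(df$final_rank), seq_len(nrow(df))))
      msg <- c(msg, "final_rank must be a permutation of 1..n")
  }
  if (length(msg)) msg else TRUE
})

#' FilterReport: audit trail of the library-filter cascade
#'
#' @slot stages data.frame: stage, n_input, n_passed, n_removed.
#' @slot removed data.frame: compound_id, stage, reason.
#' @exportClass FilterReport
setClass("FilterReport", representation(
  stages = "data.frame",
  removed = "data.frame"
))

setValidity("FilterReport", function(object) {
  df <- object@stages
  msg <- character()
  if (nrow(df)) {
    if (any(df$n_input != df$n_passed + df$n_removed))
      msg <- c(msg, "n_input must equal n_passed + n_removed")
    if (nrow(df) > 1 && any(df$n_input[-1] != df$n_passed[-nrow(df)]))
      msg <- c(msg, "stage inputs must chain from previous stage outputs")
  }
  if (length(msg)) msg else TRUE
})

#' FingerprintSet: fixed-length circular fingerprints for a compound set
#'
#' @slot ids character vector of compound ids.
#' @slot bits logical matrix (compounds x nBits).
#' @slot radius,nBits integer fingerprint parameters (radius 2, 2048 bits
#'   by default, i.e. ECFP4 folded to 2048).
#' @exportClass FingerprintSet
setClass("FingerprintSet", representation(
  ids = "character",
  bits = "matrix",
  radius = "integer",
  nBits = "integer"
))

setValidity("FingerprintSet", function(object) {
  msg <- character()
  if (nrow(object@bits) != length(object@ids))
    msg <- c(msg, "one bit row per id required")
  if (ncol(object@bits) != object@nBits)
    msg <- c(msg, "bit matrix width must equal nBits")
  if (!is.logical(object@bits)) msg <- c(msg, "bits must be logical")
  if (length(msg)) msg else TRUE
})

#' BenchmarkSpec: parameters of the synthetic planted-signal benchmark
#'
#' Defines a fully synthetic actives-vs-decoys benchmark: geometric binding
#' pockets, ligand poses that realize a planted set of key interactions with
#' class probabilities, and Gaussian mock docking scores whose active/decoy
#' mean shift controls the docking-only enrichment.
#'
#' @slot nStructures,nActives,nDecoys integer benchmark sizes.
#' @slot nResidues integer residues per synthetic pocket.
#' @slot nPlantedHB,nPlantedHP integer planted key interactions per structure.
#' @slot pActive,pDecoy,pNoise numeric in \[0, 1\]: probability that an
#'   active (decoy) realizes each planted interaction, and that any compound
#'   forms a contact with a non-planted residue.
#' @slot activeMean,decoyMean,scoreSd numeric Gaussian docking-score model.
#' @slot seed integer master seed recorded in all outputs.
#' @exportClass BenchmarkSpec
setClass("BenchmarkSpec", representation(
  nStructures = "integer", nActives = "integer", nDecoys = "integer",
  nResidues = "integer", nPlantedHB = "integer", nPlantedHP = "integer",
  pActive = "numeric", pDecoy = "numeric", pNoise = "numeric",
  activeMean = "numeric", decoyMean = "numeric", scoreSd = "numeric",
  seed = "integer"
))

setValidity("BenchmarkSpec", function(object) {
  msg <- character()
  for (p in c(object@pActive, object@pDecoy, object@pNoise))
    if (!(p >= 0 && p <= 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@nActives < 1L || object@nDecoys < 1L)
    msg <- c(msg, "need >= 1 active and >= 1 decoy")
  if (object@nStructures < 1L) msg <- c(msg, "need >= 1 structure")
  if (object@nResidues < 3L) msg <- c(msg, "need >= 3 pocket residues")
  if (object@scoreSd < 0) msg <- c(msg, "scoreSd must be non-negative")
  if (length(msg)) msg else TRUE
})
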