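#' @include AllClasses.R scoring.R
NULL

.heavy_graph <- function(mol) {
  heavy <- which(mol@elements != "H")
  .assert(length(heavy) > 0, "molecule has no heavy atoms")
  idx <- match(seq_along(mol@elements), heavy)
  b <- mol@bonds
  keep <- b[, 1] %in% heavy & b[, 2] %in% heavy
  b <- b[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(b))
    g <- igraph::add_edges(g, rbind(idx[b[, 1]], idx[b[, 2]]))
  list(graph = g, elem = mol@elements[heavy],
       order = if (nrow(b)) b[, 3] else integer(),
       coords = mol@coords[heavy, , drop = FALSE])
}

#' In-place RMSD between two poses of the same molecule
#'
#' Root-mean-square deviation over heavy atoms, computed without
#' re-superposition (redocked and reference poses share the receptor
#' frame). With `symmetryAware = TRUE` (default) the minimum over all
#' element- and bond-order-preserving graph isomorphisms is returned, so
#' that e.g. a benzene ring rotated by 60 degrees has RMSD 0.
#'
#' @param reference,redocked [Molecule-class] objects with identical
#'   heavy-atom graphs and coordinates.
#' @param symmetryAware minimize over graph automorphisms (default TRUE).
#' @return RMSD in Angstrom.
#' @examples
#' m <- Molecule("m", c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
#'               bonds = cbind(1, 2, 1))
#' poseRMSD(m, m)  # 0
#' @export
poseRMSD <- function(reference, redocked, symmetryAware = TRUE) {
  ga <- .heavy_graph(reference)
  gb <- .heavy_graph(redocked)
  .assert(all(!is.na(ga$coords)) && all(!is.na(gb$coords)),
          "both poses need full heavy-atom coordinates")
  .assert(length(ga$elem) == length(gb$elem),
          "heavy-atom counts differ: ", length(ga$elem), " vs ",
          length(gb$elem))
  elem_levels <- sort(unique(c(ga$elem, gb$elem)))
  ca <- as.integer(factor(ga$elem, levels = elem_levels))
  cb <- as.integer(factor(gb$elem, levels = elem_levels))
  rmsd_for <- function(perm) {
    d <- ga$coords - gb$coords[perm, , drop = FALSE]
    sqrt(mean(rowSums(d * d)))
  }
  if (!symmetryAware) {
    .assert(identical(ga$elem, gb$elem),
            "atom ordering differs; use symmetryAware = TRUE")
    return(rmsd_for(seq_along(ga$elem)))
  }
  maps <- igraph::graph.get.isomorphisms.vf2(
    ga$graph, gb$graph, vertex.color1 = ca, vertex.color2 = cb,
    edge.color1 = as.integer(ga$order), edge.color2 = as.integer(gb$order))
  .assert(length(maps) > 0, "heavy-atom graphs do not match")
  min(vapply(maps, function(m) rmsd_for(as.integer(m)), numeric(1)))
}

#' ROC-AUC with the midrank (Mann-Whitney) tie convention
#'
#' `AUC = P(score_active > score_decoy) + 0.5 * P(tie)` over all
#' active-decoy pairs; higher scores predict the active class.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) actives indicator, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAUC(c(3, 2, 1), c(TRUE, FALSE, FALSE))  # 1
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  .assert(length(scores) == length(labels), "length mismatch")
  .assert(all(is.finite(scores)), "scores must be finite")
  na <- sum(labels); nd <- sum(!labels)
  .assert(na >= 1 && nd >= 1, "need at least one active and one decoy")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - na * (na + 1) / 2) / (na * nd)
}

#' ROC curve points
#'
#' @inheritParams rocAUC
#' @return data.frame of (fpr, tpr) sorted by decreasing score threshold,
#'   starting at (0, 0) and ending at (1, 1).
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  na <- sum(labels); nd <- sum(!labels)
  .assert(na >= 1 && nd >= 1, "need at least one active and one decoy")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, cumsum(!l)[keep] / nd),
             tpr = c(0, cumsum(l)[keep] / na))
}

#' Evaluate enrichment of several rankers over one active/decoy set
#'
#' Each ranker is a named numeric score vector over the same compounds
#' (higher = predicted active); for consensus rankers pass the negated
#' consensus rank sum, since a lower sum is better.
#'
#' @param rankerScores named list of named numeric vectors.
#' @param activeIds character vector of active compound ids; all other
#'   compounds in a ranker's vector count as decoys.
#' @return data.frame with columns model, n_actives, n_decoys, auc.
#' @export
evaluateRankers <- function(rankerScores, activeIds) {
  .assert(length(rankerScores) >= 1 && !is.null(names(rankerScores)),
          "rankerScores must be a non-empty named list")
  rows <- lapply(names(rankerScores), function(nm) {
    sc <- rankerScores[[nm]]
    .assert(!is.null(names(sc)), "ranker ", nm, " must be a named vector")
    lab <- names(sc) %in% activeIds
    data.frame(model = nm, n_actives = sum(lab), n_decoys = sum(!lab),
               auc = rocAUC(sc, lab), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build ranker score sets from per-structure scored tables
#'
#' Produces the standard comparison set: per-structure docking-only rankers
#' (`-D`, so that higher = better), per-structure pharmacological rankers
#' (`S`) and, for each requested structure subset, a consensus ranker
#' (negated rank sum of the pharmacological rankings).
#'
#' @param scored named list of per-structure scored tables from
#'   [scoreCompoundSet()].
#' @param consensusSubsets list of character vectors of structure ids
#'   (each of length >= 2) to combine; defaults to the single subset of
#'   all structures when >= 2 are present.
#' @return named list of named score vectors for [evaluateRankers()].
#' @export
rankerScoreSets <- function(scored, consensusSubsets = NULL) {
  sids <- names(scored)
  out <- list()
  for (s in sids) {
    tab <- scored[[s]]
    out[[paste0("docking_", s)]] <-
      stats::setNames(-tab$D, tab$compound_id)
    out[[paste0("pharm_", s)]] <- stats::setNames(tab$S, tab$compound_id)
  }
  if (is.null(consensusSubsets))
    consensusSubsets <- if (length(sids) >= 2) list(sids) else list()
  for (subset in consensusSubsets) {
    .assert(all(subset %in% sids), "unknown structure id in subset")
    cr <- consensusRank(lapply(stats::setNames(subset, subset),
                               function(s) scored[[s]]))
    tab <- ranking(cr)
    out[[paste0("consensus_", paste(subset, collapse = "+"))]] <-
      stats::setNames(-tab$consensus_score, tab$compound_id)
  }
  out
}

#' Redocking validation against crystal poses
#'
#' A redocked pose validates the docking protocol for its structure when
#' its heavy-atom RMSD to the crystal pose is below the threshold
#' (strictly; the conventional cutoff is 2.5 Angstrom).
#'
#' @param referencePoses,redockedPoses named lists of [Molecule-class]
#'   conformers (names = structure ids), matched by name.
#' @param threshold RMSD pass cutoff in Angstrom (default 2.5; strict `<`).
#' @param symmetryAware see [poseRMSD()].
#' @return data.frame with columns structure_id, rmsd, pass.
#' @export
redockValidate <- function(referencePoses, redockedPoses, threshold = 2.5,
                           symmetryAware = TRUE) {
  sids <- names(referencePoses)
  .assert(!is.null(sids) && setequal(sids, names(redockedPoses)),
          "reference and redocked pose sets must share structure ids")
  rows <- lapply(sids, function(s) {
    r <- poseRMSD(referencePoses[[s]], redockedPoses[[s]], symmetryAware)
    data.frame(structure_id = s, rmsd = r, pass = r < threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
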