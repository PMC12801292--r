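#' @include AllClasses.R pharm-model.R
NULL

#' Pharmacological score S = N - 0.01 * D
#'
#' Combines the number of pharmacological interactions a compound forms,
#' N, with its docking score D (more negative = better) as
#' `S = N + (-0.01) * D`. The small docking-score weight makes N dominate
#' while D breaks ties between compounds with equal interaction counts.
#'
#' @param N non-negative integer interaction match count (vectorized).
#' @param D finite docking score (vectorized).
#' @return numeric S, exactly `N - 0.01 * D`.
#' @examples
#' pharmacologicalScore(4, -10)   # 4.1
#' @export
pharmacologicalScore <- function(N, D) {
  .assert(all(N >= 0), "N must be non-negative")
  .assert(all(is.finite(D)), "D must be finite")
  N + (-0.01) * D
}

#' Rank compounds of one structure by pharmacological score
#'
#' Rank 1 is the highest S. Ties break deterministically: first by more
#' negative docking score, then by compound id ascending. Ranks are a
#' gap-free permutation of 1..K.
#'
#' @param scored data.frame with columns compound_id, structure_id, D, N
#'   (S is recomputed to enforce exactness).
#' @return the input with columns S and rank added, ordered by rank.
#' @export
rankByScore <- function(scored) {
  need <- c("compound_id", "structure_id", "D", "N")
  .assert(all(need %in% names(scored)),
          "scored table needs columns: ", paste(need, collapse = ", "))
  .assert(length(unique(scored$structure_id)) <= 1,
          "rows span multiple structures")
  dup <- duplicated(scored$compound_id)
  .assert(!any(dup), "duplicate compound_id: ",
          paste(unique(scored$compound_id[dup]), collapse = ", "))
  scored$S <- pharmacologicalScore(scored$N, scored$D)
  o <- order(-scored$S, scored$D, scored$compound_id, method = "radix")
  scored <- scored[o, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored
}

#' Consensus ranking across two or more structures
#'
#' For each compound the per-structure ranks are summed into an integer
#' consensus score; compounds are then reranked ascending by that score
#' (ties by compound id). A compound absent from a structure's ranking
#' (e.g. a docking failure) receives rank K+1 there, where K is that
#' ranking's size, so the consensus stays defined over the union of
#' compounds while penalizing the failure.
#'
#' @param rankings named list (names = structure ids) of data.frames with
#'   columns compound_id and rank, as returned by [rankByScore()].
#' @return a [ConsensusRanking-class].
#' @export
consensusRank <- function(rankings) {
  .assert(length(rankings) >= 2, "need >= 2 rankings")
  sids <- names(rankings) %||% paste0("structure_", seq_along(rankings))
  if (is.null(names(rankings))) names(rankings) <- sids
  .assert(!anyDuplicated(sids), "duplicate structure ids")
  for (r in rankings)
    .assert(all(c("compound_id", "rank") %in% names(r)),
            "each ranking needs compound_id and rank columns")
  compounds <- sort(unique(unlist(lapply(rankings,
                                         function(r) r$compound_id))))
  rank_cols <- lapply(sids, function(s) {
    r <- rankings[[s]]
    k <- nrow(r)
    out <- r$rank[match(compounds, r$compound_id)]
    out[is.na(out)] <- k + 1L
    as.integer(out)
  })
  tab <- data.frame(compound_id = compounds, stringsAsFactors = FALSE)
  for (i in seq_along(sids)) tab[[paste0("rank_", sids[i])]] <- rank_cols[[i]]
  tab$consensus_score <- as.integer(Reduce(`+`, rank_cols))
  o <- order(tab$consensus_score, tab$compound_id, method = "radix")
  tab <- tab[o, , drop = FALSE]
  tab$final_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  # column order is canonical by sorted structure id: consensus is
  # permutation-invariant in the order structures are supplied
  sids_sorted <- sort(sids)
  tab <- tab[, c("compound_id", paste0("rank_", sids_sorted),
                 "consensus_score", "final_rank")]
  new("ConsensusRanking", structureIds = sids_sorted, ranking = tab)
}

#' Score and rank a compound set against per-structure models
#'
#' Composition of the per-structure steps: profile each pose, count model
#' matches N, compute S = N - 0.01 * D and rank. Compounds with a pose on
#' some structures only are still ranked where they have one; the
#' consensus (if requested downstream) penalizes the missing structures.
#'
#' @param poses list of [PoseRecord-class] covering one or more structures.
#' @param models named list of [PharmacologicalModel-class] (names =
#'   structure ids); every pose's structure needs a model.
#' @param receptors named list of [ReceptorStructure-class] used for
#'   profiling.
#' @param criteria detection criteria, see [interactionCriteria()].
#' @return named list of per-structure scored data.frames (columns
#'   compound_id, structure_id, D, N, S, rank).
#' @export
scoreCompoundSet <- function(poses, models, receptors,
                             criteria = interactionCriteria()) {
  sids <- vapply(poses, structureId, character(1))
  .assert(all(sids %in% names(models)),
          "no model for structure(s): ",
          paste(setdiff(unique(sids), names(models)), collapse = ", "))
  .assert(all(sids %in% names(receptors)),
          "no receptor for structure(s): ",
          paste(setdiff(unique(sids), names(receptors)), collapse = ", "))
  out <- list()
  for (s in sort(unique(sids))) {
    sub <- poses[sids == s]
    # best pose per compound
    cid <- vapply(sub, compoundId, character(1))
    d <- vapply(sub, dockingScore, numeric(1))
    o <- order(cid, d, method = "radix")
    first <- o[!duplicated(cid[o])]
    sub <- sub[first]
    ctx <- .receptor_context(receptors[[s]])
    model_keys <- unique(interactionKeys(models[[s]]))
    ns <- vapply(sub, function(p) {
      prof <- profilePose(receptors[[s]], p, criteria, context = ctx)
      length(intersect(unique(interactionKeys(prof)), model_keys))
    }, integer(1))
    out[[s]] <- rankByScore(data.frame(
      compound_id = vapply(sub, compoundId, character(1)),
      structure_id = s, D = vapply(sub, dockingScore, numeric(1)),
      N = ns, stringsAsFactors = FALSE))
  }
  out
}
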