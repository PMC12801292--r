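#' @include AllClasses.R filters.R scoring.R similarity.R fixtures.R
NULL

#' Configuration for the end-to-end screening pipeline
#'
#' Docking itself is an external adapter contract: the pipeline consumes
#' already-docked poses (a list of [PoseRecord-class], e.g. loaded with
#' [loadPoseSet()] from an engine's output, or planted by the synthetic
#' benchmark generator) and never runs a docking engine.
#'
#' @param library named character vector of SMILES (names = compound ids).
#' @param receptors named list of [ReceptorStructure-class].
#' @param models named list of [PharmacologicalModel-class], one per
#'   receptor structure.
#' @param poses list of [PoseRecord-class] for the library compounds.
#' @param topKDocking compounds carried past the docking-score cut
#'   (default 5000; each compound is ranked by its best score across
#'   structures).
#' @param topKConsensus compounds carried past the consensus rerank
#'   (default 500).
#' @param clusterThreshold Tanimoto threshold for leader clustering.
#' @param kRepresentatives cap on cluster representatives (default: one
#'   per cluster).
#' @param criteria interaction-detection criteria.
#' @param filter a [filterConfig()].
#' @param fingerprintRadius,fingerprintBits ECFP parameters.
#' @param seed integer seed recorded in the run report.
#' @param outDir optional directory for stage artifacts (CSV/JSON); when
#'   `NULL` nothing is written.
#' @return named list of class `screen_config`.
#' @export
screenConfig <- function(library, receptors, models, poses,
                         topKDocking = 5000, topKConsensus = 500,
                         clusterThreshold = 0.6, kRepresentatives = NULL,
                         criteria = interactionCriteria(),
                         filter = filterConfig(),
                         fingerprintRadius = 2, fingerprintBits = 2048,
                         seed = 1, outDir = NULL) {
  .assert(topKDocking >= 1 && topKConsensus >= 1, "top-K values must be >= 1")
  .assert(!is.null(names(library)), "library must be a named SMILES vector")
  .assert(setequal(names(receptors), names(models)),
          "receptors and models must cover the same structures")
  structure(list(library = library, receptors = receptors, models = models,
                 poses = poses, topKDocking = topKDocking,
                 topKConsensus = topKConsensus,
                 clusterThreshold = clusterThreshold,
                 kRepresentatives = kRepresentatives, criteria = criteria,
                 filter = filter, fingerprintRadius = fingerprintRadius,
                 fingerprintBits = fingerprintBits, seed = seed,
                 outDir = outDir), class = "screen_config")
}

.write_stage <- function(outDir, name, df) {
  if (is.null(outDir)) return(invisible(NULL))
  utils::write.csv(df, file.path(outDir, paste0(name, ".csv")),
                   row.names = FALSE, quote = FALSE)
}

#' Run the end-to-end virtual screen
#'
#' Stages: drug-likeness filter cascade on the library; docking-score
#' cut to the top `topKDocking` compounds (best score across structures);
#' per-structure pharmacological scoring (S = N - 0.01 D) and ranking;
#' consensus rerank by rank sum; cut to the top `topKConsensus`; leader
#' clustering of the survivors' ECFP fingerprints; representative
#' selection (best consensus rank per cluster). Each stage's compound
#' count is recorded in the run report; compound counts shrink (or stay)
#' monotonically after the filter stage. All artifacts are plain CSV/JSON
#' and the run is deterministic for a fixed config and seed.
#'
#' @param config a [screenConfig()].
#' @return list: `filter` (report), `topDocking` (data.frame), `scored`
#'   (per-structure tables), `consensus` ([ConsensusRanking-class]),
#'   `topConsensus` (data.frame), `clusters`, `representatives`,
#'   `report` (stage counts and provenance).
#' @export
runScreen <- function(config) {
  .assert(inherits(config, "screen_config"), "config must be a screenConfig")
  outDir <- config$outDir
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # stage 1: library filter cascade
  lib_sdf <- smilesToSDFset(config$library)
  chain <- applyFilterChain(lib_sdf, config$filter)
  survivors <- ChemmineR::cid(chain$survivors)
  counts$library <- length(config$library)
  counts$filter_survivors <- length(survivors)
  if (!is.null(outDir)) {
    writeLines(paste(config$library[survivors], survivors),
               file.path(outDir, "survivors.smi"))
    jsonlite::write_json(
      list(stages = filterStages(chain$report),
           removed = removedCompounds(chain$report)),
      file.path(outDir, "filter_report.json"), auto_unbox = TRUE,
      digits = NA)
  }

  # stage 2: docking-score cut (best score across structures)
  poses <- config$poses[vapply(config$poses, compoundId,
                               character(1)) %in% survivors]
  .assert(length(poses) > 0, paste(
    "no docked poses for any filter survivor; supply poses from your",
    "docking adapter (a score manifest loadable with loadPoseSet())"))
  pcid <- vapply(poses, compoundId, character(1))
  pd <- vapply(poses, dockingScore, numeric(1))
  best <- tapply(pd, pcid, min)
  k <- min(config$topKDocking, length(best))
  if (config$topKDocking > length(best))
    warning("topKDocking (", config$topKDocking, ") exceeds the ",
            length(best), " docked compounds; keeping all")
  top_dock <- data.frame(compound_id = names(best), best_score = as.numeric(best),
                         stringsAsFactors = FALSE)
  top_dock <- top_dock[order(top_dock$best_score, top_dock$compound_id,
                             method = "radix"), , drop = FALSE][seq_len(k), ]
  rownames(top_dock) <- NULL
  counts$top_docking <- nrow(top_dock)
  .write_stage(outDir, "top_docking", top_dock)

  # stage 3: pharmacological scoring + consensus rerank
  poses <- poses[pcid %in% top_dock$compound_id]
  scored <- scoreCompoundSet(poses, config$models, config$receptors,
                             config$criteria)
  for (s in names(scored)) .write_stage(outDir, paste0("scored_", s),
                                        scored[[s]])
  consensus <- consensusRank(lapply(scored, function(t)
    t[, c("compound_id", "rank")]))
  ctab <- ranking(consensus)
  .write_stage(outDir, "consensus", ctab)
  counts$consensus <- nrow(ctab)

  # stage 4: consensus cut + clustering + representatives
  k2 <- min(config$topKConsensus, nrow(ctab))
  topc <- ctab[seq_len(k2), , drop = FALSE]
  counts$top_consensus <- nrow(topc)
  .write_stage(outDir, "top_consensus", topc)
  fps <- ecfpFingerprints(config$library[topc$compound_id],
                          radius = config$fingerprintRadius,
                          nBits = config$fingerprintBits)
  cl <- clusterSelect(fps,
                      ranks = stats::setNames(topc$final_rank,
                                              topc$compound_id),
                      simThreshold = config$clusterThreshold,
                      kRepresentatives = config$kRepresentatives)
  counts$clusters <- max(cl$assignments$cluster)
  counts$representatives <- length(cl$representatives)
  reps <- data.frame(compound_id = cl$representatives,
                     cluster = cl$assignments$cluster[
                       match(cl$representatives,
                             cl$assignments$compound_id)],
                     final_rank = topc$final_rank[
                       match(cl$representatives, topc$compound_id)],
                     smiles = unname(config$library[cl$representatives]),
                     stringsAsFactors = FALSE)
  .write_stage(outDir, "clusters", cl$assignments)
  .write_stage(outDir, "representatives", reps)

  report <- list(seed = config$seed,
                 structures = sort(names(config$receptors)),
                 topKDocking = config$topKDocking,
                 topKConsensus = config$topKConsensus,
                 clusterThreshold = config$clusterThreshold,
                 counts = counts)
  if (!is.null(outDir))
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  list(filter = chain$report, topDocking = top_dock, scored = scored,
       consensus = consensus, topConsensus = topc,
       clusters = cl$assignments, representatives = reps, report = report)
}
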