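#' @include AllClasses.R interactions.R
NULL

#' Select the best-scored pose per compound, then the top n compounds
#'
#' Used to pick the top-ranked known actives whose interaction patterns
#' define the pharmacological model (the default protocol uses the top 30).
#' If a compound has several poses on the structure only its best-scored
#' pose is considered. Selection keeps the n most negative docking scores;
#' ties break by compound id ascending. If fewer than n compounds are
#' available, all are returned with a warning (recorded by callers in the
#' model provenance).
#'
#' @param poses list of [PoseRecord-class] for one structure.
#' @param n number of compounds to keep.
#' @return list of [PoseRecord-class], best first.
#' @export
selectTopPoses <- function(poses, n = 30) {
  .assert(n >= 1, "n must be >= 1")
  .assert(length(poses) > 0, "no poses supplied")
  sid <- unique(vapply(poses, structureId, character(1)))
  .assert(length(sid) == 1,
          "poses span multiple structures: ", paste(sid, collapse = ", "))
  cid <- vapply(poses, compoundId, character(1))
  d <- vapply(poses, dockingScore, numeric(1))
  # best pose per compound
  o <- order(cid, d, method = "radix")
  first <- o[!duplicated(cid[o])]
  cid <- cid[first]; d <- d[first]; poses <- poses[first]
  if (length(poses) < n)
    warning("only ", length(poses), " compounds available; n = ", n,
            " requested")
  sel <- order(d, cid, method = "radix")[seq_len(min(n, length(poses)))]
  poses[sel]
}

#' Interaction frequencies over a set of profiles
#'
#' For each interaction key, the fraction of the M profiles containing it.
#' By default keys are residue-level within each interaction class
#' (hydrogen bond / hydrophobic), matching frequency profiles that report
#' one subtype letter per residue; the reported subtype is the most common
#' one across profiles (`"mixed"` stays mixed). With `subtypeKeys = TRUE`
#' hydrophobic subtypes are counted as separate keys.
#'
#' @param profiles list of [InteractionProfile-class], all from the same
#'   structure.
#' @param subtypeKeys count hydrophobic subtypes separately (default FALSE).
#' @return a [FrequencyTable-class].
#' @export
interactionFrequencies <- function(profiles, subtypeKeys = FALSE) {
  .assert(length(profiles) >= 1, "need >= 1 profile")
  sid <- unique(vapply(profiles, structureId, character(1)))
  .assert(length(sid) == 1,
          "profiles span multiple structures: ", paste(sid, collapse = ", "))
  m <- length(profiles)
  all_rows <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    df <- profiles[[i]]@interactions
    if (!nrow(df)) return(NULL)
    df$.profile <- i
    df
  }))
  if (is.null(all_rows)) {
    entries <- data.frame(chain = character(), resno = integer(),
                          resname = character(), kind = character(),
                          subtype = character(), count = integer(),
                          frequency = numeric(), stringsAsFactors = FALSE)
    return(new("FrequencyTable", structureId = sid, nPoses = as.integer(m),
               entries = entries))
  }
  key <- if (subtypeKeys)
    .interaction_key_sub(all_rows$chain, all_rows$resno, all_rows$kind,
                         all_rows$subtype)
  else .interaction_key(all_rows$chain, all_rows$resno, all_rows$kind)
  entries <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- all_rows[key == k, , drop = FALSE]
    cnt <- length(unique(sub$.profile))
    st <- sort(table(sub$subtype), decreasing = TRUE)
    data.frame(chain = sub$chain[1], resno = sub$resno[1],
               resname = sub$resname[1], kind = sub$kind[1],
               subtype = names(st)[1], count = cnt, frequency = cnt / m,
               stringsAsFactors = FALSE)
  }))
  entries <- entries[order(entries$chain, entries$resno, entries$kind,
                           entries$subtype, method = "radix"), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  new("FrequencyTable", structureId = sid, nPoses = as.integer(m),
      entries = entries)
}

#' Identify pharmacological (key) interactions by frequency thresholds
#'
#' Hydrogen-bond keys are kept when their frequency is at least
#' `hbThreshold` and hydrophobic keys when at least `hpThreshold` — both
#' bounds inclusive ("at least"), so a frequency of exactly 0.50 (HB) or
#' 0.80 (HP) qualifies.
#'
#' @param freq a [FrequencyTable-class].
#' @param hbThreshold hydrogen-bond frequency threshold in (0, 1\];
#'   default 0.50.
#' @param hpThreshold hydrophobic frequency threshold in (0, 1\];
#'   default 0.80.
#' @param provenance optional list merged into the model provenance
#'   (e.g. source compound ids).
#' @return a [PharmacologicalModel-class].
#' @export
identifyPharmacological <- function(freq, hbThreshold = 0.50,
                                    hpThreshold = 0.80,
                                    provenance = list()) {
  .assert(hbThreshold > 0 && hbThreshold <= 1 &&
            hpThreshold > 0 && hpThreshold <= 1,
          "thresholds must lie in (0, 1]")
  df <- freq@entries
  keep <- if (nrow(df))
    ifelse(df$kind == "HB", df$frequency >= hbThreshold,
           df$frequency >= hpThreshold)
  else logical(0)
  key <- df[keep, c("chain", "resno", "resname", "kind", "subtype",
                    "frequency"), drop = FALSE]
  rownames(key) <- NULL
  new("PharmacologicalModel", structureId = freq@structureId,
      hbThreshold = hbThreshold, hpThreshold = hpThreshold,
      keyInteractions = key,
      provenance = c(list(nPoses = freq@nPoses,
                          hbThreshold = hbThreshold,
                          hpThreshold = hpThreshold), provenance))
}

#' Build a pharmacological model from active poses in one call
#'
#' Convenience composition: best pose per compound, top-n selection by
#' docking score, interaction profiling, frequency aggregation and
#' thresholding.
#'
#' @param receptor a [ReceptorStructure-class].
#' @param activePoses list of [PoseRecord-class] of known actives docked
#'   into `receptor`.
#' @param nTop number of top-scored actives used (default 30).
#' @param criteria detection criteria, see [interactionCriteria()].
#' @inheritParams identifyPharmacological
#' @return a [PharmacologicalModel-class].
#' @export
buildPharmacologicalModel <- function(receptor, activePoses, nTop = 30,
                                      hbThreshold = 0.50, hpThreshold = 0.80,
                                      criteria = interactionCriteria()) {
  top <- selectTopPoses(activePoses, nTop)
  ctx <- .receptor_context(receptor)
  profiles <- lapply(top, function(p)
    profilePose(receptor, p, criteria, context = ctx))
  freq <- interactionFrequencies(profiles)
  identifyPharmacological(
    freq, hbThreshold, hpThreshold,
    provenance = list(compoundIds = vapply(top, compoundId, character(1)),
                      nTopRequested = nTop))
}

#' Count the pharmacological interactions a profile matches
#'
#' N(i): the number of the model's key interactions present in the
#' compound's interaction profile, each key counted at most once.
#'
#' @param profile an [InteractionProfile-class].
#' @param model a [PharmacologicalModel-class] for the same structure.
#' @return integer count in `0..nrow(keyInteractions(model))`.
#' @export
countMatches <- function(profile, model) {
  .assert(structureId(profile) == structureId(model),
          "profile structure ", structureId(profile),
          " does not match model structure ", structureId(model))
  length(intersect(unique(interactionKeys(profile)),
                   unique(interactionKeys(model))))
}

#' Serialize a pharmacological model to JSON
#'
#' @param model a [PharmacologicalModel-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writePharmacologicalModel <- function(model, path) {
  ki <- model@keyInteractions
  obj <- list(
    structure_id = model@structureId,
    thresholds = list(hb = model@hbThreshold, hp = model@hpThreshold),
    key_interactions = data.frame(
      chain = ki$chain, resnum = ki$resno, resname = ki$resname,
      kind = ki$kind, subtype = ki$subtype, frequency = ki$frequency,
      stringsAsFactors = FALSE),
    provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pharmacological model from JSON
#'
#' @param path JSON file written by [writePharmacologicalModel()].
#' @return a [PharmacologicalModel-class].
#' @export
readPharmacologicalModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ki <- obj$key_interactions
  ki <- if (is.null(ki) || !length(ki))
    data.frame(chain = character(), resno = integer(), resname = character(),
               kind = character(), subtype = character(),
               frequency = numeric(), stringsAsFactors = FALSE)
  else data.frame(chain = ki$chain, resno = as.integer(ki$resnum),
                  resname = ki$resname, kind = ki$kind, subtype = ki$subtype,
                  frequency = ki$frequency, stringsAsFactors = FALSE)
  new("PharmacologicalModel", structureId = obj$structure_id,
      hbThreshold = obj$thresholds$hb, hpThreshold = obj$thresholds$hp,
      keyInteractions = ki, provenance = as.list(obj$provenance))
}
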