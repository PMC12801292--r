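#' @include AllClasses.R chem-io.R qed-data.R
NULL

# Organic element whitelist for the HTS structural filter.
.organic_elements <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# Reactive-substructure catalogue for the HTS filter (SMARTS).
.reactive_catalog <- c(
  acyl_halide        = "[CX3](=[OX1])[F,Cl,Br,I]",
  aldehyde           = "[CX3H1](=O)[#6]",
  michael_acceptor   = "[CX3]=[CX3][CX3]=[OX1]",
  epoxide            = "[C;r3][O;r3][C;r3]",
  aziridine          = "[C;r3][NX3;r3][C;r3]",
  isocyanate         = "[NX2]=[CX2]=[OX1]",
  isothiocyanate     = "[NX2]=[CX2]=[SX1]",
  acid_anhydride     = "[CX3](=[OX1])[OX2][CX3](=[OX1])",
  azide              = "[NX2]~[NX2]~[NX1]",
  diazo              = "[CX3]=[NX2+]=[NX1-]",
  peroxide           = "[OX2][OX2]",
  acyl_cyanide       = "[CX3](=[OX1])C#N",
  sulfonyl_halide    = "[SX4](=[OX1])(=[OX1])[F,Cl,Br,I]")

.obmols <- function(sdfset, addHydrogens = FALSE) {
  om <- ChemmineR::obmol(sdfset)
  if (addHydrogens) {
    # explicit hydrogens are needed by the published PAINS patterns;
    # pinned SWIG binding of OpenBabel's OBMol::AddHydrogens()
    addH <- get("OBMol_AddHydrogens__SWIG_3", envir = asNamespace("ChemmineOB"))
    for (m in om) addH(m)
  }
  om
}

# Count matrix (molecules x patterns) of unique SMARTS matches.
.smarts_counts <- function(obmols, patterns) {
  out <- matrix(0L, length(obmols), length(patterns),
                dimnames = list(NULL, names(patterns)))
  for (j in seq_along(patterns))
    out[, j] <- ChemmineOB::smartsSearch_OB(obmols, patterns[[j]],
                                            uniqueMatches = TRUE)
  out
}

.element_counts <- function(sdfset) {
  abl <- ChemmineR::atomblock(sdfset)
  lapply(abl, function(ab) table(sub("_\\d+$", "", rownames(ab))))
}

# Rotatable bonds: acyclic single bonds between two non-terminal heavy
# atoms, excluding amide C-N bonds.
.rotatable_bonds <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0) return(0L)
  elem <- sub("_\\d+$", "", rownames(ab))
  n <- length(elem)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(bb[, 1], bb[, 2]))
  bridge <- seq_len(nrow(bb)) %in% igraph::bridges(g)
  deg <- igraph::degree(g)
  dbl_o <- rep(FALSE, n)  # carbon with a double-bonded oxygen
  dbl <- bb[, 3] == 2
  for (k in which(dbl)) {
    a <- bb[k, 1]; b <- bb[k, 2]
    if (elem[a] == "C" && elem[b] == "O") dbl_o[a] <- TRUE
    if (elem[b] == "C" && elem[a] == "O") dbl_o[b] <- TRUE
  }
  rot <- 0L
  for (k in seq_len(nrow(bb))) {
    if (bb[k, 3] != 1 || !bridge[k]) next
    a <- bb[k, 1]; b <- bb[k, 2]
    if (deg[a] < 2 || deg[b] < 2) next
    amide <- (dbl_o[a] && elem[b] == "N") || (dbl_o[b] && elem[a] == "N")
    if (!amide) rot <- rot + 1L
  }
  rot
}

# QED structural-alert hits. Dot-separated alert patterns (multiple
# occurrences of one substructure, e.g. ">= 3 ester groups") are evaluated
# per component: the alert fires when each component's unique-match count
# reaches its multiplicity.
.qed_alert_hits <- function(obmols) {
  alerts <- .qed_alert_smarts
  dotted <- grepl(".", alerts, fixed = TRUE)
  hits <- matrix(FALSE, length(obmols), length(alerts))
  if (any(!dotted))
    hits[, !dotted] <- .smarts_counts(
      obmols, stats::setNames(alerts[!dotted],
                              seq_len(sum(!dotted)))) > 0
  for (j in which(dotted)) {
    comp <- table(strsplit(alerts[j], ".", fixed = TRUE)[[1]])
    cnt <- .smarts_counts(obmols, stats::setNames(names(comp),
                                                  seq_along(comp)))
    hits[, j] <- apply(cnt >= matrix(as.integer(comp), nrow(cnt),
                                     length(comp), byrow = TRUE), 1, all)
  }
  as.integer(rowSums(hits))
}

# Aromatic ring count for QED, via unique aromatic-ring SMARTS matches.
.aromatic_ring_count <- function(obmols) {
  counts <- .smarts_counts(obmols, c(r5 = "a1aaaa1", r6 = "a1aaaaa1",
                                     r7 = "a1aaaaaa1"))
  as.integer(rowSums(counts))
}

#' Physicochemical descriptors for a compound set
#'
#' OpenBabel-backed descriptors (molecular weight, atom-contribution logP,
#' topological polar surface area, hydrogen-bond donors/acceptors) plus
#' graph-derived counts (Lipinski N+O acceptors, rotatable bonds, aromatic
#' rings) and the count of matched QED structural-alert patterns.
#'
#' @param sdfset a `ChemmineR::SDFset` (see [smilesToSDFset()]).
#' @return data.frame with one row per compound: id, MW, logP, TPSA, HBD,
#'   HBA (OpenBabel acceptor typing), HBA_NO (Lipinski N+O count), ROTB,
#'   AROM, ALERTS.
#' @export
moleculeDescriptors <- function(sdfset) {
  .assert(is(sdfset, "SDFset"), "sdfset must be an SDFset")
  props <- ChemmineR::propOB(sdfset)
  ec <- .element_counts(sdfset)
  hba_no <- vapply(ec, function(tb)
    sum(tb[names(tb) %in% c("N", "O")]), numeric(1))
  rotb <- vapply(seq_along(sdfset), function(i)
    .rotatable_bonds(sdfset[[i]]), integer(1))
  om <- .obmols(sdfset)
  arom <- .aromatic_ring_count(om)
  alerts <- .qed_alert_hits(om)
  data.frame(id = ChemmineR::cid(sdfset), MW = props$MW, logP = props$logP,
             TPSA = props$TPSA, HBD = props$HBD, HBA = props$HBA1,
             HBA_NO = as.integer(hba_no), ROTB = rotb, AROM = arom,
             ALERTS = alerts, stringsAsFactors = FALSE, row.names = NULL)
}

#' HTS structural filter: nonorganic atoms and reactive substructures
#'
#' Fails any compound containing an element outside
#' H/C/N/O/S/P/F/Cl/Br/I or matching a pattern of the reactive-group
#' catalogue (acyl halides, aldehydes, Michael acceptors, epoxides,
#' isocyanates, ...). The failing pattern or element is named in the
#' reason.
#'
#' @param sdfset a `ChemmineR::SDFset`.
#' @param catalog named SMARTS vector; defaults to the built-in catalogue.
#' @return data.frame: id, pass, reason ("" when passing).
#' @export
htsFilter <- function(sdfset, catalog = .reactive_catalog) {
  ec <- .element_counts(sdfset)
  bad_elem <- vapply(ec, function(tb) {
    bad <- setdiff(names(tb), .organic_elements)
    if (length(bad)) paste0("nonorganic:", paste(bad, collapse = ","))
    else ""
  }, character(1))
  hits <- .smarts_counts(.obmols(sdfset), catalog) > 0
  reason <- vapply(seq_along(ec), function(i) {
    if (nzchar(bad_elem[i])) return(bad_elem[i])
    pat <- colnames(hits)[hits[i, ]]
    if (length(pat)) paste0("reactive:", paste(pat, collapse = ","))
    else ""
  }, character(1))
  data.frame(id = ChemmineR::cid(sdfset), pass = !nzchar(reason),
             reason = reason, stringsAsFactors = FALSE, row.names = NULL)
}

#' Lipinski rule-of-five check
#'
#' Violation flags: MW > 500, logP > 5, HBD > 5, N+O acceptors > 10
#' (boundaries are strict `>`, so MW exactly 500 does not violate). A
#' compound fails when its violation count reaches `maxViolations`
#' (default 1: any violation excludes; set 2 for the classical
#' one-violation-allowed reading).
#'
#' @param x an `SDFset` or a descriptor data.frame from
#'   [moleculeDescriptors()].
#' @param maxViolations violation count at which a compound fails.
#' @return data.frame: id, pass, n_violations, violations (comma list).
#' @export
lipinskiPass <- function(x, maxViolations = 1) {
  d <- if (is.data.frame(x)) x else moleculeDescriptors(x)
  v <- cbind(`MW>500` = d$MW > 500, `logP>5` = d$logP > 5,
             `HBD>5` = d$HBD > 5, `HBA>10` = d$HBA_NO > 10)
  nv <- rowSums(v)
  viol <- apply(v, 1, function(r) paste(colnames(v)[r], collapse = ","))
  data.frame(id = d$id, pass = nv < maxViolations, n_violations = nv,
             violations = viol, stringsAsFactors = FALSE, row.names = NULL)
}

#' Veber oral-bioavailability check
#'
#' Pass iff rotatable bonds <= 10 and TPSA <= 140 A^2.
#'
#' @inheritParams lipinskiPass
#' @return data.frame: id, pass, ROTB, TPSA.
#' @export
veberPass <- function(x) {
  d <- if (is.data.frame(x)) x else moleculeDescriptors(x)
  data.frame(id = d$id, pass = d$ROTB <= 10 & d$TPSA <= 140,
             ROTB = d$ROTB, TPSA = d$TPSA, stringsAsFactors = FALSE,
             row.names = NULL)
}

.load_pains_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pains_smarts.tsv",
                                package = "PharmScreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' PAINS (pan-assay interference) substructure flags
#'
#' Matches the published PAINS SMARTS catalogue (families A, B and C;
#' 480 patterns). The patterns are written against explicit-hydrogen
#' structures, so hydrogens are added before matching. An empty match list
#' means pass.
#'
#' @param sdfset a `ChemmineR::SDFset`.
#' @param catalog data.frame with columns pattern_id, family, smarts;
#'   defaults to the bundled catalogue.
#' @param families subset of families to apply (default all: A, B, C).
#' @return named list (by compound id) of matched pattern-id vectors.
#' @export
painsFlag <- function(sdfset, catalog = NULL, families = c("A", "B", "C")) {
  cat <- catalog %||% .load_pains_catalog()
  cat <- cat[cat$family %in% families, , drop = FALSE]
  om <- .obmols(sdfset, addHydrogens = TRUE)
  hits <- .smarts_counts(om, stats::setNames(cat$smarts, cat$pattern_id)) > 0
  out <- lapply(seq_along(om), function(i) colnames(hits)[hits[i, ]])
  stats::setNames(out, ChemmineR::cid(sdfset))
}

# Asymmetric desirability function of the QED publication; normalized by
# the property's maximum desirability.
.qed_ads <- function(x, p) {
  raw <- p[["a"]] + p[["b"]] /
    (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  pmin(pmax(raw / p[["dmax"]], 1e-9), 1)
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' The published QED desirability composite: each of the eight properties
#' (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS) is mapped through its
#' published asymmetric desirability function, and QED is the weighted
#' geometric mean of the desirabilities (mean-weight scheme by default;
#' `weights = "unit"` gives the unweighted variant).
#'
#' @param descriptors data.frame from [moleculeDescriptors()], or a named
#'   numeric vector/list with entries MW, logP (used as ALOGP), HBA, HBD,
#'   TPSA (used as PSA), ROTB, AROM, ALERTS for a single compound.
#' @param weights `"mean"` (default) or `"unit"`.
#' @return numeric QED in \[0, 1\], one per compound.
#' @export
qedScore <- function(descriptors, weights = c("mean", "unit")) {
  weights <- match.arg(weights)
  if (!is.data.frame(descriptors)) descriptors <- as.data.frame(as.list(descriptors))
  d <- descriptors
  props <- cbind(MW = d$MW, ALOGP = d$logP, HBA = d$HBA, HBD = d$HBD,
                 PSA = d$TPSA, ROTB = d$ROTB, AROM = d$AROM,
                 ALERTS = d$ALERTS)
  .assert(!anyNA(props), "descriptors incomplete for QED")
  des <- vapply(colnames(props), function(p)
    .qed_ads(props[, p], .qed_ads_params[[p]]), numeric(nrow(props)))
  des <- matrix(des, nrow = nrow(props),
                dimnames = list(NULL, colnames(props)))
  w <- if (weights == "mean") .qed_weights_mean[colnames(props)]
  else rep(1, ncol(props))
  exp(as.vector(log(des) %*% w) / sum(w))
}

#' QED threshold filter
#'
#' Fails compounds whose QED is strictly below the threshold ("below"
#' is strict: a compound exactly at the threshold is retained).
#'
#' @inheritParams lipinskiPass
#' @param threshold QED cutoff (default 0.25).
#' @param weights see [qedScore()].
#' @return data.frame: id, pass, qed.
#' @export
qedFilter <- function(x, threshold = 0.25, weights = "mean") {
  d <- if (is.data.frame(x)) x else moleculeDescriptors(x)
  q <- qedScore(d, weights)
  data.frame(id = d$id, pass = q >= threshold, qed = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter-cascade configuration
#'
#' @param stages stage order; any subset/permutation of
#'   `c("hts", "lipinski", "veber", "pains", "qed")`.
#' @param lipinskiMaxViolations see [lipinskiPass()].
#' @param qedThreshold see [qedFilter()] (default 0.25).
#' @param qedWeights see [qedScore()].
#' @param painsFamilies see [painsFlag()].
#' @param reactiveCatalog see [htsFilter()].
#' @return named list of class `filter_config`; records the logP estimator
#'   used, for provenance.
#' @export
filterConfig <- function(stages = c("hts", "lipinski", "veber", "pains",
                                    "qed"),
                         lipinskiMaxViolations = 1, qedThreshold = 0.25,
                         qedWeights = "mean",
                         painsFamilies = c("A", "B", "C"),
                         reactiveCatalog = .reactive_catalog) {
  .assert(all(stages %in% c("hts", "lipinski", "veber", "pains", "qed")),
          "unknown stage name(s)")
  structure(list(stages = stages,
                 lipinskiMaxViolations = lipinskiMaxViolations,
                 qedThreshold = qedThreshold, qedWeights = qedWeights,
                 painsFamilies = painsFamilies,
                 reactiveCatalog = reactiveCatalog,
                 logPEstimator = "OpenBabel atom-contribution logP"),
            class = "filter_config")
}

#' Apply the screening-library filter cascade
#'
#' Stages run in the configured order (default HTS, Lipinski, Veber,
#' PAINS, QED); each compound is removed at the first stage it fails, with
#' a machine-readable reason. The stage audit satisfies
#' `passed(stage k) = input(stage k+1)` and the chain is idempotent.
#'
#' @param sdfset the library as a `ChemmineR::SDFset`.
#' @param config a [filterConfig()].
#' @return list: `survivors` (SDFset subset), `report`
#'   ([FilterReport-class]), `descriptors` (data.frame for the full
#'   input).
#' @export
applyFilterChain <- function(sdfset, config = filterConfig()) {
  ids <- ChemmineR::cid(sdfset)
  desc <- if (length(sdfset)) moleculeDescriptors(sdfset) else NULL
  alive <- rep(TRUE, length(sdfset))
  stage_rows <- list()
  removed <- data.frame(compound_id = character(), stage = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (st in config$stages) {
    n_in <- sum(alive)
    if (n_in == 0) {
      stage_rows[[st]] <- data.frame(stage = st, n_input = 0L,
                                     n_passed = 0L, n_removed = 0L)
      next
    }
    sub <- sdfset[which(alive)]
    sub_ids <- ids[alive]
    res <- switch(st,
      hts = {
        h <- htsFilter(sub, config$reactiveCatalog)
        list(pass = h$pass, reason = h$reason)
      },
      lipinski = {
        l <- lipinskiPass(desc[alive, , drop = FALSE],
                          config$lipinskiMaxViolations)
        list(pass = l$pass, reason = paste0("lipinski:", l$violations))
      },
      veber = {
        v <- veberPass(desc[alive, , drop = FALSE])
        list(pass = v$pass,
             reason = sprintf("veber:ROTB=%d,TPSA=%.1f", v$ROTB, v$TPSA))
      },
      pains = {
        p <- painsFlag(sub, families = config$painsFamilies)
        hit <- lengths(p) > 0
        list(pass = !hit,
             reason = paste0("pains:", vapply(p, paste, character(1),
                                              collapse = ",")))
      },
      qed = {
        q <- qedFilter(desc[alive, , drop = FALSE],
                       config$qedThreshold, config$qedWeights)
        list(pass = q$pass, reason = sprintf("qed:%.3f", q$qed))
      })
    fail <- !res$pass
    if (any(fail))
      removed <- rbind(removed, data.frame(
        compound_id = sub_ids[fail], stage = st,
        reason = res$reason[fail], stringsAsFactors = FALSE))
    alive[alive] <- res$pass
    stage_rows[[st]] <- data.frame(stage = st, n_input = n_in,
                                   n_passed = sum(res$pass),
                                   n_removed = sum(fail))
  }
  stages <- do.call(rbind, stage_rows)
  rownames(stages) <- NULL
  list(survivors = sdfset[which(alive)],
       report = new("FilterReport", stages = stages, removed = removed),
       descriptors = desc)
}
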