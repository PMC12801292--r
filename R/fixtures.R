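#' @include AllClasses.R chem-io.R interactions.R pharm-model.R scoring.R evaluate.R
NULL

# Side-chain templates: atom name, element, offset along the pocket axis
# (du: positive = away from the pocket centre) and two tangential offsets,
# all relative to the residue anchor on the pocket sphere. The geometry is
# a detector test scaffold, not force-field chemistry: depths are chosen so
# that planted ligand fragments reach only their target residue while every
# other residue stays outside all detection cutoffs.
.residue_templates <- list(
  SER = list(atoms = list(c("CB", "C", -1.5, 0, 0), c("OG", "O", -2.5, 0, 0)),
             hb = "OG", hb_role = "acceptor", hp = "CB", aromatic = FALSE),
  THR = list(atoms = list(c("CB", "C", -1.5, 0, 0), c("OG1", "O", -2.5, 0, 0),
                          c("CG2", "C", -1.5, 1.4, 0)),
             hb = "OG1", hb_role = "acceptor", hp = "CB", aromatic = FALSE),
  ASN = list(atoms = list(c("CB", "C", -1.0, 0, 0), c("CG", "C", -1.6, 0, 0),
                          c("OD1", "O", -2.8, 0, 0), c("ND2", "N", -1.6, 1.3, 0)),
             hb = "OD1", hb_role = "acceptor", hp = "CB", aromatic = FALSE),
  GLN = list(atoms = list(c("CB", "C", -0.8, 0, 0), c("CG", "C", -1.6, 0.3, 0),
                          c("CD", "C", -2.2, 0, 0), c("OE1", "O", -3.0, 0, 0),
                          c("NE2", "N", -2.2, 1.3, 0)),
             hb = "OE1", hb_role = "acceptor", hp = "CB", aromatic = FALSE),
  ASP = list(atoms = list(c("CB", "C", -1.0, 0, 0), c("CG", "C", -1.6, 0, 0),
                          c("OD1", "O", -2.8, 0, 0), c("OD2", "O", -1.6, 1.3, 0)),
             hb = "OD1", hb_role = "acceptor", hp = "CB", aromatic = FALSE),
  LYS = list(atoms = list(c("CB", "C", -0.7, 0.4, 0), c("CG", "C", -1.3, -0.3, 0),
                          c("CD", "C", -1.9, 0.3, 0), c("CE", "C", -2.2, 0.5, 0),
                          c("NZ", "N", -2.8, 0, 0)),
             hb = "NZ", hb_role = "donor", hp = "CD", aromatic = FALSE),
  LEU = list(atoms = list(c("CB", "C", -0.8, 0, 0), c("CG", "C", -1.6, 0.3, 0),
                          c("CD1", "C", -2.5, 0, 0), c("CD2", "C", -1.6, 1.5, 0)),
             hb = NULL, hb_role = NULL, hp = "CD1", aromatic = FALSE),
  VAL = list(atoms = list(c("CB", "C", -1.2, 0, 0), c("CG1", "C", -2.4, 0, 0),
                          c("CG2", "C", -1.2, 1.4, 0)),
             hb = NULL, hb_role = NULL, hp = "CG1", aromatic = FALSE),
  ILE = list(atoms = list(c("CB", "C", -0.8, 0, 0), c("CG1", "C", -1.6, 0.3, 0),
                          c("CG2", "C", -0.8, 1.4, 0), c("CD1", "C", -2.5, 0, 0)),
             hb = NULL, hb_role = NULL, hp = "CD1", aromatic = FALSE),
  ALA = list(atoms = list(c("CB", "C", -1.8, 0, 0)),
             hb = NULL, hb_role = NULL, hp = "CB", aromatic = FALSE),
  PHE = list(atoms = NULL, hb = NULL, hb_role = NULL, hp = NULL,
             aromatic = TRUE, oh = FALSE),
  TYR = list(atoms = NULL, hb = "OH", hb_role = "acceptor", hp = NULL,
             aromatic = TRUE, oh = TRUE)
)

.pocket_type_cycle <- c("SER", "LEU", "ASN", "PHE", "LYS", "THR", "ASP",
                        "TYR")

# Residue anchor directions: two rings of four on the pocket sphere cap
# (polar angles 52 and 100 degrees, azimuth step 90 with a 45-degree
# offset between rings). Nearest-neighbour angular separation stays
# >= ~64 degrees, which keeps non-target residues outside every detection
# cutoff for planted ligand fragments.
.pocket_directions <- function(n) {
  .assert(n <= 8, "synthetic pockets support at most 8 residues")
  polar <- c(52, 100) * pi / 180
  dirs <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ring <- (i - 1) %/% 4 + 1
    j <- (i - 1) %% 4
    az <- (j * 90 + (ring - 1) * 45) * pi / 180
    th <- polar[ring]
    dirs[i, ] <- c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  }
  dirs
}

# Orthonormal tangent basis for a unit direction u.
.tangent_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * u) * u
  t1 <- t1 / sqrt(sum(t1 * t1))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

.pocket_radius <- 10
.contact_depth <- 2.5      # side-chain contact atoms sit at r ~ 7.5
.aromatic_depth <- 2.2     # aromatic ring centroids sit at r ~ 7.8

.residue_atoms <- function(resname, anchor, u, jitter) {
  tb <- .tangent_basis(u)
  place <- function(du, dt1, dt2)
    anchor + du * u + dt1 * tb$t1 + dt2 * tb$t2 + jitter()
  rows <- list(
    data.frame(atom = "N", elem = "N", t(place(1.2, 0.8, 0))),
    data.frame(atom = "CA", elem = "C", t(place(0, 0, 0))),
    data.frame(atom = "C", elem = "C", t(place(1.2, -0.8, 0))),
    data.frame(atom = "O", elem = "O", t(place(2.3, -0.9, 0))))
  tpl <- .residue_templates[[resname]]
  if (tpl$aromatic) {
    rows[[length(rows) + 1L]] <-
      data.frame(atom = "CB", elem = "C", t(place(-1.5, 1.39, 0)))
    centroid <- anchor - .aromatic_depth * u
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    for (k in 0:5) {
      th <- k * pi / 3
      pos <- centroid + 1.39 * (cos(th) * tb$t1 + sin(th) * tb$t2) + jitter()
      rows[[length(rows) + 1L]] <-
        data.frame(atom = nm[k + 1], elem = "C", t(pos))
    }
    if (isTRUE(tpl$oh))
      rows[[length(rows) + 1L]] <-
        data.frame(atom = "OH", elem = "O", t(centroid - 2.75 * tb$t1 +
                                                jitter()))
  } else {
    for (a in tpl$atoms)
      rows[[length(rows) + 1L]] <- data.frame(
        atom = a[1], elem = a[2],
        t(place(as.numeric(a[3]), as.numeric(a[4]), as.numeric(a[5]))))
  }
  out <- do.call(rbind, rows)
  names(out)[3:5] <- c("x", "y", "z")
  out
}

#' Generate a synthetic binding pocket
#'
#' Residues with a mix of hydrogen-bond-capable and hydrophobic/aromatic
#' side chains are arranged on a sphere of radius 10 Angstrom around an
#' origin-centred cavity, side chains pointing inward. Output is
#' deterministic per seed (coordinates carry a small seeded jitter).
#'
#' @param nResidues number of residues (3-8).
#' @param seed integer seed.
#' @param id structure identifier.
#' @param types optional residue-name vector (length `nResidues`) drawn
#'   from the supported set; defaults to a fixed diverse cycle.
#' @return a [ReceptorStructure-class] whose binding site is all residues.
#' @examples
#' generatePocket(nResidues = 6, seed = 1)
#' @export
generatePocket <- function(nResidues, seed, id = "pocket", types = NULL) {
  .assert(nResidues >= 3, "need >= 3 residues")
  types <- types %||% .pocket_type_cycle[(seq_len(nResidues) - 1) %%
                                           length(.pocket_type_cycle) + 1]
  .assert(length(types) == nResidues, "types length must match nResidues")
  .assert(all(types %in% names(.residue_templates)),
          "unsupported residue type(s): ",
          paste(setdiff(types, names(.residue_templates)), collapse = ", "))
  with_seed(seed, {
    dirs <- .pocket_directions(nResidues)
    jitter <- function() stats::runif(3, -0.1, 0.1)
    rows <- lapply(seq_len(nResidues), function(i) {
      u <- dirs[i, ]
      df <- .residue_atoms(types[i], .pocket_radius * u, u, jitter)
      df$chain <- "A"
      df$resno <- 80L + 7L * i
      df$resname <- types[i]
      df
    })
    atoms <- do.call(rbind, rows)[, c("chain", "resno", "resname", "atom",
                                      "elem", "x", "y", "z")]
    new("ReceptorStructure", id = id, atoms = atoms,
        bindingSite = unique(atoms[, c("chain", "resno")]))
  })
}

.pocket_geometry <- function(pocket) {
  at <- pocket@atoms
  res <- residues(pocket)
  lapply(stats::setNames(seq_len(nrow(res)), res$resno), function(i) {
    resno <- res$resno[i]
    tpl <- .residue_templates[[res$resname[i]]]
    sel <- at$resno == resno
    ca <- unlist(at[sel & at$atom == "CA", c("x", "y", "z")])
    u <- ca / sqrt(sum(ca * ca))
    get_atom <- function(nm) unlist(at[sel & at$atom == nm,
                                       c("x", "y", "z")])
    arom_centroid <- if (tpl$aromatic) {
      ring <- at[sel & at$atom %in% c("CG", "CD1", "CE1", "CZ", "CE2",
                                      "CD2"), c("x", "y", "z")]
      colMeans(as.matrix(ring))
    } else NULL
    list(resname = res$resname[i], chain = res$chain[i], resno = resno,
         u = u, tpl = tpl, get_atom = get_atom,
         arom_centroid = arom_centroid)
  })
}

#' Plant a ligand pose realizing a requested interaction set
#'
#' Builds ligand fragments whose geometry satisfies each requested
#' interaction with margin inside the default cutoffs: hydrogen-bond
#' heavy-atom distances are sampled in 2.7-3.3 Angstrom (with an explicit,
#' collinear donor hydrogen when the ligand donates), alkyl contacts in
#' 3.7-4.2 Angstrom and parallel aromatic stacks at 3.3-3.5 Angstrom
#' centroid separation. All non-requested residues stay outside every
#' cutoff. A two-carbon scaffold at the pocket origin anchors the pose.
#'
#' @param pocket a pocket from [generatePocket()].
#' @param spec data.frame with columns `resno` and `kind` (`"HB"` or
#'   `"HP"`); zero rows plant a contact-free pose.
#' @param seed integer seed for the distance sampling.
#' @param compoundId,dockingScore pose metadata.
#' @param geometry precomputed pocket geometry (internal optimization;
#'   leave `NULL`).
#' @return a [PoseRecord-class].
#' @export
plantPose <- function(pocket, spec, seed, compoundId = "planted",
                      dockingScore = -8, geometry = NULL) {
  geom <- geometry %||% .pocket_geometry(pocket)
  if (nrow(spec) > 0) {
    .assert(all(c("resno", "kind") %in% names(spec)),
            "spec needs resno and kind columns")
    .assert(all(as.character(spec$resno) %in% names(geom)),
            "unknown residue number(s): ",
            paste(setdiff(as.character(spec$resno), names(geom)),
                  collapse = ", "))
  }
  with_seed(seed, {
    # two-carbon scaffold at the pocket origin anchors every pose (and
    # keeps each record within the SDF toolchain's bonded-molecule model)
    elements <- c("C", "C")
    coords <- rbind(c(0, 0, 0), c(1.5, 0, 0))
    bonds <- matrix(c(1L, 2L, 1L), 1, 3)
    for (k in seq_len(nrow(spec))) {
      g <- geom[[as.character(spec$resno[k])]]
      tb <- .tangent_basis(g$u)
      kind <- spec$kind[k]
      if (kind == "HB") {
        .assert(!is.null(g$tpl$hb), "residue ", g$resno, " (", g$resname,
                ") cannot form a hydrogen bond")
        contact <- g$get_atom(g$tpl$hb)
        # fragments point from the contact atom towards the pocket origin,
        # which keeps them clear of every other residue's cutoffs
        inward <- -contact / sqrt(sum(contact * contact))
        d <- stats::runif(1, 2.7, 3.3)
        pos <- contact + d * inward
        if (g$tpl$hb_role == "acceptor") {
          # receptor accepts -> ligand donates: N with collinear H
          elements <- c(elements, "N", "H")
          coords <- rbind(coords, pos, pos - 1.02 * inward)
          n_idx <- length(elements) - 1L
          bonds <- rbind(bonds, c(n_idx, n_idx + 1L, 1L))
        } else {
          # receptor donates -> ligand accepts: carbonyl-like O
          elements <- c(elements, "O")
          coords <- rbind(coords, pos)
        }
      } else if (kind == "HP") {
        if (g$tpl$aromatic) {
          d <- stats::runif(1, 3.3, 3.5)
          centroid <- g$arom_centroid - d * g$u
          phase <- stats::runif(1, 0, pi / 3)
          start <- length(elements)
          for (j in 0:5) {
            th <- phase + j * pi / 3
            coords <- rbind(coords, centroid +
                              1.39 * (cos(th) * tb$t1 + sin(th) * tb$t2))
            elements <- c(elements, "C")
          }
          ring_idx <- start + 1:6
          bonds <- rbind(bonds, cbind(ring_idx,
                                      c(ring_idx[-1], ring_idx[1]), 4L))
        } else {
          contact <- g$get_atom(g$tpl$hp)
          inward <- -contact / sqrt(sum(contact * contact))
          d <- stats::runif(1, 3.7, 4.2)
          elements <- c(elements, "C")
          coords <- rbind(coords, contact + d * inward + 1.0 * tb$t1)
        }
      } else stop("kind must be HB or HP", call. = FALSE)
    }
    mol <- Molecule(compoundId, elements, coords, bonds)
    PoseRecord(compoundId, structureId(pocket), mol, dockingScore)
  })
}

#' Benchmark specification with the default study conditions
#'
#' Defaults: 3 receptor structures, 30 actives vs 90 decoys, pockets of 8
#' residues with 1 planted hydrogen bond and 4 planted hydrophobic contacts
#' per structure (one hinge hydrogen bond flanked by a consistent
#' hydrophobic shell, the pattern typical of ATP-competitive kinase
#' inhibitors). Actives realize each planted interaction with probability
#' 0.9, decoys 0.3; everyone contacts non-planted residues with
#' probability 0.05. Docking scores are Gaussian with an active/decoy mean
#' shift of 0.95 at unit sd, putting docking-only enrichment near
#' AUC 0.75.
#'
#' @param nStructures,nActives,nDecoys,nResidues,nPlantedHB,nPlantedHP
#'   integer sizes, see description.
#' @param pActive,pDecoy,pNoise interaction realization probabilities.
#' @param activeMean,decoyMean,scoreSd docking-score model.
#' @param seed integer master seed.
#' @return a [BenchmarkSpec-class].
#' @export
benchmarkSpec <- function(nStructures = 3, nActives = 30, nDecoys = 90,
                          nResidues = 8, nPlantedHB = 1, nPlantedHP = 4,
                          pActive = 0.9, pDecoy = 0.3, pNoise = 0.05,
                          activeMean = -6.95, decoyMean = -6.0,
                          scoreSd = 1.0, seed = 1) {
  new("BenchmarkSpec", nStructures = as.integer(nStructures),
      nActives = as.integer(nActives), nDecoys = as.integer(nDecoys),
      nResidues = as.integer(nResidues),
      nPlantedHB = as.integer(nPlantedHB),
      nPlantedHP = as.integer(nPlantedHP),
      pActive = pActive, pDecoy = pDecoy, pNoise = pNoise,
      activeMean = activeMean, decoyMean = decoyMean, scoreSd = scoreSd,
      seed = as.integer(seed))
}

# Deterministic small-molecule SMILES catalogue for benchmark compounds
# (used by the similarity and filtering stages; pose geometry is planted
# independently of the 2D structure).
.benchmark_smiles <- function(n) {
  cores <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1",
             "c1ccsc1", "C1CCNCC1")
  tails <- c("", "C", "CC", "CCC", "O", "OC", "N", "NC", "Cl", "Br",
             "C(=O)O", "C(=O)N", "CO", "CN", "OCC", "CCO")
  pres <- c("", "C", "CC", "O=C(C)", "N#C")
  smi <- character()
  for (p in pres) for (co in cores) for (ta in tails)
    smi <- c(smi, paste0(p, co, ta))
  .assert(n <= length(smi), "at most ", length(smi),
          " benchmark compounds supported")
  smi[seq_len(n)]
}

#' Generate a planted-signal actives/decoys benchmark
#'
#' Builds `nStructures` synthetic pockets, selects per-structure planted
#' key interactions (HB on hydrogen-bond-capable residues, HP on the
#' rest), and for every compound and structure plants a pose that realizes
#' each planted interaction with probability `pActive` (actives) or
#' `pDecoy` (decoys), plus noise contacts on non-planted residues with
#' probability `pNoise`. Docking scores are drawn from the Gaussian score
#' model. Everything is deterministic given `spec@seed`.
#'
#' @param spec a [benchmarkSpec()].
#' @return list with elements `spec`, `receptors` (named list),
#'   `poses` (list of [PoseRecord-class]), `manifest` (data.frame),
#'   `activeIds`, `compoundIds`, `smiles` (named vector) and `planted`
#'   (per-structure data.frame of planted interactions).
#' @export
generateBenchmark <- function(spec) {
  .assert(is(spec, "BenchmarkSpec"), "spec must be a BenchmarkSpec")
  with_seed(spec@seed, {
    sub_seeds <- sample.int(2^30, spec@nStructures + 1L)
    sids <- sprintf("SYN%d", seq_len(spec@nStructures))
    receptors <- lapply(seq_len(spec@nStructures), function(s)
      generatePocket(spec@nResidues, seed = sub_seeds[s], id = sids[s]))
    names(receptors) <- sids
    # planted interactions per structure
    planted <- lapply(receptors, function(rec) {
      res <- residues(rec)
      hb_ok <- vapply(res$resname, function(rn)
        !is.null(.residue_templates[[rn]]$hb), logical(1))
      .assert(sum(hb_ok) >= spec@nPlantedHB &&
                nrow(res) >= spec@nPlantedHB + spec@nPlantedHP,
              "pocket too small for the requested planted interactions")
      hb_res <- sample(res$resno[hb_ok], spec@nPlantedHB)
      hp_res <- sample(setdiff(res$resno, hb_res), spec@nPlantedHP)
      data.frame(resno = c(hb_res, hp_res),
                 kind = rep(c("HB", "HP"), c(spec@nPlantedHB,
                                             spec@nPlantedHP)))
    })
    n_cpd <- spec@nActives + spec@nDecoys
    cids <- c(sprintf("ACT%03d", seq_len(spec@nActives)),
              sprintf("DEC%03d", seq_len(spec@nDecoys)))
    active <- c(rep(TRUE, spec@nActives), rep(FALSE, spec@nDecoys))
    smiles <- stats::setNames(.benchmark_smiles(n_cpd), cids)
    poses <- list()
    manifest <- list()
    for (s in sids) {
      res <- residues(receptors[[s]])
      geom_s <- .pocket_geometry(receptors[[s]])
      pl <- planted[[s]]
      other <- setdiff(res$resno, pl$resno)
      for (j in seq_len(n_cpd)) {
        p_hit <- if (active[j]) spec@pActive else spec@pDecoy
        keep <- stats::runif(nrow(pl)) < p_hit
        noise_hit <- other[stats::runif(length(other)) < spec@pNoise]
        noise_kind <- vapply(noise_hit, function(rn) {
          rn_name <- res$resname[res$resno == rn]
          if (!is.null(.residue_templates[[rn_name]]$hb) &&
              stats::runif(1) < 0.5) "HB" else "HP"
        }, character(1))
        pose_spec <- rbind(pl[keep, , drop = FALSE],
                           if (length(noise_hit))
                             data.frame(resno = noise_hit,
                                        kind = noise_kind))
        d <- stats::rnorm(1, if (active[j]) spec@activeMean
                          else spec@decoyMean, spec@scoreSd)
        pose <- plantPose(receptors[[s]], pose_spec,
                          seed = sample.int(2^30, 1), compoundId = cids[j],
                          dockingScore = d, geometry = geom_s)
        poses[[length(poses) + 1L]] <- pose
        manifest[[length(manifest) + 1L]] <- data.frame(
          compound_id = cids[j], structure_id = s, docking_score = d,
          pose_file = paste0(cids[j], "_", s, ".sdf"),
          stringsAsFactors = FALSE)
      }
    }
    list(spec = spec, receptors = receptors, poses = poses,
         manifest = do.call(rbind, manifest),
         activeIds = cids[active], compoundIds = cids, smiles = smiles,
         planted = planted)
  })
}

#' Write a generated benchmark to disk in standard formats
#'
#' Pockets as PDB, poses as SDF with a per-structure score manifest CSV,
#' labels and SMILES as plain text, and the spec as JSON.
#'
#' @param bench output of [generateBenchmark()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(bench$receptors))
    writeReceptorPDB(bench$receptors[[s]], file.path(dir, paste0(s, ".pdb")))
  writePoseSet(bench$poses, file.path(dir, "poses"))
  utils::write.csv(data.frame(compound_id = bench$compoundIds,
                              active = bench$compoundIds %in% bench$activeIds),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(paste(bench$smiles, names(bench$smiles)),
             file.path(dir, "library.smi"))
  sp <- bench$spec
  jsonlite::write_json(
    list(nStructures = sp@nStructures, nActives = sp@nActives,
         nDecoys = sp@nDecoys, nResidues = sp@nResidues,
         nPlantedHB = sp@nPlantedHB, nPlantedHP = sp@nPlantedHP,
         pActive = sp@pActive, pDecoy = sp@pDecoy, pNoise = sp@pNoise,
         activeMean = sp@activeMean, decoyMean = sp@decoyMean,
         scoreSd = sp@scoreSd, seed = sp@seed),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full model-building + scoring protocol on a benchmark
#'
#' Per structure: build the pharmacological model from the top-scored
#' active poses, score every compound (S = N - 0.01 D), rank, and compute
#' ROC-AUCs for the docking-only, pharmacological and consensus rankers.
#'
#' @param bench output of [generateBenchmark()].
#' @param nTop actives used for model building (default 30).
#' @param criteria detection criteria.
#' @param consensusSubsets see [rankerScoreSets()].
#' @return list: `models`, `scored` (per-structure tables), `aucs`
#'   (data.frame from [evaluateRankers()]).
#' @export
evaluateBenchmark <- function(bench, nTop = 30,
                              criteria = interactionCriteria(),
                              consensusSubsets = NULL) {
  sids <- names(bench$receptors)
  cid <- vapply(bench$poses, compoundId, character(1))
  sid <- vapply(bench$poses, structureId, character(1))
  is_active <- cid %in% bench$activeIds
  models <- lapply(stats::setNames(sids, sids), function(s)
    buildPharmacologicalModel(bench$receptors[[s]],
                              bench$poses[sid == s & is_active],
                              nTop = nTop, criteria = criteria))
  scored <- scoreCompoundSet(bench$poses, models, bench$receptors, criteria)
  rankers <- rankerScoreSets(scored, consensusSubsets)
  list(models = models, scored = scored,
       aucs = evaluateRankers(rankers, bench$activeIds))
}
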