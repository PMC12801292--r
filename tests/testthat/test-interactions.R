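# minimal hand-built receptor, residues spaced far apart: an asparagine
# carbonyl acceptor, a leucine side-chain carbon, a phenylalanine ring
.mini_receptor <- function() {
  ring <- cbind(20 + 1.39 * cos(0:5 * pi / 3), 1.39 * sin(0:5 * pi / 3), 5)
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, 1L, 2L, 2L, rep(3L, 6)),
    resname = c("ASN", "ASN", "LEU", "LEU", rep("PHE", 6)),
    atom = c("CG", "OD1", "CB", "CD1", "CG", "CD1", "CE1", "CZ", "CE2",
             "CD2"),
    elem = c("C", "O", "C", "C", rep("C", 6)),
    x = c(0, 0, 8, 8, ring[, 1]),
    y = c(1.4, 0, 1, 0, ring[, 2]),
    z = c(0, 0, 0, 0, ring[, 3]),
    stringsAsFactors = FALSE)
  new("ReceptorStructure", id = "mini", atoms = atoms,
      bindingSite = data.frame(chain = character(), resno = integer()))
}

.pose_at <- function(elements, coords, bonds = NULL, id = "lig") {
  PoseRecord(id, "mini", Molecule(id, elements, coords, bonds), -5)
}

test_that("a collinear N-H...O pair within 3.5 A is one hydrogen bond", {
  # ligand N at 2.8 A from the ASN carbonyl O, H on the N->O axis (180 deg)
  pose <- .pose_at(c("N", "H"), rbind(c(0, 0, 2.8), c(0, 0, 1.8)),
                   cbind(1, 2, 1))
  hb <- detectHBonds(.mini_receptor(), pose)
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$resname, "ASN")
  expect_identical(hb$subtype, "donor")
  expect_equal(hb$distance, 2.8, tolerance = 1e-12)
  expect_equal(hb$angle, 180, tolerance = 1e-9)
})

test_that("the same donor at 4.0 A is not a hydrogen bond", {
  pose <- .pose_at(c("N", "H"), rbind(c(0, 0, 4.0), c(0, 0, 3.0)),
                   cbind(1, 2, 1))
  expect_identical(nrow(detectHBonds(.mini_receptor(), pose)), 0L)
})

test_that("a bent explicit hydrogen fails the angle criterion", {
  # H placed perpendicular: D-H...A angle ~ 45 degrees < 120
  pose <- .pose_at(c("N", "H"), rbind(c(0, 0, 2.8), c(0, 1.0, 2.8)),
                   cbind(1, 2, 1))
  expect_identical(nrow(detectHBonds(.mini_receptor(), pose)), 0L)
  # with an implicit hydrogen instead, the angle test is skipped
  pose2 <- .pose_at("N", rbind(c(0, 0, 2.8)))
  hb <- detectHBonds(.mini_receptor(), pose2)
  expect_identical(nrow(hb), 1L)
  expect_true(is.na(hb$angle[hb$subtype == "donor"][1]))
})

test_that("an apolar carbon near a leucine side chain is an alkyl contact", {
  pose <- .pose_at("C", rbind(c(8, 0, 4.0)))
  hp <- detectHydrophobic(.mini_receptor(), pose)
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$resname, "LEU")
  expect_identical(hp$subtype, "alkyl")
  expect_equal(hp$distance, 4.0, tolerance = 1e-12)
  # a carbon bonded to oxygen is polarized and does not count
  pose2 <- .pose_at(c("C", "O"), rbind(c(8, 0, 4.0), c(8, 0, 5.4)),
                    cbind(1, 2, 1))
  hp2 <- detectHydrophobic(.mini_receptor(), pose2)
  expect_identical(nrow(hp2), 0L)
})

test_that("parallel rings at 3.6 A centroid distance pi-stack", {
  ring <- cbind(20 + 1.39 * cos(0:5 * pi / 3), 1.39 * sin(0:5 * pi / 3), 8.6)
  pose <- .pose_at(rep("C", 6), ring, cbind(1:6, c(2:6, 1), 4L))
  hp <- detectHydrophobic(.mini_receptor(), pose)
  hp <- hp[hp$resname == "PHE", ]
  expect_identical(hp$subtype, "pi")
  expect_equal(hp$distance, 3.6, tolerance = 1e-9)
  expect_lt(hp$angle, 1e-6)
})

test_that("alkyl + pi contacts to one residue merge as mixed", {
  ring <- cbind(20 + 1.39 * cos(0:5 * pi / 3), 1.39 * sin(0:5 * pi / 3), 8.6)
  coords <- rbind(ring, c(20, 0, 9.2))  # extra apolar C near the PHE ring
  pose <- .pose_at(rep("C", 7), coords, cbind(1:6, c(2:6, 1), 4L))
  hp <- detectHydrophobic(.mini_receptor(), pose)
  hp <- hp[hp$resname == "PHE", ]
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$subtype, "mixed")
})

test_that("profiles deduplicate multiple contacts to one residue", {
  # two apolar carbons near the same leucine -> one profile entry
  pose <- .pose_at(c("C", "C"), rbind(c(8, 0, 4.0), c(8, 0.8, 4.0)))
  prof <- profilePose(.mini_receptor(), pose)
  expect_identical(interactionKeys(prof), "A:2:HP")
  # pose with nothing in range -> empty profile
  far <- .pose_at("C", rbind(c(50, 50, 50)))
  expect_identical(nrow(interactions(profilePose(.mini_receptor(), far))), 0L)
})

test_that("a five-key pose profiles to exactly those five keys", {
  # hinge-like pattern: one hydrogen bond plus four hydrophobic contacts
  pocket <- generatePocket(8, seed = 5, id = "hinge")
  res <- residues(pocket)
  hb_res <- res$resno[res$resname == "SER"][1]
  hp_res <- setdiff(res$resno, hb_res)[1:4]
  pose <- plantPose(pocket, data.frame(resno = c(hb_res, hp_res),
                                       kind = c("HB", rep("HP", 4))),
                    seed = 9)
  keys <- interactionKeys(profilePose(pocket, pose))
  expect_setequal(keys, c(paste0("A:", hb_res, ":HB"),
                          paste0("A:", hp_res, ":HP")))
})

test_that("profiles are invariant to ligand atom reordering", {
  pocket <- generatePocket(8, seed = 21)
  res <- residues(pocket)
  pose <- plantPose(pocket, data.frame(resno = res$resno[c(1, 3, 5)],
                                       kind = c("HB", "HP", "HP")), seed = 4)
  mol <- conformer(pose)
  perm <- rev(seq_along(mol@elements))
  inv <- order(perm)
  mol2 <- Molecule(mol@id, mol@elements[perm], mol@coords[perm, ],
                   cbind(inv[mol@bonds[, 1]], inv[mol@bonds[, 2]],
                         mol@bonds[, 3]))
  pose2 <- PoseRecord(compoundId(pose), structureId(pose), mol2,
                      dockingScore(pose))
  expect_identical(
    profile_keys_with_subtype(profilePose(pocket, pose)),
    profile_keys_with_subtype(profilePose(pocket, pose2)))
})

test_that("enlarging cutoffs never removes interactions", {
  pocket <- generatePocket(8, seed = 33)
  res <- residues(pocket)
  for (seed in 1:5) {
    set.seed(seed)
    pose <- plantPose(pocket,
                      data.frame(resno = sample(res$resno, 4),
                                 kind = c("HP", "HP", "HP", "HP")),
                      seed = seed)
    base <- interactionKeys(profilePose(pocket, pose))
    wide <- interactionKeys(profilePose(pocket, pose,
      interactionCriteria(hbDistMax = 4.5, hpDistMax = 6.0,
                          piDistMax = 7.0)))
    expect_true(all(base %in% wide))
  }
})

test_that("profiles are invariant under rigid motion of receptor + pose", {
  pocket <- generatePocket(8, seed = 13)
  res <- residues(pocket)
  pose <- plantPose(pocket, data.frame(resno = res$resno[c(1, 2, 6)],
                                       kind = c("HB", "HP", "HP")), seed = 2)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  at <- receptorAtoms(pocket)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]; at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  pocket2 <- new("ReceptorStructure", id = "moved", atoms = at,
                 bindingSite = bindingSite(pocket))
  mol <- conformer(pose)
  mol2 <- Molecule(mol@id, mol@elements,
                   sweep(mol@coords %*% t(R), 2, -shift), mol@bonds)
  pose2 <- PoseRecord(compoundId(pose), "moved", mol2, dockingScore(pose))
  expect_identical(
    profile_keys_with_subtype(profilePose(pocket, pose)),
    profile_keys_with_subtype(profilePose(pocket2, pose2)))
})

test_that("detector output equals the brute-force all-pairs oracle", {
  for (seed in 1:8) {
    pocket <- generatePocket(8, seed = 100 + seed)
    res <- residues(pocket)
    set.seed(seed)
    n_int <- sample(0:5, 1)
    spec <- if (n_int > 0) {
      picked <- sample(res$resno, n_int)
      kinds <- vapply(picked, function(rn) {
        hbok <- !res$resname[res$resno == rn] %in% c("LEU", "PHE")
        if (hbok && runif(1) < 0.5) "HB" else "HP"
      }, character(1))
      data.frame(resno = picked, kind = kinds)
    } else data.frame()
    pose <- plantPose(pocket, spec, seed = 200 + seed)
    # add random stray atoms to stress the enumeration
    mol <- conformer(pose)
    extra <- matrix(runif(9, -12, 12), 3, 3)
    mol2 <- Molecule(mol@id, c(mol@elements, "C", "N", "O"),
                     rbind(mol@coords, extra), mol@bonds)
    pose2 <- PoseRecord(compoundId(pose), structureId(pose), mol2,
                        dockingScore(pose))
    expect_identical(
      profile_keys_with_subtype(profilePose(pocket, pose2)),
      oracle_profile_keys(pocket, pose2),
      info = paste("seed", seed))
  }
})

test_that("criteria configs validate and load from JSON", {
  expect_error(interactionCriteria(hbDistMax = -1), "non-negative")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(hbDistMax = 3.2, hpDistMax = 4.0), path,
                       auto_unbox = TRUE)
  crit <- readInteractionCriteria(path)
  expect_equal(crit$hbDistMax, 3.2)
  expect_equal(crit$piDistMax, 5.5)  # default preserved
  expect_error(readInteractionCriteria({
    p <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(bogus = 1), p, auto_unbox = TRUE); p
  }), "unknown")
})

test_that("a pose without coordinates is a precondition error", {
  pose <- PoseRecord("x", "mini", Molecule("x", "C",
                                           matrix(c(0, 0, 0), 1, 3)), -1)
  pose@conformer@coords <- matrix(NA_real_, 1, 3)
  expect_error(detectHBonds(.mini_receptor(), pose), "coordinates")
})
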