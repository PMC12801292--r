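.mk_pose <- function(cid, sid, score) {
  PoseRecord(cid, sid, Molecule(cid, "C", matrix(0, 1, 3)), score)
}

.mk_profile <- function(cid, sid, resnos, kinds,
                        subtypes = ifelse(kinds == "HB", "donor", "alkyl")) {
  df <- if (length(resnos))
    data.frame(chain = "A", resno = as.integer(resnos), resname = "XXX",
               kind = kinds, subtype = subtypes,
               distance = 3.0, angle = NA_real_, stringsAsFactors = FALSE)
  else PharmScreen:::.empty_interactions()
  new("InteractionProfile", compoundId = cid, structureId = sid,
      interactions = PharmScreen:::.order_interactions(df))
}

test_that("top-pose selection keeps the n best scores with id tie-break", {
  set.seed(1)
  poses <- lapply(1:60, function(i)
    .mk_pose(sprintf("c%02d", i), "S", -runif(1, 5, 10)))
  top <- selectTopPoses(poses, 30)
  expect_length(top, 30)
  d <- vapply(top, dockingScore, numeric(1))
  all_d <- sort(vapply(poses, dockingScore, numeric(1)))
  expect_equal(sort(d), all_d[1:30])

  # equal scores: lexicographically smallest ids win
  tied <- list(.mk_pose("b", "S", -5), .mk_pose("a", "S", -5),
               .mk_pose("c", "S", -5))
  expect_identical(vapply(selectTopPoses(tied, 2), compoundId,
                          character(1)), c("a", "b"))
  # n equal to the pool size is the identity (ordered by score)
  expect_length(selectTopPoses(poses, 60), 60)
  # shortfall warns and returns everything
  expect_warning(short <- selectTopPoses(tied, 5), "3 compounds")
  expect_length(short, 3)
  # duplicate poses per compound: only the best-scored one counts
  dup <- list(.mk_pose("a", "S", -9), .mk_pose("a", "S", -2),
              .mk_pose("b", "S", -5))
  sel <- selectTopPoses(dup, 2)
  expect_identical(vapply(sel, compoundId, character(1)), c("a", "b"))
  expect_equal(dockingScore(sel[[1]]), -9)
})

test_that("interaction frequencies are exact counts over profiles", {
  profs <- c(
    lapply(1:15, function(i) .mk_profile(paste0("c", i), "S", c(10, 20),
                                         c("HB", "HP"))),
    lapply(16:30, function(i) .mk_profile(paste0("c", i), "S", 10, "HB")))
  ft <- interactionFrequencies(profs)
  expect_identical(ft@nPoses, 30L)
  e <- frequencies(ft)
  expect_equal(e$frequency[e$resno == 10 & e$kind == "HB"], 1.0)
  expect_equal(e$frequency[e$resno == 20 & e$kind == "HP"], 0.5)

  # randomized sets agree with a naive recount
  set.seed(7)
  for (rep in 1:5) {
    profs <- lapply(1:20, function(i) {
      picked <- sample(1:6, sample(0:4, 1))
      .mk_profile(paste0("c", i), "S", picked,
                  ifelse(picked %% 2 == 0, "HB", "HP"))
    })
    ft <- interactionFrequencies(profs)
    e <- frequencies(ft)
    for (j in seq_len(nrow(e))) {
      key <- paste("A", e$resno[j], e$kind[j], sep = ":")
      naive <- sum(vapply(profs, function(p)
        key %in% interactionKeys(p), logical(1)))
      expect_identical(e$count[j], naive)
      expect_equal(e$frequency[j], naive / 20)
    }
  }
  expect_error(interactionFrequencies(list(
    .mk_profile("a", "S1", 1, "HB"), .mk_profile("b", "S2", 1, "HB"))),
    "multiple structures")
})

test_that("threshold application is inclusive at the boundary", {
  entries <- data.frame(
    chain = "A", resno = c(162L, 86L, 88L, 161L),
    resname = c("CYS", "LYS", "LEU", "TYR"),
    kind = c("HB", "HB", "HP", "HP"),
    subtype = c("donor", "donor", "alkyl", "alkyl"),
    count = c(19L, 9L, 26L, 21L), frequency = c(19, 9, 26, 21) / 30,
    stringsAsFactors = FALSE)
  ft <- new("FrequencyTable", structureId = "S", nPoses = 30L,
            entries = entries)
  m <- identifyPharmacological(ft, 0.50, 0.80)
  expect_setequal(interactionKeys(m), c("A:162:HB", "A:88:HP"))

  # exactly at the boundary: 15/30 = 0.50 HB and 24/30 = 0.80 HP included
  entries2 <- entries
  entries2$count <- c(15L, 14L, 24L, 23L)
  entries2$frequency <- entries2$count / 30
  m2 <- identifyPharmacological(new("FrequencyTable", structureId = "S",
                                    nPoses = 30L, entries = entries2))
  expect_setequal(interactionKeys(m2), c("A:162:HB", "A:88:HP"))

  # empty table -> empty model
  ft0 <- interactionFrequencies(list(.mk_profile("a", "S", integer(),
                                                 character())))
  expect_identical(nrow(keyInteractions(identifyPharmacological(ft0))), 0L)
  expect_error(identifyPharmacological(ft, 0, 0.8), "0, 1")
})

test_that("raising thresholds never adds key interactions", {
  set.seed(11)
  profs <- lapply(1:25, function(i) {
    picked <- sample(1:8, sample(1:5, 1))
    .mk_profile(paste0("c", i), "S", picked,
                ifelse(picked <= 4, "HB", "HP"))
  })
  ft <- interactionFrequencies(profs)
  prev <- NULL
  for (th in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    keys <- interactionKeys(identifyPharmacological(ft, th, th))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("frequency tables re-aggregate as means over equal halves", {
  set.seed(3)
  mk <- function(ids) lapply(ids, function(i) {
    picked <- sample(1:5, sample(0:3, 1))
    .mk_profile(paste0("c", i), "S", picked, rep("HP", length(picked)))
  })
  a <- mk(1:10); b <- mk(11:20)
  fa <- frequencies(interactionFrequencies(a))
  fb <- frequencies(interactionFrequencies(b))
  fab <- frequencies(interactionFrequencies(c(a, b)))
  for (j in seq_len(nrow(fab))) {
    key <- paste(fab$resno[j], fab$kind[j])
    va <- fa$frequency[paste(fa$resno, fa$kind) == key]
    vb <- fb$frequency[paste(fb$resno, fb$kind) == key]
    expect_equal(fab$frequency[j],
                 (sum(va, numeric(1)) + sum(vb, numeric(1))) / 2)
  }
})

test_that("match counting is a set intersection bounded by the model size", {
  entries <- data.frame(chain = "A", resno = 1:5, resname = "XXX",
                        kind = c("HB", rep("HP", 4)),
                        subtype = c("donor", rep("alkyl", 4)),
                        count = 30L, frequency = 1.0,
                        stringsAsFactors = FALSE)
  model <- identifyPharmacological(new("FrequencyTable", structureId = "S",
                                       nPoses = 30L, entries = entries))
  full <- .mk_profile("x", "S", 1:5, c("HB", rep("HP", 4)))
  expect_identical(countMatches(full, model), 5L)
  expect_identical(countMatches(.mk_profile("y", "S", integer(),
                                            character()), model), 0L)
  partial <- .mk_profile("z", "S", c(1, 2, 7, 8, 9),
                         c("HB", "HP", "HP", "HP", "HP"))
  expect_identical(countMatches(partial, model), 2L)
  expect_error(countMatches(.mk_profile("w", "OTHER", 1, "HB"), model),
               "does not match")
})

test_that("models serialize to JSON and back", {
  pocket <- generatePocket(6, seed = 2, id = "SER1")
  poses <- lapply(1:10, function(i) {
    res <- residues(pocket)
    p <- plantPose(pocket, data.frame(resno = res$resno[c(1, 2)],
                                      kind = c("HB", "HP")),
                   seed = i, compoundId = paste0("a", i),
                   dockingScore = -6 - i * 0.1)
    p
  })
  m <- buildPharmacologicalModel(pocket, poses, nTop = 10)
  path <- withr::local_tempfile(fileext = ".json")
  writePharmacologicalModel(m, path)
  back <- readPharmacologicalModel(path)
  expect_identical(structureId(back), structureId(m))
  expect_identical(interactionKeys(back), interactionKeys(m))
  expect_equal(back@hbThreshold, m@hbThreshold)
  expect_identical(back@provenance$nPoses, 10L)
})
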