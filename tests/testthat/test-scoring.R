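test_that("the pharmacological score is exactly N - 0.01 D", {
  expect_identical(pharmacologicalScore(4, -10), 4.1)
  expect_identical(pharmacologicalScore(0, 0), 0)
  expect_equal(pharmacologicalScore(3, -9.53), 3.0953, tolerance = 1e-15)
  expect_error(pharmacologicalScore(1, Inf), "finite")
  expect_error(pharmacologicalScore(-1, 0), "non-negative")
})

test_that("per-structure ranking orders by S with documented tie-breaks", {
  tab <- data.frame(compound_id = c("a", "b", "c"), structure_id = "S",
                    D = c(-10, -8, -9), N = c(5, 3, 4))
  r <- rankByScore(tab)
  expect_identical(r$compound_id, c("a", "c", "b"))
  expect_identical(r$rank, 1:3)
  expect_equal(r$S, c(5.1, 4.09, 3.08))

  # same S and D: id decides
  tab2 <- data.frame(compound_id = c("b", "a"), structure_id = "S",
                     D = c(-9, -9), N = c(2, 2))
  expect_identical(rankByScore(tab2)$compound_id, c("a", "b"))
  # equal N: the more negative docking score yields the higher S
  tab3 <- data.frame(compound_id = c("a", "b"), structure_id = "S",
                     D = c(-8, -9), N = c(2, 2))
  expect_identical(rankByScore(tab3)$compound_id[1], "b")

  expect_error(rankByScore(data.frame(compound_id = c("a", "a"),
                                      structure_id = "S", D = -1, N = 0)),
               "duplicate")
})

test_that("random score tables rank identically to a sort oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    tab <- data.frame(compound_id = sprintf("c%03d", sample(n)),
                      structure_id = "S",
                      D = round(-runif(n, 4, 11), 2),
                      N = sample(0:5, n, replace = TRUE))
    r <- rankByScore(tab)
    s <- tab$N - 0.01 * tab$D
    oracle <- tab$compound_id[order(-s, tab$D, tab$compound_id)]
    expect_identical(r$compound_id, oracle)
    expect_identical(r$rank, seq_len(n))
  }
})

test_that("consensus scores are exact rank sums with K+1 for absentees", {
  r1 <- data.frame(compound_id = c("a", "b", "c"), rank = c(10L, 20L, 30L))
  # ranks do not have to be 1..K for the sum to be well-defined
  cr <- consensusRank(list(S1 = r1, S2 = r1, S3 = r1))
  tab <- ranking(cr)
  expect_identical(tab$consensus_score[tab$compound_id == "c"], 90L)

  # A = (1, 2), B = (2, 1): both 3, tie broken by id
  rA <- data.frame(compound_id = c("A", "B"), rank = c(1L, 2L))
  rB <- data.frame(compound_id = c("B", "A"), rank = c(1L, 2L))
  tab2 <- ranking(consensusRank(list(S1 = rA, S2 = rB)))
  expect_identical(tab2$compound_id, c("A", "B"))
  expect_identical(tab2$consensus_score, c(3L, 3L))
  expect_identical(tab2$final_rank, 1:2)

  # a compound missing from one ranking gets K+1 there
  rC <- data.frame(compound_id = "A", rank = 1L)
  tab3 <- ranking(consensusRank(list(S1 = rA, S2 = rC)))
  expect_identical(tab3$consensus_score[tab3$compound_id == "B"],
                   2L + 2L)  # rank 2 in S1, K+1 = 2 in S2
  expect_error(consensusRank(list(S1 = rA)), ">= 2")
})

test_that("consensus equals the brute-force rank-sum oracle", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    ids <- sprintf("c%02d", 1:n)
    rankings <- lapply(1:3, function(s) {
      keep <- sort(sample(n, sample(3:n, 1)))
      data.frame(compound_id = ids[keep],
                 rank = sample(length(keep)))
    })
    names(rankings) <- c("S1", "S2", "S3")
    got <- ranking(consensusRank(rankings))$compound_id
    want <- oracle_consensus_order(lapply(rankings, function(r)
      stats::setNames(r$rank, r$compound_id)))
    expect_identical(got, want)
  }
})

test_that("consensus is invariant to the order structures are supplied", {
  set.seed(2)
  ids <- sprintf("c%02d", 1:15)
  rankings <- lapply(1:3, function(s)
    data.frame(compound_id = ids, rank = sample(15)))
  names(rankings) <- c("S1", "S2", "S3")
  a <- consensusRank(rankings)
  b <- consensusRank(rankings[c(3, 1, 2)])
  expect_identical(ranking(a), ranking(b))
  expect_identical(a@structureIds, b@structureIds)
})

test_that("rank sums are conserved over the full compound set", {
  set.seed(4)
  ids <- sprintf("c%02d", 1:12)
  rankings <- lapply(1:3, function(s)
    data.frame(compound_id = ids, rank = sample(12)))
  names(rankings) <- paste0("S", 1:3)
  tab <- ranking(consensusRank(rankings))
  expect_identical(sum(tab$consensus_score), 3L * sum(1:12))
})

test_that("compound scoring composes profiles, models and ranking", {
  pocket1 <- generatePocket(6, seed = 31, id = "X1")
  pocket2 <- generatePocket(6, seed = 32, id = "X2")
  receptors <- list(X1 = pocket1, X2 = pocket2)
  res1 <- residues(pocket1); res2 <- residues(pocket2)
  mk_model <- function(pocket, resnos, kinds) {
    res <- residues(pocket)
    entries <- data.frame(chain = "A", resno = resnos,
                          resname = res$resname[match(resnos, res$resno)],
                          kind = kinds,
                          subtype = ifelse(kinds == "HB", "donor", "alkyl"),
                          count = 30L, frequency = 1.0,
                          stringsAsFactors = FALSE)
    identifyPharmacological(new("FrequencyTable",
                                structureId = structureId(pocket),
                                nPoses = 30L, entries = entries))
  }
  models <- list(X1 = mk_model(pocket1, res1$resno[c(1, 2)], c("HB", "HP")),
                 X2 = mk_model(pocket2, res2$resno[c(1, 3)], c("HB", "HP")))
  poses <- list(
    plantPose(pocket1, data.frame(resno = res1$resno[c(1, 2)],
                                  kind = c("HB", "HP")), seed = 1,
              compoundId = "full", dockingScore = -7),
    plantPose(pocket1, data.frame(resno = res1$resno[2], kind = "HP"),
              seed = 2, compoundId = "half", dockingScore = -9),
    plantPose(pocket1, data.frame(), seed = 3, compoundId = "none",
              dockingScore = -12),
    plantPose(pocket2, data.frame(resno = res2$resno[c(1, 3)],
                                  kind = c("HB", "HP")), seed = 4,
              compoundId = "full", dockingScore = -6),
    plantPose(pocket2, data.frame(), seed = 5, compoundId = "half",
              dockingScore = -5))
  scored <- scoreCompoundSet(poses, models, receptors)
  x1 <- scored$X1
  expect_identical(x1$N[x1$compound_id == "full"], 2L)
  expect_identical(x1$N[x1$compound_id == "half"], 1L)
  expect_identical(x1$N[x1$compound_id == "none"], 0L)
  expect_equal(x1$S, x1$N - 0.01 * x1$D)
  # "none" docked best but interactions dominate the ranking
  expect_identical(x1$compound_id[1], "full")

  # compound missing on X2 ("none") gets K+1 in the consensus
  cr <- ranking(consensusRank(lapply(scored, function(t)
    t[, c("compound_id", "rank")])))
  expect_identical(cr$rank_X2[cr$compound_id == "none"], 3L)

  # all-N-zero degenerate case reduces to the docking ranking
  models0 <- list(
    X1 = mk_model(pocket1, res1$resno[5], "HB"),
    X2 = mk_model(pocket2, res2$resno[5], "HB"))
  scored0 <- scoreCompoundSet(poses, models0, receptors)
  expect_true(all(scored0$X1$N == 0))
  expect_identical(scored0$X1$compound_id,
                   c("none", "half", "full"))  # by D ascending
})
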