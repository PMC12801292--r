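# The designed 10-compound library: exactly one compound fails at each
# cascade stage (in default stage order), five pass everything.
.designed_library <- function() c(
  acylcl    = "CC(=O)Cl",                   # HTS: acyl halide
  fatty     = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",  # Lipinski: logP > 5
  peg       = "OCCOCCOCCOCCOCCOCCO",        # Veber: > 10 rotatable bonds
  catechol  = "Oc1ccccc1O",                 # PAINS: catechol_A
  hydraz    = "NNC(=O)NN",                  # QED < 0.25
  benzamide = "NC(=O)c1ccccc1",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  caffeine  = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  aspirin   = "CC(=O)Oc1ccccc1C(=O)O",
  crown     = "C1COCCOCCOCCOCCOCCO1")

test_that("the HTS filter rejects nonorganic atoms and reactive groups", {
  sdf <- smilesToSDFset(c(tms = "C[Si](C)(C)CC", benzamide = "NC(=O)c1ccccc1",
                          acylcl = "ClC(=O)c1ccccc1"))
  h <- htsFilter(sdf)
  expect_identical(h$pass, c(FALSE, TRUE, FALSE))
  expect_match(h$reason[1], "nonorganic:Si")
  expect_match(h$reason[3], "acyl_halide")
})

test_that("Lipinski violations use strict boundaries and a violation limit", {
  sdf <- smilesToSDFset(c(ethanol = "CCO"))
  l <- lipinskiPass(sdf)
  expect_true(l$pass)
  expect_identical(l$n_violations, 0)

  # constructed descriptor rows exercise the boundary logic directly
  d <- data.frame(id = c("at500", "over"), MW = c(500, 600),
                  logP = c(5, 6), HBD = c(5, 0), HBA_NO = c(10, 0))
  l2 <- lipinskiPass(d)
  expect_true(l2$pass[1])                 # rule is ">": 500/5/5/10 is clean
  expect_identical(l2$n_violations[1], 0)
  expect_identical(l2$n_violations[2], 2) # MW > 500 and logP > 5
  expect_false(l2$pass[2])
  expect_false(lipinskiPass(d, maxViolations = 2)$pass[2])
  expect_true(lipinskiPass(d[2, , drop = FALSE], maxViolations = 3)$pass)
})

test_that("Veber checks rotatable bonds and TPSA", {
  sdf <- smilesToSDFset(c(benzene = "c1ccccc1",
                          c20 = "CCCCCCCCCCCCCCCCCCCC"))
  v <- veberPass(sdf)
  expect_true(v$pass[1])
  expect_identical(v$ROTB[1], 0L)
  expect_equal(v$TPSA[1], 0)
  expect_false(v$pass[2])
  expect_gt(v$ROTB[2], 10)
})

test_that("rotatable-bond counting follows the acyclic non-terminal rule", {
  sdf <- smilesToSDFset(c(
    butane = "CCCC",          # 1 rotatable (the central bond)
    benzamide = "NC(=O)c1ccccc1",  # ring-C(=O) bond only; amide excluded
    tbu = "CC(C)(C)C"))       # all bonds terminal -> 0
  d <- moleculeDescriptors(sdf)
  expect_identical(d$ROTB, c(1L, 1L, 0L))
})

test_that("PAINS flags use the published catalogue and are order-invariant", {
  sdf <- smilesToSDFset(c(toluene = "Cc1ccccc1",
                          enerho = "O=C1N(C)C(=S)SC1=Cc1ccccc1"))
  p <- painsFlag(sdf)
  expect_length(p$toluene, 0)
  expect_true(any(grepl("ene_rhod", p$enerho)))

  # the same structure written with different atom orders matches equally
  sdf2 <- smilesToSDFset(c(a = "Oc1ccccc1O", b = "c1cc(O)c(O)cc1"))
  p2 <- painsFlag(sdf2)
  expect_identical(sort(p2$a), sort(p2$b))
  expect_true(any(grepl("catechol", p2$a)))
})

test_that("QED desirability math reproduces published-parameter values", {
  # frozen reference values computed from the published ADS parameters
  c1 <- list(MW = 300, logP = 2.5, HBA = 4, HBD = 1, TPSA = 70,
             ROTB = 5, AROM = 2, ALERTS = 0)
  c2 <- list(MW = 520, logP = 6.1, HBA = 11, HBD = 6, TPSA = 150,
             ROTB = 12, AROM = 4, ALERTS = 3)
  c3 <- list(MW = 76.1, logP = -1.3, HBA = 2, HBD = 2, TPSA = 60,
             ROTB = 0, AROM = 0, ALERTS = 1)
  expect_equal(qedScore(c1, "mean"), 0.920698210151, tolerance = 1e-9)
  expect_equal(qedScore(c2, "mean"), 0.073110171264, tolerance = 1e-9)
  expect_equal(qedScore(c3, "mean"), 0.352187252910, tolerance = 1e-9)
  expect_equal(qedScore(c1, "unit"), 0.927483589235, tolerance = 1e-9)
  expect_equal(qedScore(c3, "unit"), 0.424041171027, tolerance = 1e-9)
})

test_that("the QED cutoff is strict below, retaining the boundary", {
  d <- data.frame(id = c("a", "b"), MW = c(300, 300), logP = c(2.5, 2.5),
                  HBA = c(4, 4), HBD = c(1, 1), TPSA = c(70, 70),
                  ROTB = c(5, 5), AROM = c(2, 2), ALERTS = c(0, 0))
  q <- qedScore(d)
  out <- qedFilter(d, threshold = q[1])  # exactly at the cutoff
  expect_true(all(out$pass))
  out2 <- qedFilter(d, threshold = q[1] + 1e-9)
  expect_false(any(out2$pass))
})

test_that("a sugar-like polyol scores as poorly drug-like", {
  sdf <- smilesToSDFset(c(glucitolish = "OCC(O)C(O)C(O)C(O)CO"))
  q <- qedFilter(sdf, threshold = 0.25)
  expect_lt(q$qed, 0.4)
})

test_that("the filter chain removes one designed failure per stage", {
  sdf <- smilesToSDFset(.designed_library())
  out <- applyFilterChain(sdf)
  st <- filterStages(out$report)
  expect_identical(st$stage, c("hts", "lipinski", "veber", "pains", "qed"))
  expect_identical(st$n_input, c(10L, 9L, 8L, 7L, 6L))
  expect_identical(st$n_removed, rep(1L, 5))
  expect_identical(st$n_passed, c(9L, 8L, 7L, 6L, 5L))
  rem <- removedCompounds(out$report)
  expect_identical(rem$compound_id[rem$stage == "hts"], "acylcl")
  expect_identical(rem$compound_id[rem$stage == "lipinski"], "fatty")
  expect_identical(rem$compound_id[rem$stage == "veber"], "peg")
  expect_identical(rem$compound_id[rem$stage == "pains"], "catechol")
  expect_identical(rem$compound_id[rem$stage == "qed"], "hydraz")
  expect_setequal(ChemmineR::cid(out$survivors),
                  c("benzamide", "ibuprofen", "caffeine", "aspirin",
                    "crown"))
  # every removal carries a machine-readable reason
  expect_true(all(nzchar(rem$reason)))
})

test_that("the chain is idempotent and order changes keep the final set", {
  sdf <- smilesToSDFset(.designed_library())
  out <- applyFilterChain(sdf)
  again <- applyFilterChain(out$survivors)
  expect_identical(sum(filterStages(again$report)$n_removed), 0L)
  expect_setequal(ChemmineR::cid(again$survivors),
                  ChemmineR::cid(out$survivors))

  perm <- filterConfig(stages = c("qed", "pains", "veber", "lipinski",
                                  "hts"))
  out2 <- applyFilterChain(sdf, perm)
  expect_setequal(ChemmineR::cid(out2$survivors),
                  ChemmineR::cid(out$survivors))
})

test_that("an empty library produces an empty, zero-count report", {
  sdf <- smilesToSDFset(c(a = "CCO"))
  out <- applyFilterChain(sdf[integer(0)])
  expect_identical(length(out$survivors), 0L)
  expect_true(all(filterStages(out$report)$n_input == 0L))
})
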