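test_that("pearson correlation handles perfect, inverse and degenerate profiles", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(pearsonCorrelation(c(1, 2), c(1, 2, 3)), "length")
})

test_that("co-clustering probability is the ECC x PCC product with neutral missing data", {
  net <- triangleNet()
  ecc <- edgeClusteringCoefficient(net)
  expr <- rbind(
    a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1)
  )
  expect_equal(coClusterProbability(ecc, expr, "a", "b"), 0.5 * 1)
  expect_equal(coClusterProbability(ecc, expr, "a", "c"), 0.5 * -1)
  expect_equal(coClusterProbability(ecc, expr[1:2, ], "a", "c"), 0)
  expect_error(coClusterProbability(ecc, expr, "a", "z"), "not scored")
})

test_that("PeC sums co-clustering over neighbors and is bounded by NC", {
  net <- triangleNet()
  # all pairwise PCC = 1 -> PeC = sum of incident ECC = 1 per node
  expr <- rbind(a = 1:4, b = 2 * (1:4), c = (1:4) + 10)
  expect_equal(unname(pecScores(net, expr)), rep(1, 3))
  iso <- proteinNetwork(rbind(c("a", "b")), nodes = "z")
  expect_equal(pecScores(iso, expr)[["z"]], 0)

  set.seed(21)
  rnet <- randomSimpleNet(25L, 0.3)
  rexpr <- matrix(rnorm(25 * 8), 25, 8,
                  dimnames = list(proteins(rnet), paste0("t", 1:8)))
  pec <- pecScores(rnet, rexpr)
  expect_equal(pec, bruteForcePeC(rnet, rexpr), tolerance = 1e-12)
  expect_true(all(pec <= neighborhoodCentrality(rnet) + 1e-12))
})

test_that("location frequencies are the essential-record distribution", {
  sub <- data.frame(
    protein = c("e1", "e1", "e2", "x"),
    location = c("nucleus", "cytosol", "nucleus", "peroxisome")
  )
  freq <- locationFrequencies(sub, c("e1", "e2"))
  expect_equal(freq[["nucleus"]], 2 / 3)
  expect_equal(freq[["cytosol"]], 1 / 3)
  expect_equal(freq[["peroxisome"]], 0)
  expect_equal(sum(freq), 1)
  expect_error(locationFrequencies(sub, "nobody"), "undefined")
  # excluding a benchmark protein removes its records from the estimate
  freqEx <- locationFrequencies(sub, c("e1", "e2"), exclude = "e1")
  expect_equal(freqEx[["nucleus"]], 1)
})

test_that("SL sums a protein's own location frequencies", {
  sub <- data.frame(
    protein = c("e1", "e1", "e2", "x"),
    location = c("nucleus", "cytosol", "nucleus", "peroxisome")
  )
  freq <- locationFrequencies(sub, c("e1", "e2"))
  sl <- slScores(sub, freq)
  expect_equal(sl[["e1"]], 1)          # 2/3 + 1/3
  expect_equal(sl[["e2"]], 2 / 3)
  expect_equal(sl[["x"]], 0)           # only the essential-free location
  expect_false("absent" %in% names(sl))
  expect_true(all(sl >= 0 & sl <= 1))
})

test_that("PC counts complex memberships with the double-counting identity", {
  cx <- list(c("a", "b"), c("a", "c", "d"), c("b", "a"))
  pc <- pcScores(cx)
  expect_equal(pc[["a"]], 3L)
  expect_equal(pc[["d"]], 1L)
  expect_equal(sum(pc), sum(lengths(cx)))
  # removing a complex never increases any count
  pc2 <- pcScores(cx[-2L])
  expect_true(all(pc2[names(pc2)] <= pc[names(pc2)]))
})

test_that("the assembled score table covers all proteins with neutral defaults", {
  ds <- smallDataset(seed = 3L)
  tab <- scoreDataset(ds)
  expect_setequal(tab$protein, proteins(ds@network))
  expect_true(all(tab$sl >= 0 & tab$sl <= 1))
  expect_true(all(tab$pc >= 0 & tab$pc == round(tab$pc)))
  nc <- neighborhoodCentrality(ds@network)
  expect_true(all(tab$pec <= nc[tab$protein] + 1e-12))
  # a protein only present in a biological file still gets a row
  sub2 <- rbind(ds@subcellular,
                data.frame(protein = "GHOST", location = "loc01"))
  tab2 <- proteinScores(ds@network, ds@expression, sub2, ds@complexes,
                        ds@essentials)
  expect_true("GHOST" %in% tab2$protein)
  expect_equal(tab2$pec[tab2$protein == "GHOST"], 0)
})
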