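test_that("edge clustering coefficient matches hand values and the brute-force oracle", {
  tri <- triangleNet()
  expect_equal(unname(edgeClusteringCoefficient(tri)), rep(1 / 2, 3))
  expect_equal(unname(edgeClusteringCoefficient(pathNet())), c(0, 0))
  expect_equal(unname(edgeClusteringCoefficient(completeNet(4L))), rep(2 / 3, 6))

  set.seed(101)
  for (rep in 1:30) {
    net <- randomSimpleNet(sample(5:25, 1L), runif(1, 0.2, 0.5))
    if (numEdges(net) == 0L) next
    ecc <- edgeClusteringCoefficient(net)
    expect_identical(ecc, bruteForceECC(net))
    expect_true(all(ecc >= 0 & ecc <= 1))
  }
})

test_that("degree centrality reads off the adjacency structure", {
  star <- starNet(5L)
  dc <- degreeCentrality(star)
  expect_equal(dc[["hub"]], 5)
  expect_equal(dc[["l01"]], 1)
  iso <- proteinNetwork(rbind(c("a", "b")), nodes = "z")
  expect_equal(degreeCentrality(iso)[["z"]], 0)
})

test_that("subgraph centrality agrees with spectral closed forms", {
  # K2: closed walks of even length l contribute 1/l! -> cosh(1)
  expect_equal(unname(subgraphCentrality(completeNet(2L))),
               rep(cosh(1), 2), tolerance = 1e-10)
  # K3: eigenvalues 2, -1, -1
  expect_equal(unname(subgraphCentrality(completeNet(3L))),
               rep((exp(2) + 2 * exp(-1)) / 3, 3), tolerance = 1e-10)
  # isolated node: exp of a zero matrix
  iso <- proteinNetwork(rbind(c("a", "b")), nodes = "z")
  expect_equal(subgraphCentrality(iso)[["z"]], 1, tolerance = 1e-10)
  # series fallback must agree with the spectral path
  set.seed(11)
  net <- randomSimpleNet(15L, 0.3)
  expect_equal(subgraphCentrality(net),
               subgraphCentrality(net, seriesThreshold = 1L),
               tolerance = 1e-8)
  expect_true(all(subgraphCentrality(net) >= 1))
})

test_that("eigenvector centrality is the non-negative unit-norm Perron vector per component", {
  ec <- eigenvectorCentrality(completeNet(3L))
  expect_equal(unname(ec), rep(1 / sqrt(3), 3), tolerance = 1e-10)
  # path a-b-c: eigenvector (1, sqrt(2), 1)/2
  ecp <- eigenvectorCentrality(pathNet())
  expect_equal(ecp[["b"]] / ecp[["a"]], sqrt(2), tolerance = 1e-10)
  # vertex-transitive ring: all equal
  ring <- netFromPairs("a", "b", "b", "c", "c", "d", "d", "e", "e", "a")
  expect_equal(diff(range(eigenvectorCentrality(ring))), 0, tolerance = 1e-10)
  # disconnected: per-component unit norm, isolated nodes 0
  two <- proteinNetwork(rbind(c("a", "b"), c("x", "y")), nodes = "z")
  ec2 <- eigenvectorCentrality(two)
  expect_equal(sum(ec2[c("a", "b")]^2), 1, tolerance = 1e-10)
  expect_equal(sum(ec2[c("x", "y")]^2), 1, tolerance = 1e-10)
  expect_equal(ec2[["z"]], 0)
  expect_true(all(ec2 >= 0))
})

test_that("information centrality is symmetric on transitive graphs and favors path centers", {
  ic2 <- informationCentrality(completeNet(2L))
  expect_equal(diff(range(ic2)), 0, tolerance = 1e-10)
  ic3 <- informationCentrality(completeNet(3L))
  expect_equal(diff(range(ic3)), 0, tolerance = 1e-10)
  icp <- informationCentrality(pathNet())
  expect_gt(icp[["b"]], icp[["a"]])
  expect_equal(icp[["a"]], icp[["c"]], tolerance = 1e-12)
  # independent 3x3 oracle for the path: B = D - A + J, C = B^-1
  B <- diag(c(1, 2, 1)) - rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)) + 1
  C <- solve(B)
  oracle <- 3 / (3 * diag(C) + sum(diag(C)) - 2 * rowSums(C))
  expect_equal(unname(icp[c("a", "b", "c")]), oracle, tolerance = 1e-12)
})

test_that("local average connectivity counts induced-neighborhood degrees", {
  expect_equal(unname(localAverageConnectivity(completeNet(4L))), rep(2, 4))
  lacs <- localAverageConnectivity(starNet(4L))
  expect_equal(unname(lacs), rep(0, 5))
})

test_that("neighborhood centrality sums incident edge clustering", {
  expect_equal(unname(neighborhoodCentrality(triangleNet())), rep(1, 3))
  expect_equal(unname(neighborhoodCentrality(pathNet())), rep(0, 3))
  iso <- proteinNetwork(rbind(c("a", "b")), nodes = "z")
  expect_equal(neighborhoodCentrality(iso)[["z"]], 0)
})

test_that("every centrality assigns one finite value per node and ranks deterministically", {
  set.seed(5)
  net <- randomSimpleNet(20L, 0.25)
  for (fn in list(degreeCentrality, subgraphCentrality, eigenvectorCentrality,
                  informationCentrality, localAverageConnectivity,
                  neighborhoodCentrality)) {
    v <- fn(net)
    expect_identical(names(v), proteins(net))
    expect_true(all(is.finite(v)))
  }
  expect_equal(centralityRanking(c(a = 3, b = 5, c = 3)), c("b", "a", "c"))
})
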