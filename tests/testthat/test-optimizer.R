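optFixture <- function(seed = 2L) {
  ds <- smallDataset(seed = seed)
  list(ds = ds, scores = scoreDataset(ds))
}

test_that("initialization builds a degree-elite population with beta perturbation", {
  fx <- optFixture()
  ctl0 <- fpeControl(Q = 20L, beta = 0, popSize = 5L)
  set.seed(1)
  st <- initializePopulation(fx$ds@network, fx$scores, ctl0)
  elite <- st$population[[1L]]$members
  deg <- degrees(fx$ds@network)
  ids <- proteins(fx$ds@network)
  expect_equal(elite, ids[order(-deg, ids, method = "radix")][1:20])
  # beta = 0: every pollen identical to the elite
  for (p in st$population) expect_setequal(p$members, elite)

  ctl1 <- fpeControl(Q = 20L, beta = 1, popSize = 5L)
  set.seed(1)
  st1 <- initializePopulation(fx$ds@network, fx$scores, ctl1)
  expect_setequal(st1$population[[1L]]$members, elite)
  for (p in st1$population) {
    expect_length(unique(p$members), 20L)
    expect_true(all(p$members %in% ids))
  }
  expect_error(
    initializePopulation(fx$ds@network, fx$scores,
                         fpeControl(Q = 10000L)),
    "exceeds"
  )
})

test_that("global pollination preserves cardinality and has the gamma=1 fixed point", {
  fx <- optFixture()
  ctl <- fpeControl(Q = 15L)
  set.seed(4)
  st <- initializePopulation(fx$ds@network, fx$scores, ctl)
  gb <- st$gbest
  # pollen == gbest, gamma = 1: position unchanged
  fixed <- globalPollination(gb, gb, st$nodes, st$gsc,
                             fpeControl(Q = 15L, gamma = 1))
  expect_setequal(fixed$members, gb$members)
  expect_equal(fixed$fitness, gb$fitness)
  # disjoint pollen: the result is an entirely random refill, still size Q
  disjoint <- list(members = setdiff(st$nodes, gb$members)[1:15], fitness = 0)
  for (rep in 1:20) {
    out <- globalPollination(disjoint, gb, st$nodes, st$gsc, ctl)
    expect_length(unique(out$members), 15L)
    expect_true(all(out$members %in% st$nodes))
  }
})

test_that("local pollination is the identity and idempotent", {
  pollen <- list(members = c("a", "b"), fitness = 1.5)
  expect_identical(localPollination(pollen), pollen)
  expect_identical(localPollination(localPollination(pollen)), pollen)
})

test_that("stepping keeps pollen invariants and a non-decreasing gbest trace", {
  fx <- optFixture()
  ctl <- fpeControl(Q = 25L, popSize = 10L)
  set.seed(11)
  st <- initializePopulation(fx$ds@network, fx$scores, ctl)
  for (t in 1:40) {
    st <- fpeStep(st, ctl)
    for (p in st$population) {
      expect_length(unique(p$members), 25L)
      expect_true(all(p$members %in% proteins(fx$ds@network)))
      expect_equal(p$fitness, sum(st$gsc[p$members]))
    }
  }
  expect_true(all(diff(st$history) >= 0))
  expect_equal(st$gbest$fitness, max(st$history))
})

test_that("p = 0 makes the run a no-op beyond initialization", {
  fx <- optFixture()
  ctl <- fpeControl(Q = 20L, p = 0, iterations = 30L)
  set.seed(3)
  st <- initializePopulation(fx$ds@network, fx$scores, ctl)
  bestInit <- st$gbest
  res <- runFPE(fx$ds@network, fx$scores, ctl, seed = 3)
  expect_setequal(gbestMembers(res), bestInit$members)
  expect_equal(res@fitness, bestInit$fitness)
  expect_equal(length(unique(fitnessHistory(res))), 1L)
})

test_that("identical seeds give byte-identical results; T_max = 0 returns the elite ranking", {
  fx <- optFixture()
  ctl <- fpeControl(Q = 20L, iterations = 60L)
  r1 <- runFPE(fx$ds@network, fx$scores, ctl, seed = 99)
  r2 <- runFPE(fx$ds@network, fx$scores, ctl, seed = 99)
  expect_identical(gscRanking(r1), gscRanking(r2))
  expect_identical(fitnessHistory(r1), fitnessHistory(r2))

  r0 <- runFPE(fx$ds@network, fx$scores,
               fpeControl(Q = 20L, iterations = 0L), seed = 5)
  set.seed(5)
  st0 <- initializePopulation(fx$ds@network, fx$scores,
                              fpeControl(Q = 20L, iterations = 0L))
  expect_setequal(gbestMembers(r0), st0$gbest$members)
  expect_length(fitnessHistory(r0), 1L)
})

test_that("higher gbest retention converges better on average (gamma sensitivity)", {
  ds <- generateDataset(nProteins = 60L, nComplexes = 3L,
                        complexSizeRange = c(3L, 6L), seed = 11L)
  sc <- scoreDataset(ds)
  frac <- function(gamma) {
    mean(vapply(1:3, function(s) {
      runFPE(ds@network, sc,
             fpeControl(Q = 8L, iterations = 200L, gamma = gamma),
             seed = s)@fitness
    }, numeric(1)))
  }
  expect_gt(frac(0.9), frac(0.3))
})

test_that("the optimizer recovers a dominant planted optimum exactly", {
  # 60-protein fixture whose top-Q GSC values dominate: the closed-form
  # optimum (top-Q of the descending ranking) must be reached
  ds <- generateDataset(nProteins = 60L, nComplexes = 3L,
                        complexSizeRange = c(3L, 6L), seed = 21L)
  sc <- scoreDataset(ds)
  res <- runFPE(ds@network, sc, fpeControl(Q = 8L, iterations = 500L),
                seed = 7)
  oracle <- rankDescending(proteins(ds@network), sc)$protein[1:8]
  expect_setequal(gbestMembers(res), oracle)
})
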