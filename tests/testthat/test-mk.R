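test_that("constraint patterns have the documented free-parameter counts", {
  expect_equal(mkPattern("two-state", "ER")$K, 1)
  expect_equal(mkPattern("two-state", "ARD")$K, 2)
  expect_equal(mkPattern("two-state", "NR")$K, 1)
  Ks <- c(ER = 1, SYM = 6, ARD = 12, `NR-ER` = 1, `NR-SYM` = 6,
          `NR-ARD` = 9, `NR-ALL` = 3)
  for (m in names(Ks)) {
    expect_equal(mkPattern("four-state", m)$K, unname(Ks[m]), info = m)
  }
  expect_error(mkPattern("two-state", "SYM"), "unknown")

  # NR variants force every diving -> non-diving rate to zero
  dive <- c("plunge", "foot", "wing")
  for (m in c("NR-ER", "NR-SYM", "NR-ARD", "NR-ALL")) {
    pat <- mkPattern("four-state", m)$pattern
    expect_true(all(pat[dive, "non-diving"] == 0), info = m)
  }
  # NR-ALL additionally forbids transitions among diving states
  patA <- mkPattern("four-state", "NR-ALL")$pattern
  expect_true(all(patA[dive, dive] == 0))
  expect_equal(sort(unique(patA["non-diving", dive])), 1:3)
  # two-state NR: diving -> non-diving fixed at zero
  patN <- mkPattern("two-state", "NR")$pattern
  expect_equal(patN["diving", "non-diving"], 0L)
})

test_that("matrix exponential rows sum to one and obey NR structure", {
  set.seed(5)
  for (k in 2:4) {
    Q <- randomQ(k)
    for (t in c(0, 0.3, 7, 100)) {
      P <- ratchetphy:::cpp_expm(unname(Q), t)
      expect_equal(rowSums(P), rep(1, k), tolerance = 1e-9)
      expect_true(all(P >= -1e-12))
    }
  }
  # irreversibility: no probability can flow diving -> non-diving under NR
  Qnr <- buildQ(mkPattern("two-state", "NR"), 0.05)
  P <- ratchetphy:::cpp_expm(unname(Qnr), 50)
  expect_equal(P[2, 1], 0)
})

test_that("two-state ER transition probability matches the closed form", {
  q <- 0.07
  Q <- buildQ(mkPattern("two-state", "ER"), q)
  for (t in c(0.1, 1, 5, 20)) {
    P <- ratchetphy:::cpp_expm(unname(Q), t)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * q * t), tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force enumeration on small trees", {
  # trivial case: zero rates, cherry, both tips state 1
  cherry <- readNewick("(A:1,B:1);")
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mkLoglik(cherry, c(A = "a", B = "a"), Q0, c(0.5, 0.5)),
               log(0.5))
  set.seed(7)
  for (case in 1:8) {
    n <- sample(4:6, 1)
    k <- sample(2:4, 1)
    tr <- randomTree(n, seed = 300 + case)
    Q <- randomQ(k, scale = 0.3)
    st <- setNames(sample(rownames(Q), n, replace = TRUE), tr$tip.label)
    pi <- rep(1 / k, k)
    expect_equal(mkLoglik(tr, st, Q, pi), mkBruteForce(tr, st, Q, pi),
                 tolerance = 1e-8, info = paste("case", case))
  }
})

test_that("likelihood is invariant to tip ordering", {
  tr <- randomTree(15, seed = 41)
  Q <- randomQ(3, 0.2)
  st <- setNames(sample(rownames(Q), 15, replace = TRUE), tr$tip.label)
  l1 <- mkLoglik(tr, st, Q, rep(1 / 3, 3))
  l2 <- mkLoglik(tr, st[sample(names(st))], Q, rep(1 / 3, 3))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("ML fitting respects model nesting and handles constant traits", {
  set.seed(13)
  for (rep in 1:5) {
    tr <- randomTree(40, seed = 500 + rep)
    sim <- simulateDiscrete(tr, buildQ(mkPattern("two-state", "NR"), 0.02),
                            "non-diving", seed = rep)
    if (length(unique(sim$tip_states)) < 2) next
    fnr <- fitMkModel(tr, sim$tip_states, mkPattern("two-state", "NR"),
                      restarts = 3, seed = 1)
    fard <- fitMkModel(tr, sim$tip_states, mkPattern("two-state", "ARD"),
                       restarts = 3, seed = 1)
    expect_gte(fard$logL, fnr$logL - 1e-6)
  }
  tr <- randomTree(10, seed = 77)
  const <- setNames(rep("non-diving", 10), tr$tip.label)
  f <- fitMkModel(tr, const, mkPattern("two-state", "ER"), seed = 1)
  expect_equal(f$rates, 1e-9)
  expect_equal(f$logL, log(0.5), tolerance = 1e-4)
})

test_that("fitted likelihood agrees with an independent implementation", {
  tr <- randomTree(60, seed = 91)
  sim <- simulateDiscrete(tr, buildQ(mkPattern("two-state", "ER"), 0.02),
                          "non-diving", seed = 4)
  ours <- fitMkModel(tr, sim$tip_states, mkPattern("two-state", "ER"),
                     restarts = 4, seed = 1)
  x <- factor(sim$tip_states[tr$tip.label], nicheStates2())
  names(x) <- tr$tip.label
  ref <- phytools::fitMk(tr, x, model = "ER", pi = c(0.5, 0.5))
  expect_equal(ours$logL, as.numeric(ref$logLik), tolerance = 1e-4)
  expect_equal(unname(ours$rates), ref$rates[1], tolerance = 0.02)
})

test_that("model batteries return complete ranked tables", {
  tr <- randomTree(80, seed = 19)
  Qt <- buildQ(mkPattern("four-state", "NR-ALL"),
               c(0.015, 0.008, 0.008))
  sim <- simulateDiscrete(tr, Qt, "non-diving", seed = 6)
  bat4 <- runMkBattery(tr, sim$tip_states, "four-state", restarts = 3,
                       seed = 2)
  expect_equal(nrow(bat4$comparison), 7)
  expect_equal(sum(bat4$comparison$weight), 1, tolerance = 1e-9)
  expect_equal(sort(bat4$comparison$name), sort(mkBatteryModels("four-state")))

  st2 <- setNames(ifelse(sim$tip_states == "non-diving", "non-diving",
                         "diving"), names(sim$tip_states))
  bat2 <- runMkBattery(tr, st2, "two-state", restarts = 3, seed = 2)
  expect_equal(nrow(bat2$comparison), 3)
  expect_equal(min(bat2$comparison$delta_AIC), 0)
})
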