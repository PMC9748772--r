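test_that("pure-birth limit matches the closed-form Yule likelihood", {
  tr <- simulateTree(0.12, 0, 30, seed = 5)
  lam <- 0.1
  p <- sseParams("dull null", tau = lam, eps = 1e-12, q01 = 1e-12,
                 q10 = 1e-12)
  ll <- sseLoglik(tr, setNames(rep("0", 30), tr$tip.label), p,
                  root = "obs")
  n <- ape::Ntip(tr)
  expect_equal(ll, (n - 2) * log(lam) - lam * sum(tr$edge.length),
               tolerance = 1e-5)
})

test_that("state-independent SSE factorizes into birth-death times Mk", {
  for (case in 1:4) {
    tr <- simulateTree(0.15, 0.05, 30, seed = 1100 + case)
    set.seed(case)
    lam <- runif(1, 0.08, 0.25)
    mu <- runif(1, 0.01, 0.8) * lam
    q01 <- runif(1, 0.005, 0.05)
    q10 <- runif(1, 0.005, 0.05)
    sim <- simulateDiscrete(tr, buildQ(mkPattern("two-state", "ARD"),
                                       c(q01, q10)), "non-diving",
                            seed = case)
    st <- setNames(ifelse(sim$tip_states == "diving", "1", "0"),
                   names(sim$tip_states))
    p <- sseParams("BiSSE", tau = rep(lam + mu, 2),
                   eps = rep(mu / lam, 2), q01 = q01, q10 = q10)
    ll_sse <- sseLoglik(tr, st, p, root = "equal")
    ll_mk <- mkLoglik(tr, sim$tip_states,
                      buildQ(mkPattern("two-state", "ARD"), c(q01, q10)),
                      "equal")
    expect_equal(ll_sse, bdLoglikOracle(tr, lam, mu) + ll_mk,
                 tolerance = 1e-4, info = paste("case", case))
  }
})

test_that("likelihood is invariant to swapping hidden-state labels", {
  tr <- simulateTree(0.15, 0.05, 40, seed = 11)
  set.seed(3)
  st <- setNames(sample(c("0", "1"), 40, replace = TRUE), tr$tip.label)
  p1 <- sseParams("HiSSE full", tau = c(0.2, 0.3, 0.25, 0.15),
                  eps = c(0.3, 0.5, 0.2, 0.6), q01 = 0.01, q10 = 0.02,
                  h = 0.005)
  p2 <- sseParams("HiSSE full", tau = c(0.3, 0.2, 0.15, 0.25),
                  eps = c(0.5, 0.3, 0.6, 0.2), q01 = 0.01, q10 = 0.02,
                  h = 0.005)
  expect_equal(sseLoglik(tr, st, p1), sseLoglik(tr, st, p2),
               tolerance = 1e-8)
})

test_that("extinction probabilities stay in bounds and vanish when mu=0", {
  tr <- simulateTree(0.15, 0.03, 25, seed = 13)
  st <- setNames(rep(c("0", "1"), length.out = 25), tr$tip.label)
  p <- sseParams("BiSSE", tau = c(0.3, 0.2), eps = c(0.5, 0.9),
                 q01 = 0.02, q10 = 0.02)
  po <- ratchetphy:::postorderEdges(tr)
  tipD <- matrix(0, 25, 2)
  for (i in 1:25) tipD[i, p$compound$obs == st[tr$tip.label][i]] <- 1
  res <- ratchetphy:::cpp_sse_loglik(po$edge, po$len, po$ntip, tipD,
                                     unname(p$lambda), unname(p$mu),
                                     unname(p$Qr), 1e-8, 1e-10, 0L,
                                     c(0.5, 0.5), TRUE)
  expect_true(all(res$rootE >= 0 & res$rootE <= 1))
  p0 <- sseParams("BiSSE", tau = c(0.3, 0.2), eps = c(0, 0), q01 = 0.02,
                  q10 = 0.02)
  res0 <- ratchetphy:::cpp_sse_loglik(po$edge, po$len, po$ntip, tipD,
                                      unname(p0$lambda), unname(p0$mu),
                                      unname(p0$Qr), 1e-8, 1e-10, 0L,
                                      c(0.5, 0.5), TRUE)
  expect_equal(unname(as.numeric(res0$rootE)), c(0, 0), tolerance = 1e-9)
})

test_that("turnover parameterization and net diversification behave", {
  expect_equal(netDiversification(list(lambda = 0.2, mu = 0.1)), 0.1)
  lm <- turnoverToRates(0.3, 0.5)
  expect_equal(lm$lambda, 0.2)
  expect_equal(lm$mu, 0.1)
  expect_equal(lm$lambda - lm$mu, 0.1)
  # extinction fraction above one implies decline
  lm2 <- turnoverToRates(0.3, 1.5)
  expect_lt(lm2$lambda - lm2$mu, 0)
})

test_that("the seven-scenario battery reports the published regime counts", {
  sim <- simulateSse(sseParams("BiSSE", tau = c(0.22, 0.33),
                               eps = c(0.1, 0.1), q01 = 0.01,
                               q10 = 0.002), 80, seed = 4)
  bat <- runSseBattery(sim$tree, sim$tip_states, restarts = 1, seed = 2)
  expect_equal(nrow(bat$comparison), 7)
  counts <- setNames(bat$comparison$regimes, bat$comparison$name)
  expect_equal(unname(counts[c("HiSSE full", "HiSSE null", "BiSSE null",
                               "HiSSE non-diving", "HiSSE diving",
                               "BiSSE", "dull null")]),
               c(4L, 4L, 2L, 3L, 3L, 2L, 1L))
  expect_equal(sum(bat$comparison$weight), 1, tolerance = 1e-9)
})

test_that("tip regime probabilities are coherent and symmetric", {
  tr <- simulateTree(0.15, 0.03, 12, seed = 19)
  set.seed(1)
  st <- setNames(sample(c("0", "1"), 12, replace = TRUE), tr$tip.label)
  # identical parameters for hidden classes A and B -> 0.5 / 0.5
  model <- sseModel("HiSSE full")
  psym <- sseParams(model, tau = c(0.25, 0.25, 0.2, 0.2),
                    eps = c(0.3, 0.3, 0.4, 0.4), q01 = 0.02, q10 = 0.01,
                    h = 0.01)
  fit <- structure(list(params = psym, model = model), class = "sseFit")
  pr <- tipRegimeProbs(fit, tr, st)
  for (i in seq_len(12)) {
    obs <- st[tr$tip.label][i]
    on <- pr[i, model$compound$obs == obs]
    expect_equal(unname(on), c(0.5, 0.5), tolerance = 1e-6)
    expect_equal(sum(pr[i, ]), 1, tolerance = 1e-9)
  }
  # marginalization identity: summing clamped likelihoods over a tip's
  # compatible states recovers the full likelihood
  pasym <- sseParams(model, tau = c(0.25, 0.4, 0.2, 0.1),
                     eps = c(0.3, 0.6, 0.4, 0.2), q01 = 0.02, q10 = 0.01,
                     h = 0.01)
  # linear root weightings make the likelihood linear in each tip's
  # initial condition, so clamped likelihoods must sum to the full one
  full <- sseLoglik(tr, st, pasym, root = "equal")
  po <- ratchetphy:::postorderEdges(tr)
  comp <- model$compound
  tipD <- matrix(0, 12, 4)
  for (i in 1:12) tipD[i, comp$obs == st[tr$tip.label][i]] <- 1
  for (i in c(1, 5, 9)) {
    lls <- vapply(which(tipD[i, ] == 1), function(j) {
      td <- tipD
      td[i, ] <- 0
      td[i, j] <- 1
      ratchetphy:::cpp_sse_loglik(po$edge, po$len, po$ntip, td,
                                  unname(pasym$lambda),
                                  unname(pasym$mu), unname(pasym$Qr),
                                  1e-8, 1e-10, 1L, rep(0.25, 4),
                                  TRUE)$logL
    }, numeric(1))
    m <- max(lls)
    expect_equal(m + log(sum(exp(lls - m))), full, tolerance = 1e-3)
  }
})

test_that("hidden regimes are weakly recoverable from simulated data", {
  p <- sseParams("HiSSE full", tau = c(0.12, 0.12, 0.45, 0.05),
                 eps = c(0.2, 0.2, 0.1, 0.9), q01 = 0.01, q10 = 0.002,
                 h = 0.004)
  sim <- simulateSse(p, 150, seed = 31)
  fit <- fitSse(sim$tree, sim$tip_states, "HiSSE full", restarts = 2,
                seed = 3)
  pr <- tipRegimeProbs(fit, sim$tree, sim$tip_states)
  truth <- sim$tip_regimes[rownames(pr)]
  # hidden labels are exchangeable in the fit; score both label mappings
  sc <- function(map) {
    mean(pr[cbind(seq_len(nrow(pr)), match(map[truth],
                                           colnames(pr)))])
  }
  ident <- setNames(c("0A", "0B", "1A", "1B"), c("0A", "0B", "1A", "1B"))
  swap <- setNames(c("0B", "0A", "1B", "1A"), c("0A", "0B", "1A", "1B"))
  expect_gt(max(sc(ident), sc(swap)), 0.5)
})
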