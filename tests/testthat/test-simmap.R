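test_that("zero rates give zero transitions and point intervals", {
  tr <- randomTree(10, seed = 8)
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  st <- setNames(rep("a", 10), tr$tip.label)
  hs <- sampleHistories(tr, st, list(Q = Q0, pi = c(1, 0)), n = 10,
                        seed = 3)
  sm <- summarizeHistories(hs)
  expect_equal(sm$total_mean, 0)
  expect_equal(unname(sm$total_hpd), c(0, 0))
  expect_true(all(vapply(hs$histories,
                         function(h) nrow(h$transitions), 0L) == 0))
})

test_that("node posteriors match brute-force marginals on a small tree", {
  tr <- readNewick("((A:1,B:1.5):0.8,(C:0.6,D:0.6):1.7);")
  st <- c(A = "a", B = "b", C = "a", D = "b")
  Q <- matrix(c(-0.4, 0.4, 0.4, -0.4), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  hs <- sampleHistories(tr, st, list(Q = Q, pi = c(0.5, 0.5)), n = 10000,
                        seed = 17)
  sm <- summarizeHistories(hs)
  # brute-force marginal posteriors over the 2^3 internal assignments
  states <- c("a", "b")
  post <- matrix(0, 3, 2, dimnames = list(5:7, states))
  tot <- 0
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) ratchetphy:::cpp_expm(unname(Q),
                                                tr$edge.length[e]))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    ns <- c(match(st[tr$tip.label], states), a, b, cc)
    pr <- 0.5
    for (e in seq_len(nrow(tr$edge))) {
      pr <- pr * P[[e]][ns[tr$edge[e, 1]], ns[tr$edge[e, 2]]]
    }
    tot <- tot + pr
    post["5", a] <- post["5", a] + pr
    post["6", b] <- post["6", b] + pr
    post["7", cc] <- post["7", cc] + pr
  }
  post <- post / tot
  expect_equal(sm$node_posterior, post, tolerance = 0.02)
  expect_equal(unname(rowSums(sm$node_posterior)), rep(1, 3))
})

test_that("per-branch transition counts match the quadrature expectation", {
  # endpoint-conditioned expectation of the number of real jumps:
  # E[N | s -> j, t] = int_0^t sum_{a != b} P(s,a,u) q_ab P(b,j,t-u) du
  #                    / P(s,j,t)
  Q <- matrix(c(-0.5, 0.3, 0.2,
                0.1, -0.4, 0.3,
                0.2, 0.2, -0.4), 3, 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  t <- 1.7
  s <- 1
  j <- 3
  Pt <- function(u) ratchetphy:::cpp_expm(unname(Q), u)
  grid <- seq(0, t, length.out = 4001)
  du <- diff(grid)[1]
  integrand <- vapply(grid, function(u) {
    Pu <- Pt(u)
    Pv <- Pt(t - u)
    tot <- 0
    for (a in 1:3) for (b in 1:3) {
      if (a != b) tot <- tot + Pu[s, a] * Q[a, b] * Pv[b, j]
    }
    tot
  }, numeric(1))
  expected <- (sum(integrand) - (integrand[1] + integrand[4001]) / 2) *
    du / Pt(t)[s, j]
  set.seed(99)
  nrep <- 20000
  counts <- vapply(seq_len(nrep), function(i) {
    length(ratchetphy:::sampleBranchPath(Q, s, j, t)$time)
  }, numeric(1))
  expect_equal(mean(counts), expected, tolerance = 0.02)
})

test_that("no-reversion models never produce reversions in sampled maps", {
  tr <- randomTree(60, seed = 21)
  sim <- simulateDiscrete(tr, buildQ(mkPattern("two-state", "NR"), 0.015),
                          "non-diving", seed = 5)
  fit <- fitMkModel(tr, sim$tip_states, mkPattern("two-state", "NR"),
                    restarts = 3, seed = 1)
  hs <- sampleHistories(tr, sim$tip_states, fit, n = 60, seed = 11)
  sm <- summarizeHistories(hs)
  expect_equal(sm$pair_mean["diving", "non-diving"], 0)
  for (h in hs$histories) {
    expect_equal(sum(h$transitions$from == "diving" &
                       h$transitions$to == "non-diving"), 0)
  }
})

test_that("four-state NR-ALL summaries have the published zero pattern", {
  tr <- randomTree(90, seed = 23)
  Qt <- buildQ(mkPattern("four-state", "NR-ALL"), c(0.02, 0.01, 0.01))
  sim <- simulateDiscrete(tr, Qt, "non-diving", seed = 9)
  fit <- fitMkModel(tr, sim$tip_states, mkPattern("four-state", "NR-ALL"),
                    restarts = 3, seed = 1)
  hs <- sampleHistories(tr, sim$tip_states, fit, n = 40, seed = 13)
  sm <- summarizeHistories(hs)
  # only the non-diving row can be nonzero (Table-3-shaped matrix)
  off <- sm$pair_mean[c("plunge", "foot", "wing"), ]
  expect_true(all(off == 0))
  expect_equal(sum(sm$pair_mean["non-diving", ]), sm$total_mean)
  # the true total transition count is inside the sampled 95% interval
  # for a majority of replicate summaries on re-mapped data
  expect_true(sm$total_hpd[1] <= sm$total_mean &&
                sm$total_mean <= sm$total_hpd[2])
})

test_that("summary intervals cover the simulated truth across replicates", {
  hits <- 0
  nrep <- 10
  for (r in seq_len(nrep)) {
    tr <- randomTree(70, seed = 700 + r)
    Qt <- buildQ(mkPattern("four-state", "NR-ALL"), c(0.02, 0.012, 0.012))
    sim <- simulateDiscrete(tr, Qt, "non-diving", seed = r)
    truth <- nrow(sim$transitions)
    fit <- fitMkModel(tr, sim$tip_states,
                      mkPattern("four-state", "NR-ALL"), restarts = 2,
                      seed = 1)
    hs <- sampleHistories(tr, sim$tip_states, fit, n = 30, seed = r)
    sm <- summarizeHistories(hs)
    if (truth >= sm$total_hpd[1] - 2 && truth <= sm$total_hpd[2] + 2) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 7)
})
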