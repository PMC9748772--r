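twoRegimePainting <- function(n, seed, q = 0.04) {
  tr <- randomTree(n, seed = seed)
  Q <- matrix(c(-q, q, q, -q), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  simulateDiscrete(tr, Q, "a", seed = seed + 1)$history
}

test_that("half-life reproduces the published conversions", {
  expect_equal(signif(halfLife(0.025), 3), 27.7)
  expect_equal(signif(halfLife(0.044), 3), 15.8)
  expect_equal(halfLife(log(2)), 1)
  expect_equal(halfLife(0), Inf)
  expect_error(halfLife(-0.1), ">= 0")
})

test_that("OU collapses to BM as alpha tends to zero", {
  for (case in 1:5) {
    tr <- randomTree(20, seed = 1300 + case)
    set.seed(case)
    y <- setNames(rnorm(20, 3, 0.8), tr$tip.label)
    s2 <- runif(1, 0.1, 1)
    llbm <- contLoglik(tr, y, "BM1", list(theta = 2.5, sigma2 = s2,
                                          x0 = 2.5))
    llou <- contLoglik(tr, y, "OU1", list(theta = 2.5, alpha = 1e-12,
                                          sigma2 = s2))
    expect_equal(llou, llbm, tolerance = 1e-5, info = paste(case))
  }
})

test_that("single-branch OU variance matches the closed form", {
  t <- 4.2
  alpha <- c(a = 0.3)
  s2 <- c(a = 0.7)
  tr <- readNewick(sprintf("(A:%g,B:%g);", t, t))
  pt <- paintFromTips(tr, c(A = "a", B = "a"), "a")
  str <- ratchetphy:::contStructure(pt, alpha, s2)
  expect_equal(str$V[1], s2[["a"]] / (2 * alpha[["a"]]) *
                 (1 - exp(-2 * alpha[["a"]] * t)), tolerance = 1e-12)
  expect_equal(str$A[1], alpha[["a"]] * t)
})

test_that("multi-regime OU moments match the path-product oracle", {
  pt <- twoRegimePainting(12, seed = 41)
  alpha <- c(a = 0.08, b = 0.3)
  s2 <- c(a = 0.4, b = 0.1)
  theta <- c(a = 1, b = 3)
  x0 <- 1
  oracle <- ouPathOracle(pt, alpha, s2, theta, x0)
  str <- ratchetphy:::contStructure(pt, alpha, s2)
  C <- ratchetphy:::contCovariance(str, ape::mrca(pt))
  tips <- seq_len(12)
  mu <- as.numeric(str$W[tips, ] %*% theta + str$c0[tips] * x0)
  expect_equal(mu, unname(oracle$mean), tolerance = 1e-10)
  expect_equal(C, unname(oracle$C), tolerance = 1e-10)
  # and the assembled likelihood agrees with an eigen-based MVN density
  set.seed(7)
  y <- setNames(rnorm(12, 2, 1), pt$tip.label)
  ll <- contLoglik(pt, y, "OUMVA", list(theta = theta, alpha = alpha,
                                        sigma2 = s2, x0 = x0))
  expect_equal(ll, dmvnormEigen(y[pt$tip.label], oracle$mean, oracle$C),
               tolerance = 1e-8)
})

test_that("likelihood is invariant to tip value ordering", {
  pt <- twoRegimePainting(15, seed = 43)
  set.seed(4)
  y <- setNames(rnorm(15, 2, 1), pt$tip.label)
  pars <- list(theta = c(a = 2, b = 3), alpha = c(a = 0.05, b = 0.1),
               sigma2 = c(a = 0.3, b = 0.2))
  expect_equal(contLoglik(pt, y, "OUMVA", pars),
               contLoglik(pt, y[sample(names(y))], "OUMVA", pars),
               tolerance = 1e-12)
})

test_that("star phylogeny likelihoods reduce to iid normal", {
  n <- 15
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(2, n)
  set.seed(5)
  y <- setNames(rnorm(n, 1, 0.5), tr$tip.label)
  llbm <- contLoglik(tr, y, "BM1", list(theta = 0.8, sigma2 = 0.3,
                                        x0 = 0.8))
  expect_equal(llbm, sum(dnorm(y, 0.8, sqrt(0.3 * 2), log = TRUE)),
               tolerance = 1e-8)
  a <- 0.4
  llou <- contLoglik(tr, y, "OU1", list(theta = 0.8, alpha = a,
                                        sigma2 = 0.3))
  vr <- 0.3 / (2 * a) * (1 - exp(-2 * a * 2))
  expect_equal(llou, sum(dnorm(y, 0.8, sqrt(vr), log = TRUE)),
               tolerance = 1e-8)
})

test_that("fits respect the nesting hierarchy of the OU family", {
  for (case in 1:2) {
    pt <- twoRegimePainting(60, seed = 1400 + case)
    y <- simulateContinuous(pt, "OUMV",
                            list(theta = c(a = 2, b = 3.5),
                                 alpha = 0.06,
                                 sigma2 = c(a = 0.2, b = 0.05)),
                            seed = case)
    lls <- vapply(c("OU1", "OUM", "OUMV", "OUMVA"), function(m) {
      fitCont(pt, y, m, restarts = 2, seed = 1)$logL
    }, numeric(1))
    expect_true(all(diff(lls) > -1e-4), info = paste(lls, collapse = " "))
  }
})

test_that("EB at rate zero matches BM and Trend warns when unidentified", {
  tr <- randomTree(20, seed = 47)
  set.seed(6)
  y <- setNames(rnorm(20, 0, 1), tr$tip.label)
  llbm <- contLoglik(tr, y, "BM1", list(theta = 0.2, sigma2 = 0.5,
                                        x0 = 0.2))
  lleb <- contLoglik(tr, y, "EB", list(theta = 0.2, sigma2 = 0.5,
                                       x0 = 0.2, eb_r = 0))
  expect_equal(lleb, llbm, tolerance = 1e-12)
  expect_warning(fitCont(tr, y, "Trend", restarts = 1, seed = 1),
                 "weakly identified")
})

test_that("parameter counts follow each model's sharing structure", {
  expect_equal(contModelInfo("BM1")$K, 2)
  expect_equal(contModelInfo("OU1")$K, 3)
  expect_equal(contModelInfo("EB")$K, 3)
  expect_equal(contModelInfo("Trend")$K, 3)
  expect_equal(contModelInfo("BMS", 4)$K, 5)
  expect_equal(contModelInfo("OUM", 4)$K, 6)
  expect_equal(contModelInfo("OUMA", 4)$K, 9)
  expect_equal(contModelInfo("OUMV", 4)$K, 9)
  expect_equal(contModelInfo("OUMVA", 4)$K, 12)
})

test_that("the 14-model battery is complete and BM data favour simplicity", {
  pt2 <- twoRegimePainting(50, seed = 51)
  tr <- unpaint(pt2)
  Q4 <- buildQ(mkPattern("four-state", "NR-ALL"), c(0.02, 0.01, 0.01))
  pt4 <- simulateDiscrete(tr, Q4, "non-diving", seed = 52)$history
  y <- simulateContinuous(
    paintFromTips(tr, setNames(rep("x", 50), tr$tip.label), "x"),
    "BM1", list(theta = 2.8, sigma2 = 0.05), seed = 3)
  bat <- runContBattery(tr, list("two-state" = pt2, "four-state" = pt4),
                        y, restarts = 1, seed = 9)
  expect_equal(nrow(bat$comparison), 14)
  expect_equal(sum(bat$comparison$weight), 1, tolerance = 1e-9)
  # OU fits carry one half-life per realized regime of the painting
  oum <- bat$fits[["OUM (four-state)"]]
  expect_equal(length(oum$params$half_life),
               length(paintingStates(pt4)))
  expect_true(all(oum$params$half_life > 0))
  # data simulated under BM: a regime-independent model should do well
  top <- bat$comparison$name[1]
  expect_true(top %in% c("BM1", "OU1", "EB", "Trend") ||
                bat$comparison$weight[1] < 0.8)
})

test_that("flightless three-regime painting adds a five-model run", {
  pt2 <- twoRegimePainting(40, seed = 53)
  tr <- unpaint(pt2)
  # paint a third regime onto terminal branches of a few tips
  pt3 <- pt2
  set.seed(8)
  for (i in sample(seq_len(40), 5)) {
    e <- which(pt3$edge[, 2] == i)
    len <- pt3$edge.length[e]
    first <- pt3$maps[[e]][1]
    pt3$maps[[e]] <- setNames(c(len / 2, len / 2), c(names(first)[1],
                                                     "flightless"))
  }
  pt3$mapped.edge <- ratchetphy:::mappedEdgeMatrix(pt3$maps,
                                                   c("a", "b",
                                                     "flightless"))
  y <- simulateContinuous(pt2, "OUM",
                          list(theta = c(a = 2, b = 3), alpha = 0.05,
                               sigma2 = 0.1), seed = 4)
  bat <- runContBattery(tr, list("two-state" = pt2,
                                 "four-state" = pt2,
                                 "flightless" = pt3), y,
                        restarts = 1, seed = 10)
  expect_equal(nrow(bat$comparison), 19)
  f <- bat$fits[["OUM (flightless)"]]
  expect_equal(length(f$params$theta), 3)
})

test_that("constant tip values raise the divergence warning", {
  tr <- randomTree(10, seed = 57)
  y <- setNames(rep(2, 10), tr$tip.label)
  expect_warning(fitCont(tr, y, "BM1", restarts = 1, seed = 1),
                 "constant")
})
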