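# Independent oracles used across tests. These deliberately avoid the code
# paths they check: likelihoods by explicit enumeration or closed form,
# covariances by per-pair segment products along explicit root-to-tip paths.

# closed-form constant-rate birth-death log-likelihood for an ultrametric
# tree, conditioned on survival of both crown lineages (Nee et al. form)
bdLoglikOracle <- function(tree, lambda, mu) {
  r <- lambda - mu
  n <- ape::Ntip(tree)
  dep <- max(nodeDepths(tree))
  E <- function(t) 1 - r / (lambda - mu * exp(-r * t))
  Phi <- function(t) exp(-r * t) * r^2 / (lambda - mu * exp(-r * t))^2
  H <- dep - nodeDepths(tree) # time before present
  ll <- (n - 1) * log(lambda)
  for (e in seq_len(nrow(tree$edge))) {
    ll <- ll + log(Phi(H[tree$edge[e, 1]]) / Phi(H[tree$edge[e, 2]]))
  }
  ll - log(lambda * (1 - E(dep))^2)
}

# brute-force Mk likelihood: sum over all internal-node state assignments
mkBruteForce <- function(tree, tip_states, Q, pi) {
  states <- rownames(Q)
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(e) ratchetphy:::cpp_expm(unname(Q),
                                                 tree$edge.length[e]))
  tot <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  tipidx <- match(tip_states[tree$tip.label], states)
  root <- ntip + 1
  for (g in seq_len(nrow(grid))) {
    ns <- c(tipidx, grid[g, ])
    pr <- pi[ns[root]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pm[[e]][ns[tree$edge[e, 1]], ns[tree$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# random valid rate matrix on k states
randomQ <- function(k, scale = 0.5) {
  Q <- matrix(runif(k * k, 0.05, 1) * scale, k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(letters[seq_len(k)], letters[seq_len(k)])
  Q
}

# random ultrametric tree via the package simulator (varied seeds)
randomTree <- function(n, seed) simulateTree(0.2, 0.05, n, seed = seed)

# root-to-tip segment path (state, duration) per node of a painted tree
segmentPaths <- function(ptree) {
  ntip <- ape::Ntip(ptree)
  paths <- vector("list", ntip + ptree$Nnode)
  ord <- ape::reorder.phylo(ptree, "cladewise")$edge
  key <- paste(ptree$edge[, 1], ptree$edge[, 2])
  idx <- match(paste(ord[, 1], ord[, 2]), key)
  empty <- data.frame(state = character(0), dur = numeric(0))
  paths[[ntip + 1]] <- empty
  for (e in idx) {
    sg <- ptree$maps[[e]]
    paths[[ptree$edge[e, 2]]] <-
      rbind(paths[[ptree$edge[e, 1]]],
            data.frame(state = names(sg), dur = unname(sg)))
  }
  paths
}

# forward per-path OU moment recursion (mean and variance at path end)
pathMeanVar <- function(path, alpha, sigma2, theta, x0) {
  m <- x0
  v <- 0
  for (s in seq_len(nrow(path))) {
    st <- path$state[s]
    d <- path$dur[s]
    a <- alpha[[st]]
    if (a > 0) {
      ea <- exp(-a * d)
      m <- theta[[st]] + (m - theta[[st]]) * ea
      v <- v * ea^2 + sigma2[[st]] / (2 * a) * (1 - ea^2)
    } else {
      v <- v + sigma2[[st]] * d
    }
  }
  c(mean = m, var = v)
}

# full mean vector / covariance matrix for a multi-regime OU model, built
# per pair from explicit paths (independent of the package's accumulation)
ouPathOracle <- function(ptree, alpha, sigma2, theta, x0) {
  ntip <- ape::Ntip(ptree)
  paths <- segmentPaths(ptree)
  mv <- vapply(seq_len(ntip), function(i) {
    pathMeanVar(paths[[i]], alpha, sigma2, theta, x0)
  }, numeric(2))
  aInt <- vapply(seq_len(length(paths)), function(i) {
    p <- paths[[i]]
    if (!nrow(p)) 0 else sum(alpha[p$state] * p$dur)
  }, numeric(1))
  M <- ape::mrca(ptree)
  C <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) {
      C[i, j] <- mv["var", i]
    } else {
      a <- M[i, j]
      va <- pathMeanVar(paths[[a]], alpha, sigma2, theta, x0)[["var"]]
      C[i, j] <- va * exp(-(aInt[i] - aInt[a]) - (aInt[j] - aInt[a]))
    }
  }
  list(mean = mv["mean", ], C = C)
}

# log density of a multivariate normal via eigendecomposition (distinct
# from the package's Cholesky route)
dmvnormEigen <- function(y, mu, C) {
  ev <- eigen(C, symmetric = TRUE)
  r <- t(ev$vectors) %*% (y - mu)
  -0.5 * length(y) * log(2 * pi) - 0.5 * sum(log(ev$values)) -
    0.5 * sum(r^2 / ev$values)
}
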