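# R-side pruning that keeps the per-node partial likelihood vectors
# (needed for conditional node-state sampling).
mkPartials <- function(tree, tip_states, Q, pi) {
  states <- rownames(Q)
  po <- postorderEdges(tree)
  k <- length(states)
  nn <- po$ntip + tree$Nnode
  L <- matrix(1, nn, k)
  logsc <- numeric(nn)
  L[seq_len(po$ntip), ] <- mkTipMatrix(tree, tip_states, states)
  P <- cpp_branch_pmats(unname(Q), po$len)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    c <- po$edge[e, 2]
    v <- as.numeric(P[, , e] %*% L[c, ])
    m <- max(v)
    if (m <= 0) stopf("zero likelihood during pruning (branch %d)", e)
    L[p, ] <- L[p, ] * v / m
    logsc[p] <- logsc[p] + logsc[c] + log(m)
  }
  root <- po$edge[nrow(po$edge), 1]
  list(L = L, logsc = logsc, P = P, edge = po$edge, len = po$len,
       root = root, ntip = po$ntip, states = states,
       logL = log(sum(pi * L[root, ])) + logsc[root])
}

# endpoint-conditioned CTMC path on one branch: rejection first,
# uniformization fallback. Returns data.frame(time, from, to) of real jumps.
sampleBranchPath <- function(Q, s, j, t, max_reject = 30) {
  k <- nrow(Q)
  if (t <= 0) {
    if (s != j) stopf("state change on zero-length branch")
    return(list(jumps = NULL, path = s))
  }
  exit <- -diag(Q)
  # forward rejection
  for (try in seq_len(max_reject)) {
    cur <- s
    tm <- 0
    jumps_t <- numeric(0)
    jumps_from <- integer(0)
    jumps_to <- integer(0)
    repeat {
      rate <- exit[cur]
      dt <- if (rate > 0) rexp(1, rate) else Inf
      if (tm + dt > t) break
      tm <- tm + dt
      probs <- Q[cur, ]
      probs[cur] <- 0
      nxt <- sample.int(k, 1, prob = probs)
      jumps_t <- c(jumps_t, tm)
      jumps_from <- c(jumps_from, cur)
      jumps_to <- c(jumps_to, nxt)
      cur <- nxt
    }
    if (cur == j) {
      return(list(time = jumps_t, from = jumps_from, to = jumps_to))
    }
  }
  uniformizedBranchPath(Q, s, j, t)
}

# uniformization: sample jump count conditional on endpoints, then a Markov
# bridge over the jump chain; virtual (self) jumps are dropped.
uniformizedBranchPath <- function(Q, s, j, t) {
  k <- nrow(Q)
  omega <- max(-diag(Q))
  if (omega <= 0) {
    if (s != j) stopf("endpoint change with zero rates")
    return(list(time = numeric(0), from = integer(0), to = integer(0)))
  }
  R <- diag(k) + Q / omega
  nmax <- max(10, ceiling(omega * t + 10 * sqrt(omega * t + 1)))
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (n in seq_len(nmax)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  logpois <- stats::dpois(0:nmax, omega * t, log = TRUE)
  wn <- vapply(0:nmax, function(n) {
    exp(logpois[n + 1]) * Rpow[[n + 1]][s, j]
  }, numeric(1))
  if (sum(wn) <= 0) stopf("uniformization failed: unreachable endpoint")
  n <- sample.int(nmax + 1, 1, prob = wn) - 1
  if (n == 0) return(list(time = numeric(0), from = integer(0),
                          to = integer(0)))
  times <- sort(runif(n, 0, t))
  v <- integer(n + 1)
  v[1] <- s
  v[n + 1] <- j
  if (n > 1) {
    for (i in 2:n) {
      p <- R[v[i - 1], ] * Rpow[[n - i + 2]][, j]
      v[i] <- sample.int(k, 1, prob = p)
    }
  }
  keep <- v[-1] != v[-(n + 1)]
  list(time = times[keep], from = v[-(n + 1)][keep], to = v[-1][keep])
}

#' Sample stochastic character maps
#'
#' Empirical-Bayes stochastic mapping: with the rate matrix fixed at its MLE,
#' node states are drawn from their conditional distributions (backward
#' pruning pass, forward sampling) and branch interiors from the
#' endpoint-conditioned CTMC (forward rejection with a uniformization
#' fallback). Each history is one draw from `P(history | tips, Q)`.
#'
#' @param tree a `phylo` object.
#' @param tip_states named character vector, species to state.
#' @param fit an `mkFit` (or any list with `Q` and `pi`).
#' @param n number of replicate maps (the study default is 100).
#' @param seed RNG seed (mandatory for reproducible pipelines).
#' @return a `historySet`: list of `mappedHistory` objects, each with a
#'   painted tree, a transition record, sampled node states, and the seed.
#' @export
sampleHistories <- function(tree, tip_states, fit, n = 100, seed = 1) {
  stopifnot(n >= 1)
  Q <- fit$Q
  pi <- fit$pi %||% rep(1 / nrow(Q), nrow(Q))
  states <- rownames(Q)
  pr <- mkPartials(tree, tip_states, Q, pi)
  nedge <- nrow(pr$edge)
  # preorder = reversed postorder
  ord <- rev(seq_len(nedge))
  ntip <- pr$ntip
  set.seed(seed)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    node_state <- integer(ntip + tree$Nnode)
    wr <- pi * pr$L[pr$root, ]
    node_state[pr$root] <- sample.int(length(states), 1, prob = wr)
    maps <- vector("list", nedge)
    trs <- list()
    for (e in ord) {
      p <- pr$edge[e, 1]
      c <- pr$edge[e, 2]
      s <- node_state[p]
      w <- pr$P[s, , e] * pr$L[c, ]
      j <- sample.int(length(states), 1, prob = w)
      node_state[c] <- j
      path <- sampleBranchPath(Q, s, j, pr$len[e])
      brk <- c(0, path$time, pr$len[e])
      segst <- c(s, path$to)
      dur <- diff(brk)
      if (pr$len[e] == 0) {
        maps[[e]] <- setNames(0, states[s])
      } else {
        keep <- dur > 0
        maps[[e]] <- setNames(dur[keep], states[segst[keep]])
      }
      if (length(path$time)) {
        trs[[length(trs) + 1]] <- data.frame(
          branch = e, time = path$time,
          from = states[path$from], to = states[path$to],
          stringsAsFactors = FALSE)
      }
    }
    transitions <- if (length(trs)) do.call(rbind, trs) else
      data.frame(branch = integer(0), time = numeric(0),
                 from = character(0), to = character(0))
    ptree <- tree
    ptree$maps <- maps
    ptree$mapped.edge <- mappedEdgeMatrix(maps, states)
    class(ptree) <- c("simmap", "phylo")
    out[[r]] <- structure(list(tree = ptree, transitions = transitions,
                               node_states = setNames(
                                 states[node_state],
                                 seq_along(node_state)),
                               replicate = r, seed = seed),
                          class = "mappedHistory")
  }
  # edges of the sampled paintings follow postorder ordering of the pruning
  structure(list(histories = out, states = states, edge = pr$edge,
                 len = pr$len, ntip = ntip, seed = seed, logL = pr$logL),
            class = "historySet")
}

#' Summarize a set of stochastic maps
#'
#' Per ordered state pair: mean transition count and a 95% highest-posterior-
#' density set of the empirical count distribution (greedy inclusion of the
#' highest-frequency counts until at least 95% mass; ties included). Node
#' posteriors are the relative frequencies of each state at each internal
#' node across maps. The total transition count ("independent transitions")
#' is the number of state-change events per history, averaged.
#'
#' @param hs a `historySet` from [sampleHistories()] (at least 2 histories).
#' @return a `transitionSummary` list: `pair_mean`, `pair_hpd`, `total_mean`,
#'   `total_hpd`, `node_posterior`, `n`.
#' @export
summarizeHistories <- function(hs) {
  H <- hs$histories
  if (length(H) < 2) stopf("need at least 2 histories")
  states <- hs$states
  k <- length(states)
  n <- length(H)
  counts <- array(0L, c(n, k, k), dimnames = list(NULL, states, states))
  totals <- integer(n)
  for (r in seq_len(n)) {
    tr <- H[[r]]$transitions
    totals[r] <- nrow(tr)
    if (nrow(tr)) {
      tb <- table(factor(tr$from, states), factor(tr$to, states))
      counts[r, , ] <- tb
    }
  }
  pair_mean <- apply(counts, c(2, 3), mean)
  pair_hpd <- array(NA_integer_, c(k, k, 2),
                    dimnames = list(states, states, c("lower", "upper")))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    h <- discreteHpd(counts[, i, j])
    pair_hpd[i, j, ] <- h
  }
  ntip <- hs$ntip
  nodes <- (ntip + 1):(ntip + length(H[[1]]$node_states) - ntip)
  node_post <- matrix(0, length(nodes), k,
                      dimnames = list(nodes, states))
  for (r in seq_len(n)) {
    st <- H[[r]]$node_states[as.character(nodes)]
    for (ii in seq_along(nodes)) {
      node_post[ii, st[ii]] <- node_post[ii, st[ii]] + 1
    }
  }
  node_post <- node_post / n
  structure(list(pair_mean = pair_mean, pair_hpd = pair_hpd,
                 total_mean = mean(totals), total_hpd = discreteHpd(totals),
                 totals = totals, node_posterior = node_post, n = n),
            class = "transitionSummary")
}

# 95% HPD set of an integer sample by greedy inclusion; returns [lower, upper]
discreteHpd <- function(x, mass = 0.95) {
  tb <- table(x)
  freq <- as.numeric(tb) / length(x)
  vals <- as.numeric(names(tb))
  ord <- order(-freq, vals)
  cum <- cumsum(freq[ord])
  m <- which(cum >= mass)[1]
  thr <- freq[ord][m]
  sel <- vals[freq >= thr] # greedy set, ties at the threshold included
  sel <- union(sel, stats::median(x)) # HPD set always covers the median
  c(lower = min(sel), upper = max(sel))
}

#' @export
print.transitionSummary <- function(x, ...) {
  cat(sprintf("Stochastic-map summary over %d replicates\n", x$n))
  cat(sprintf("Mean total transitions: %.2f (95%% HPD %d-%d)\n",
              x$total_mean, x$total_hpd[1], x$total_hpd[2]))
  cat("Mean per-pair transitions (from rows to columns):\n")
  print(round(x$pair_mean, 2))
  invisible(x)
}

#' Write stochastic maps and their summary to disk
#'
#' Histories go to one multi-line mapped-newick file; the pair-count matrix
#' to CSV; intervals and node posteriors to JSON.
#'
#' @param hs a `historySet`.
#' @param summary a `transitionSummary`.
#' @param dir output directory.
#' @export
writeHistories <- function(hs, summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePaintedNewick(lapply(hs$histories, `[[`, "tree"),
                     file.path(dir, "histories.tre"))
  utils::write.csv(summary$pair_mean, file.path(dir, "transitions_mean.csv"))
  jsonlite::write_json(
    list(seed = hs$seed, n = summary$n, total_mean = summary$total_mean,
         total_hpd = as.list(summary$total_hpd),
         pair_hpd_lower = summary$pair_hpd[, , "lower"],
         pair_hpd_upper = summary$pair_hpd[, , "upper"],
         node_posterior = summary$node_posterior),
    file.path(dir, "transitions.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
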