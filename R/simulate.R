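# forward birth-death engine shared by simulateTree and simulateSse.
# Lineages carry a (compound) state; birth/death rates and state-transition
# rates are per state. Stops when the living count first reaches n_tips,
# then extends all living branches by the exponential sojourn at n lineages
# ("simple sampling" stop). Returns NULL if the process dies out.
forwardBD <- function(lambda, mu, Qr, root_state, n_tips, t_max = 1e4) {
  nstate <- length(lambda)
  rowq <- if (nstate > 1) rowSums(Qr) else 0
  # lineage book-keeping: start time, state, alive; events build children
  start <- c(0, 0)
  state <- c(root_state, root_state)
  parent <- c(0L, 0L)
  alive <- c(TRUE, TRUE)
  end <- c(NA_real_, NA_real_)
  kids <- list(integer(0), integer(0))
  segs <- list(setNames(numeric(0), character(0)),
               setNames(numeric(0), character(0)))
  seg_start <- c(0, 0)
  t <- 0
  repeat {
    liv <- which(alive)
    n <- length(liv)
    if (n == 0) return(NULL)
    rates <- lambda[state[liv]] + mu[state[liv]] +
      (if (nstate > 1) rowq[state[liv]] else 0)
    tot <- sum(rates)
    dt <- rexp(1, tot)
    if (n == n_tips) {
      # sojourn with exactly n lineages: stop here, extend by dt
      t <- t + dt
      break
    }
    t <- t + dt
    if (t > t_max) return(NULL)
    i <- liv[sample.int(n, 1, prob = rates)]
    s <- state[i]
    ev <- sample.int(3, 1, prob = c(lambda[s], mu[s],
                                    if (nstate > 1) rowq[s] else 0))
    if (ev == 1) { # speciation
      segs[[i]] <- c(segs[[i]], setNames(t - seg_start[i],
                                         as.character(s)))
      end[i] <- t
      alive[i] <- FALSE
      for (ch in 1:2) {
        start <- c(start, t)
        state <- c(state, s)
        parent <- c(parent, i)
        alive <- c(alive, TRUE)
        end <- c(end, NA_real_)
        kids[[length(kids) + 1]] <- integer(0)
        segs[[length(segs) + 1]] <- setNames(numeric(0), character(0))
        seg_start <- c(seg_start, t)
        kids[[i]] <- c(kids[[i]], length(start))
      }
    } else if (ev == 2) { # extinction
      segs[[i]] <- c(segs[[i]], setNames(t - seg_start[i],
                                         as.character(s)))
      end[i] <- t
      alive[i] <- FALSE
    } else { # state transition
      snew <- sample.int(nstate, 1, prob = Qr[s, ])
      segs[[i]] <- c(segs[[i]], setNames(t - seg_start[i],
                                         as.character(s)))
      seg_start[i] <- t
      state[i] <- snew
    }
  }
  liv <- which(alive)
  for (i in liv) {
    segs[[i]] <- c(segs[[i]], setNames(t - seg_start[i],
                                       as.character(state[i])))
    end[i] <- t
  }
  list(start = start, end = end, state = state, parent = parent,
       alive = alive, kids = kids, segs = segs, t = t)
}

# convert a forwardBD record (extinct lineages pruned) to a phylo + painting.
# Every node gets a unique label in the emitted newick so per-branch segment
# maps can be attached unambiguously after parsing.
bdToPhylo <- function(rec, state_names) {
  # survives: lineage leads to a living descendant
  nl <- length(rec$start)
  surv <- logical(nl)
  ord <- order(rec$start, decreasing = TRUE)
  for (i in ord) {
    surv[i] <- rec$alive[i] || any(surv[rec$kids[[i]]])
  }
  tipc <- 0L
  nodec <- 0L
  seg_by_label <- list()
  # a surviving lineage with exactly one surviving child fuses with it
  build <- function(i) {
    sk <- rec$kids[[i]][surv[rec$kids[[i]]]]
    my <- rec$segs[[i]]
    if (length(sk) == 0) {
      tipc <<- tipc + 1L
      lab <- paste0("t", tipc)
      seg_by_label[[lab]] <<- my
      return(list(str = paste0(lab, ":", format(sum(my), digits = 12)),
                  label = lab))
    }
    if (length(sk) == 1) {
      ch <- build_raw(sk[1])
      return(finish(i, c(my, ch$inner), ch))
    }
    finish(i, my, NULL, sk)
  }
  # build returning inner segments without emitting, for chain fusion
  build_raw <- function(i) {
    sk <- rec$kids[[i]][surv[rec$kids[[i]]]]
    my <- rec$segs[[i]]
    if (length(sk) == 0) return(list(inner = my, kids = integer(0)))
    if (length(sk) == 1) {
      ch <- build_raw(sk[1])
      return(list(inner = c(my, ch$inner), kids = ch$kids))
    }
    list(inner = my, kids = sk)
  }
  finish <- function(i, segs, raw, sk = NULL) {
    kids <- if (!is.null(raw)) raw$kids else sk
    if (length(kids) == 0) {
      tipc <<- tipc + 1L
      lab <- paste0("t", tipc)
      seg_by_label[[lab]] <<- segs
      return(list(str = paste0(lab, ":", format(sum(segs), digits = 12)),
                  label = lab))
    }
    l <- build(kids[1])
    r <- build(kids[2])
    nodec <<- nodec + 1L
    lab <- paste0("n", nodec)
    seg_by_label[[lab]] <<- segs
    list(str = paste0("(", l$str, ",", r$str, ")", lab, ":",
                      format(sum(segs), digits = 12)),
         label = lab)
  }
  roots <- which(rec$parent == 0 & surv)
  if (length(roots) < 2) return(NULL) # crown did not survive on both sides
  l <- build(roots[1])
  r <- build(roots[2])
  txt <- paste0("(", l$str, ",", r$str, ")root;")
  tree <- ape::read.tree(text = txt)
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  maps <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    sg <- seg_by_label[[labs[tree$edge[e, 2]]]]
    keep <- sg > 0
    sg <- if (any(keep)) sg[keep] else sg[1]
    if (length(sg) > 1) { # merge adjacent equal states
      grp <- cumsum(c(TRUE, names(sg)[-1] != names(sg)[-length(sg)]))
      sg <- setNames(as.numeric(tapply(sg, grp, sum)),
                     names(sg)[!duplicated(grp)])
    }
    maps[[e]] <- setNames(as.numeric(sg),
                          state_names[as.integer(names(sg))])
  }
  tree$node.label <- NULL
  ptree <- tree
  ptree$maps <- maps
  ptree$mapped.edge <- mappedEdgeMatrix(maps, state_names)
  class(ptree) <- c("simmap", "phylo")
  ptree
}

#' Simulate a birth-death tree conditioned on its extant tip count
#'
#' Constant-rate forward simulation from a crown pair, stopped when the
#' number of living lineages first reaches `n_tips` (plus the exponential
#' sojourn), with extinct lineages pruned; attempts where the crown fails to
#' survive are rejected. Lengths are in Myr and the tree is ultrametric.
#'
#' @param birth speciation rate (per Myr, > death).
#' @param death extinction rate (per Myr, >= 0).
#' @param n_tips number of extant tips to condition on.
#' @param seed RNG seed.
#' @param max_attempts rejection bound.
#' @return a `phylo`; the number of rejected attempts is in
#'   `attr(, "attempts")`.
#' @export
simulateTree <- function(birth, death, n_tips, seed = 1,
                         max_attempts = 1000) {
  if (!(birth > death) || death < 0) stopf("need birth > death >= 0")
  if (n_tips < 2) stopf("n_tips must be >= 2")
  set.seed(seed)
  Qr <- matrix(0, 1, 1)
  for (a in seq_len(max_attempts)) {
    rec <- forwardBD(birth, death, Qr, 1L, n_tips)
    if (is.null(rec)) next
    ptree <- bdToPhylo(rec, "s")
    if (is.null(ptree)) next
    if (ape::Ntip(ptree) != n_tips) next
    tree <- unpaint(ptree)
    attr(tree, "attempts") <- a
    return(tree)
  }
  stopf("tree simulation failed after %d attempts", max_attempts)
}

#' Simulate a discrete character along a tree (forward CTMC)
#'
#' @param tree a `phylo`.
#' @param Q rate matrix with state dimnames.
#' @param root_state state at the root.
#' @param seed RNG seed.
#' @return list with `tip_states` (named vector), `history` (the true
#'   painted tree), and `transitions` (data frame).
#' @export
simulateDiscrete <- function(tree, Q, root_state, seed = 1) {
  states <- rownames(Q)
  if (!root_state %in% states) stopf("unknown root state")
  set.seed(seed)
  nn <- ape::Ntip(tree) + tree$Nnode
  node_state <- integer(nn)
  root <- ape::Ntip(tree) + 1
  node_state[root] <- match(root_state, states)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  idx <- match(paste(ord[, 1], ord[, 2]), key)
  maps <- rep(list(NULL), nrow(tree$edge))
  trs <- list()
  exit <- -diag(Q)
  k <- length(states)
  for (e in idx) {
    p <- tree$edge[e, 1]
    v <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    s <- node_state[p]
    tm <- 0
    sg <- numeric(0)
    sn <- character(0)
    repeat {
      dt <- if (exit[s] > 0) rexp(1, exit[s]) else Inf
      if (tm + dt >= len) {
        sg <- c(sg, len - tm)
        sn <- c(sn, states[s])
        break
      }
      tm <- tm + dt
      pr <- Q[s, ]
      pr[s] <- 0
      snew <- sample.int(k, 1, prob = pr)
      sg <- c(sg, dt)
      sn <- c(sn, states[s])
      trs[[length(trs) + 1]] <- data.frame(branch = e, time = tm,
                                           from = states[s],
                                           to = states[snew],
                                           stringsAsFactors = FALSE)
      s <- snew
    }
    if (len == 0) {
      maps[[e]] <- setNames(0, states[s])
    } else {
      keep <- sg > 0
      maps[[e]] <- setNames(sg[keep], sn[keep])
    }
    node_state[v] <- s
  }
  ptree <- tree
  ptree$maps <- maps
  ptree$mapped.edge <- mappedEdgeMatrix(maps, states)
  class(ptree) <- c("simmap", "phylo")
  tip_states <- setNames(states[node_state[seq_len(ape::Ntip(tree))]],
                         tree$tip.label)
  transitions <- if (length(trs)) do.call(rbind, trs) else
    data.frame(branch = integer(0), time = numeric(0),
               from = character(0), to = character(0))
  list(tip_states = tip_states, history = ptree,
       transitions = transitions, node_states = states[node_state],
       seed = seed)
}

#' Jointly simulate tree growth and a binary state (SSE forward simulation)
#'
#' Forward simulation with state-dependent speciation and extinction;
#' extinct lineages are pruned and the run is conditioned on `n_tips`
#' extant species by rejection.
#'
#' @param params an [sseParams()] list (per-compound-state `lambda`, `mu`,
#'   `Qr`, `compound`).
#' @param n_tips extant tip count to condition on.
#' @param seed RNG seed.
#' @param max_attempts rejection bound.
#' @return list with `tree`, `tip_states` (observed 0/1), `tip_regimes`
#'   (true compound states), `history` (painted tree), `attempts`.
#' @export
simulateSse <- function(params, n_tips, seed = 1, max_attempts = 1000) {
  comp <- params$compound
  if (any(params$lambda <= 0)) stopf("all regime lambda must be > 0")
  set.seed(seed)
  root_state <- 1L
  for (a in seq_len(max_attempts)) {
    rec <- forwardBD(unname(params$lambda), unname(params$mu),
                     unname(params$Qr), root_state, n_tips)
    if (is.null(rec)) next
    ptree <- bdToPhylo(rec, comp$state)
    if (is.null(ptree)) next
    if (ape::Ntip(ptree) != n_tips) next
    # tip regimes: state of the last (tipward) segment of each tip edge
    ntip <- ape::Ntip(ptree)
    tipreg <- character(ntip)
    for (e in seq_len(nrow(ptree$edge))) {
      ch <- ptree$edge[e, 2]
      if (ch <= ntip) {
        sg <- ptree$maps[[e]]
        tipreg[ch] <- names(sg)[length(sg)]
      }
    }
    names(tipreg) <- ptree$tip.label
    obs <- setNames(comp$obs[match(tipreg, comp$state)], names(tipreg))
    return(list(tree = unpaint(ptree), tip_states = obs,
                tip_regimes = tipreg, history = ptree, attempts = a,
                seed = seed))
  }
  stopf("SSE simulation failed after %d attempts (extinction-prone?)",
        max_attempts)
}

#' Simulate a continuous trait along a painted tree
#'
#' Exact Gaussian transition sampling segment-by-segment: OU segments use
#' the conditional mean and variance, BM segments variance `sigma^2 * dt`,
#' EB the time-integrated rate, and Trend adds drift to the mean.
#'
#' @inheritParams contLoglik
#' @param seed RNG seed.
#' @return named numeric vector of tip values.
#' @export
simulateContinuous <- function(ptree, model, params, seed = 1) {
  info <- contModelInfo(model)
  regimes <- paintingStates(ptree)
  alpha <- if (info$type == "OU") perRegime(params$alpha, regimes) else
    setNames(rep(0, length(regimes)), regimes)
  sigma2 <- perRegime(params$sigma2, regimes)
  theta <- if (info$type == "OU") perRegime(params$theta, regimes) else
    setNames(rep(0, length(regimes)), regimes)
  eb_r <- params$eb_r %||% 0
  drift <- params$drift %||% 0
  x0 <- params$x0 %||% (if (info$type == "OU")
    theta[[rootRegime(ptree)]] else params$theta[[1]])
  set.seed(seed)
  ntip <- ape::Ntip(ptree)
  nn <- ntip + ptree$Nnode
  val <- numeric(nn)
  depth <- numeric(nn)
  val[ntip + 1] <- x0
  ord <- ape::reorder.phylo(ptree, "cladewise")$edge
  key <- paste(ptree$edge[, 1], ptree$edge[, 2])
  idx <- match(paste(ord[, 1], ord[, 2]), key)
  for (e in idx) {
    p <- ptree$edge[e, 1]
    v <- ptree$edge[e, 2]
    x <- val[p]
    t0 <- depth[p]
    for (s in seq_along(ptree$maps[[e]])) {
      st <- names(ptree$maps[[e]])[s]
      d <- ptree$maps[[e]][[s]]
      if (d <= 0) next
      al <- alpha[[st]]
      if (al > 0) {
        mn <- theta[[st]] + (x - theta[[st]]) * exp(-al * d)
        vr <- sigma2[[st]] / (2 * al) * -expm1(-2 * al * d)
      } else {
        mn <- x + (if (info$trend) drift * d else 0)
        vr <- if (eb_r != 0) {
          sigma2[[st]] * (exp(eb_r * (t0 + d)) - exp(eb_r * t0)) / eb_r
        } else sigma2[[st]] * d
      }
      x <- rnorm(1, mn, sqrt(vr))
      t0 <- t0 + d
    }
    val[v] <- x
    depth[v] <- t0
  }
  setNames(val[seq_len(ntip)], ptree$tip.label)
}
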