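#' Constrained Mk rate-matrix patterns for the diving systems
#'
#' Builds the integer constraint pattern for a named model: `0` entries are
#' rates fixed at zero, equal positive integers share one free parameter.
#' No-reversion (NR) variants force every diving-to-non-diving rate to zero;
#' `NR-ALL` additionally forbids transitions between diving states, leaving
#' only the three acquisition rates; `NR-SYM` pairs symmetric rates among the
#' three diving states and leaves each non-diving-to-diving rate free.
#'
#' @param system `"two-state"` or `"four-state"`.
#' @param model model name: `ER`, `ARD`, `NR` (two-state); `ER`, `SYM`,
#'   `ARD`, `NR-ER`, `NR-SYM`, `NR-ARD`, `NR-ALL` (four-state).
#' @return a list with `states`, `pattern` (k x k integer matrix), `K`,
#'   `name`, `system`.
#' @export
mkPattern <- function(system = c("two-state", "four-state"), model) {
  system <- match.arg(system)
  if (system == "two-state") {
    states <- nicheStates2()
    pat <- matrix(0L, 2, 2, dimnames = list(states, states))
    if (model == "ER") {
      pat["non-diving", "diving"] <- 1L
      pat["diving", "non-diving"] <- 1L
    } else if (model == "ARD") {
      pat["non-diving", "diving"] <- 1L
      pat["diving", "non-diving"] <- 2L
    } else if (model == "NR") {
      pat["non-diving", "diving"] <- 1L
    } else stopf("unknown two-state model '%s'", model)
  } else {
    states <- nicheStates4()
    dive <- setdiff(states, "non-diving")
    pat <- matrix(0L, 4, 4, dimnames = list(states, states))
    off <- which(row(pat) != col(pat))
    if (model == "ER") {
      pat[off] <- 1L
    } else if (model == "SYM") {
      lab <- 0L
      for (i in 1:3) for (j in (i + 1):4) {
        lab <- lab + 1L
        pat[i, j] <- lab
        pat[j, i] <- lab
      }
    } else if (model == "ARD") {
      pat[off] <- seq_along(off)
    } else if (model == "NR-ER") {
      pat[off] <- 1L
      pat[dive, "non-diving"] <- 0L
    } else if (model == "NR-SYM") {
      lab <- 0L
      for (s in dive) {
        lab <- lab + 1L
        pat["non-diving", s] <- lab
      }
      for (i in 1:2) for (j in (i + 1):3) {
        lab <- lab + 1L
        pat[dive[i], dive[j]] <- lab
        pat[dive[j], dive[i]] <- lab
      }
    } else if (model == "NR-ARD") {
      pat[off] <- seq_along(off)
      pat[dive, "non-diving"] <- 0L
      free <- which(pat > 0)
      pat[free] <- match(pat[free], sort(unique(pat[free])))
    } else if (model == "NR-ALL") {
      lab <- 0L
      for (s in dive) {
        lab <- lab + 1L
        pat["non-diving", s] <- lab
      }
    } else stopf("unknown four-state model '%s'", model)
  }
  diag(pat) <- 0L
  list(states = states, pattern = pat,
       K = length(unique(pat[pat > 0])), name = model, system = system)
}

#' Model names of the two Mk batteries
#' @param system `"two-state"` or `"four-state"`.
#' @return character vector of model names.
#' @export
mkBatteryModels <- function(system = c("two-state", "four-state")) {
  system <- match.arg(system)
  if (system == "two-state") c("ER", "ARD", "NR")
  else c("ER", "SYM", "ARD", "NR-ER", "NR-SYM", "NR-ARD", "NR-ALL")
}

#' Build a rate matrix from a pattern and free rates
#'
#' @param pattern output of [mkPattern()] (or a bare integer matrix with
#'   state dimnames).
#' @param rates numeric vector, one entry per distinct positive pattern label.
#' @return k x k rate matrix `Q` (rows sum to zero).
#' @export
buildQ <- function(pattern, rates) {
  pat <- if (is.list(pattern)) pattern$pattern else pattern
  labs <- sort(unique(pat[pat > 0]))
  if (length(rates) != length(labs)) {
    stopf("pattern has %d free parameters but %d rates supplied",
          length(labs), length(rates))
  }
  if (any(rates < 0)) stopf("rates must be >= 0")
  Q <- matrix(0, nrow(pat), ncol(pat), dimnames = dimnames(pat))
  for (i in seq_along(labs)) Q[pat == labs[i]] <- rates[i]
  diag(Q) <- -rowSums(Q)
  Q
}

# tip partial-likelihood matrix: indicator rows; NA state -> uniform row
mkTipMatrix <- function(tree, tip_states, states) {
  ntip <- ape::Ntip(tree)
  st <- tip_states[tree$tip.label]
  if (anyNA(names(tip_states)) || is.null(names(tip_states))) {
    stopf("`tip_states` must be named by species")
  }
  missing <- tree$tip.label[!tree$tip.label %in% names(tip_states)]
  if (length(missing)) stopf("no state for tip(s): %s",
                             paste(head(missing, 5), collapse = ", "))
  bad <- setdiff(unique(st[!is.na(st)]), states)
  if (length(bad)) stopf("tip state(s) outside state set: %s",
                         paste(bad, collapse = ", "))
  L <- matrix(0, ntip, length(states))
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) L[i, ] <- 1 else L[i, match(st[i], states)] <- 1
  }
  L
}

#' Mk pruning log-likelihood
#'
#' Felsenstein pruning with per-branch transition probabilities
#' `P(t) = exp(Qt)` (scaling-and-squaring matrix exponential, robust to the
#' defective no-reversion matrices) and a root prior over states.
#'
#' @param tree a `phylo` object.
#' @param tip_states named character vector, species to state.
#' @param Q rate matrix with state dimnames.
#' @param root_prior `"equal"`, `"stationary"`, or a numeric simplex over
#'   the states.
#' @return log-likelihood.
#' @export
mkLoglik <- function(tree, tip_states, Q, root_prior = "equal") {
  states <- rownames(Q)
  if (is.null(states)) stopf("Q needs state dimnames")
  pi <- rootPrior(root_prior, Q)
  po <- postorderEdges(tree)
  tipL <- mkTipMatrix(tree, tip_states, states)
  cpp_mk_loglik(po$edge, po$len, po$ntip, tipL, unname(Q), pi)
}

rootPrior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || abs(sum(root_prior) - 1) > 1e-9) {
      stopf("fixed root prior must be a length-%d simplex", k)
    }
    return(as.numeric(root_prior))
  }
  if (identical(root_prior, "equal")) return(rep(1 / k, k))
  if (identical(root_prior, "stationary")) {
    # left null vector of Q; NR matrices are absorbing, solved via limiting P
    P <- cpp_expm(unname(Q), 1e6 / max(abs(Q), 1e-12))
    pi <- colMeans(P)
    return(pi / sum(pi))
  }
  stopf("unknown root prior")
}

#' Maximum-likelihood fit of a constrained Mk model
#'
#' Optimizes the free rates on the log scale (bounds `[1e-9, 1e3]` per Myr)
#' with multiple restarts drawn log-uniformly; restarts guard against the
#' multimodality seen in constrained fits.
#'
#' @inheritParams mkLoglik
#' @param pattern output of [mkPattern()].
#' @param restarts number of optimizer restarts.
#' @param seed RNG seed for restart draws (recorded in the fit).
#' @param lower,upper rate bounds (per Myr).
#' @return an `mkFit` list: `Q`, `rates`, `logL`, `K`, `pi`, `pattern`,
#'   `diagnostics`.
#' @export
fitMkModel <- function(tree, tip_states, pattern, root_prior = "equal",
                       restarts = 10, seed = 1, lower = 1e-9, upper = 1e3) {
  states <- pattern$states
  st <- tip_states[tree$tip.label]
  if (pattern$K > 0 && length(unique(st[!is.na(st)])) < 2) {
    # constant trait: likelihood is maximized as rates -> 0
    Q <- buildQ(pattern, rep(lower, pattern$K))
    ll <- mkLoglik(tree, tip_states, Q, root_prior)
    return(structure(list(states = states, Q = Q,
                          rates = rep(lower, pattern$K), logL = ll,
                          K = pattern$K, pi = rootPrior(root_prior, Q),
                          pattern = pattern,
                          diagnostics = list(constant_trait = TRUE,
                                             seed = seed)),
                     class = "mkFit"))
  }
  po <- postorderEdges(tree)
  tipL <- mkTipMatrix(tree, tip_states, states)
  pi <- if (identical(root_prior, "stationary")) NULL else
    rootPrior(root_prior, buildQ(pattern, rep(1, pattern$K)))
  nll <- function(logr) {
    Q <- buildQ(pattern, exp(logr))
    p <- pi %||% rootPrior("stationary", Q)
    ll <- cpp_mk_loglik(po$edge, po$len, po$ntip, tipL, unname(Q), p)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  # first start scaled to parsimony-flavoured guess: ~k changes over the tree
  tl <- sum(tree$edge.length)
  starts <- c(log(length(states) / tl),
              runif(restarts - 1, log(1e-5), log(1)))
  best <- NULL
  per_restart <- numeric(0)
  for (s in starts) {
    o <- tryCatch(
      nlminb(rep(s, pattern$K), nll, lower = log(lower), upper = log(upper)),
      error = function(e) NULL)
    if (is.null(o)) next
    per_restart <- c(per_restart, -o$objective)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stopf("all %d Mk restarts failed", restarts)
  rates <- exp(best$par)
  Q <- buildQ(pattern, rates)
  p <- pi %||% rootPrior("stationary", Q)
  structure(list(states = states, Q = Q, rates = rates,
                 logL = -best$objective, K = pattern$K, pi = p,
                 pattern = pattern,
                 diagnostics = list(restarts = length(per_restart),
                                    best_per_restart = per_restart,
                                    convergence = best$convergence,
                                    seed = seed)),
            class = "mkFit")
}

#' @export
print.mkFit <- function(x, ...) {
  cat(sprintf("Mk fit: %s (%s), logL = %.4f, K = %d\n",
              x$pattern$name, x$pattern$system, x$logL, x$K))
  cat("Rates (per Myr):\n")
  print(signif(x$Q, 4))
  invisible(x)
}

#' Fit the full Mk model battery for one state system
#'
#' Fits the three two-state or seven four-state models and ranks them by AIC
#' weight. Delta-AIC is reported to 4 decimals in the comparison table.
#'
#' @inheritParams fitMkModel
#' @param system `"two-state"` or `"four-state"`.
#' @return a list with `comparison` (ranked data frame) and `fits` (named
#'   list of `mkFit` objects).
#' @export
runMkBattery <- function(tree, tip_states, system = c("two-state",
                                                      "four-state"),
                         root_prior = "equal", restarts = 10, seed = 1) {
  system <- match.arg(system)
  models <- mkBatteryModels(system)
  fits <- lapply(seq_along(models), function(i) {
    fitMkModel(tree, tip_states, mkPattern(system, models[i]),
               root_prior = root_prior, restarts = restarts,
               seed = deriveSeed(seed, i))
  })
  names(fits) <- models
  cmp <- aicCompare(data.frame(name = models,
                               logL = vapply(fits, `[[`, 0, "logL"),
                               K = vapply(fits, `[[`, 0L, "K")))
  cmp$delta_AIC <- round(cmp$delta_AIC, 4)
  cmp$rates <- vapply(cmp$name, function(m) {
    paste(signif(fits[[m]]$rates, 4), collapse = ";")
  }, character(1))
  list(comparison = cmp, fits = fits, system = system)
}
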