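#' Convert turnover / extinction-fraction to speciation and extinction
#'
#' The diversification models are parameterized by turnover `tau = lambda +
#' mu` and extinction fraction `eps = mu / lambda` per regime, the
#' parameterization under which all seven scenarios are estimated.
#'
#' @param tau turnover (per Myr, > 0).
#' @param eps extinction fraction (>= 0; > 1 means declining).
#' @return list with `lambda` and `mu`.
#' @export
turnoverToRates <- function(tau, eps) {
  lambda <- tau / (1 + eps)
  list(lambda = lambda, mu = tau - lambda)
}

#' Net diversification per regime
#'
#' Net diversification is speciation minus extinction per regime, sign
#' preserved (regimes with `eps > 1` are declining).
#'
#' @param params an `sseParams`/`sseFit` parameter list with `lambda`, `mu`.
#' @return named numeric vector of net diversification rates.
#' @export
netDiversification <- function(params) {
  params$lambda - params$mu
}

#' Define one of the seven diversification scenarios
#'
#' Builds the compound-state structure (observed state 0 = non-diving, 1 =
#' diving; hidden classes A, B, ...) for the battery: `dull null` (one
#' regime), `BiSSE` (regimes by observed state), `BiSSE null` (CID-2, regimes
#' by hidden state), `HiSSE full` (four regimes), `HiSSE non-diving` /
#' `HiSSE diving` (hidden state on one observed state only; three regimes),
#' and `HiSSE null` (CID-4; diversification on four hidden classes only).
#' Observed-state transitions get one free rate per direction (shared across
#' hidden classes), hidden-state transitions share a single symmetric rate,
#' and dual transitions are disallowed.
#'
#' @param name model name (see above).
#' @return an `sseModel` list: `compound` (data frame with `state`, `obs`,
#'   `hidden`, `class`), `regimes`, `K`, `hidden_present`, `name`.
#' @export
sseModel <- function(name) {
  mk <- function(obs, hidden, class) {
    data.frame(state = paste0(obs, ifelse(is.na(hidden), "", hidden)),
               obs = obs, hidden = hidden, class = class,
               stringsAsFactors = FALSE)
  }
  comp <- switch(name,
    "dull null" = mk(c("0", "1"), c(NA, NA), c(1, 1)),
    "BiSSE" = mk(c("0", "1"), c(NA, NA), c(1, 2)),
    "BiSSE null" = mk(c("0", "0", "1", "1"), c("A", "B", "A", "B"),
                      c(1, 2, 1, 2)),
    "HiSSE full" = mk(c("0", "0", "1", "1"), c("A", "B", "A", "B"),
                      c(1, 2, 3, 4)),
    "HiSSE non-diving" = mk(c("0", "0", "1"), c("A", "B", NA), c(1, 2, 3)),
    "HiSSE diving" = mk(c("0", "1", "1"), c(NA, "A", "B"), c(1, 2, 3)),
    "HiSSE null" = mk(rep(c("0", "1"), each = 4),
                      rep(c("A", "B", "C", "D"), 2),
                      rep(1:4, 2)),
    stopf("unknown SSE model '%s'", name))
  hidden_present <- any(!is.na(comp$hidden))
  nclass <- length(unique(comp$class))
  K <- 2L * nclass + 2L + as.integer(hidden_present)
  regimes <- switch(name, "dull null" = 1L, "BiSSE" = 2L,
                    "BiSSE null" = 2L, "HiSSE full" = 4L,
                    "HiSSE non-diving" = 3L, "HiSSE diving" = 3L,
                    "HiSSE null" = 4L)
  structure(list(name = name, compound = comp, regimes = regimes, K = K,
                 hidden_present = hidden_present, nclass = nclass),
            class = "sseModel")
}

#' Model names of the seven-scenario battery (paper table order)
#' @return character vector.
#' @export
sseBatteryModels <- function() {
  c("dull null", "BiSSE", "BiSSE null", "HiSSE full",
    "HiSSE non-diving", "HiSSE diving", "HiSSE null")
}

# regime transition-rate matrix from the compound table
sseTransMatrix <- function(comp, q01, q10, h) {
  m <- nrow(comp)
  Qr <- matrix(0, m, m, dimnames = list(comp$state, comp$state))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    same_hidden <- (is.na(comp$hidden[i]) || is.na(comp$hidden[j]) ||
                      comp$hidden[i] == comp$hidden[j])
    if (comp$obs[i] != comp$obs[j] && same_hidden) {
      Qr[i, j] <- if (comp$obs[i] == "0") q01 else q10
    } else if (comp$obs[i] == comp$obs[j] && !is.na(comp$hidden[i]) &&
               !is.na(comp$hidden[j]) && comp$hidden[i] != comp$hidden[j]) {
      Qr[i, j] <- h
    }
  }
  Qr
}

normalizeBinaryStates <- function(tip_states) {
  st <- as.character(tip_states)
  map <- c("0" = "0", "1" = "1", "non-diving" = "0", "diving" = "1")
  if (!all(st %in% names(map))) {
    stopf("binary states must be 0/1 or non-diving/diving")
  }
  setNames(unname(map[st]), names(tip_states))
}

#' Construct SSE parameters from turnover and extinction fraction per regime
#'
#' @param model an [sseModel()] or model name.
#' @param tau,eps turnover and extinction fraction, one per regime class.
#' @param q01,q10 observed-state transition rates (0 to 1 and back).
#' @param h shared hidden-state flip rate (ignored without hidden states).
#' @return an `sseParams` list (`lambda`, `mu`, `Qr`, `compound`, ...).
#' @export
sseParams <- function(model, tau, eps, q01, q10, h = 0) {
  if (is.character(model)) model <- sseModel(model)
  stopifnot(length(tau) == model$nclass, length(eps) == model$nclass)
  lm <- turnoverToRates(tau[model$compound$class],
                        eps[model$compound$class])
  list(lambda = setNames(lm$lambda, model$compound$state),
       mu = setNames(lm$mu, model$compound$state),
       tau = tau, eps = eps, q01 = q01, q10 = q10, h = h,
       Qr = sseTransMatrix(model$compound, q01, q10, h),
       compound = model$compound, model = model)
}

sseParamsFromVector <- function(model, par) {
  nc <- model$nclass
  tau <- exp(par[seq_len(nc)])
  eps <- exp(par[nc + seq_len(nc)])
  q01 <- exp(par[2 * nc + 1])
  q10 <- exp(par[2 * nc + 2])
  h <- if (model$hidden_present) exp(par[2 * nc + 3]) else 0
  lm <- turnoverToRates(tau[model$compound$class],
                        eps[model$compound$class])
  list(lambda = setNames(lm$lambda, model$compound$state),
       mu = setNames(lm$mu, model$compound$state),
       tau = tau, eps = eps, q01 = q01, q10 = q10, h = h,
       Qr = sseTransMatrix(model$compound, q01, q10, h))
}

#' State-dependent speciation-extinction log-likelihood
#'
#' Integrates the standard D/E ordinary differential equations tipward to
#' rootward along every branch (adaptive Cash-Karp Runge-Kutta, `rtol` 1e-8 /
#' `atol` 1e-10), combines daughter lineages with the regime's speciation
#' rate, applies survival conditioning and the configured root weighting.
#'
#' @param tree an ultrametric `phylo`.
#' @param tip_states named binary states (`0`/`1` or
#'   `non-diving`/`diving`).
#' @param params list with per-compound-state `lambda`, `mu` and regime
#'   transition matrix `Qr` (as from internal parameterization), plus the
#'   model's `compound` table under `compound`.
#' @param root `"obs"` (weight each regime by its conditional likelihood,
#'   the default), `"equal"`, or a numeric prior over compound states.
#' @param condition condition on survival of the two root lineages?
#' @param rtol,atol ODE tolerances.
#' @return log-likelihood.
#' @export
sseLoglik <- function(tree, tip_states, params, root = "obs",
                      condition = TRUE, rtol = 1e-8, atol = 1e-10) {
  comp <- params$compound
  st <- normalizeBinaryStates(tip_states)[tree$tip.label]
  po <- postorderEdges(tree)
  m <- nrow(comp)
  tipD <- matrix(0, po$ntip, m)
  for (i in seq_len(po$ntip)) tipD[i, comp$obs == st[i]] <- 1
  root_type <- if (identical(root, "obs")) 0L else
    if (identical(root, "equal")) 1L else 2L
  root_pi <- if (is.numeric(root)) root else rep(1 / m, m)
  res <- cpp_sse_loglik(po$edge, po$len, po$ntip, tipD,
                        unname(params$lambda), unname(params$mu),
                        unname(params$Qr), rtol, atol, root_type, root_pi,
                        condition)
  if (!isTRUE(res$ok)) {
    stopf("ODE integration failed on branch %d (rtol=%g, atol=%g)",
          res$branch, rtol, atol)
  }
  res$logL
}

#' Fit one diversification scenario by maximum likelihood
#'
#' Optimization is over log turnover and log extinction fraction per regime
#' class plus log transition rates, with multiple restarts.
#'
#' @inheritParams sseLoglik
#' @param model an [sseModel()] or model name.
#' @param restarts optimizer restarts (default 8).
#' @param seed RNG seed for restart draws.
#' @return an `sseFit`: `params`, `logL`, `K`, `model`, `regimes`,
#'   `net_div` (per regime class), `diagnostics`.
#' @export
fitSse <- function(tree, tip_states, model, root = "obs", restarts = 8,
                   seed = 1, rtol = 1e-7, atol = 1e-9) {
  if (is.character(model)) model <- sseModel(model)
  st <- normalizeBinaryStates(tip_states)
  comp <- model$compound
  po <- postorderEdges(tree)
  m <- nrow(comp)
  sts <- st[tree$tip.label]
  tipD <- matrix(0, po$ntip, m)
  for (i in seq_len(po$ntip)) tipD[i, comp$obs == sts[i]] <- 1
  nc <- model$nclass
  npar <- 2 * nc + 2 + as.integer(model$hidden_present)
  nll <- function(par) {
    p <- sseParamsFromVector(model, par)
    res <- cpp_sse_loglik(po$edge, po$len, po$ntip, tipD,
                          unname(p$lambda), unname(p$mu), unname(p$Qr),
                          rtol, atol, 0L, rep(1 / m, m), TRUE)
    if (!isTRUE(res$ok) || !is.finite(res$logL)) return(1e10)
    -res$logL
  }
  depth <- max(nodeDepths(tree))
  lam0 <- log(max(po$ntip / 2, 2)) / depth
  base <- c(rep(log(1.5 * lam0), nc), rep(log(0.3), nc),
            log(2 / sum(tree$edge.length)), log(2 / sum(tree$edge.length)),
            if (model$hidden_present) log(0.01))
  lower <- c(rep(log(1e-6), nc), rep(log(1e-6), nc), rep(log(1e-9), 2),
             if (model$hidden_present) log(1e-9))
  upper <- c(rep(log(10), nc), rep(log(5), nc), rep(log(1), 2),
             if (model$hidden_present) log(1))
  set.seed(seed)
  best <- NULL
  objs <- numeric(0)
  for (r in seq_len(restarts)) {
    start <- if (r == 1) base else
      pmin(pmax(base + rnorm(npar, 0, 1), lower), upper)
    o <- tryCatch(nlminb(start, nll, lower = lower, upper = upper,
                         control = list(eval.max = 500, iter.max = 300)),
                  error = function(e) NULL)
    if (is.null(o)) next
    objs <- c(objs, -o$objective)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stopf("all %d SSE restarts failed", restarts)
  p <- sseParamsFromVector(model, best$par)
  p$compound <- comp
  cls <- !duplicated(comp$class)
  structure(list(params = p, logL = -best$objective, K = model$K,
                 model = model, regimes = model$regimes,
                 net_div = setNames((p$lambda - p$mu)[cls],
                                    comp$state[cls]),
                 diagnostics = list(restarts = length(objs),
                                    best_per_restart = objs, seed = seed)),
            class = "sseFit")
}

#' @export
print.sseFit <- function(x, ...) {
  cat(sprintf("SSE fit: %s (%d regimes), logL = %.4f, K = %d\n",
              x$model$name, x$regimes, x$logL, x$K))
  cat("Net diversification per regime:\n")
  print(signif(x$net_div, 4))
  invisible(x)
}

#' Fit the seven-scenario diversification battery
#'
#' @inheritParams fitSse
#' @return list with `comparison` (ranked AIC table incl. regime counts) and
#'   `fits`.
#' @export
runSseBattery <- function(tree, tip_states, root = "obs", restarts = 8,
                          seed = 1, rtol = 1e-7, atol = 1e-9) {
  models <- sseBatteryModels()
  fits <- lapply(seq_along(models), function(i) {
    fitSse(tree, tip_states, models[i], root = root, restarts = restarts,
           seed = deriveSeed(seed, i), rtol = rtol, atol = atol)
  })
  names(fits) <- models
  cmp <- aicCompare(data.frame(name = models,
                               logL = vapply(fits, `[[`, 0, "logL"),
                               K = vapply(fits, `[[`, 0L, "K")))
  cmp$regimes <- vapply(cmp$name, function(m) fits[[m]]$regimes, integer(1))
  list(comparison = cmp, fits = fits)
}

#' Per-tip hidden-regime assignment probabilities
#'
#' For each tip, the probability of each compound (observed, hidden) state is
#' proportional to the full-tree likelihood with that tip clamped to the
#' state, normalized over the tip's compatible states.
#'
#' @param fit an `sseFit` whose model has hidden states.
#' @inheritParams sseLoglik
#' @return matrix (tips x compound states) of probabilities; incompatible
#'   states have probability 0.
#' @export
tipRegimeProbs <- function(fit, tree, tip_states, rtol = 1e-7,
                           atol = 1e-9) {
  model <- fit$model
  if (!model$hidden_present) stopf("model has no hidden states")
  comp <- model$compound
  p <- fit$params
  st <- normalizeBinaryStates(tip_states)[tree$tip.label]
  po <- postorderEdges(tree)
  m <- nrow(comp)
  tipD <- matrix(0, po$ntip, m)
  for (i in seq_len(po$ntip)) tipD[i, comp$obs == st[i]] <- 1
  out <- matrix(0, po$ntip, m,
                dimnames = list(tree$tip.label, comp$state))
  for (i in seq_len(po$ntip)) {
    idx <- which(tipD[i, ] == 1)
    ll <- rep(-Inf, m)
    for (j in idx) {
      td <- tipD
      td[i, ] <- 0
      td[i, j] <- 1
      res <- cpp_sse_loglik(po$edge, po$len, po$ntip, td,
                            unname(p$lambda), unname(p$mu), unname(p$Qr),
                            rtol, atol, 0L, rep(1 / m, m), TRUE)
      ll[j] <- res$logL
    }
    if (all(!is.finite(ll))) stopf("tip %s incompatible with every regime",
                                   tree$tip.label[i])
    w <- exp(ll - max(ll, na.rm = TRUE))
    w[!is.finite(w)] <- 0
    out[i, ] <- w / sum(w)
  }
  out
}
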