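#' Phylogenetic half-life of an OU process
#'
#' Time for the expected trait value to decay half the distance to the
#' optimum: `t_half = log(2) / alpha` (Myr for alpha per Myr).
#'
#' @param alpha selection strength (per Myr, >= 0).
#' @return half-life in Myr (`Inf` for `alpha = 0`).
#' @export
halfLife <- function(alpha) {
  if (any(alpha < 0)) stopf("alpha must be >= 0")
  ifelse(alpha == 0, Inf, log(2) / alpha)
}

#' Names and structure of the continuous-trait model family
#'
#' Regime-independent: `BM1` (single-rate Brownian motion), `OU1` (single-
#' optimum Ornstein-Uhlenbeck), `EB` (early burst: exponentially decaying
#' rate), `Trend` (BM with drift). Regime-dependent on a painted tree:
#' `BMS` (per-regime rate), `OUM` (per-regime optima, shared alpha and
#' sigma^2), `OUMA` (+ per-regime alpha), `OUMV` (+ per-regime sigma^2),
#' `OUMVA` (everything per regime).
#'
#' @param model model name.
#' @param m number of regimes (for parameter counting).
#' @return list describing parameter sharing and the free-parameter count.
#' @export
contModelInfo <- function(model, m = 1) {
  info <- switch(model,
    BM1   = list(type = "BM", theta_pr = FALSE, alpha_pr = FALSE,
                 sigma_pr = FALSE, eb = FALSE, trend = FALSE, K = 2),
    OU1   = list(type = "OU", theta_pr = FALSE, alpha_pr = FALSE,
                 sigma_pr = FALSE, eb = FALSE, trend = FALSE, K = 3),
    EB    = list(type = "BM", theta_pr = FALSE, alpha_pr = FALSE,
                 sigma_pr = FALSE, eb = TRUE, trend = FALSE, K = 3),
    Trend = list(type = "BM", theta_pr = FALSE, alpha_pr = FALSE,
                 sigma_pr = FALSE, eb = FALSE, trend = TRUE, K = 3),
    BMS   = list(type = "BM", theta_pr = FALSE, alpha_pr = FALSE,
                 sigma_pr = TRUE, eb = FALSE, trend = FALSE, K = m + 1),
    OUM   = list(type = "OU", theta_pr = TRUE, alpha_pr = FALSE,
                 sigma_pr = FALSE, eb = FALSE, trend = FALSE, K = m + 2),
    OUMA  = list(type = "OU", theta_pr = TRUE, alpha_pr = TRUE,
                 sigma_pr = FALSE, eb = FALSE, trend = FALSE, K = 2 * m + 1),
    OUMV  = list(type = "OU", theta_pr = TRUE, alpha_pr = FALSE,
                 sigma_pr = TRUE, eb = FALSE, trend = FALSE, K = 2 * m + 1),
    OUMVA = list(type = "OU", theta_pr = TRUE, alpha_pr = TRUE,
                 sigma_pr = TRUE, eb = FALSE, trend = FALSE, K = 3 * m),
    stopf("unknown continuous model '%s'", model))
  info$name <- model
  info$regime_dependent <- info$theta_pr || info$alpha_pr || info$sigma_pr
  info
}

#' @rdname contModelInfo
#' @export
contBatteryModels <- function() {
  list(regime_independent = c("BM1", "OU1", "EB", "Trend"),
       regime_dependent = c("BMS", "OUM", "OUMA", "OUMV", "OUMVA"))
}

# Per-node accumulation of the Gaussian structure along root-to-tip paths.
# Returns, per node: A (integrated alpha), V (accumulated variance, already
# attenuated to the node), W (theta weights per regime), c0 (weight of the
# root value), depth. Segment-by-segment, handles every model in the family.
contStructure <- function(ptree, alpha, sigma2, eb_r = 0) {
  regimes <- names(alpha)
  ntip <- ape::Ntip(ptree)
  nn <- ntip + ptree$Nnode
  m <- length(regimes)
  A <- numeric(nn)
  V <- numeric(nn)
  c0 <- numeric(nn)
  depth <- numeric(nn)
  W <- matrix(0, nn, m, dimnames = list(NULL, regimes))
  root <- ntip + 1
  c0[root] <- 1
  pre <- order(match(ptree$edge[, 1], c(root, ptree$edge[, 2])))
  # cladewise: parents always appear as child earlier; use ape ordering
  pre <- seq_len(nrow(ptree$edge))
  ord <- ape::reorder.phylo(ptree, "cladewise")$edge
  # map cladewise rows back to original edge indices to find the right maps
  key <- paste(ptree$edge[, 1], ptree$edge[, 2])
  idx <- match(paste(ord[, 1], ord[, 2]), key)
  for (r in seq_along(idx)) {
    e <- idx[r]
    p <- ptree$edge[e, 1]
    v <- ptree$edge[e, 2]
    seg <- ptree$maps[[e]]
    a <- A[p]
    vv <- V[p]
    cc <- c0[p]
    ww <- W[p, ]
    t0 <- depth[p]
    for (s in seq_along(seg)) {
      st <- names(seg)[s]
      d <- seg[[s]]
      if (!st %in% regimes) stopf("painting state '%s' not a model regime",
                                  st)
      al <- alpha[[st]]
      sg <- sigma2[[st]]
      if (al > 0) {
        ea <- exp(-al * d)
        em2 <- -expm1(-2 * al * d) # 1 - e^(-2 a d), stable for tiny a
        vv <- vv * ea^2 + sg / (2 * al) * em2
        cc <- cc * ea
        ww <- ww * ea
        ww[st] <- ww[st] - expm1(-al * d)
        a <- a + al * d
      } else {
        vseg <- if (eb_r != 0) {
          sg * (exp(eb_r * (t0 + d)) - exp(eb_r * t0)) / eb_r
        } else sg * d
        vv <- vv + vseg
      }
      t0 <- t0 + d
    }
    A[v] <- a
    V[v] <- vv
    c0[v] <- cc
    W[v, ] <- ww
    depth[v] <- t0
  }
  list(A = A, V = V, c0 = c0, W = W, depth = depth, ntip = ntip,
       regimes = regimes)
}

# tip covariance matrix from the accumulated structure
contCovariance <- function(str, mrcaM) {
  tips <- seq_len(str$ntip)
  Am <- matrix(str$A[mrcaM], str$ntip, str$ntip)
  C <- str$V[mrcaM] * exp(-(outer(str$A[tips], str$A[tips], "+") - 2 * Am))
  diag(C) <- str$V[tips]
  C
}

rootRegime <- function(ptree) {
  root <- ape::Ntip(ptree) + 1
  e <- which(ptree$edge[, 1] == root)[1]
  names(ptree$maps[[e]])[1]
}

# expand possibly-scalar parameter to per-regime named vector
perRegime <- function(x, regimes) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(x, length(regimes)), regimes))
  }
  if (!all(regimes %in% names(x))) stopf("missing regime parameter(s)")
  x[regimes]
}

#' Continuous-trait log-likelihood on a painted tree
#'
#' Multivariate-normal likelihood with mean vector and covariance matrix
#' assembled segment-by-segment along every root-to-tip path: Hansen-type
#' weighting of regime optima for OU models, per-regime variance
#' accumulation for BMS, time-rescaled BM for EB, and a drift term for
#' Trend. The root value is the root regime's optimum for OU models
#' (stationarity assumption) unless `params$x0` is supplied.
#'
#' @param ptree a painted phylogeny (any `phylo` works for the
#'   regime-independent models; it is treated as painted in one regime).
#' @param tip_values named numeric vector (species to value, e.g. log10
#'   body mass in grams).
#' @param model model name (see [contModelInfo()]).
#' @param params list with `theta`, `alpha`, `sigma2` (scalars or named
#'   per-regime vectors per the model's sharing), and optionally `x0`,
#'   `eb_r`, `drift`.
#' @return log-likelihood.
#' @export
contLoglik <- function(ptree, tip_values, model, params) {
  info <- contModelInfo(model)
  if (is.null(ptree$maps)) {
    ptree <- paintFromTips(unpaint(ptree),
                           setNames(rep("all", ape::Ntip(ptree)),
                                    ptree$tip.label), "all")
  }
  regimes <- paintingStates(ptree)
  alpha <- if (info$type == "OU") perRegime(params$alpha, regimes) else
    setNames(rep(0, length(regimes)), regimes)
  sigma2 <- perRegime(params$sigma2, regimes)
  eb_r <- params$eb_r %||% 0
  str <- contStructure(ptree, alpha, sigma2, eb_r)
  y <- tip_values[ptree$tip.label]
  if (anyNA(y)) stopf("missing tip value(s)")
  mrcaM <- ape::mrca(ptree)
  C <- contCovariance(str, mrcaM)
  tips <- seq_len(str$ntip)
  if (info$type == "OU") {
    theta <- perRegime(params$theta, regimes)
    x0 <- params$x0 %||% theta[[rootRegime(ptree)]]
    mu <- as.numeric(str$W[tips, , drop = FALSE] %*% theta +
                       str$c0[tips] * x0)
  } else {
    x0 <- params$x0 %||% params$theta[[1]]
    mu <- rep(x0, length(tips))
    if (info$trend) mu <- mu + (params$drift %||% 0) * str$depth[tips]
  }
  mvnLoglik(y, mu, C)
}

mvnLoglik <- function(y, mu, C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stopf("covariance not positive definite (condition number %.3g)",
          kappa(C))
  }
  r <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

# profiled GLS given relative covariance Ct (C = s * Ct) and design X:
# returns beta-hat, s-hat (ML), and the maximized log-likelihood
glsProfile <- function(y, X, Ct) {
  n <- length(y)
  ch <- tryCatch(chol(Ct), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  qrX <- qr(Xw)
  beta <- rep(0, ncol(X))
  beta[qrX$pivot[seq_len(qrX$rank)]] <-
    qr.coef(qrX, yw)[seq_len(qrX$rank)]
  beta[is.na(beta)] <- 0
  res <- yw - Xw %*% beta
  s <- sum(res^2) / n
  if (s <= 0) s <- .Machine$double.eps
  logL <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s) -
    sum(log(diag(ch))) - 0.5 * n
  list(beta = as.numeric(beta), s = s, logL = logL)
}

#' Fit a continuous-trait model on a painted tree
#'
#' Optima (and the root value / drift) are profiled out by generalized least
#' squares; the overall variance scale is profiled analytically; the
#' remaining nonlinear parameters (alpha values, relative variance weights,
#' the EB exponent) are optimized on the log scale with restarts.
#'
#' @inheritParams contLoglik
#' @param restarts optimizer restarts for the nonlinear parameters.
#' @param seed RNG seed for restart jitter.
#' @return a `contFit`: `params` (per-regime `theta`, `alpha`, `sigma2`,
#'   `x0`, `half_life`), `logL`, `K`, `model`, `diagnostics`.
#' @export
fitCont <- function(ptree, tip_values, model, restarts = 3, seed = 1) {
  info <- contModelInfo(model)
  if (is.null(ptree$maps) || !info$regime_dependent) {
    base <- if (is.null(ptree$maps)) ptree else unpaint(ptree)
    ptree <- paintFromTips(base,
                           setNames(rep("all", ape::Ntip(base)),
                                    base$tip.label), "all")
  }
  regimes <- paintingStates(ptree)
  m <- length(regimes)
  info <- contModelInfo(model, m)
  y <- tip_values[ptree$tip.label]
  if (anyNA(y)) stopf("missing tip value(s)")
  if (sd(y) == 0) {
    warnf("constant tip values: variance at lower bound, logL diverges")
  }
  mrcaM <- ape::mrca(ptree)
  tips <- seq_len(ape::Ntip(ptree))
  maxdepth <- max(nodeDepths(ptree))
  ultra <- isUltrametric(ptree)
  if (info$trend && ultra) {
    warnf("Trend on an ultrametric tree is weakly identified")
  }
  nA <- if (info$alpha_pr) m else if (info$type == "OU") 1 else 0
  nS <- if (info$sigma_pr) m - 1 else 0
  nE <- if (info$eb) 1 else 0
  eval_fn <- function(par) {
    alpha <- if (info$type == "OU") {
      a <- exp(par[seq_len(nA)])
      setNames(if (info$alpha_pr) a else rep(a, m), regimes)
    } else setNames(rep(0, m), regimes)
    sigw <- if (info$sigma_pr) {
      setNames(c(1, exp(par[nA + seq_len(nS)])), regimes)
    } else setNames(rep(1, m), regimes)
    eb_r <- if (info$eb) -exp(par[nA + nS + 1]) else 0
    str <- contStructure(ptree, alpha, sigw, eb_r)
    Ct <- contCovariance(str, mrcaM)
    X <- if (info$type == "OU") {
      # fold the root value into the root regime's optimum (stationarity)
      W <- str$W[tips, , drop = FALSE]
      W[, rootRegime(ptree)] <- W[, rootRegime(ptree)] + str$c0[tips]
      if (!info$theta_pr) matrix(rowSums(W), ncol = 1) else W
    } else if (info$trend) {
      cbind(1, str$depth[tips])
    } else matrix(1, length(tips), 1)
    g <- glsProfile(y, X, Ct)
    if (is.null(g) || !is.finite(g$logL)) return(NULL)
    list(g = g, alpha = alpha, sigw = sigw, eb_r = eb_r, X = X)
  }
  nll <- function(par) {
    r <- eval_fn(par)
    if (is.null(r)) return(1e10)
    -r$g$logL
  }
  npar <- nA + nS + nE
  if (npar == 0) {
    best_par <- numeric(0)
    objs <- -eval_fn(numeric(0))$g$logL
  } else {
    lower <- c(rep(log(1e-9), nA), rep(log(1e-6), nS),
               if (nE) log(1e-8 / maxdepth))
    upper <- c(rep(log(100 / maxdepth), nA), rep(log(1e6), nS),
               if (nE) log(10 / maxdepth))
    base <- c(rep(log(1 / maxdepth), nA), rep(0, nS),
              if (nE) log(1 / maxdepth))
    set.seed(seed)
    best <- NULL
    objs <- numeric(0)
    for (r in seq_len(restarts)) {
      start <- if (r == 1) base else
        pmin(pmax(base + rnorm(npar, 0, 1.5), lower), upper)
      o <- tryCatch(nlminb(start, nll, lower = lower, upper = upper),
                    error = function(e) NULL)
      if (is.null(o)) next
      objs <- c(objs, -o$objective)
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    if (is.null(best)) stopf("continuous-model fit failed (%s)", model)
    best_par <- best$par
  }
  fin <- eval_fn(best_par)
  g <- fin$g
  sigma2 <- fin$sigw * g$s
  theta <- if (info$type == "OU") {
    if (info$theta_pr) setNames(g$beta, regimes) else
      setNames(rep(g$beta[1], m), regimes)
  } else setNames(rep(g$beta[1], m), regimes)
  x0 <- if (info$type == "OU") theta[[rootRegime(ptree)]] else g$beta[1]
  drift <- if (info$trend) g$beta[2] else NULL
  structure(list(
    params = list(theta = theta, alpha = fin$alpha, sigma2 = sigma2,
                  x0 = x0, eb_r = fin$eb_r, drift = drift,
                  half_life = if (info$type == "OU") halfLife(fin$alpha)),
    logL = g$logL, K = info$K, model = model, regimes = regimes,
    diagnostics = list(restarts = length(objs), best_per_restart = objs,
                       seed = seed)), class = "contFit")
}

#' @export
print.contFit <- function(x, ...) {
  cat(sprintf("Continuous fit: %s (%d regimes), logL = %.4f, K = %d\n",
              x$model, length(x$regimes), x$logL, x$K))
  tab <- data.frame(regime = x$regimes, theta = x$params$theta,
                    alpha = x$params$alpha, sigma2 = x$params$sigma2)
  if (!is.null(x$params$half_life)) tab$half_life <- x$params$half_life
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fit the 14-model continuous-trait battery
#'
#' Four regime-independent models on the bare tree plus the five
#' regime-dependent models on each of the two-state and four-state
#' paintings (4 + 5 + 5 = 14 rows), optionally plus a third run with
#' flightless taxa as their own regime. Regime-dependent rows are named
#' `"<model> (<system>)"`.
#'
#' @param tree a `phylo`.
#' @param paintings named list of painted trees, e.g.
#'   `list("two-state" = ..., "four-state" = ...)`; an optional
#'   `"flightless"` element adds the third run.
#' @param tip_values named numeric vector of trait values.
#' @param restarts,seed passed to [fitCont()].
#' @return list with `comparison` (ranked AIC table) and `fits`; OU fits
#'   report per-regime half-lives.
#' @export
runContBattery <- function(tree, paintings, tip_values, restarts = 3,
                           seed = 1) {
  fits <- list()
  i <- 0
  for (mod in contBatteryModels()$regime_independent) {
    i <- i + 1
    fits[[mod]] <- fitCont(tree, tip_values, mod, restarts = restarts,
                           seed = deriveSeed(seed, i))
  }
  for (sys in names(paintings)) {
    for (mod in contBatteryModels()$regime_dependent) {
      i <- i + 1
      nm <- sprintf("%s (%s)", mod, sys)
      fits[[nm]] <- fitCont(paintings[[sys]], tip_values, mod,
                            restarts = restarts, seed = deriveSeed(seed, i))
    }
  }
  cmp <- aicCompare(data.frame(name = names(fits),
                               logL = vapply(fits, `[[`, 0, "logL"),
                               K = vapply(fits, function(f)
                                 as.integer(f$K), 0L)))
  list(comparison = cmp, fits = fits)
}
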