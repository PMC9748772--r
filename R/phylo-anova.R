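#' Effect size eta squared
#'
#' `SS_between / SS_total` for a one-way layout.
#'
#' @param groups factor or character vector of group labels.
#' @param values numeric vector, same length.
#' @return eta squared in `[0, 1]`.
#' @export
etaSquared <- function(groups, values) {
  groups <- as.factor(groups)
  if (length(groups) != length(values)) stopf("length mismatch")
  sst <- sum((values - mean(values))^2)
  if (sst == 0) stopf("zero total variance")
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (gm - mean(values))^2)
  ssb / sst
}

# one-way F and pairwise t statistics for a matrix of datasets (columns)
anovaStats <- function(V, gidx, ng) {
  g <- length(ng)
  n <- nrow(V)
  m <- colMeans(V)
  Gm <- rowsum(V, gidx) / ng # g x nsim group means
  ssb <- colSums(ng * (Gm - rep(m, each = g))^2)
  sst <- colSums(V^2) - n * m^2
  ssw <- pmax(sst - ssb, 0)
  mse <- ssw / (n - g)
  f <- (ssb / (g - 1)) / mse
  pairs <- utils::combn(g, 2)
  tmat <- matrix(0, ncol(pairs), ncol(V))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    tmat[p, ] <- (Gm[i, ] - Gm[j, ]) /
      sqrt(mse * (1 / ng[i] + 1 / ng[j]))
  }
  list(F = f, t = tmat, pairs = pairs, df2 = n - g)
}

#' Phylogenetic (simulation-based) ANOVA
#'
#' One-way ANOVA of a tip trait across groups, with the null F distribution
#' generated by Brownian-motion simulation on the phylogeny: `nsim` datasets
#' are drawn with the evolutionary rate set from the data (mean squared
#' phylogenetically independent contrast), and the phylogenetic p value is
#' the `(+1/+1)`-corrected proportion of simulated F at or above the observed
#' one. Pairwise t statistics are treated identically and Holm-corrected
#' across all pairs; eta squared measures effect size.
#'
#' @param tree a `phylo` object.
#' @param groups named character/factor vector (species to category).
#' @param values named numeric vector (species to trait value).
#' @param nsim number of Brownian null simulations (default 1000).
#' @param seed RNG seed.
#' @return a `phyloAnova` list: `F`, `p_standard`, `p_phylo`, `eta_squared`,
#'   `pairwise_t`, `pairwise_p_standard`, `pairwise_p_phylo` (both
#'   Holm-corrected, symmetric matrices), `nsim`, `seed`.
#' @export
phyloAnova <- function(tree, groups, values, nsim = 1000, seed = 1) {
  if (nsim < 100) stopf("nsim must be >= 100")
  sp <- tree$tip.label
  if (!all(sp %in% names(groups)) || !all(sp %in% names(values))) {
    stopf("groups/values must cover every tip")
  }
  gr <- factor(unname(groups[sp]))
  y <- unname(values[sp])
  ng <- tabulate(gr)
  if (nlevels(gr) < 2 || any(ng < 2)) {
    stopf("need >= 2 groups with >= 2 members each")
  }
  if (sd(y) == 0) stopf("constant trait values")
  gidx <- as.integer(gr)
  obs <- anovaStats(matrix(y, ncol = 1), gidx, ng)
  g <- nlevels(gr)
  n <- length(y)
  p_std <- pf(obs$F, g - 1, obs$df2, lower.tail = FALSE)
  # Brownian null on the tree, rate from independent contrasts
  bt <- if (ape::is.binary(tree)) tree else ape::multi2di(tree)
  contrasts <- ape::pic(setNames(y, sp), bt)
  sig2 <- mean(contrasts^2)
  C <- ape::vcv.phylo(tree)[sp, sp]
  set.seed(seed)
  Z <- matrix(rnorm(n * nsim), n, nsim)
  V <- crossprod(chol(C), Z) * sqrt(sig2)
  null <- anovaStats(V, gidx, ng)
  p_phy <- (1 + sum(null$F >= obs$F)) / (nsim + 1)
  # pairwise matrices
  lv <- levels(gr)
  np <- ncol(obs$pairs)
  t_obs <- obs$t[, 1]
  p_t_std <- 2 * pt(abs(t_obs), obs$df2, lower.tail = FALSE)
  p_t_phy <- vapply(seq_len(np), function(p) {
    (1 + sum(abs(null$t[p, ]) >= abs(t_obs[p]))) / (nsim + 1)
  }, numeric(1))
  p_t_std_h <- p.adjust(p_t_std, "holm")
  p_t_phy_h <- p.adjust(p_t_phy, "holm")
  toMat <- function(v, diag_val = NA) {
    M <- matrix(diag_val, g, g, dimnames = list(lv, lv))
    for (p in seq_len(np)) {
      i <- obs$pairs[1, p]
      j <- obs$pairs[2, p]
      M[i, j] <- M[j, i] <- v[p]
    }
    M
  }
  structure(list(F = obs$F, p_standard = p_std, p_phylo = p_phy,
                 eta_squared = etaSquared(gr, y),
                 pairwise_t = toMat(t_obs, 0),
                 pairwise_p_standard = toMat(p_t_std_h, 1),
                 pairwise_p_phylo = toMat(p_t_phy_h, 1),
                 sig2 = sig2, nsim = nsim, seed = seed,
                 groups = lv, n = n),
            class = "phyloAnova")
}

#' @export
print.phyloAnova <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ANOVA (%d tips, %d groups, %d BM simulations)\n",
    x$n, length(x$groups), x$nsim))
  cat(sprintf("F = %.4g, standard p = %.3g, phylogenetic p = %.3g, ",
              x$F, x$p_standard, x$p_phylo))
  cat(sprintf("eta^2 = %.3f\n", x$eta_squared))
  invisible(x)
}
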