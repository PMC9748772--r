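#' Akaike information criterion
#'
#' `AIC = -2 log L + 2 K`. The paper-style comparison tables in this package
#' all use plain AIC (no small-sample correction).
#'
#' @param logL log-likelihood (finite).
#' @param K number of free parameters (non-negative integer).
#' @return the AIC value.
#' @export
aic <- function(logL, K) {
  if (!is.finite(logL)) stopf("non-finite log-likelihood")
  if (!isCount(K)) stopf("K must be a non-negative integer")
  -2 * logL + 2 * K
}

#' Compare models by AIC weight
#'
#' Computes `AIC`, `delta_AIC = AIC_i - AIC_min` and Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`, working from delta values
#' for numerical stability. Rows are sorted by weight (descending), ties
#' broken by fewer parameters then by name. The `support` column applies the
#' conventional bands: substantial (delta < 2), minimal (2-7), none (> 7).
#'
#' @param scores a data frame with columns `name`, `logL`, `K`.
#' @return a data frame of model scores sorted by weight.
#' @export
aicCompare <- function(scores) {
  if (!all(c("name", "logL", "K") %in% names(scores))) {
    stopf("`scores` needs columns name, logL, K")
  }
  if (nrow(scores) < 1) stopf("at least one model required")
  if (anyDuplicated(scores$name)) stopf("duplicate model names")
  if (any(!is.finite(scores$logL))) stopf("non-finite log-likelihood")
  out <- data.frame(name = as.character(scores$name),
                    logL = as.numeric(scores$logL),
                    K = as.integer(scores$K),
                    stringsAsFactors = FALSE)
  out$AIC <- -2 * out$logL + 2 * out$K
  out$delta_AIC <- out$AIC - min(out$AIC)
  rel <- exp(-out$delta_AIC / 2)
  out$weight <- rel / sum(rel)
  out$support <- supportCategory(out$delta_AIC)
  ord <- order(-out$weight, out$K, out$name)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "name", "logL", "K", "AIC", "delta_AIC", "weight",
          "support")]
}

#' Support category from delta-AIC
#'
#' @param delta numeric vector of delta-AIC values.
#' @return character vector: "substantial", "minimal" or "none".
#' @export
supportCategory <- function(delta) {
  ifelse(delta < 2, "substantial", ifelse(delta <= 7, "minimal", "none"))
}

#' Write a model-comparison table as CSV
#'
#' @param comparison output of [aicCompare()] (possibly with extra columns).
#' @param file output path.
#' @export
writeComparison <- function(comparison, file) {
  utils::write.csv(comparison, file, row.names = FALSE)
  invisible(file)
}
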