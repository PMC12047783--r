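#' Classify the modality of an estimate distribution
#'
#' Fits univariate Gaussian mixtures with 1..`k_max` components (via mclust)
#' and selects the component count by BIC. The selected count is reported as
#' the distribution's "modality" label (unimodal / bimodal / trimodal), the
#' convention used when describing estimate distributions, even though
#' mixture components and density modes are not identical in general.
#'
#' @param est Numeric sample of estimates (length >= 10).
#' @param k_max Maximum number of components (default 3).
#' @return A list with `k` (selected component count), `label`, `bic`
#'   (per-k BIC, mclust convention: larger is better), and `fit` (the mclust
#'   object).
#' @export
gmm_modality <- function(est, k_max = 3) {
  stopifnot(is.numeric(est), k_max >= 1)
  if (length(est) < 10) stop("sample too small for modality classification (need >= 10)")
  bic <- mclust::mclustBIC(est, G = seq_len(k_max), verbose = FALSE)
  fit <- mclust::Mclust(est, x = bic)
  if (is.null(fit)) stop("mixture fit failed")
  k <- fit$G
  labels <- c("unimodal", "bimodal", "trimodal",
              paste0(seq(4, max(4, k_max)), "-modal"))
  bic <- apply(fit$BIC, 1, max, na.rm = TRUE)
  list(k = k, label = labels[k], bic = bic, fit = fit)
}
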