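#' Likelihood-ratio test between nested models from reported likelihoods
#'
#' Compares two nested models given only their *negative* log-likelihoods,
#' as printed by range-evolution or other model-fitting software:
#' `D = 2 (negLnL_null - negLnL_alt)` against a chi-square upper tail with
#' `df` degrees of freedom. The tail is computed in full double precision
#' (no underflow to zero above ~1e-300). A negative `D` (inverted or
#' non-nested input) is flagged and reported with `p = 1`.
#'
#' @param neg_lnl_null Negative log-likelihood of the simpler model.
#' @param neg_lnl_alt Negative log-likelihood of the richer model.
#' @param df Number of added parameters (>= 1).
#' @return One-row tibble: `neg_lnl_null`, `neg_lnl_alt`, `statistic`, `df`,
#'   `p_value`, `inverted`.
#' @examples
#' nested_lrt(149.74, 119.92, df = 1)
#' @export
nested_lrt <- function(neg_lnl_null, neg_lnl_alt, df = 1) {
  if (df < 1) abort("`df` must be >= 1")
  D <- 2 * (neg_lnl_null - neg_lnl_alt)
  inverted <- D < 0
  if (inverted) {
    warn("alternative model has a worse likelihood than the null; models may not be nested")
  }
  tibble(
    neg_lnl_null = neg_lnl_null,
    neg_lnl_alt = neg_lnl_alt,
    statistic = D,
    df = as.integer(df),
    p_value = if (inverted) 1 else pchisq(D, df = df, lower.tail = FALSE),
    inverted = inverted
  )
}

#' Correlation between species richness and a substrate measure
#'
#' Pearson correlation between per-island species counts and a measure of
#' habitat availability (e.g. rocky-coast length in km, or percent rocky
#' shore), with the two-sided t-test `t = r sqrt(df / (1 - r^2))`,
#' `df = n - 2`. The conventional compact report is `r(df) = r, p = p`.
#'
#' @param data Data frame with one row per island.
#' @param richness,measure Columns of `data` (tidy-eval) holding species
#'   counts and the substrate measure.
#' @return One-row tibble: `n`, `r`, `df`, `statistic`, `p_value`.
#' @examples
#' d <- tibble::tibble(island = letters[1:8],
#'                     species = c(1, 3, 2, 1, 2, 1, 1, 2),
#'                     rocky_km = c(120, 15, 60, 80, 30, 90, 100, 45))
#' richness_correlation(d, species, rocky_km)
#' @export
richness_correlation <- function(data, richness, measure) {
  x <- dplyr::pull(data, {{ richness }})
  y <- dplyr::pull(data, {{ measure }})
  if (length(x) != length(y)) abort("`richness` and `measure` must have equal length")
  if (length(x) < 3) abort("at least 3 islands are required")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in richness or measure; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(
    n = length(x),
    r = unname(ct$estimate),
    df = as.integer(unname(ct$parameter)),
    statistic = unname(ct$statistic),
    p_value = ct$p.value
  )
}
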