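#' Upper-tail chi-squared p-value for a score
#'
#' @param score non-negative G or Wald score (vectorised).
#' @param df degrees of freedom (>= 1).
#' @return `P(chi2_df >= score)`.
#' @export
chi2_pvalue <- function(score, df = 1L) {
  if (any(!is.na(score) & score < 0)) stop("negative score")
  stopifnot(all(df >= 1))
  pchisq(score, df = df, lower.tail = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid
#' \{0.05, 0.10, ..., 0.95\} as `mean(p > lambda) / (1 - lambda)` and
#' extrapolates to lambda = 1 with a cubic smoothing spline (df = 3). With
#' fewer than 100 p-values the plug-in estimate at lambda = 0.5 is used
#' instead. pi0 is clipped to (0, 1]. q-values are
#' `pi0 * min_{p_(j) >= p_(i)} (m p_(j) / j)`; ties share the minimum.
#' Forcing `pi0 = 1` recovers Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @param pi0 optional fixed pi0 overriding the estimate.
#' @return List: `q` (same length/order as `p`), `pi0`.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  ok <- !is.na(p)
  if (!length(p) || !any(ok)) stop("empty p-value vector")
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  pv <- p[ok]
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- mean(pv > 0.5) / 0.5
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0l <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1L))
      fit <- smooth.spline(lam, pi0l, df = 3)
      pi0 <- predict(fit, x = 1)$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(pv, decreasing = TRUE)
  qv <- numeric(m)
  qv[o] <- cummin(m / (m:1) * pv[o])   # BH step-up from the largest p down
  qv <- pmin(pi0 * qv, 1)
  out <- rep(NA_real_, length(p))
  out[ok] <- qv
  list(q = out, pi0 = pi0)
}

#' Bonferroni-adjusted p-values
#'
#' `min(1, m * p)` elementwise. `m` may exceed `length(p)` when the table
#' holds only a stored subset of a larger test universe.
#'
#' @param p p-value vector.
#' @param m number of tests in the correction universe (default
#'   `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Attach p-, q- and Bonferroni-adjusted values to a scan table
#'
#' Adds `p_G`, `p_Wald` (upper-tail chi-squared on `df`), `q_G`, `q_Wald`
#' (Storey) and `p_bonf` (Bonferroni on `p_G`). By default the correction
#' universe is per environmental variable (each variable's Manhattan plot is
#' corrected on its own tests); `global_m = TRUE` corrects across the whole
#' table instead.
#'
#' @param results data.frame from [run_scan()].
#' @param global_m logical: correct over all rows jointly.
#' @param m_override optional explicit test count for Bonferroni.
#' @return `ResultTable`: the input with significance columns appended and
#'   attribute `pi0` (named per env variable, or `"global"`).
#' @export
add_significance <- function(results, global_m = FALSE, m_override = NULL) {
  res <- results
  scored <- !is.na(res$G) & res$status %in% c("converged", "separated")
  res$p_G <- res$p_Wald <- NA_real_
  res$p_G[scored] <- chi2_pvalue(pmax(res$G[scored], 0), res$df[scored])
  wok <- scored & !is.na(res$Wald)
  res$p_Wald[wok] <- chi2_pvalue(pmax(res$Wald[wok], 0), res$df[wok])
  res$q_G <- res$q_Wald <- res$p_bonf <- NA_real_
  groups <- if (global_m) list(global = seq_len(nrow(res)))
  else split(seq_len(nrow(res)), res$env)
  pi0s <- numeric(0)
  for (gn in names(groups)) {
    i <- groups[[gn]]
    if (!any(!is.na(res$p_G[i]))) next
    sg <- storey_qvalues(res$p_G[i])
    res$q_G[i] <- sg$q
    if (any(!is.na(res$p_Wald[i])))
      res$q_Wald[i] <- storey_qvalues(res$p_Wald[i])$q
    m <- if (is.null(m_override)) sum(!is.na(res$p_G[i])) else m_override
    res$p_bonf[i] <- bonferroni(res$p_G[i], m)
    pi0s[gn] <- sg$pi0
  }
  attr(res, "pi0") <- pi0s
  res
}

#' Filter a result table for plotting
#'
#' Keeps rows whose best score, `max(G, Wald)`, strictly exceeds
#' `score_min`. The conventional display cut-off of 6 (roughly p < 0.014 on
#' 1 df) thins the uninteresting bulk of a Manhattan plot. The input table
#' is not modified.
#'
#' @param rt result table.
#' @param score_min score cut-off (default 6).
#' @return Filtered copy of `rt`.
#' @export
filter_for_plot <- function(rt, score_min = 6) {
  if (!nrow(rt)) return(rt)
  s <- pmax(rt$G, rt$Wald, na.rm = TRUE)
  keep <- !is.na(s) & s > score_min
  rt[keep, , drop = FALSE]
}
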