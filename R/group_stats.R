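# Group summaries and the Tukey-Kramer all-pairs multiple comparison.

#' Summarize per-cell focus counts by group
#'
#' @param counts Numeric vector of per-cell counts.
#' @param group Group labels (same length).
#' @param min_n Groups below this size are flagged.
#' @return Data frame of `GroupSummary` rows: `group`, `n`, `mean`, `sd`,
#'   `sem`, `flagged`.
#' @export
summarize_groups <- function(counts, group, min_n = 2) {
  if (length(counts) == 0)
    return(data.frame(group = character(), n = integer(), mean = numeric(),
                      sd = numeric(), sem = numeric(), flagged = logical()))
  g <- factor(group, levels = unique(group))
  n <- as.integer(tapply(counts, g, length))
  m <- as.numeric(tapply(counts, g, mean))
  s <- as.numeric(tapply(counts, g, function(x) if (length(x) > 1) sd(x) else 0))
  data.frame(group = levels(g), n = n, mean = m, sd = s,
             sem = s / sqrt(n), flagged = n < min_n)
}

#' Tukey-Kramer all-pairs comparison
#'
#' Studentized-range test on all group pairs with the pooled within-group
#' variance from one-way ANOVA; the Kramer adjustment handles unequal group
#' sizes. The p-value is `1 - ptukey(q, k, N - k)` with
#' `q = |m_a - m_b| / sqrt(MSW/2 * (1/n_a + 1/n_b))`.
#'
#' @param groups Named list of numeric sample vectors (>= 2 groups, each
#'   n >= 2).
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return Data frame of `PairwiseComparison` rows: `group_a`, `group_b`,
#'   `mean_diff`, `q_statistic`, `p_value`, `significant`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("every group needs at least two observations: ",
                       paste(names(groups)[n < 2], collapse = ", "))
  m <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  msw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) /
    (N - k)
  pairs <- utils::combn(k, 2)
  out <- data.frame(group_a = names(groups)[pairs[1, ]],
                    group_b = names(groups)[pairs[2, ]],
                    mean_diff = m[pairs[2, ]] - m[pairs[1, ]])
  if (msw <= 0) {
    if (any(abs(out$mean_diff) > 0))
      warning("zero within-group variance with unequal means; p set to 0")
    out$q_statistic <- ifelse(abs(out$mean_diff) > 0, Inf, 0)
    out$p_value <- ifelse(abs(out$mean_diff) > 0, 0, 1)
  } else {
    se <- sqrt(msw / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
    out$q_statistic <- abs(out$mean_diff) / se
    out$p_value <- 1 - stats::ptukey(out$q_statistic, k, N - k)
  }
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Yield reduction under half-field exposure
#'
#' Ratio of the mean per-Gy yield of in-field half-field cells to the mean
#' full-field yield, in percent, with the SD from first-order propagation
#' of the two per-cell SDs assuming independent samples:
#' `sd% = ratio * sqrt((sd_h/m_h)^2 + (sd_f/m_f)^2)`.
#'
#' @param in_field_half Per-cell yields (foci per Gy) of in-field cells
#'   under half-field exposure.
#' @param full_field Per-cell yields under uniform (full-field) exposure.
#' @return List with `ratio_pct`, `sd_pct`, and the two group means.
#' @export
yield_reduction <- function(in_field_half, full_field) {
  mh <- mean(in_field_half); mf <- mean(full_field)
  if (mf == 0) stop("full-field mean yield is zero")
  ratio <- mh / mf * 100
  sdh <- sd(in_field_half); sdf <- sd(full_field)
  sd_pct <- if (mh > 0) ratio * sqrt((sdh / mh)^2 + (sdf / mf)^2) else 0
  list(ratio_pct = ratio, sd_pct = sd_pct, mean_half = mh, mean_full = mf)
}
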