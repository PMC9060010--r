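# Group summaries and two-sample tests for young-vs-aged style comparisons.
# Both the Mann-Whitney U test (exact by enumeration at small n, the test
# named in the study's figure legends) and the equal-variance Student's t
# (named in its Methods) are always computed; the headline test is
# Mann-Whitney. With n = 3 per group the exact two-sided Mann-Whitney p
# cannot fall below 0.1 - a documented small-sample limit.

#' Mann-Whitney U test with exact small-sample p
#'
#' U is computed from midrank sums. For `n_A + n_B <= exact_limit` (default
#' 12) the p-value is obtained by exhaustively enumerating all
#' `choose(n_A + n_B, n_A)` assignments of the observed (possibly tied)
#' pooled ranks; above that a normal approximation with tie correction and
#' continuity correction is used. The two-sided exact p is the probability
#' of a U at least as far from `n_A n_B / 2` as observed.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (A tends larger)
#'   or `"less"`.
#' @param exact_limit Largest `n_A + n_B` for exact enumeration.
#' @return List with `U` (the U statistic of sample `a`), `p`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p # 0.1, the n=3 floor
#' @export
mann_whitney_exact <- function(a, b,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               exact_limit = 12L) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b)) # midranks for ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exact_limit) {
    splits <- utils::combn(n, na)
    Us <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
      greater = mean(Us >= U - 1e-9),
      less = mean(Us <= U + 1e-9))
    return(list(U = U, p = p, method = "exact"))
  }
  # normal approximation with tie correction
  ties <- table(r)
  sigma2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
    two.sided = (abs(U - mu) - 0.5) / sigma,
    greater = (U - mu - 0.5) / sigma,
    less = -(U - mu + 0.5) / sigma)
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-max(z, 0))
       else stats::pnorm(-z)
  list(U = U, p = min(p, 1), method = "normal")
}

#' Equal-variance two-sample Student's t test
#'
#' Pooled-variance t with `n_A + n_B - 2` degrees of freedom, two-sided p.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
students_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Percent-difference conventions
#'
#' "165% thicker" is ambiguous between a ratio of 165% (1.65x) and an
#' increase of 165% (2.65x); both conventions are therefore returned,
#' labelled. `percent_ratio = 100 * comparison / reference`;
#' `percent_change = 100 * (comparison / reference - 1)`.
#'
#' @param reference_mean Reference (e.g. young) group mean; non-zero.
#' @param comparison_mean Comparison (e.g. aged) group mean.
#' @return Named list `percent_ratio`, `percent_change`.
#' @examples
#' percent_difference(10, 16.5) # ratio 165%, change +65%
#' percent_difference(10, 5.5)  # ratio 55%,  change -45%
#' @export
percent_difference <- function(reference_mean, comparison_mean) {
  if (!is.finite(reference_mean) || reference_mean == 0)
    stop("reference mean must be non-zero")
  ratio <- comparison_mean / reference_mean
  list(percent_ratio = 100 * ratio, percent_change = 100 * (ratio - 1))
}

star_annotation <- function(p, levels = c(0.05, 0.01, 0.005)) {
  levels <- sort(levels, decreasing = TRUE)
  strrep("*", sum(p < levels))
}

#' Compare metric distributions between two groups
#'
#' Per metric: group means, SDs and sizes; Mann-Whitney U with exact
#' small-sample p; Student's t; both percent conventions (group A is the
#' reference); and a star annotation from the Mann-Whitney p at the given
#' significance levels. No multiple-testing correction is applied.
#'
#' @param records A metrics `data.frame` (see [metrics_record()]) with a
#'   `group` column containing exactly two levels, or a list of two
#'   data frames.
#' @param metrics Character vector of metric columns to compare (default:
#'   all standard metric columns present).
#' @param reference Reference group label (default: first level
#'   encountered, e.g. `"young"`).
#' @param levels Significance thresholds for stars.
#' @return `data.frame` with one row per metric: `metric`, `group_a`,
#'   `group_b`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `U`,
#'   `p_mwu`, `t`, `p_t`, `percent_ratio`, `percent_change`, `stars`.
#' @export
compare_groups <- function(records, metrics = NULL, reference = NULL,
                           levels = c(0.05, 0.01, 0.005)) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (!"group" %in% names(records)) stop("records need a `group` column")
  groups <- unique(records$group)
  if (length(groups) != 2L)
    stop("exactly two groups are required (found ",
         length(groups), ")")
  if (!is.null(reference)) {
    if (!reference %in% groups) stop("reference group not present")
    groups <- c(reference, setdiff(groups, reference))
  }
  explicit <- !is.null(metrics)
  if (!explicit)
    metrics <- intersect(metrics_value_cols, names(records))
  out <- list()
  for (m in metrics) {
    va <- records[records$group == groups[1], m, drop = TRUE]
    vb <- records[records$group == groups[2], m, drop = TRUE]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) && !length(vb)) {
      if (explicit) stop("metric ", m, " is absent from all records")
      next # auto-selected metrics that were never computed are skipped
    }
    if (!length(va) || !length(vb)) next
    mw <- mann_whitney_exact(va, vb)
    tt <- if (length(va) >= 2 && length(vb) >= 2 &&
              (stats::var(va) > 0 || stats::var(vb) > 0))
      students_t(va, vb) else list(t = NA_real_, p = NA_real_)
    pc <- if (mean(va) != 0) percent_difference(mean(va), mean(vb))
          else list(percent_ratio = NA_real_, percent_change = NA_real_)
    out[[m]] <- data.frame(
      metric = m, group_a = groups[1], group_b = groups[2],
      mean_a = mean(va), sd_a = sd(va), n_a = length(va),
      mean_b = mean(vb), sd_b = sd(vb), n_b = length(vb),
      U = mw$U, p_mwu = mw$p, t = tt$t, p_t = tt$p,
      percent_ratio = pc$percent_ratio,
      percent_change = pc$percent_change,
      stars = star_annotation(mw$p, levels),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
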