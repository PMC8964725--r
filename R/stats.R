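# The statistical reporting surface: fold changes, normalization to the
# regular-pegRNA baseline, the one-tailed Wilcoxon signed-rank test and
# median/IQR summaries.

#' Fold change between two frequencies
#'
#' `treated / control`, optionally flooring the control at a detection
#' limit; e.g. `fold_change(49.76, 0.01)` is 4976.
#'
#' @param treated,control frequencies in percent (vectorised).
#' @param floor optional lower bound applied to `control` before division
#'   (documents how a 0.01% control yields large but finite folds).
#' @return numeric vector of ratios.
#' @export
fold_change <- function(treated, control, floor = NULL) {
  if (any(treated < 0)) pc_stop("treated must be >= 0", "pegcraft_invalid_spec")
  if (!is.null(floor)) control <- pmax(control, floor)
  if (any(control <= 0))
    pc_stop("control frequency is zero; supply a floor", "pegcraft_undefined_fold")
  treated / control
}

#' Normalize frequencies to a reference condition
#'
#' Element-wise `values / reference_values`; setting the frequencies induced
#' by the reference condition (e.g. regular pegRNAs) as 1.
#'
#' @param values,reference_values equal-length numeric vectors.
#' @param floor optional flooring of the reference values.
#' @return normalized values.
#' @export
normalize_to_reference <- function(values, reference_values, floor = NULL) {
  stopifnot(length(values) == length(reference_values))
  fold_change(values, reference_values, floor)
}

#' One-tailed Wilcoxon signed-rank test
#'
#' Tests paired measurements `a` vs `b`. Zero differences are dropped
#' before ranking (Wilcoxon's treatment); tied absolute differences receive
#' mid-ranks. The p-value is exact -- P(W+ >= w) for "greater",
#' P(W+ <= w) for "less", with the null distribution obtained over all 2^m
#' sign assignments -- when m <= 25 and no absolute differences are tied;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @param alternative "greater" (a > b, the default) or "less".
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact computation;
#'   NULL (default) for the rule above.
#' @return list with `statistic` (W+), `n` (nonzero pairs) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("greater", "less"),
                                 exact = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    pc_stop("all paired differences are zero; the test is degenerate",
            "pegcraft_degenerate_test")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (is.null(exact)) exact <- m <= 25L && !ties
  if (exact && ties)
    warning("tied absolute differences: exact distribution uses mid-ranks")
  if (exact) {
    p <- signrank_exact_p(r, w, alternative)
  } else {
    mu <- m * (m + 1) / 4
    tie_counts <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    z <- if (alternative == "greater") (w - mu - 0.5) / sqrt(sigma2)
         else (w - mu + 0.5) / sqrt(sigma2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
  }
  list(statistic = w, n = m, p_value = min(1, p))
}

# Exact tail probability of W+ over all sign assignments of the given
# ranks, by convolution (ranks doubled so mid-ranks stay integral).
signrank_exact_p <- function(ranks, w, alternative) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # dist[s+1] = #assignments with 2*W+ == s
  dist[1] <- 1
  for (rk in r2) {
    shifted <- c(rep(0, rk), dist[seq_len(length(dist) - rk)])
    dist <- dist + shifted
  }
  dist <- dist / 2^length(r2)
  w2 <- round(2 * w)
  if (alternative == "greater") sum(dist[(w2 + 1L):(total + 1L)])
  else sum(dist[1:(w2 + 1L)])
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation of the empirical distribution (the
#' common default convention, type 7).
#'
#' @param values non-empty numeric vector.
#' @return named vector `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (!length(values) || all(is.na(values)))
    pc_stop("values must be non-empty", "pegcraft_invalid_spec")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE,
                       na.rm = TRUE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Compare treated vs control editing frequencies
#'
#' Assembles the standard comparison report: per-site frequencies, values
#' normalized to the control (control = 1), fold changes, the one-tailed
#' Wilcoxon signed-rank p-value and median/IQR of the normalized values.
#'
#' @param treated,control equal-length numeric vectors of frequencies in
#'   percent, one entry per edit/site.
#' @param labels optional site labels.
#' @param alternative direction for the Wilcoxon test (default "greater").
#' @param floor optional flooring of control values for normalization.
#' @return list with `table` (per-site data frame), `wilcoxon` and
#'   `summary` (median/IQR of normalized values).
#' @export
report_comparison <- function(treated, control, labels = NULL,
                              alternative = "greater", floor = NULL) {
  stopifnot(length(treated) == length(control))
  if (is.null(labels)) labels <- paste0("site", seq_along(treated))
  norm <- normalize_to_reference(treated, control, floor)
  tab <- data.frame(site = labels, treated = treated, control = control,
                    normalized = norm,
                    fold = fold_change(treated, control, floor))
  wt <- wilcoxon_signed_rank(treated, control, alternative)
  list(table = tab, wilcoxon = wt, summary = median_iqr(norm))
}
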