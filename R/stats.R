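## Duration-normalised score aggregation and the nonparametric comparison
## battery: Wilcoxon-Mann-Whitney with tie-corrected normal approximation
## (exact tail for small tie-free samples), Kruskal-Wallis, Dunn-type
## pairwise rank comparison, Bonferroni-Holm step-down correction and
## Cliff's delta effect sizes.

REBA_SCORE_RANGE <- 1:14

#' Duration-normalised REBA score histogram
#'
#' Relative frequency of each final REBA score over a series; the mean
#' score is taken from the relative distribution, so merging histograms
#' across sequences ([merge_reba_histograms()]) weights by sequence length.
#'
#' @param x A `reba_series` (from [compute_reba_series()]) or an integer
#'   vector of final scores in 1-14.
#' @param source Identifier for the sequence/subject/group the histogram
#'   summarises.
#' @return A `reba_histogram`: list with `rel_freq` (named, scores 1-14),
#'   `mean_reba`, `total_frames`, `source`.
#' @export
reba_histogram <- function(x, source = NULL) {
  scores <- if (inherits(x, "reba_series")) {
    if (is.null(source)) source <- x$sequence_label
    x$scores$final
  } else x
  if (!length(scores)) stop("empty score series", call. = FALSE)
  if (any(!scores %in% REBA_SCORE_RANGE)) {
    stop("final REBA scores must lie in 1..14", call. = FALSE)
  }
  counts <- tabulate(scores, nbins = max(REBA_SCORE_RANGE))
  rel <- counts / length(scores)
  names(rel) <- REBA_SCORE_RANGE
  structure(
    list(rel_freq = rel, mean_reba = sum(REBA_SCORE_RANGE * rel),
         total_frames = length(scores), source = source %||% "scores"),
    class = "reba_histogram")
}

#' Merge REBA histograms, weighting by duration
#'
#' @param ... `reba_histogram` objects, or a single list of them.
#' @param source Label for the merged histogram.
#' @return A `reba_histogram` whose relative frequencies are the
#'   frame-count-weighted average of the inputs (equivalently, the
#'   histogram of the pooled frames).
#' @export
merge_reba_histograms <- function(..., source = "merged") {
  hs <- list(...)
  if (length(hs) == 1L && !inherits(hs[[1]], "reba_histogram")) hs <- hs[[1]]
  stopifnot(length(hs) >= 1L,
            all(vapply(hs, inherits, TRUE, "reba_histogram")))
  w <- vapply(hs, `[[`, 0, "total_frames")
  rel <- Reduce(`+`, Map(function(h, wi) h$rel_freq * wi, hs, w)) / sum(w)
  structure(
    list(rel_freq = rel, mean_reba = sum(REBA_SCORE_RANGE * rel),
         total_frames = sum(w), source = source),
    class = "reba_histogram")
}

#' Aggregate a score histogram into the five REBA risk bands
#'
#' Band edges follow the published action levels: 1 negligible; 2-3 low;
#' 4-7 medium; 8-10 high; 11+ very high.
#'
#' @param hist A [reba_histogram()].
#' @return A `risk_band_summary`: named numeric vector (`negligible`,
#'   `low`, `medium`, `high`, `very_high`) summing to 1.
#' @export
risk_bands <- function(hist) {
  stopifnot(inherits(hist, "reba_histogram"))
  f <- hist$rel_freq
  structure(
    c(negligible = unname(f["1"]),
      low = sum(f[as.character(2:3)]),
      medium = sum(f[as.character(4:7)]),
      high = sum(f[as.character(8:10)]),
      very_high = sum(f[as.character(11:14)])),
    class = "risk_band_summary")
}

risk_band_colors <- function() {
  c(negligible = "#2ca02c", low = "#ffd92f", medium = "#ff7f0e",
    high = "#fdae6b", very_high = "#d62728")
}

#' @export
print.reba_histogram <- function(x, ...) {
  cat(sprintf("<reba_histogram> %s: %d frames, mean REBA %.2f\n",
              x$source, x$total_frames, x$mean_reba))
  df <- data.frame(score = REBA_SCORE_RANGE, rel_freq = round(x$rel_freq, 4))
  print(df[df$rel_freq > 0, ], row.names = FALSE)
  invisible(x)
}

#' @export
print.risk_band_summary <- function(x, ...) {
  cat("<risk_band_summary>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
plot.reba_histogram <- function(x, main = NULL, ...) {
  band <- c(1, rep(2, 2), rep(3, 4), rep(4, 3), rep(5, 4))
  graphics::barplot(x$rel_freq, names.arg = REBA_SCORE_RANGE,
                    col = risk_band_colors()[band],
                    xlab = "REBA score", ylab = "Relative frequency",
                    main = main %||% paste("REBA distribution:", x$source), ...)
  invisible(x)
}

## ---- effect size ----------------------------------------------------------

#' Cliff's delta effect size
#'
#' `delta = (#\{a > b\} - #\{a < b\}) / (n_a * n_b)` over all cross-group
#' pairs. Interpretation bands: |delta| below 0.33 small, 0.33 to 0.5
#' medium, above 0.5 large.
#'
#' @param group_a,group_b Numeric samples.
#' @return List with `delta` and `band` (`"small"`, `"medium"`,
#'   `"large"`).
#' @export
#' @examples
#' cliffs_delta(c(1, 2), c(3, 4))  # delta -1, large
cliffs_delta <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  s <- sign(outer(group_a, group_b, `-`))
  delta <- mean(s)
  band <- if (abs(delta) < 0.33) "small"
          else if (abs(delta) <= 0.5) "medium"
          else "large"
  list(delta = delta, band = band)
}

## ---- two-group and k-group tests ------------------------------------------

tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Wilcoxon-Mann-Whitney U test
#'
#' Reports the U statistic of group a and a tie-corrected,
#' continuity-corrected normal-approximation z; `z` is negative when group
#' a is stochastically smaller than group b (pipeline convention: a = male,
#' b = female). For small tie-free samples (`n_a * n_b <= exact_max`) the
#' two-sided p-value uses the exact U distribution; otherwise the normal
#' approximation.
#'
#' @param group_a,group_b Numeric samples.
#' @param alpha Nominal significance level.
#' @param adjusted_alpha Multiplicity-adjusted threshold against which
#'   significance is declared (defaults to `alpha`).
#' @param exact_max Largest `n_a * n_b` for which the exact tail is used.
#' @return A `comparison_result`: list with `method`, `statistic_z`, `U`,
#'   `p_value`, `alpha`, `adjusted_alpha`, `significant`, `cliffs_delta`,
#'   `effect_band`, `n`.
#' @export
mwu_test <- function(group_a, group_b, alpha = 0.05,
                     adjusted_alpha = alpha, exact_max = 400) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate variance: all values identical across both groups",
         call. = FALSE)
  }
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  sigma2 <- (n_a * n_b / 12) * ((n + 1) - tie_term(r) / (n * (n - 1)))
  sigma <- sqrt(sigma2)
  dev <- u_a - mu
  z <- if (dev == 0) 0 else (dev - sign(dev) * 0.5) / sigma
  ties <- anyDuplicated(pooled) > 0L
  p <- if (!ties && n_a * n_b <= exact_max) {
    min(1, 2 * min(stats::pwilcox(u_a, n_a, n_b),
                   1 - stats::pwilcox(u_a - 1, n_a, n_b)))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  cd <- cliffs_delta(group_a, group_b)
  structure(
    list(method = "mwu", statistic_z = z, U = u_a, p_value = p,
         alpha = alpha, adjusted_alpha = adjusted_alpha,
         significant = p < adjusted_alpha,
         cliffs_delta = cd$delta, effect_band = cd$band,
         n = c(n_a = n_a, n_b = n_b)),
    class = "comparison_result")
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H with a chi-square p-value on k - 1 degrees of freedom
#' (computed via [stats::kruskal.test()]).
#'
#' @param groups List of (>= 3) non-empty numeric samples.
#' @inheritParams mwu_test
#' @return A `comparison_result` with `statistic_h` in place of a z.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05, adjusted_alpha = alpha) {
  if (length(groups) < 3L) {
    stop("kruskal_wallis needs >= 3 groups (use mwu_test for two)",
         call. = FALSE)
  }
  if (any(!lengths(groups))) stop("all groups must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  structure(
    list(method = "kruskal_wallis",
         statistic_h = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, alpha = alpha,
         adjusted_alpha = adjusted_alpha,
         significant = kt$p.value < adjusted_alpha,
         cliffs_delta = NA_real_, effect_band = NA_character_,
         n = lengths(groups)),
    class = "comparison_result")
}

#' Pairwise mean-rank comparison of three groups
#'
#' Dunn-type follow-up to a Kruskal-Wallis test: for each pair the
#' difference in mean pooled ranks, a tie-corrected normal-approximation z
#' and p, Bonferroni-Holm-adjusted p-values, and simultaneous
#' (Bonferroni-adjusted quantile) confidence limits on the rank
#' difference.
#'
#' @param groups Named list of three non-empty numeric samples.
#' @param alpha Family significance level.
#' @return A data.frame with one row per pair: `pair`, `rank_diff`,
#'   `lower`, `upper`, `z`, `p_value`, `p_holm`, `significant`.
#' @export
pairwise_phase_comparison <- function(groups, alpha = 0.05) {
  if (length(groups) != 3L || any(!lengths(groups))) {
    stop("pairwise_phase_comparison needs exactly three non-empty groups",
         call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", 1:3)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  nn <- lengths(groups)
  big_n <- sum(nn)
  mean_ranks <- tapply(r, g, mean)
  var_term <- (big_n * (big_n + 1) / 12) -
    tie_term(r) / (12 * (big_n - 1))
  pairs <- utils::combn(3L, 2L)
  m <- ncol(pairs)
  q <- stats::qnorm(1 - alpha / (2 * m))
  out <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- mean_ranks[i] - mean_ranks[j]
    se <- sqrt(var_term * (1 / nn[i] + 1 / nn[j]))
    z <- diff / se
    data.frame(pair = paste(names(groups)[i], names(groups)[j], sep = " vs "),
               rank_diff = unname(diff),
               lower = unname(diff - q * se), upper = unname(diff + q * se),
               z = unname(z), p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  bh <- bonferroni_holm(out$p_value, alpha = alpha)
  out$p_holm <- pmin(1, out$p_value * (m - rank(out$p_value,
                                                ties.method = "first") + 1))
  out$p_holm <- cummax_by_rank(out$p_holm, out$p_value)
  out$significant <- bh$reject
  rownames(out) <- NULL
  out
}

## Holm adjusted p-values must be monotone in the raw p ordering.
cummax_by_rank <- function(p_adj, p_raw) {
  o <- order(p_raw)
  p_adj[o] <- cummax(p_adj[o])
  p_adj
}

#' Bonferroni-Holm step-down correction
#'
#' Sorts the p-values, compares the k-th smallest against
#' `alpha / (m - k + 1)` and stops at the first failure; the strictest
#' (first) threshold is `alpha / m` (0.05 / 12 = 0.0042 for a 12-score
#' family at the 5% level).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return A data.frame in the input order: `p_value`, `threshold` (the
#'   step-down threshold the p-value was compared against), `reject`.
#' @export
#' @examples
#' bonferroni_holm(rep(0.001, 12))$threshold[1]  # 0.0042 (strictest)
bonferroni_holm <- function(p_values, alpha = 0.05) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  thresholds_sorted <- alpha / (m - seq_len(m) + 1)
  ok <- p_values[o] <= thresholds_sorted
  reject_sorted <- cumprod(ok) > 0      # step-down: stop at first failure
  out <- data.frame(p_value = p_values,
                    threshold = NA_real_, reject = NA)
  out$threshold[o] <- thresholds_sorted
  out$reject[o] <- reject_sorted
  out
}

#' Kolmogorov-Smirnov normality gate
#'
#' Tests the sample against a normal with the sample mean and SD
#' (one-sample KS). Reported for transparency; the comparison battery is
#' nonparametric regardless of the outcome.
#'
#' @param x Numeric sample, n >= 5.
#' @param alpha Significance level.
#' @return `TRUE` when normality is *not* rejected, `FALSE` when it is. A
#'   degenerate (constant) sample is reported as rejected.
#' @export
ks_normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 5L) stop("need n >= 5 for the normality gate", call. = FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  p <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  p >= alpha
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$method == "mwu") {
    cat(sprintf("MWU: z = %.3f (U = %g), p = %.4g%s; Cliff's delta = %.3f (%s)\n",
                x$statistic_z, x$U, x$p_value,
                if (x$significant) " *" else "",
                x$cliffs_delta, x$effect_band))
  } else {
    cat(sprintf("Kruskal-Wallis: H = %.3f (df = %d), p = %.4g%s\n",
                x$statistic_h, x$df, x$p_value,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}
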