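# Nonparametric two-group machinery: Mann-Whitney U (exact or normal
# approximation), 2x2 chi-square, and the significance-star annotation.

#' Mann-Whitney U test between two groups
#'
#' Computes the Mann-Whitney U statistic (rank-sum based, midranks for
#' ties) and a two-sided p-value. For small tie-free samples
#' (`n_a + n_b <= 12`) the p-value is exact (full enumeration of label
#' assignments via the exact U distribution); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (each nonempty).
#' @param label_a,label_b group labels recorded in the result.
#' @return one-row data.frame (a `GroupComparison`): `label_a`, `label_b`,
#'   `n_a`, `n_b`, `statistic` (U of sample `a`), `p_value`, `method`,
#'   `stars`.
#' @export
mann_whitney <- function(a, b, label_a = "a", label_b = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  data.frame(
    label_a = label_a, label_b = label_b,
    n_a = length(a), n_b = length(b),
    statistic = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    method = if (exact) "exact" else "normal-approximation",
    stars = significance_stars(min(1, wt$p.value)),
    stringsAsFactors = FALSE
  )
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square statistic without continuity correction, with the
#' p-value from the chi-square distribution with 1 degree of freedom. Both
#' row and column margins must be positive.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param label_a,label_b labels recorded in the result.
#' @return one-row `GroupComparison` data.frame (method `"chi-square"`).
#' @export
chi_square_2x2 <- function(tab, label_a = "a", label_b = "b") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi_square_2x2: zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(
    label_a = label_a, label_b = label_b,
    n_a = sum(tab[1, ]), n_b = sum(tab[2, ]),
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    method = "chi-square",
    stars = significance_stars(ct$p.value),
    stringsAsFactors = FALSE
  )
}

#' Significance-star annotation
#'
#' `"***"` for highly significant p < 0.0001, `"*"` for significant
#' p < 0.05, empty otherwise (both boundaries strict).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 1e-4, "***", ifelse(p < 0.05, "*", ""))
}

# Standard error of the mean; 0 for a single observation.
sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
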