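# Cross-cutting statistics: Pearson association, paired-change
# classification, Mann-Whitney U with Holm-Bonferroni, Welch t.

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning the product-moment r
#' and its two-sided p.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_association <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Classify the paired change between stroma regions
#'
#' Relative change `(peritumoral - distant) / |distant|`: above +threshold
#' is "increased", below -threshold "decreased", otherwise "unchanged"
#' (default threshold 5%).
#'
#' @param peritumoral,distant Paired parameter values (distant nonzero).
#' @param threshold Relative-change threshold (fraction).
#' @return Factor with levels `increased`, `decreased`, `unchanged`.
#' @export
change_classification <- function(peritumoral, distant, threshold = 0.05) {
  if (any(distant == 0, na.rm = TRUE))
    stop("distant value of 0: relative change undefined")
  rel <- (peritumoral - distant) / abs(distant)
  eps <- 1e-10                      # a change of exactly 5% is not "> 5%"
  lv <- c("increased", "decreased", "unchanged")
  factor(ifelse(rel > threshold + eps, "increased",
                ifelse(rel < -threshold - eps, "decreased", "unchanged")),
         levels = lv)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups: exact p when
#' both groups have at most 8 observations and no ties, normal approximation
#' with continuity and tie correction otherwise. If every value in both
#' groups is identical the test is uninformative and p = 1 is returned by
#' convention.
#'
#' @param a,b Numeric vectors (nonempty).
#' @return List with elements `U` (statistic for group `a`) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1))
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 8L && length(b) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Holm-Bonferroni step-down correction
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return List with `adjusted` (monotone step-down adjusted p-values, in
#'   input order) and `reject` (logical, `adjusted <= alpha`).
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal-variance t comparison (used for the tissue-level
#' alignment-coefficient contrast).
#'
#' @param a,b Numeric vectors.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Correlate T-cell measures with collagen parameters
#'
#' Builds the correlation table between one T-cell column and several
#' collagen-parameter columns of a per-image result table, with
#' Holm-Bonferroni-adjusted p-values.
#'
#' @param data Data frame of per-image results.
#' @param tcell_col Name of the T-cell measure column.
#' @param collagen_cols Names of collagen parameter columns.
#' @param alpha Family-wise error level.
#' @return Data frame with one row per collagen parameter: `parameter`, `r`,
#'   `p`, `p_adjusted`, `significant`.
#' @export
correlation_table <- function(data, tcell_col, collagen_cols, alpha = 0.05) {
  res <- lapply(collagen_cols, function(cc) {
    ok <- is.finite(data[[tcell_col]]) & is.finite(data[[cc]])
    pa <- pearson_association(data[[tcell_col]][ok], data[[cc]][ok])
    data.frame(parameter = cc, r = pa$r, p = pa$p)
  })
  out <- do.call(rbind, res)
  hb <- holm_bonferroni(out$p, alpha)
  out$p_adjusted <- hb$adjusted
  out$significant <- hb$reject
  out
}
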