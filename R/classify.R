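#' Classify differentially expressed genes by fold-change and FDR
#'
#' Applies the study's decision rule to a differential-expression table:
#' a gene is `down` if `fdr <= fdr_max` and its expression falls at
#' least `fold_change`-fold (`log2fc <= -log2(fold_change)`), `up` if
#' `fdr <= fdr_max` and `log2fc >= log2(fold_change)`, otherwise
#' `not_significant`. Genes with missing `log2fc` or `fdr` are flagged
#' and excluded from the class counts.
#'
#' @param table Data frame with columns `gene`, `log2fc`, `fdr`.
#' @param fdr_max FDR gate (default 0.01).
#' @param fold_change Minimum fold change (default 1.5).
#' @return A tibble of class `de_classification` with columns `gene`,
#'   `log2fc`, `fdr`, `class`
#'   (`"down"`/`"up"`/`"not_significant"`/`"flagged"`); attribute
#'   `counts` is a named vector of class totals.
#' @examples
#' classify_de(data.frame(
#'   gene = c("a", "b", "c"),
#'   log2fc = c(-1, -0.5, 1), fdr = c(0.001, 0.001, 0.02)
#' ))
#' @export
classify_de <- function(table, fdr_max = 0.01, fold_change = 1.5) {
  stopifnot(is.data.frame(table))
  need <- c("gene", "log2fc", "fdr")
  if (!all(need %in% names(table))) {
    abort(paste0("`table` must have columns ", paste(need, collapse = ", "), "."))
  }
  ok <- is.finite(table$log2fc) & is.finite(table$fdr)
  if (any(table$fdr[ok] < 0 | table$fdr[ok] > 1)) {
    abort("`fdr` values must lie in [0, 1].")
  }
  thr <- log2(fold_change)
  class <- rep("not_significant", nrow(table))
  class[ok & table$fdr <= fdr_max & table$log2fc <= -thr] <- "down"
  class[ok & table$fdr <= fdr_max & table$log2fc >= thr] <- "up"
  class[!ok] <- "flagged"
  out <- tibble(
    gene = table$gene, log2fc = table$log2fc, fdr = table$fdr,
    class = class
  )
  counts <- c(
    down = sum(class == "down"), up = sum(class == "up"),
    not_significant = sum(class == "not_significant"),
    flagged = sum(class == "flagged")
  )
  structure(out, counts = counts, class = c("de_classification", class(out)))
}

#' Classify genes as lowly expressed by nuclear RNA-seq signal
#'
#' A gene counts as lowly expressed when its gene-body nuclear RNA-seq
#' signal is strictly below the threshold (default −2.5 log2 FPKM);
#' values at or above the threshold are `"expressed"`.
#'
#' @param log2_fpkm Numeric vector of gene-body log2 FPKM values
#'   (finite).
#' @param threshold Strict lower cutoff (default -2.5).
#' @return Character vector of `"lowly_expressed"` / `"expressed"`.
#' @examples
#' classify_expression(c(-3, -2.5, 0))
#' @export
classify_expression <- function(log2_fpkm, threshold = -2.5) {
  if (any(!is.finite(log2_fpkm))) abort("`log2_fpkm` must be finite.")
  ifelse(log2_fpkm < threshold, "lowly_expressed", "expressed")
}

#' Nonparametric two-group difference test
#'
#' Two-sided rank test for a difference between two samples:
#' `"mann_whitney"` for independent samples (Wilcoxon rank-sum) or
#' `"wilcoxon_signed_rank"` for paired samples of equal length. Ties
#' are handled by average ranks (normal approximation when ties are
#' present, as in [wilcox.test()]).
#'
#' @param a,b Numeric vectors; paired and equal-length for the
#'   signed-rank mode, each n >= 2 for Mann-Whitney.
#' @param mode `"mann_whitney"` or `"wilcoxon_signed_rank"`.
#' @return Two-sided p value.
#' @export
group_difference_test <- function(a, b, mode = c("mann_whitney", "wilcoxon_signed_rank")) {
  mode <- match.arg(mode)
  if (anyNA(a) || anyNA(b)) abort("Missing values are not allowed.")
  if (mode == "mann_whitney") {
    if (length(a) < 2 || length(b) < 2) abort("Each sample needs n >= 2.")
    suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))$p.value
  } else {
    if (length(a) != length(b)) abort("Paired samples must have equal length.")
    if (all(a - b == 0)) {
      abort("All paired differences are zero; the signed-rank test is undefined.")
    }
    suppressWarnings(wilcox.test(a, b, paired = TRUE, alternative = "two.sided"))$p.value
  }
}
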