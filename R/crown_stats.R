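#' Morphotype frequency in a cohort
#'
#' Counts specimen-sides showing a given trait state among all scored
#' sides of a cohort; sides scored as missing are excluded from the
#' denominator.
#'
#' @param table a [read_morphotype_table()] data frame (or one from
#'   [simulate_morphotypes()]).
#' @param cohort `"WT"` or `"mutant"`.
#' @param trait one of `m1_c1c2_profile`, `m2_spur`, `m3_c1`.
#' @param state the state to count (e.g. `"U"`, `"absent"`, `"reduced"`).
#' @return object of class `frequency_report`: `observed`, `scored`,
#'   `percentage` (NA when nothing is scored), plus the query fields.
#' @export
morphotype_frequencies <- function(table, cohort, trait, state) {
  if (!trait %in% names(.morpho_vocab))
    stop("unknown trait: ", trait)
  if (!state %in% .morpho_vocab[[trait]])
    stop("unknown state '", state, "' for trait ", trait)
  rows <- table[table$cohort == cohort, , drop = FALSE]
  vals <- rows[[trait]]
  scored <- sum(vals != "missing")
  observed <- sum(vals == state)
  structure(list(cohort = cohort, trait = trait, state = state,
                 observed = observed, scored = scored,
                 percentage = if (scored > 0) 100 * observed / scored
                              else NA_real_),
            class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat(sprintf("%s %s = %s: %d/%d (%s)\n", x$cohort, x$trait, x$state,
              x$observed, x$scored,
              if (is.na(x$percentage)) "undefined"
              else sprintf("%.1f%%", x$percentage)))
  invisible(x)
}

two_sample_result <- function(statistic, p_value, kind, n) {
  structure(list(statistic = statistic, p_value = p_value, kind = kind,
                 n = n), class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %d, %d)\n",
              x$kind, x$statistic, x$p_value, x$n[1L], x$n[2L]))
  invisible(x)
}

#' Pooled-variance Student's t test
#'
#' Two-sided equal-variance t test of mean equality; the statistic is
#' positive when `mean(x) > mean(y)`.
#'
#' @param x,y numeric samples.
#' @return a `two_sample_test` with `kind = "student_t"`.
#' @export
student_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  pooled_var <- ((length(x) - 1L) * stats::var(x) +
                 (length(y) - 1L) * stats::var(y)) /
    (length(x) + length(y) - 2L)
  if (pooled_var == 0) {
    if (mean(x) == mean(y))
      return(two_sample_result(0, 1, "student_t", c(length(x), length(y))))
    return(two_sample_result(sign(mean(x) - mean(y)) * Inf, 0, "student_t",
                             c(length(x), length(y))))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  two_sample_result(unname(tt$statistic), tt$p.value, "student_t",
                    c(length(x), length(y)))
}

#' Two-sided F test of variance equality
#'
#' F = var(x) / var(y), with a two-sided p value from the F distribution.
#'
#' @param x,y numeric samples.
#' @return a `two_sample_test` with `kind = "variance_F"`.
#' @export
variance_f_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  vt <- stats::var.test(x, y)
  two_sample_result(unname(vt$statistic), vt$p.value, "variance_F",
                    c(length(x), length(y)))
}

#' Mark differentially expressed genes
#'
#' Applies the three-part marking rule to a gene table: a gene is flagged
#' as DE when (i) it has at least `min_count` counts in at least half of
#' the samples of one group (half = ceiling of the group size over two),
#' (ii) its p value is at most `p_max`, and (iii) its fold change is at
#' least `lfc_min` on the log2 scale in absolute value. The statistical
#' test producing the p values is external to this rule.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param groups two-level factor over the samples.
#' @param p per-gene p values.
#' @param log2fc per-gene log2 fold changes.
#' @param min_count expression threshold for criterion (i).
#' @param p_max significance threshold for criterion (ii).
#' @param lfc_min fold-change threshold for criterion (iii).
#' @param lfc_scale `"log2"` (default: |log2fc| >= lfc_min) or `"linear"`
#'   (fold change 2^log2fc >= lfc_min).
#' @return data frame with per-gene `expressed`, `p`, `log2fc`, `de_flag`.
#' @export
mark_de_genes <- function(counts, groups, p, log2fc, min_count = 10,
                          p_max = 0.05, lfc_min = 0.5,
                          lfc_scale = c("log2", "linear")) {
  lfc_scale <- match.arg(lfc_scale)
  counts <- as.matrix(counts)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (length(g) != ncol(counts))
    stop("groups length must match sample count")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (length(p) != nrow(counts) || length(log2fc) != nrow(counts))
    stop("p and log2fc must have one value per gene")
  expressed <- rep(FALSE, nrow(counts))
  for (lev in levels(g)) {
    cg <- counts[, g == lev, drop = FALSE]
    need <- ceiling(ncol(cg) / 2)
    expressed <- expressed | rowSums(cg >= min_count) >= need
  }
  fc_ok <- if (lfc_scale == "log2") abs(log2fc) >= lfc_min
           else 2^log2fc >= lfc_min
  data.frame(gene = if (!is.null(rownames(counts))) rownames(counts)
                    else paste0("g", seq_len(nrow(counts))),
             expressed = expressed, p = p, log2fc = log2fc,
             de_flag = expressed & !is.na(p) & p <= p_max & fc_ok,
             stringsAsFactors = FALSE)
}

#' Fisher's exact enrichment test
#'
#' Two-sided Fisher's exact p value for the 2 x 2 contingency table of
#' significant/non-significant genes inside/outside a functional category.
#'
#' @param k_sig_in significant genes in the category.
#' @param k_sig_out significant genes outside it.
#' @param k_ns_in non-significant genes in the category.
#' @param k_ns_out non-significant genes outside it.
#' @return the p value.
#' @export
fisher_enrichment <- function(k_sig_in, k_sig_out, k_ns_in, k_ns_out) {
  tab <- matrix(c(k_sig_in, k_ns_in, k_sig_out, k_ns_out), 2L, 2L)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("cell counts must be non-negative integers")
  stats::fisher.test(tab)$p.value
}

#' Relative expression by the comparative delta-Ct method
#'
#' Computes 2^-(Ct_target - Ct_housekeeping), the expression of a target
#' gene relative to a housekeeping gene from quantitative PCR cycle
#' thresholds. Vectorized over replicates.
#'
#' @param ct_target cycle threshold(s) of the target gene.
#' @param ct_housekeeping cycle threshold(s) of the housekeeping gene.
#' @return relative expression value(s).
#' @export
delta_ct_expression <- function(ct_target, ct_housekeeping) {
  2^(-(ct_target - ct_housekeeping))
}
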