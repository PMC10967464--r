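# Experiment statistics: segregation check of the cross, R x C Pearson
# chi-square with pairwise post hoc comparisons for the RNAi outcome tables,
# rate summaries, and delta-Ct relative expression with one-way ANOVA.

#' Pearson chi-square test of an R x C contingency table
#'
#' Direct Sum (O-E)^2 / E with E = row total x column total / grand total, no
#' continuity correction (matching values reported from SPSS), df =
#' (R-1)(C-1), p from the upper tail.
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @return list: `statistic`, `df`, `p`, `expected`.
#' @examples
#' pearson_chi_square(rbind(c(58, 20), c(40, 13), c(45, 12)))
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2 x 2")
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero row or column marginal")
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Pairwise post hoc chi-square comparisons between treatments
#'
#' Every pair of rows is tested as its own 2 x C Pearson chi-square
#' (uncorrected). Raw p values are reported alongside Bonferroni-adjusted
#' ones.
#'
#' @param table matrix with >= 3 rows (named rows label the comparisons).
#' @return data.frame per pair: `pair`, `statistic`, `df`, `p`, `p_adjusted`.
#' @export
posthoc_pairwise <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 3L) stop("post hoc comparisons need at least 3 rows")
  if (is.null(rownames(table))) rownames(table) <- paste0("row", seq_len(nrow(table)))
  pairs <- utils::combn(nrow(table), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- pearson_chi_square(table[c(i, j), , drop = FALSE])
    data.frame(pair = paste(rownames(table)[i], "vs", rownames(table)[j]),
               statistic = res$statistic, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Goodness-of-fit test of a two-class segregation ratio
#'
#' One-degree-of-freedom chi-square of observed class counts against an
#' expected ratio (1:1 for the drones of a heterozygous queen).
#'
#' @param n_class1,n_class2 observed counts (not both zero).
#' @param ratio expected ratio, length-2 numeric (default `c(1, 1)`).
#' @param alpha significance level for the verdict (default 0.05).
#' @return list: `statistic`, `df`, `p`, `conclusion` ("consistent" when
#'   p > alpha, else "inconsistent").
#' @examples
#' segregation_test(75, 25)  # chi-square 25, inconsistent with 1:1
#' @export
segregation_test <- function(n_class1, n_class2, ratio = c(1, 1), alpha = 0.05) {
  if (n_class1 < 0 || n_class2 < 0 || n_class1 + n_class2 == 0)
    stop("counts must be non-negative and not both zero")
  if (length(ratio) != 2L || any(ratio <= 0)) stop("ratio must be two positive numbers")
  total <- n_class1 + n_class2
  E <- total * ratio / sum(ratio)
  stat <- sum((c(n_class1, n_class2) - E)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p = p,
       conclusion = if (p > alpha) "consistent" else "inconsistent")
}

#' Percentage summary of a count over its denominator
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @return 100 * numerator / denominator, rounded half-up to one decimal.
#' @examples
#' rate_summary(58, 78)  # 74.4
#' @export
rate_summary <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  floor(1000 * numerator / denominator + 0.5) / 10
}

#' Normalised relative expression with one-way ANOVA across groups
#'
#' Expression is normalised per sample as `2^-(Ct_target - mean(reference
#' Cts))` — the delta-Ct method with the reference genes combined by the
#' arithmetic mean of their quantification cycles. Groups are then compared
#' by standard one-way ANOVA on the normalised values.
#'
#' @param group factor/character of group labels (>= 2 groups, >= 2 samples
#'   per group).
#' @param ct_target target-gene quantification cycles.
#' @param ct_reference numeric vector (one reference) or matrix/data.frame
#'   with one column per reference gene.
#' @return list: `samples` (data.frame with per-sample `rel_expr`),
#'   `group_means`, `anova` (list `F`, `df1`, `df2`, `p`).
#' @export
relative_expression <- function(group, ct_target, ct_reference) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("need at least 2 samples per group")
  ref <- as.matrix(ct_reference)
  if (nrow(ref) != length(ct_target) || length(group) != length(ct_target))
    stop("group, ct_target and ct_reference must have matching lengths")
  if (any(ct_target <= 0) || any(ref <= 0)) stop("cycles must be positive")
  rel <- 2^-(ct_target - rowMeans(ref))
  av <- stats::oneway.test(rel ~ group, var.equal = TRUE)
  list(samples = data.frame(group = group, rel_expr = rel),
       group_means = tapply(rel, group, mean),
       anova = list(F = unname(av$statistic),
                    df1 = as.integer(av$parameter[["num df"]]),
                    df2 = as.integer(av$parameter[["denom df"]]),
                    p = unname(av$p.value)))
}
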