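## Normality-gated two-sample comparison between specificity groups.

#' Compare a metric between two groups
#'
#' Implements the gated two-sample procedure: a Shapiro-Wilk normality
#' test is run on each sample and, when both p-values exceed
#' `alphaNormality`, a two-sided two-sample Student's t-test (equal
#' variances) is used; otherwise a two-sided Wilcoxon rank-sum test.
#' Constant (zero-variance) samples, for which the Shapiro-Wilk
#' statistic is undefined, are treated as non-normal and routed to the
#' rank-sum branch; identical samples therefore yield a p-value of 1.
#'
#' @param valuesA,valuesB numeric vectors, one observation per complex;
#'   each of length at least 3.
#' @param alphaNormality significance level of the normality gate.
#' @param metric,groupA,groupB descriptive labels copied into the
#'   result.
#' @return data.frame with one row: sample sizes, normality p-values,
#'   `test_used` (`"t_test"` or `"wilcoxon_rank_sum"`), the test
#'   statistic and the two-sided `p_value`.
#' @examples
#' compareGroups(c(81, 75, 100, 66, 90), c(60, 55, 72, 58, 64),
#'               metric = "pct_dominant", groupA = "HS", groupB = "MS")
#' @export
compareGroups <- function(valuesA, valuesB, alphaNormality = 0.05,
                          metric = "", groupA = "", groupB = "") {
  valuesA <- as.numeric(valuesA); valuesB <- as.numeric(valuesB)
  if (anyNA(valuesA) || anyNA(valuesB))
    stop("missing values in the compared samples")
  if (length(valuesA) < 3 || length(valuesB) < 3)
    stop("each sample needs at least 3 observations ",
         "(Shapiro-Wilk is undefined below n = 3)")
  swP <- function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  pA <- swP(valuesA); pB <- swP(valuesB)
  if (pA > alphaNormality && pB > alphaNormality) {
    tt <- stats::t.test(valuesA, valuesB, var.equal = TRUE,
                        alternative = "two.sided")
    used <- "t_test"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(valuesA, valuesB, alternative = "two.sided"))
    used <- "wilcoxon_rank_sum"; stat <- unname(wt$statistic)
    p <- wt$p.value
    ## every observation tied at one value: the normal approximation
    ## degenerates (0/0); identical samples carry no evidence at all
    if (is.nan(p)) p <- 1
  }
  data.frame(metric = metric, group_a = groupA, group_b = groupB,
             n_a = length(valuesA), n_b = length(valuesB),
             normality_p_a = pA, normality_p_b = pB, test_used = used,
             statistic = stat, p_value = p, stringsAsFactors = FALSE,
             row.names = NULL)
}
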