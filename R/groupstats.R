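#' Per-group incidence rates of a trial outcome
#'
#' @param table Trial table (`group`, `outcome`, ...) as produced by
#'   [generate_trial_table()] or [read_trial_table()].
#' @param outcome One of `"BLOCKAGE"`, `"HEMORRHAGE"`, `"NONE"`.
#' @return Data frame: `group`, `k` (trials with the outcome), `n` (trials),
#'   `rate` (k/n), `rate_pct`.
#' @export
incidence_rates <- function(table, outcome = "BLOCKAGE") {
  if (!outcome %in% .OUTCOMES)
    stop("unknown outcome label: ", outcome)
  stopifnot(nrow(table) > 0)
  groups <- unique(table$group)
  rows <- lapply(groups, function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    k <- sum(sub$outcome == outcome)
    data.frame(group = g, k = k, n = nrow(sub), rate = k / nrow(sub))
  })
  out <- do.call(rbind, rows)
  out$rate_pct <- 100 * out$rate
  out
}

#' Pooled two-proportion z-test
#'
#' Tests equality of two binomial proportions with the pooled-variance z
#' statistic
#' \deqn{z = \frac{p_1 - p_2}{\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#'   \quad \hat p = \frac{k_1 + k_2}{n_1 + n_2}}
#' and the standard-normal reference distribution. Two-sided by default; the
#' one-sided alternative is \eqn{p_1 > p_2}. No continuity correction is
#' applied unless requested.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param sided `"two"` (default) or `"one"`.
#' @param continuity Apply the Yates-style correction
#'   `(1/n1 + 1/n2)/2` to `|p1 - p2|`? Default FALSE.
#' @return List of class `proportion_test`: `k1, n1, k2, n2, p1, p2, z,
#'   p_value, sided`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2, sided = c("two", "one"),
                                 continuity = FALSE) {
  sided <- match.arg(sided)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1)
    stop("pooled proportion is 0 or 1: z is undefined")
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  num <- p1 - p2
  if (continuity) {
    corr <- (1 / n1 + 1 / n2) / 2
    num <- sign(num) * max(0, abs(num) - corr)
  }
  z <- num / se
  p_value <- if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
  p_value <- min(1, max(p_value, .Machine$double.xmin))
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
                 z = z, p_value = p_value, sided = sided),
            class = "proportion_test")
}

#' Group comparison of an outcome's incidence
#'
#' Convenience wrapper mapping a two-group trial table onto
#' [two_proportion_ztest()] for a chosen outcome.
#'
#' @param table Two-group trial table.
#' @param outcome Outcome label to compare, default `"HEMORRHAGE"`.
#' @param groups Optional length-2 character vector fixing group order
#'   (group 1 minus group 2); defaults to order of appearance.
#' @param ... Passed to [two_proportion_ztest()].
#' @return A `proportion_test` with an added `groups` field.
#' @export
outcome_comparison <- function(table, outcome = "HEMORRHAGE", groups = NULL,
                               ...) {
  rates <- incidence_rates(table, outcome)
  if (is.null(groups)) groups <- rates$group
  if (length(groups) != 2) stop("outcome comparison needs exactly 2 groups")
  r1 <- rates[rates$group == groups[1], ]
  r2 <- rates[rates$group == groups[2], ]
  res <- two_proportion_ztest(r1$k, r1$n, r2$k, r2$n, ...)
  res$groups <- groups
  res$outcome <- outcome
  res
}

#' Two-group hemorrhage-rate comparison
#'
#' Applies the pooled two-proportion z-test to the HEMORRHAGE outcome, the
#' companion analysis to the blockage comparison: similar hemorrhage rates in
#' photosensitizer and control groups indicate the occlusion mechanism is not
#' generic laser damage.
#'
#' @inheritParams outcome_comparison
#' @return A `proportion_test`.
#' @export
hemorrhage_comparison <- function(table, groups = NULL, ...) {
  outcome_comparison(table, outcome = "HEMORRHAGE", groups = groups, ...)
}
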