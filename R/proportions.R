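#' Two-population proportion z test
#'
#' Pooled two-sided z test for the difference of two proportions,
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with
#' `pbar = (x1 + x2) / (n1 + n2)`, used to compare sub-population
#' proportions between conditions.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return A one-row tibble: `estimate1`, `estimate2`, `z`, `p_value`.
#'   When the pooled proportion is 0 or 1 the statistic is undefined
#'   (`z = NA`) and `p_value` is 1: both samples are unanimously identical.
#' @examples
#' two_proportion_z_test(30, 100, 50, 100)
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) abort("trial counts must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("successes must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar == 0 || pbar == 1) {
    return(tibble(estimate1 = p1, estimate2 = p2, z = NA_real_, p_value = 1))
  }
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  tibble(estimate1 = p1, estimate2 = p2, z = z,
         p_value = 2 * pnorm(-abs(z)))
}

#' Pairwise z tests of tag proportions between conditions
#'
#' For every pair of condition levels and every sub-population tag, tests
#' whether the fraction of labelled cells carrying that tag differs between
#' the two conditions.
#'
#' @param labels A tibble with a `tag` column and a condition column.
#' @param condition Name of the condition column.
#' @return A tibble with one row per (condition pair, tag):
#'   counts, proportions, `z`, `p_value`.
#' @export
compare_proportions <- function(labels, condition) {
  stopifnot(condition %in% names(labels), "tag" %in% names(labels))
  lv <- unique(as.character(labels[[condition]]))
  if (length(lv) < 2) abort("need at least two condition levels")
  tags <- if (is.factor(labels$tag)) levels(labels$tag) else
    sort(unique(as.character(labels$tag)))
  out <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    g1 <- labels[labels[[condition]] == lv[i], , drop = FALSE]
    g2 <- labels[labels[[condition]] == lv[j], , drop = FALSE]
    for (tg in tags) {
      zt <- two_proportion_z_test(sum(g1$tag == tg), nrow(g1),
                                  sum(g2$tag == tg), nrow(g2))
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble(condition1 = lv[i], condition2 = lv[j], tag = tg,
               x1 = sum(g1$tag == tg), n1 = nrow(g1),
               x2 = sum(g2$tag == tg), n2 = nrow(g2)),
        zt)
    }
  }
  bind_rows(out)
}
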