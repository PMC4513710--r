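# Condition comparison by the Wilcoxon rank-sum test, implemented from first
# principles: exact enumeration of the permutation null for small tie-free
# samples, otherwise the normal approximation with midranks, tie correction
# and continuity correction.

#' Wilcoxon rank-sum test (two-sided)
#'
#' The statistic is the rank sum `W` of `x` in the pooled midranked sample.
#' When `n_x + n_y <= 12` and there are no ties, the two-sided p-value is
#' computed by exact enumeration of all `choose(n, n_x)` rank assignments
#' (doubled smaller tail, capped at 1); otherwise the normal approximation
#' with tie correction and a 0.5 continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   (default) decides by the rule above.
#' @return List with `statistic` (rank sum of `x`), `p_value`, `exact`,
#'   `degenerate` (all pooled values identical) and the group sizes.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  w <- sum(r[seq_len(n1)])
  if (length(unique(pooled)) == 1)
    return(list(statistic = w, p_value = 1, exact = FALSE,
                degenerate = TRUE, n_x = n1, n_y = n2))
  ties <- any(duplicated(pooled))
  use_exact <- if (is.null(exact)) (n <= 12 && !ties) else exact
  if (use_exact && ties)
    stop("exact enumeration requires tie-free samples")
  if (use_exact) {
    sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0)
      return(list(statistic = w, p_value = 1, exact = FALSE,
                  degenerate = TRUE, n_x = n1, n_y = n2))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, exact = use_exact, degenerate = FALSE,
       n_x = n1, n_y = n2)
}

#' Compare conditions across bands, densities and metrics
#'
#' One rank-sum test per (band, density, metric) cell that contains both
#' conditions.  The statistical unit defaults to the subject (one value per
#' subject per condition, averaged if several rows share a subject);
#' `unit = "swallow"` tests the raw rows instead.  Significance is assessed
#' at `alpha` uncorrected; a Benjamini-Hochberg adjusted column is added when
#' `p_adjust = "BH"`.
#'
#' @param metrics Long-format data frame with columns `subject_id`,
#'   `condition` (exactly two levels), `band`, `density_pct`, `metric`,
#'   `value`.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param unit `"subject"` (default) or `"swallow"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per tested cell: `band`, `density_pct`,
#'   `metric`, `statistic`, `p_value`, `n1`, `n2`, `significant` (and
#'   `p_adjusted`, `significant_adjusted` when requested).
#' @export
compare_conditions <- function(metrics, alpha = 0.05,
                               unit = c("subject", "swallow"),
                               p_adjust = c("none", "BH")) {
  unit <- match.arg(unit)
  p_adjust <- match.arg(p_adjust)
  req <- c("subject_id", "condition", "band", "density_pct", "metric",
           "value")
  if (!all(req %in% names(metrics)))
    stop("metrics table needs columns ", paste(req, collapse = ", "))
  conds <- sort(unique(as.character(metrics$condition)))
  if (length(conds) != 2)
    stop("exactly two conditions required, found: ",
         paste(conds, collapse = ", "))
  cells <- unique(metrics[, c("band", "density_pct", "metric")])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    cell <- metrics[metrics$band == cells$band[r] &
                      metrics$density_pct == cells$density_pct[r] &
                      metrics$metric == cells$metric[r], ]
    cell <- cell[is.finite(cell$value), ]
    if (!nrow(cell)) next  # nothing measurable in this cell (e.g. all NA)
    if (unit == "subject") {
      agg <- stats::aggregate(value ~ subject_id + condition, cell, mean)
    } else {
      agg <- cell[, c("subject_id", "condition", "value")]
    }
    g1 <- agg$value[agg$condition == conds[1]]
    g2 <- agg$value[agg$condition == conds[2]]
    if (!length(g1) || !length(g2)) {
      warning("cell ", cells$band[r], "/", cells$density_pct[r], "/",
              cells$metric[r], " skipped: missing condition")
      next
    }
    tst <- rank_sum_test(g1, g2)
    rows[[length(rows) + 1]] <- data.frame(
      band = cells$band[r], density_pct = cells$density_pct[r],
      metric = cells$metric[r], statistic = tst$statistic,
      p_value = tst$p_value, n1 = tst$n_x, n2 = tst$n_y,
      significant = tst$p_value < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant_adjusted <- out$p_adjusted < alpha
  }
  out
}
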