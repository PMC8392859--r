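#' Mann-Kendall test for monotonic trend
#'
#' Rank-based trend test: S = sum over pairs i < j of sign(x_j - x_i);
#' Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18 with the sum over tie
#' groups of extent t; Z uses the classical continuity correction
#' ((S - 1)/sqrt(Var) for S > 0, 0 for S = 0, (S + 1)/sqrt(Var) for S < 0)
#' and the two-sided p comes from the standard normal.
#'
#' @param series Time-ordered numeric vector; NAs are dropped (positions
#'   recorded in the result).
#' @param alpha Significance level for the trend direction call.
#' @return A \code{mk_result} list: \code{S}, \code{var_S}, \code{Z},
#'   \code{p}, \code{direction} ("increasing", "decreasing", "no trend"),
#'   \code{n}, \code{dropped} (positions of removed NAs).
#' @export
mk_test <- function(series, alpha = 0.05) {
  dropped <- which(is.na(series))
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 non-missing values")
  if (n < 8L) warning("short series (n < 8): normal approximation is rough")

  S <- 0L
  for (i in seq_len(n - 1L)) {
    S <- S + sum(sign(x[(i + 1L):n] - x[i]))
  }
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18

  if (var_S == 0) {
    warning("all values tied: no trend detectable")
    Z <- 0; p <- 1
  } else if (S > 0) {
    Z <- (S - 1) / sqrt(var_S); p <- 2 * stats::pnorm(-abs(Z))
  } else if (S < 0) {
    Z <- (S + 1) / sqrt(var_S); p <- 2 * stats::pnorm(-abs(Z))
  } else {
    Z <- 0; p <- 1
  }
  direction <- if (p < alpha && S > 0) "increasing"
               else if (p < alpha && S < 0) "decreasing"
               else "no trend"
  structure(list(S = S, var_S = var_S, Z = Z, p = p, direction = direction,
                 n = n, dropped = dropped),
            class = "mk_result")
}

#' Mann-Kendall trend report per group and parameter
#'
#' Runs [mk_test()] on each (group, parameter) series of a \code{wq_matrix},
#' time-ordered. Grouping is per site or river-wide (dates averaged across
#' sites first). Monthly series are the default; annual means by flag.
#' No multiple-testing correction is applied by default (per-series p values
#' at the stated alpha); Benjamini-Hochberg adjusted p values are appended
#' when \code{adjust = TRUE}.
#'
#' @param x A \code{wq_matrix}.
#' @param grouping "site" or "river-wide".
#' @param alpha Significance level.
#' @param annual Aggregate to annual means before testing.
#' @param adjust Append Benjamini-Hochberg adjusted p values.
#' @return Data frame: group, parameter, n, S, var_S, Z, p, direction
#'   (and p_adj when requested). Groups with fewer than 4 points are
#'   skipped with a message.
#' @export
trend_report <- function(x, grouping = c("site", "river-wide"), alpha = 0.05,
                         annual = FALSE, adjust = FALSE) {
  stopifnot(inherits(x, "wq_matrix"))
  grouping <- match.arg(grouping)
  params <- colnames(x$values)
  group <- if (grouping == "site") x$meta$site_id else "river"
  df <- data.frame(group = group, date = x$meta$date, x$values,
                   check.names = FALSE)

  rows <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, , drop = FALSE]
    for (p in params) {
      tm <- if (grouping == "river-wide" || annual) {
        key <- if (annual) format(sub$date, "%Y") else format(sub$date)
        v <- tapply(sub[[p]], key, mean, na.rm = TRUE)
        v[order(names(v))]
      } else {
        sub[[p]][order(sub$date)]
      }
      tm <- tm[!is.nan(tm)]
      if (sum(!is.na(tm)) < 4L) {
        message("skipping ", g, "/", p, ": fewer than 4 data points")
        next
      }
      r <- suppressWarnings(mk_test(as.numeric(tm), alpha))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, n = r$n, S = r$S, var_S = r$var_S,
        Z = r$Z, p = r$p, direction = r$direction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  } else {
    message("note: per-series p values at alpha = ", alpha,
            "; no multiple-comparison correction applied")
  }
  out
}
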