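#' Significance-filtered Pearson correlation network
#'
#' Pairwise Pearson correlations between parameters (pairwise-complete
#' observations), two-sided p from t = r * sqrt((n - 2) / (1 - r^2)) on
#' n - 2 degrees of freedom; only edges with p below alpha are kept, with
#' the sign recorded (positive/negative). Constant columns yield no edges
#' and are flagged.
#'
#' @param x A \code{wq_matrix} or samples x parameters matrix.
#' @param alpha Significance threshold (default 0.05).
#' @param stratum Optional season name; restricts samples to that season
#'   (requires a \code{wq_matrix}).
#' @return A \code{cor_network} list: \code{edges} (data frame from, to, r,
#'   p, n, sign), \code{nodes}, \code{alpha}, \code{dropped} (constant
#'   columns).
#' @export
correlation_network <- function(x, alpha = 0.05, stratum = NULL) {
  if (inherits(x, "wq_matrix")) {
    m <- x$values
    if (!is.null(stratum)) m <- m[x$meta$season == stratum, , drop = FALSE]
  } else {
    m <- as.matrix(x)
    if (!is.null(stratum)) stop("stratum requires a wq_matrix")
  }
  params <- colnames(m)
  keep_sd <- apply(m, 2L, function(v) stats::sd(v, na.rm = TRUE))
  dropped <- params[!is.na(keep_sd) & keep_sd == 0]
  if (length(dropped)) {
    warning("constant column(s) excluded from the network: ",
            paste(dropped, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(length(params) - 1L)) {
    for (j in (i + 1L):length(params)) {
      if (params[i] %in% dropped || params[j] %in% dropped) next
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      n <- sum(ok)
      if (n < 4L) next
      r <- stats::cor(m[ok, i], m[ok, j])
      p <- if (abs(r) >= 1) 0 else {
        t <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(t), df = n - 2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        from = params[i], to = params[j], r = r, p = p, n = n,
        sign = ifelse(r >= 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  all_pairs <- do.call(rbind, rows)
  edges <- all_pairs[all_pairs$p < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = setdiff(params, dropped),
                 alpha = alpha, dropped = dropped, all_pairs = all_pairs),
            class = "cor_network")
}

#' Export a correlation network
#'
#' Writes GraphML (via \pkg{igraph}) and/or an edge-list CSV.
#'
#' @param net A \code{cor_network}.
#' @param graphml Optional GraphML output path.
#' @param csv Optional edge-list CSV path.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml = NULL, csv = NULL) {
  stopifnot(inherits(net, "cor_network"))
  if (!is.null(csv)) {
    utils::write.csv(net$edges[, c("from", "to", "r", "p", "sign")], csv,
                     row.names = FALSE)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(c(graphml = graphml, csv = csv))
}

#' Empirical single-predictor regression (nutrient-chlorophyll style)
#'
#' Ordinary least squares of response on predictor, by default after log10
#' transforming both (the standard form of empirical chlorophyll-nutrient
#' models); non-positive values are dropped under the log transform with a
#' count recorded.
#'
#' @param response,predictor Numeric vectors of equal length.
#' @param log_transform Apply log10 to both sides (default TRUE).
#' @param response_name,predictor_name Labels carried into the result.
#' @return A \code{regression_fit} list: slope, intercept, r2, n,
#'   transform, n_dropped, and the \code{lm} fit.
#' @export
empirical_regression <- function(response, predictor, log_transform = TRUE,
                                 response_name = "response",
                                 predictor_name = "predictor") {
  ok <- !is.na(response) & !is.na(predictor)
  n_dropped <- 0L
  if (log_transform) {
    pos <- ok & response > 0 & predictor > 0
    n_dropped <- sum(ok) - sum(pos)
    if (n_dropped > 0) {
      message(n_dropped, " non-positive pair(s) dropped under log transform")
    }
    y <- log10(response[pos]); xv <- log10(predictor[pos])
  } else {
    y <- response[ok]; xv <- predictor[ok]
  }
  if (length(y) < 3L) stop("need at least 3 usable pairs")
  if (stats::sd(xv) == 0) stop("zero predictor variance")
  fit <- stats::lm(y ~ xv)
  structure(list(response = response_name, predictor = predictor_name,
                 transform = if (log_transform) "log10" else "none",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = stats::cor(xv, y)^2, n = length(y),
                 n_dropped = n_dropped, lm = fit),
            class = "regression_fit")
}

#' Fold change between pre- and post-weir groups
#'
#' Ratio of group means, reported as an x-fold decrease when the pre mean
#' exceeds the post mean (ratio = mean(pre)/mean(post)) and as an x-fold
#' increase otherwise (ratio = mean(post)/mean(pre)), so the fold is always
#' >= 1.
#'
#' @param pre_values,post_values Non-empty numeric vectors with positive
#'   means.
#' @return List: \code{fold}, \code{direction} ("increase", "decrease" or
#'   "no change"), \code{mean_pre}, \code{mean_post}.
#' @export
fold_change <- function(pre_values, post_values) {
  pre_values <- pre_values[!is.na(pre_values)]
  post_values <- post_values[!is.na(post_values)]
  if (!length(pre_values) || !length(post_values)) stop("empty group")
  m_pre <- mean(pre_values); m_post <- mean(post_values)
  if (m_pre <= 0 || m_post <= 0) stop("group means must be positive")
  if (m_pre >= m_post) {
    list(fold = m_pre / m_post,
         direction = if (m_pre == m_post) "no change" else "decrease",
         mean_pre = m_pre, mean_post = m_post)
  } else {
    list(fold = m_post / m_pre, direction = "increase",
         mean_pre = m_pre, mean_post = m_post)
  }
}
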