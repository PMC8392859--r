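#' Default standards table for the weighted-arithmetic WQI
#'
#' Per-parameter standard desirable values S_n and ideal (pure-water) values
#' V_0. All parameters except water temperature participate; V_0 is 0 for
#' every parameter except pH (7) and DO (14.6, the saturation value). The
#' shipped S_n values are editable defaults drawn from the ecological
#' thresholds used elsewhere in the package (see [threshold_rules()]) —
#' regulatory standards differ between jurisdictions, so users should
#' override them with their own table where one exists.
#'
#' @param s_n Named numeric vector of standard values (parameter units).
#' @param v_0 Named numeric vector of ideal values.
#' @return A \code{wqi_standards} list with \code{s_n} and \code{v_0}.
#' @export
wqi_standards <- function(s_n = c("pH" = 8.5, "DO" = 5, "EC" = 300,
                                  "TSS" = 25, "TP" = 100, "TN" = 1.5,
                                  "BOD" = 5, "COD" = 7, "CHL-a" = 30,
                                  "TCB" = 5000),
                          v_0 = c("pH" = 7, "DO" = 14.6)) {
  if ("WT" %in% names(s_n)) stop("water temperature is excluded from the WQI")
  if (any(s_n <= 0)) stop("all S_n must be positive")
  v0 <- stats::setNames(rep(0, length(s_n)), names(s_n))
  common <- intersect(names(v_0), names(s_n))
  v0[common] <- v_0[common]
  if (any(s_n == v0)) stop("S_n must differ from V_0 for every parameter")
  structure(list(s_n = s_n, v_0 = v0), class = "wqi_standards")
}

#' Unit weight factors
#'
#' W_n = K / S_n with K = 1 / sum(1 / S_n), so that the weights sum to one
#' (unity constraint).
#'
#' @param standards A [wqi_standards()] table (or any named positive S_n
#'   vector wrapped in one).
#' @return List with \code{K} and named weight vector \code{w_n}.
#' @export
compute_unit_weights <- function(standards) {
  s <- standards$s_n
  if (any(s <= 0)) stop("all S_n must be positive")
  K <- 1 / sum(1 / s)
  list(K = K, w_n = K / s)
}

#' Sub-index Q_n for one measurement
#'
#' Q_n = (V_n - V_0) / (S_n - V_0) x 100. The signed formula applies
#' verbatim to pH and DO: a DO value below saturation gives a positive
#' sub-index because S_n - V_0 is negative there.
#'
#' @param v_n Measured value.
#' @param s_n Standard desirable value.
#' @param v_0 Ideal (pure-water) value.
#' @return Sub-index in percent.
#' @export
compute_subindex <- function(v_n, s_n, v_0 = 0) {
  if (any(s_n == v_0)) stop("S_n must differ from V_0")
  (v_n - v_0) / (s_n - v_0) * 100
}

#' Weighted-arithmetic Water Quality Index of one sample
#'
#' WQI = sum(W_n Q_n) / sum(W_n) over the parameters present in the sample;
#' weights are renormalized over the present set, so missing parameters
#' reduce the basis rather than being imputed.
#'
#' @param sample Named numeric vector (parameter -> measured value); NA or
#'   absent parameters are skipped.
#' @param standards A [wqi_standards()] table.
#' @param bands WQI class bands, see [classify_wqi()].
#' @return A \code{wqi_result} list: \code{K}, \code{w_n}, \code{q_n} (both
#'   over present parameters), \code{wqi}, \code{class}, \code{n_used}.
#' @export
compute_wqi <- function(sample, standards = wqi_standards(),
                        bands = wqi_bands()) {
  present <- intersect(names(standards$s_n), names(sample))
  present <- present[!is.na(sample[present])]
  if (length(present) == 0L) stop("no WQI parameter present in sample")
  uw <- compute_unit_weights(standards)
  w <- uw$w_n[present]
  q <- compute_subindex(sample[present], standards$s_n[present],
                        standards$v_0[present])
  wqi <- sum(w * q) / sum(w)
  structure(list(K = uw$K, w_n = w / sum(w), q_n = q, wqi = wqi,
                 class = classify_wqi(wqi, bands), n_used = length(present)),
            class = "wqi_result")
}

#' Default WQI class bands
#'
#' 0-25 excellent, >25-50 good, >50-75 poor, >75-100 very poor,
#' >100 unsuitable. Upper edges are inclusive (100 is "very poor"; the
#' "unsuitable" class is strictly above 100).
#'
#' @return List with \code{edges} and \code{labels}.
#' @export
wqi_bands <- function() {
  list(edges = c(25, 50, 75, 100),
       labels = c("excellent", "good", "poor", "very poor", "unsuitable"))
}

#' Classify a WQI score
#'
#' @param wqi Numeric vector of WQI scores (non-negative).
#' @param bands Bands config, see [wqi_bands()].
#' @return Character vector of class labels.
#' @export
classify_wqi <- function(wqi, bands = wqi_bands()) {
  if (any(is.na(wqi)) || any(wqi < 0)) stop("wqi must be non-negative")
  idx <- findInterval(wqi, bands$edges, left.open = TRUE) + 1L
  bands$labels[idx]
}

#' Per-site and per-season WQI report
#'
#' Computes the WQI of every sample in a \code{wq_matrix} and aggregates by
#' site and season.
#'
#' @param x A \code{wq_matrix}.
#' @param standards A [wqi_standards()] table.
#' @param bands Bands config.
#' @return List with \code{per_sample} (meta + wqi + class) and \code{report}
#'   (site, season, n, mean_wqi, class of the mean).
#' @export
wqi_report <- function(x, standards = wqi_standards(), bands = wqi_bands()) {
  stopifnot(inherits(x, "wq_matrix"))
  wqi <- apply(x$values, 1L, function(row) {
    compute_wqi(row, standards, bands)$wqi
  })
  per_sample <- cbind(x$meta, wqi = wqi, class = classify_wqi(wqi, bands))
  agg <- stats::aggregate(wqi ~ site_id + season, data = per_sample, FUN = mean)
  names(agg)[names(agg) == "wqi"] <- "mean_wqi"
  nagg <- stats::aggregate(wqi ~ site_id + season, data = per_sample,
                           FUN = length)
  agg$n <- nagg$wqi
  agg$class <- classify_wqi(agg$mean_wqi, bands)
  agg <- agg[order(agg$site_id, agg$season), c("site_id", "season", "n",
                                               "mean_wqi", "class")]
  rownames(agg) <- NULL
  list(per_sample = per_sample, report = agg)
}
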