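#' Parameter vocabulary
#'
#' The eleven routinely monitored water-quality parameters handled by this
#' package, in canonical column order: pH (unitless), water temperature WT
#' (degrees C), dissolved oxygen DO (mg/L), electrical conductivity EC
#' (uS/cm), total suspended solids TSS (mg/L), total phosphorus TP (ug/L),
#' total nitrogen TN (mg/L), biological and chemical oxygen demand BOD/COD
#' (mg/L), chlorophyll-a CHL-a (ug/L) and total coliform bacteria TCB
#' (MPN/100 mL).
#'
#' @return Character vector of the 11 parameter names in canonical order.
#' @export
wq_parameters <- function() {
  c("pH", "WT", "DO", "EC", "TSS", "TP", "TN", "BOD", "COD", "CHL-a", "TCB")
}

#' Measurement units per parameter
#'
#' @return Named character vector mapping each parameter to its unit.
#' @export
wq_units <- function() {
  c("pH" = "unitless", "WT" = "degC", "DO" = "mg/L", "EC" = "uS/cm",
    "TSS" = "mg/L", "TP" = "ug/L", "TN" = "mg/L", "BOD" = "mg/L",
    "COD" = "mg/L", "CHL-a" = "ug/L", "TCB" = "MPN/100mL")
}

#' Read long-format monitoring records from CSV
#'
#' Expects a header with columns \code{site_id,date,parameter,value} (UTF-8,
#' "." decimal, ISO-8601 dates). Rows with an unknown parameter name, a
#' negative value, or a pH outside [0, 14] are rejected and reported with
#' their row numbers; an unparseable date is an error.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class \code{wq_records} with columns
#'   \code{site_id}, \code{date} (Date), \code{parameter}, \code{value},
#'   and attributes \code{rejected} (data frame of rejected rows with a
#'   \code{reason} column) and \code{n_rejected}.
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site_id", "date", "parameter", "value")
  if (!all(need %in% names(raw))) {
    stop("header must name columns: ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("empty input: header only, no records")
    return(as_wq_records(data.frame(site_id = character(), date = as.Date(character()),
                                    parameter = character(), value = numeric()),
                         rejected = data.frame()))
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    stop("unparseable date(s) at row(s): ", paste(utils::head(bad, 10L), collapse = ", "))
  }
  values <- suppressWarnings(as.numeric(raw$value))

  reason <- rep(NA_character_, nrow(raw))
  reason[!(raw$parameter %in% wq_parameters())] <- "unknown parameter"
  reason[is.na(reason) & is.na(values)] <- "non-numeric value"
  reason[is.na(reason) & values < 0] <- "negative value"
  reason[is.na(reason) & raw$parameter == "pH" &
           (values < 0 | values > 14)] <- "pH outside [0,14]"

  keep <- is.na(reason)
  rejected <- cbind(row = which(!keep), raw[!keep, , drop = FALSE],
                    reason = reason[!keep])
  out <- data.frame(site_id = raw$site_id[keep], date = dates[keep],
                    parameter = raw$parameter[keep], value = values[keep],
                    stringsAsFactors = FALSE)
  as_wq_records(out, rejected = rejected)
}

as_wq_records <- function(df, rejected = data.frame()) {
  structure(df, class = c("wq_records", "data.frame"),
            rejected = rejected, n_rejected = nrow(rejected))
}

#' Pivot long records to a samples-by-parameters matrix
#'
#' One row per (site, date); duplicate (site, date, parameter) observations
#' are averaged and counted; absent observations become NA. Season and
#' pre/post-weir period labels are derived from the date.
#'
#' @param records A \code{wq_records} data frame (see [read_long_csv()]).
#' @param boundaries Period boundary config, see [period_of()].
#' @param tiers Optional named character vector mapping site_id to a
#'   pollution tier in \code{c("HP","MP","LP")}; unmapped sites get
#'   \code{"unknown"}.
#' @return A \code{wq_matrix}: list with \code{values} (numeric matrix,
#'   columns in [wq_parameters()] order, NA = missing), \code{meta} (data
#'   frame with site_id, date, season, period, tier), and
#'   \code{n_duplicates} (count of averaged duplicate observations).
#' @export
pivot_to_matrix <- function(records, boundaries = period_boundaries(),
                            tiers = NULL) {
  stopifnot(nrow(records) > 0L)
  params <- wq_parameters()
  key <- paste(records$site_id, format(records$date), sep = "\r")
  ukey <- unique(key)
  values <- matrix(NA_real_, nrow = length(ukey), ncol = length(params),
                   dimnames = list(NULL, params))
  dup <- 0L
  ri <- match(key, ukey)
  ci <- match(records$parameter, params)
  cell <- paste(ri, ci)
  agg <- tapply(records$value, cell, mean)
  cnt <- tapply(records$value, cell, length)
  dup <- sum(cnt - 1L)
  idx <- do.call(rbind, lapply(strsplit(names(agg), " "), as.integer))
  values[idx] <- agg

  first <- !duplicated(key)
  meta <- data.frame(site_id = records$site_id[first],
                     date = records$date[first], stringsAsFactors = FALSE)
  meta <- meta[order(match(paste(meta$site_id, format(meta$date), sep = "\r"), ukey)), ]
  meta$season <- season_of(as.integer(format(meta$date, "%m")))
  meta$period <- period_of(meta$date, boundaries)
  meta$tier <- if (is.null(tiers)) "unknown" else {
    t <- unname(tiers[meta$site_id]); t[is.na(t)] <- "unknown"; t
  }
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, n_duplicates = dup),
            class = "wq_matrix")
}

#' Flatten a wq_matrix back to long records
#'
#' Inverse of [pivot_to_matrix()] up to duplicate averaging: one record per
#' non-missing cell.
#'
#' @param x A \code{wq_matrix}.
#' @return A \code{wq_records} data frame.
#' @export
matrix_to_records <- function(x) {
  stopifnot(inherits(x, "wq_matrix"))
  params <- colnames(x$values)
  rows <- lapply(seq_along(params), function(j) {
    ok <- !is.na(x$values[, j])
    data.frame(site_id = x$meta$site_id[ok], date = x$meta$date[ok],
               parameter = params[j], value = x$values[ok, j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$date, match(out$parameter, params)), ]
  rownames(out) <- NULL
  as_wq_records(out)
}

#' Season of a calendar month
#'
#' Monsoon stratification used for all temporal contrasts: premonsoon
#' (January-June), monsoon (July-August), postmonsoon (September-December).
#'
#' @param month Integer vector in 1..12.
#' @return Character vector of season labels.
#' @export
season_of <- function(month) {
  if (any(is.na(month)) || any(month < 1L | month > 12L | month != round(month))) {
    stop("month must be an integer in 1..12")
  }
  ifelse(month <= 6L, "premonsoon", ifelse(month <= 8L, "monsoon", "postmonsoon"))
}

#' Default pre/post-weir period boundaries
#'
#' The in-stream weirs (and upgraded sewage-treatment facilities) were
#' commissioned during 2012, so 2012 is treated as a transition year excluded
#' from pre/post contrasts by default.
#'
#' @param pre_end Last date of the pre-weir period.
#' @param post_start First date of the post-weir period.
#' @return List with elements \code{pre_end}, \code{post_start}.
#' @export
period_boundaries <- function(pre_end = as.Date("2011-12-31"),
                              post_start = as.Date("2013-01-01")) {
  pre_end <- as.Date(pre_end); post_start <- as.Date(post_start)
  if (pre_end >= post_start) stop("pre_end must precede post_start")
  list(pre_end = pre_end, post_start = post_start)
}

#' Pre-weir / transition / post-weir period of a date
#'
#' @param date Date vector.
#' @param boundaries Output of [period_boundaries()].
#' @return Character vector in \code{c("pre-weir","transition","post-weir")}.
#' @export
period_of <- function(date, boundaries = period_boundaries()) {
  date <- as.Date(date)
  ifelse(date <= boundaries$pre_end, "pre-weir",
         ifelse(date >= boundaries$post_start, "post-weir", "transition"))
}

#' Default ecological threshold rules
#'
#' Trophic-state thresholds (eutrophic above TP 75 ug/L, TN 1.5 mg/L, CHL-a
#' 30 ug/L), organic-pollution thresholds (BOD 5, COD 7 mg/L), the severe
#' ionic-pollution EC threshold (300 uS/cm), total-coliform pollution band
#' edges, and the TN/TP mass-ratio cutoff above which algal growth is
#' considered phosphorus limited.
#'
#' @return List of thresholds; all positive, band edges strictly increasing.
#' @export
threshold_rules <- function() {
  list(
    tp_eutrophic = 75,      # ug/L
    tn_eutrophic = 1.5,     # mg/L
    chl_eutrophic = 30,     # ug/L
    bod_organic = 5,        # mg/L
    cod_organic = 7,        # mg/L
    ec_severe = 300,        # uS/cm
    tcb_bands = c(500, 1e4, 1e5, 1e6),   # MPN/100 mL band edges
    tcb_labels = c("little pollution", "moderate pollution",
                   "critical pollution", "strong pollution",
                   "excessive pollution"),
    tn_tp_p_limited = 20    # mass ratio
  )
}

#' Classify total coliform bacteria into pollution bands
#'
#' Bands (MPN/100 mL): <=500 little; >500-10,000 moderate; >10,000-100,000
#' critical; >100,000-1,000,000 strong; >1,000,000 excessive.
#'
#' @param tcb Numeric vector, MPN/100 mL, non-negative.
#' @param rules Threshold rules, see [threshold_rules()].
#' @return Character vector of band labels.
#' @export
classify_tcb <- function(tcb, rules = threshold_rules()) {
  if (any(is.na(tcb)) || any(tcb < 0)) stop("tcb must be non-negative")
  idx <- findInterval(tcb, rules$tcb_bands, left.open = TRUE) + 1L
  rules$tcb_labels[idx]
}

#' Trophic flags and nutrient-limitation status
#'
#' Flags eutrophic conditions against the TP/TN/CHL-a thresholds and computes
#' the TN/TP mass ratio (TN converted from mg/L to ug/L so both nutrients are
#' on the same mass basis). A ratio above the cutoff (default 20) labels the
#' water phosphorus limited.
#'
#' @param tp Total phosphorus, ug/L.
#' @param tn Total nitrogen, mg/L.
#' @param chl Chlorophyll-a, ug/L.
#' @param rules Threshold rules, see [threshold_rules()].
#' @return Data frame with columns \code{tp_eutrophic}, \code{tn_eutrophic},
#'   \code{chl_eutrophic} (logical), \code{tn_tp_ratio} (NA when TP = 0) and
#'   \code{limitation} ("P-limited" or "indeterminate/co-limited";
#'   "undefined" when TP = 0).
#' @export
classify_trophic <- function(tp, tn, chl, rules = threshold_rules()) {
  if (any(c(tp, tn, chl) < 0, na.rm = TRUE)) stop("inputs must be non-negative")
  ratio <- ifelse(tp > 0, (tn * 1000) / tp, NA_real_)
  data.frame(
    tp_eutrophic = tp > rules$tp_eutrophic,
    tn_eutrophic = tn > rules$tn_eutrophic,
    chl_eutrophic = chl > rules$chl_eutrophic,
    tn_tp_ratio = ratio,
    limitation = ifelse(is.na(ratio), "undefined",
                        ifelse(ratio > rules$tn_tp_p_limited, "P-limited",
                               "indeterminate/co-limited")),
    stringsAsFactors = FALSE
  )
}

#' Write a wq_matrix as wide CSV
#'
#' One row per (site, date), one column per parameter, empty cell = missing.
#'
#' @param x A \code{wq_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wide_csv <- function(x, path) {
  stopifnot(inherits(x, "wq_matrix"))
  df <- cbind(x$meta[, c("site_id", "date")], as.data.frame(x$values,
                                                            check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wide CSV back into a wq_matrix
#'
#' @param path Path to a wide CSV written by [write_wide_csv()].
#' @param boundaries Period boundary config, see [period_of()].
#' @param tiers Optional site-to-tier mapping, see [pivot_to_matrix()].
#' @return A \code{wq_matrix}.
#' @export
read_wide_csv <- function(path, boundaries = period_boundaries(), tiers = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  params <- wq_parameters()
  missing_cols <- setdiff(params, names(df))
  for (p in missing_cols) df[[p]] <- NA_real_
  values <- as.matrix(df[, params])
  storage.mode(values) <- "double"
  meta <- data.frame(site_id = as.character(df$site_id),
                     date = as.Date(df$date), stringsAsFactors = FALSE)
  meta$season <- season_of(as.integer(format(meta$date, "%m")))
  meta$period <- period_of(meta$date, boundaries)
  meta$tier <- if (is.null(tiers)) "unknown" else {
    t <- unname(tiers[meta$site_id]); t[is.na(t)] <- "unknown"; t
  }
  structure(list(values = values, meta = meta, n_duplicates = 0L),
            class = "wq_matrix")
}

#' @export
print.wq_matrix <- function(x, ...) {
  cat("wq_matrix:", nrow(x$values), "samples x", ncol(x$values), "parameters;",
      length(unique(x$meta$site_id)), "site(s),",
      sum(is.na(x$values)), "missing cell(s)\n")
  invisible(x)
}
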