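#' Synthetic monitoring-data generator configuration
#'
#' Defaults emulate a 16-site river monitoring network sampled monthly over
#' 15 years with a three-source non-negative structure: a point-source
#' (sewage-treatment-plant) factor heavy in BOD/COD/TP/TN/CHL-a, an
#' agriculture/livestock factor heavy in TP/TN/TCB/BOD, and a
#' background/ionic factor heavy in EC and DO. Sites fall into
#' high/medium/low pollution tiers (2/5/9 sites) through their mean
#' point-source activity. Monsoon months dilute nutrients and ions
#' (x0.7 on TP/TN/EC) while enriching solids and coliforms (x2.0 on TSS,
#' x1.5 on TCB), and slow monotone trends are injected (COD and CHL-a
#' rising, TP/TN/BOD falling). Noise is multiplicative lognormal; pH is
#' simulated outside the factor model as a bounded variable.
#'
#' @param n_sites Number of sites.
#' @param tier_counts Named integer vector, sites per tier (HP/MP/LP).
#' @param years Span of years sampled monthly.
#' @param start_year First calendar year.
#' @param profiles 3 x 11 non-negative source-profile matrix (rows: sources,
#'   columns in [wq_parameters()] order; the pH column is ignored).
#' @param tier_activity 3 x 3 matrix of mean source activity by tier
#'   (rows HP/MP/LP, columns source 1..3).
#' @param activity_cv Coefficient of variation of per-sample gamma-distributed
#'   source activities around the site mean.
#' @param season_multipliers Named list parameter -> multiplier applied in
#'   monsoon months.
#' @param trend_slopes Named numeric vector, fractional change per year
#'   applied as a linear multiplier on the annual index (0 = no trend).
#' @param noise_cv Lognormal noise coefficient of variation (0 = noiseless).
#' @param mdl Optional named numeric vector of method detection limits;
#'   values below the MDL are reported at MDL/2 and flagged (censoring off
#'   when NULL).
#' @param ph_mean,ph_sd Mean and s.d. of the independently simulated pH.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_sites = 16L,
                             tier_counts = c(HP = 2L, MP = 5L, LP = 9L),
                             years = 15L,
                             start_year = 2005L,
                             profiles = default_profiles(),
                             tier_activity = default_tier_activity(),
                             activity_cv = 0.5,
                             season_multipliers = list(TP = 0.7, TN = 0.7,
                                                       EC = 0.7, TSS = 2.0,
                                                       TCB = 1.5),
                             trend_slopes = c(COD = 0.02, "CHL-a" = 0.02,
                                              TP = -0.03, TN = -0.015,
                                              BOD = -0.02),
                             noise_cv = 0.2,
                             mdl = NULL,
                             ph_mean = 7.75, ph_sd = 0.25) {
  if (n_sites < 1L || years < 1L) stop("n_sites and years must be positive")
  if (sum(tier_counts) != n_sites) stop("tier_counts must sum to n_sites")
  if (any(profiles < 0) || any(tier_activity < 0)) {
    stop("profiles and activities must be non-negative")
  }
  if (any(unlist(season_multipliers) <= 0)) stop("multipliers must be positive")
  structure(list(n_sites = as.integer(n_sites), tier_counts = tier_counts,
                 years = as.integer(years), start_year = as.integer(start_year),
                 profiles = profiles, tier_activity = tier_activity,
                 activity_cv = activity_cv,
                 season_multipliers = season_multipliers,
                 trend_slopes = trend_slopes, noise_cv = noise_cv, mdl = mdl,
                 ph_mean = ph_mean, ph_sd = ph_sd),
            class = "generator_config")
}

#' Default true source-profile matrix
#'
#' Rows: source 1 "STP point", source 2 "agriculture/livestock", source 3
#' "background/ionic". Columns in [wq_parameters()] order; pH is zero (it is
#' simulated outside the factor model). Magnitudes sit in each parameter's
#' realistic field range so that unit-activity mixtures resemble the
#' monitored concentrations.
#'
#' @return 3 x 11 non-negative matrix with dimnames.
#' @export
default_profiles <- function() {
  params <- wq_parameters()
  m <- rbind(
    STP        = c(0, 4, 0.3,  40, 8, 150, 3.0, 3.5, 4.5, 25,   800),
    AgriLive   = c(0, 1, 0.1,  15, 3, 100, 1.8, 1.0, 1.0,  2, 15000),
    Background = c(0, 6, 6.0, 350, 4,  10, 0.5, 0.1, 0.8,  1,   200)
  )
  colnames(m) <- params
  m
}

#' Default mean source activity by pollution tier
#'
#' High-pollution sites have much larger point-source activity than medium
#' and low tiers; agriculture and background activities vary less.
#'
#' @return 3 x 3 matrix (rows HP/MP/LP, columns sources 1..3).
#' @export
default_tier_activity <- function() {
  m <- rbind(HP = c(3.0, 0.4, 0.8),
             MP = c(0.8, 1.6, 1.0),
             LP = c(0.05, 0.9, 1.2))
  colnames(m) <- c("STP", "AgriLive", "Background")
  m
}

#' Generate a synthetic monitoring dataset with known ground truth
#'
#' Builds X = G F from per-sample gamma-distributed source activities and the
#' configured profiles, applies monsoon multipliers, linear annual trend
#' multipliers and multiplicative lognormal noise, simulates pH
#' independently, and (optionally) left-censors at the MDL (reported MDL/2).
#' Deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed.
#' @return List with \code{records} (long \code{wq_records}), \code{matrix}
#'   (a \code{wq_matrix}), \code{truth} (list: \code{G_true} samples x 3,
#'   \code{F_true}, \code{trend_slopes}, \code{season_multipliers},
#'   \code{tiers} named site->tier vector, \code{censored} logical matrix),
#'   and \code{config}.
#' @export
generate_dataset <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  params <- wq_parameters()
  tiers <- rep(names(config$tier_counts), config$tier_counts)
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  names(tiers) <- sites

  months <- seq_len(12L * config$years)
  dates <- as.Date(sprintf("%d-%02d-15",
                           config$start_year + (months - 1L) %/% 12L,
                           (months - 1L) %% 12L + 1L))
  grid <- expand.grid(date = dates, site_id = sites, stringsAsFactors = FALSE)
  grid <- grid[, c("site_id", "date")]
  n <- nrow(grid)

  # per-sample non-negative source activities (gamma around the tier mean)
  act_mean <- config$tier_activity[tiers[grid$site_id], , drop = FALSE]
  cv <- config$activity_cv
  G <- if (cv > 0) {
    shape <- 1 / cv^2
    matrix(stats::rgamma(n * 3L, shape = shape, rate = shape / pmax(act_mean, 1e-12)),
           nrow = n)
  } else act_mean
  G[act_mean == 0] <- 0
  colnames(G) <- rownames(config$profiles)

  X <- G %*% config$profiles          # clean mixture, pH column is zero

  month_no <- as.integer(format(grid$date, "%m"))
  monsoon <- season_of(month_no) == "monsoon"
  for (p in names(config$season_multipliers)) {
    X[monsoon, p] <- X[monsoon, p] * config$season_multipliers[[p]]
  }
  year_index <- as.integer(format(grid$date, "%Y")) - config$start_year
  for (p in names(config$trend_slopes)) {
    mult <- pmax(1 + config$trend_slopes[[p]] * year_index, 0.05)
    X[, p] <- X[, p] * mult
  }
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- matrix(stats::rlnorm(n * length(params), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), nrow = n)
    X <- X * noise
  }
  X[, "pH"] <- pmin(pmax(stats::rnorm(n, config$ph_mean, config$ph_sd), 0), 14)

  censored <- matrix(FALSE, n, length(params), dimnames = list(NULL, params))
  if (!is.null(config$mdl)) {
    for (p in names(config$mdl)) {
      below <- X[, p] < config$mdl[[p]]
      X[below, p] <- config$mdl[[p]] / 2
      censored[below, p] <- TRUE
    }
  }

  meta <- data.frame(site_id = grid$site_id, date = grid$date,
                     stringsAsFactors = FALSE)
  meta$season <- season_of(month_no)
  meta$period <- period_of(meta$date)
  meta$tier <- unname(tiers[meta$site_id])
  mat <- structure(list(values = X, meta = meta, n_duplicates = 0L),
                   class = "wq_matrix")
  truth <- list(G_true = G, F_true = config$profiles,
                trend_slopes = config$trend_slopes,
                season_multipliers = config$season_multipliers,
                tiers = tiers, censored = censored)
  list(records = matrix_to_records(mat), matrix = mat, truth = truth,
       config = config)
}

#' Named small fixture datasets for method-recovery tests
#'
#' \describe{
#'   \item{tiny}{2 sites x 12 months, defaults otherwise.}
#'   \item{separated_tiers}{16 sites whose three pollution tiers are well
#'     separated (large tier contrasts, low noise, no seasonality/trends) so
#'     Bray-Curtis clustering and discriminant analysis must recover the
#'     tiers.}
#'   \item{trended}{2 sites x 10 years with strong injected monotone trends
#'     and no seasonality, for Mann-Kendall recovery.}
#'   \item{rank3_noiseless}{4 sites x 5 years with noise, seasonality and
#'     trends off: the non-pH columns are exactly the rank-3 product
#'     G_true F_true, so PMF at p = 3 must reach Q ~ 0.}
#' }
#'
#' @param seed Integer RNG seed.
#' @return Named list of [generate_dataset()] outputs.
#' @export
make_fixture_suite <- function(seed = 1L) {
  tiny <- generate_dataset(
    generator_config(n_sites = 2L, tier_counts = c(HP = 1L, MP = 1L, LP = 0L),
                     years = 1L),
    seed = seed)

  sep_act <- rbind(HP = c(5.0, 3.0, 0.5),
                   MP = c(1.5, 1.0, 1.0),
                   LP = c(0.2, 1 / 3, 2.0))
  colnames(sep_act) <- c("STP", "AgriLive", "Background")
  separated <- generate_dataset(
    generator_config(n_sites = 16L, years = 3L,
                     tier_activity = sep_act, activity_cv = 0.1,
                     season_multipliers = list(), trend_slopes = numeric(),
                     noise_cv = 0.05),
    seed = seed + 1L)

  trended <- generate_dataset(
    generator_config(n_sites = 2L, tier_counts = c(HP = 1L, MP = 1L, LP = 0L),
                     years = 10L, activity_cv = 0.1,
                     season_multipliers = list(),
                     trend_slopes = c(COD = 0.08, "CHL-a" = 0.08, TP = -0.06,
                                      TN = -0.05, BOD = -0.06),
                     noise_cv = 0.1),
    seed = seed + 2L)

  rank3 <- generate_dataset(
    generator_config(n_sites = 4L, tier_counts = c(HP = 1L, MP = 2L, LP = 1L),
                     years = 5L, season_multipliers = list(),
                     trend_slopes = numeric(), noise_cv = 0),
    seed = seed + 3L)

  list(tiny = tiny, separated_tiers = separated, trended = trended,
       rank3_noiseless = rank3)
}

#' Write a generated dataset to disk
#'
#' Emits the long CSV (core dialect), ground-truth G and F matrices as CSV,
#' and a JSON manifest echoing the seed and configuration.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @param seed The seed used (echoed into the manifest).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             G = file.path(dir, "truth_contributions.csv"),
             F = file.path(dir, "truth_profiles.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(as.data.frame(dataset$records), paths["records"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$truth$G_true), paths["G"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$truth$F_true), paths["F"],
                   row.names = TRUE)
  cfg <- dataset$config
  cfg$profiles <- as.data.frame(cfg$profiles)
  cfg$tier_activity <- as.data.frame(cfg$tier_activity)
  jsonlite::write_json(list(seed = seed, config = cfg), paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(paths)
}
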