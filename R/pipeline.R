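#' Full-analysis run configuration
#'
#' Bundles every stage's settings; echoed verbatim into the run manifest.
#'
#' @param standards WQI standards table, see [wqi_standards()].
#' @param rules Ecological threshold rules, see [threshold_rules()].
#' @param boundaries Pre/post-weir boundaries, see [period_boundaries()].
#' @param pmf List: p, n_starts, seed, ef, mdl, tol, max_iter,
#'   exclude (parameters kept out of the PMF input; pH and DO by default —
#'   bounded, non-source-like variables).
#' @param da List: f_enter, f_remove.
#' @param cluster List: linkage, cut_similarity.
#' @param network_alpha Edge significance threshold.
#' @param trend_alpha Trend significance threshold.
#' @return A \code{run_config} list.
#' @export
run_config <- function(standards = wqi_standards(),
                       rules = threshold_rules(),
                       boundaries = period_boundaries(),
                       pmf = list(p = 3L, n_starts = 10L, seed = 1L,
                                  ef = 0.1, mdl = NULL, tol = 1e-8,
                                  max_iter = 2000L,
                                  exclude = c("pH", "DO")),
                       da = list(f_enter = 3.84, f_remove = 2.71),
                       cluster = list(linkage = "average",
                                      cut_similarity = 0.60),
                       network_alpha = 0.05,
                       trend_alpha = 0.05) {
  structure(list(standards = standards, rules = rules,
                 boundaries = boundaries, pmf = pmf, da = da,
                 cluster = cluster, network_alpha = network_alpha,
                 trend_alpha = trend_alpha),
            class = "run_config")
}

#' Run the full analysis pipeline on a monitoring matrix
#'
#' Executes every stage — WQI, Mann-Kendall trends, Bray-Curtis site
#' clustering, spatial (cluster-group) and temporal (season) stepwise
#' discriminant analysis, PCA/FA with varimax rotation and KMO/Bartlett
#' diagnostics, PMF source apportionment, and the significance-filtered
#' correlation network — and writes each stage's outputs plus a JSON
#' manifest under \code{out_dir}. A failing stage is recorded in the
#' manifest and the remaining stages still run.
#'
#' @param x A \code{wq_matrix}.
#' @param config A [run_config()].
#' @param out_dir Output directory, created if absent; NULL skips all file
#'   output.
#' @return Invisibly, a list of per-stage results (\code{wqi},
#'   \code{trends}, \code{cluster}, \code{da_spatial}, \code{da_temporal},
#'   \code{fa}, \code{pmf}, \code{network}, \code{manifest}).
#' @export
run_pipeline <- function(x, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(x, "wq_matrix"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  res <- list()
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
  }
  emit <- function(df, file) {
    if (!is.null(out_dir) && !is.null(df)) {
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    }
  }

  res$wqi <- stage("wqi", wqi_report(x, config$standards))
  emit(res$wqi$report, "wqi_report.csv")

  res$trends <- stage("trends", suppressMessages(
    trend_report(x, grouping = "site", alpha = config$trend_alpha)))
  emit(res$trends, "trend_report.csv")

  res$cluster <- stage("cluster", cluster_sites(
    x, linkage = config$cluster$linkage,
    cut_similarity = config$cluster$cut_similarity))
  if (!is.null(res$cluster)) {
    emit(data.frame(site_id = names(res$cluster$groups),
                    group = res$cluster$groups), "cluster_groups.csv")
    if (!is.null(out_dir)) {
      write_newick(res$cluster, file.path(out_dir, "dendrogram.nwk"))
    }
  }

  complete <- stats::complete.cases(x$values)
  res$da_spatial <- stage("da_spatial", {
    grp <- res$cluster$groups[x$meta$site_id]
    if (length(unique(grp)) < 2L && length(unique(x$meta$tier)) >= 2L) {
      message("single cluster at the similarity cut; ",
              "using tier labels as the spatial grouping")
      grp <- x$meta$tier
    }
    stepwise_da(x$values[complete, , drop = FALSE], grp[complete],
                f_enter = config$da$f_enter, f_remove = config$da$f_remove)
  })
  res$da_temporal <- stage("da_temporal", stepwise_da(
    x$values[complete, , drop = FALSE], x$meta$season[complete],
    f_enter = config$da$f_enter, f_remove = config$da$f_remove))
  for (nm in c("da_spatial", "da_temporal")) {
    if (!is.null(res[[nm]]) && length(res[[nm]]$selected)) {
      emit(res[[nm]]$steps, paste0(nm, "_steps.csv"))
      emit(as.data.frame(res[[nm]]$classification$counts),
           paste0(nm, "_classification.csv"))
    }
  }

  res$fa <- stage("fa", {
    fl <- varimax_rotate(pca_fa(x$values))
    cc <- x$values[complete, , drop = FALSE]
    diag_r <- stats::cor(cc)
    list(loadings = fl, kmo = kmo(diag_r),
         bartlett = bartlett_sphericity(diag_r, nrow(cc)),
         labels = classify_loadings(fl$loadings))
  })
  if (!is.null(res$fa)) emit(loadings_table(res$fa$loadings), "fa_loadings.csv")

  res$pmf <- stage("pmf", {
    keep <- setdiff(colnames(x$values), config$pmf$exclude)
    Xp <- x$values[complete, keep, drop = FALSE]
    U <- uncertainty_matrix(Xp, mdl = config$pmf$mdl, ef = config$pmf$ef)
    fit <- fit_pmf(Xp, U, p = config$pmf$p, n_starts = config$pmf$n_starts,
                   seed = config$pmf$seed, tol = config$pmf$tol,
                   max_iter = config$pmf$max_iter)
    list(fit = fit, apportionment = apportion(fit, Xp))
  })
  if (!is.null(res$pmf)) {
    emit(res$pmf$apportionment, "pmf_apportionment.csv")
    emit(as.data.frame(res$pmf$fit$G), "pmf_contributions.csv")
    emit(data.frame(factor = rownames(res$pmf$fit$F), res$pmf$fit$F,
                    check.names = FALSE), "pmf_profiles.csv")
  }

  res$network <- stage("network", suppressWarnings(
    correlation_network(x, alpha = config$network_alpha)))
  if (!is.null(res$network) && !is.null(out_dir)) {
    write_network(res$network,
                  graphml = file.path(out_dir, "network.graphml"),
                  csv = file.path(out_dir, "network_edges.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("riverwq")),
    n_samples = nrow(x$values), n_sites = length(unique(x$meta$site_id)),
    stage_rows = list(
      wqi = if (!is.null(res$wqi)) nrow(res$wqi$report) else NULL,
      trends = if (!is.null(res$trends)) nrow(res$trends) else NULL,
      network_edges = if (!is.null(res$network)) nrow(res$network$edges)
                      else NULL),
    pmf = res$pmf$fit[c("Q", "p", "best_start", "converged")],
    config = list(
      pmf = config$pmf, da = config$da, cluster = config$cluster,
      network_alpha = config$network_alpha,
      trend_alpha = config$trend_alpha,
      boundaries = lapply(config$boundaries, format),
      standards = as.list(config$standards$s_n)))
  if (length(errors)) manifest$errors <- errors
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  res$manifest <- manifest
  invisible(res)
}
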