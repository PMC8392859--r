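#' Bray-Curtis similarity between two non-negative vectors
#'
#' similarity = 1 - sum|a - b| / sum(a + b); 1 for identical vectors, 0 for
#' disjoint support.
#'
#' @param a,b Non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return Similarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("vectors must be non-negative")
  tot <- sum(a + b)
  if (tot == 0) stop("both vectors all-zero: similarity undefined")
  1 - sum(abs(a - b)) / tot
}

#' Hierarchical clustering of sites on Bray-Curtis similarity
#'
#' Computes per-site mean parameter vectors (raw, unstandardized, matching
#' Bray-Curtis abundance semantics; a range-normalization flag is available
#' because large-magnitude parameters such as EC and TCB otherwise dominate
#' the index), builds the Bray-Curtis dissimilarity matrix with
#' \pkg{vegan}, and clusters agglomeratively (UPGMA by default). Groups are
#' the subtrees below dissimilarity 1 - cut_similarity.
#'
#' @param x A \code{wq_matrix}, or a sites x parameters matrix of means
#'   with site rownames.
#' @param linkage One of "average", "single", "complete".
#' @param cut_similarity Similarity threshold for group membership
#'   (default 0.60).
#' @param range_normalize Scale each parameter to [0, 1] range before the
#'   dissimilarity (default FALSE).
#' @return A \code{cluster_tree} list: \code{hclust} (the tree, heights are
#'   dissimilarities), \code{site_means}, \code{groups} (named membership
#'   vector), \code{cut_similarity}, \code{linkage}.
#' @export
cluster_sites <- function(x, linkage = c("average", "single", "complete"),
                          cut_similarity = 0.60, range_normalize = FALSE) {
  linkage <- match.arg(linkage)
  if (inherits(x, "wq_matrix")) {
    m <- site_means(x)
  } else {
    m <- as.matrix(x)
  }
  empty <- rowSums(!is.na(m)) == 0L
  if (any(empty)) {
    warning("dropping site(s) with all-missing means: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 sites")
  mm <- m
  if (range_normalize) {
    rng <- apply(mm, 2L, function(v) diff(range(v, na.rm = TRUE)))
    rng[rng == 0] <- 1
    mm <- sweep(sweep(mm, 2L, apply(mm, 2L, min, na.rm = TRUE), "-"), 2L,
                rng, "/")
  }
  d <- vegan::vegdist(mm, method = "bray", na.rm = TRUE)
  hc <- stats::hclust(d, method = linkage)
  groups <- stats::cutree(hc, h = 1 - cut_similarity)
  structure(list(hclust = hc, site_means = m, groups = groups,
                 cut_similarity = cut_similarity, linkage = linkage),
            class = "cluster_tree")
}

#' Per-site mean parameter vectors
#'
#' @param x A \code{wq_matrix}.
#' @return Sites x parameters matrix of means (NA cells ignored).
#' @export
site_means <- function(x) {
  stopifnot(inherits(x, "wq_matrix"))
  sites <- sort(unique(x$meta$site_id))
  m <- t(vapply(sites, function(s) {
    colMeans(x$values[x$meta$site_id == s, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(x$values))))
  m[is.nan(m)] <- NA_real_
  m
}

#' Export a cluster tree as Newick
#'
#' Branch lengths carry the merge dissimilarities.
#'
#' @param tree A \code{cluster_tree}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

wilks_lambda <- function(X, groups) {
  X <- as.matrix(X)
  g <- factor(groups)
  n <- nrow(X)
  grand <- colMeans(X)
  Tm <- crossprod(sweep(X, 2L, grand))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    sub <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(sub, 2L, colMeans(sub)))
  }
  dT <- det(Tm)
  if (dT <= 0) stop("singular total SSCP: collinear variables")
  det(W) / dT
}

#' Stepwise discriminant analysis with Wilks' lambda selection
#'
#' Forward-stepwise variable selection: at each step the candidate variable
#' with the largest partial F (from the ratio of Wilks' lambdas with and
#' without it) enters if the F is at least \code{f_enter}; entered
#' variables whose partial F falls below \code{f_remove} are removed.
#' Classification uses Fisher's linear classification functions from the
#' pooled within-group covariance with equal priors; the resubstitution
#' classification matrix and percent correct are returned.
#'
#' @param X Samples x parameters matrix (complete cases used).
#' @param groups Group label per sample (2+ groups).
#' @param f_enter,f_remove F-to-enter / F-to-remove thresholds (SPSS
#'   defaults 3.84 / 2.71).
#' @return A \code{da_model} list: \code{selected} (variables in entry
#'   order), \code{steps} (data frame of step, action, variable, lambda,
#'   partial_F), \code{wilks_lambda}, \code{coef} and \code{const} of the
#'   per-group classification functions, \code{group_means},
#'   \code{classification} (the [classification_matrix()] of the training
#'   data), plus the training data for reuse.
#' @export
stepwise_da <- function(X, groups, f_enter = 3.84, f_remove = 2.71) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X) & !is.na(groups)
  X <- X[keep, , drop = FALSE]
  g <- factor(groups[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  n <- nrow(X); k <- nlevels(g)
  if (min(table(g)) <= ncol(X)) {
    warning("some group has no more samples than candidate variables")
  }
  vars <- colnames(X)
  selected <- character(0)
  lambda_cur <- 1
  steps <- list()
  step_no <- 0L

  partial_F <- function(lambda_small, lambda_big, p_small) {
    # F for the variable distinguishing the two nested models
    ((lambda_small / lambda_big) - 1) * (n - k - p_small) / (k - 1)
  }

  repeat {
    changed <- FALSE
    # entry
    cand <- setdiff(vars, selected)
    if (length(cand)) {
      Fs <- vapply(cand, function(v) {
        lam <- tryCatch(wilks_lambda(X[, c(selected, v), drop = FALSE], g),
                        error = function(e) NA_real_)
        if (is.na(lam)) return(NA_real_)
        partial_F(lambda_cur, lam, length(selected))
      }, numeric(1))
      if (any(!is.na(Fs)) && max(Fs, na.rm = TRUE) >= f_enter) {
        v <- cand[which.max(Fs)]
        selected <- c(selected, v)
        lambda_cur <- wilks_lambda(X[, selected, drop = FALSE], g)
        step_no <- step_no + 1L
        steps[[step_no]] <- data.frame(step = step_no, action = "enter",
                                       variable = v, lambda = lambda_cur,
                                       partial_F = max(Fs, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # removal
    if (length(selected) > 1L) {
      Fr <- vapply(selected, function(v) {
        rest <- setdiff(selected, v)
        lam_rest <- wilks_lambda(X[, rest, drop = FALSE], g)
        partial_F(lam_rest, lambda_cur, length(rest))
      }, numeric(1))
      if (min(Fr) < f_remove) {
        v <- selected[which.min(Fr)]
        selected <- setdiff(selected, v)
        lambda_cur <- wilks_lambda(X[, selected, drop = FALSE], g)
        step_no <- step_no + 1L
        steps[[step_no]] <- data.frame(step = step_no, action = "remove",
                                       variable = v, lambda = lambda_cur,
                                       partial_F = min(Fr))
        changed <- TRUE
      }
    }
    if (!changed || step_no > 2L * length(vars) + 10L) break
  }

  if (length(selected) == 0L) {
    warning("no variable reached F-to-enter: empty model")
    return(structure(list(selected = character(0), steps = NULL,
                          wilks_lambda = 1, coef = NULL, const = NULL,
                          classification = NULL), class = "da_model"))
  }

  Xs <- X[, selected, drop = FALSE]
  means <- do.call(rbind, lapply(levels(g), function(lev) {
    colMeans(Xs[g == lev, , drop = FALSE])
  }))
  rownames(means) <- levels(g)
  Sp <- matrix(0, ncol(Xs), ncol(Xs))
  for (lev in levels(g)) {
    sub <- Xs[g == lev, , drop = FALSE]
    Sp <- Sp + crossprod(sweep(sub, 2L, colMeans(sub)))
  }
  Sp <- Sp / (n - k)
  Sinv <- tryCatch(solve(Sp), error = function(e) {
    stop("singular pooled within-group covariance over: ",
         paste(selected, collapse = ", "))
  })
  coef <- Sinv %*% t(means)                     # p x k
  const <- -0.5 * colSums(t(means) * coef)      # per group
  model <- structure(list(selected = selected,
                          steps = do.call(rbind, steps),
                          wilks_lambda = lambda_cur, coef = coef,
                          const = const, group_means = means,
                          levels = levels(g)),
                     class = "da_model")
  model$classification <- classification_matrix(model, X, g)
  model
}

#' Predict group membership with a fitted discriminant model
#'
#' @param object A \code{da_model}.
#' @param newdata Samples x parameters matrix containing the selected
#'   variables.
#' @param ... Unused.
#' @return Character vector of assigned group labels.
#' @export
predict.da_model <- function(object, newdata, ...) {
  if (length(object$selected) == 0L) stop("empty model")
  Xs <- as.matrix(newdata)[, object$selected, drop = FALSE]
  scores <- Xs %*% object$coef
  scores <- sweep(scores, 2L, object$const, "+")
  object$levels[max.col(scores, ties.method = "first")]
}

#' Resubstitution classification matrix and percent correct
#'
#' @param model A \code{da_model}.
#' @param X Samples x parameters matrix.
#' @param groups True group labels.
#' @return List: \code{counts} (true groups x assigned groups),
#'   \code{percent_correct}.
#' @export
classification_matrix <- function(model, X, groups) {
  g <- factor(groups, levels = model$levels)
  if (nlevels(g) == 1L) warning("single group: accuracy is 100% by definition")
  pred <- predict(model, X)
  counts <- table(true = g, assigned = factor(pred, levels = model$levels))
  list(counts = counts,
       percent_correct = 100 * sum(diag(counts)) / sum(counts))
}
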