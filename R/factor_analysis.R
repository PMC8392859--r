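#' Principal component / factor analysis on the correlation matrix
#'
#' Standardizes columns (zero mean, unit variance) after listwise deletion
#' of incomplete rows, eigendecomposes the correlation matrix, forms
#' loadings as eigenvector_k * sqrt(lambda_k), and retains components by the
#' Kaiser rule (lambda > 1) or a fixed count. Percent variance is reported
#' from the unrotated eigenvalues, 100 * lambda_k / n_variables.
#'
#' @param X Samples x parameters numeric matrix (rows with any NA dropped).
#' @param retain "kaiser" or an integer count of factors.
#' @return A \code{factor_loadings} list: \code{loadings} (variables x
#'   retained factors), \code{eigenvalues} (all), \code{percent_variance},
#'   \code{cumulative_percent} (for retained factors), \code{communalities},
#'   \code{rotated} (FALSE), \code{n} (rows used).
#' @export
pca_fa <- function(X, retain = "kaiser") {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete rows")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  k <- if (identical(retain, "kaiser")) sum(lambda > 1) else as.integer(retain)
  if (k < 1L) stop("no factor retained")
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lambda[seq_len(k)]),
                                                      k)
  # deterministic sign: largest-|loading| entry of each factor positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("VF", seq_len(k)))
  pct <- 100 * lambda / ncol(X)
  structure(list(loadings = L, eigenvalues = lambda,
                 percent_variance = pct[seq_len(k)],
                 cumulative_percent = cumsum(pct[seq_len(k)]),
                 communalities = rowSums(L^2), rotated = FALSE, n = nrow(X)),
            class = "factor_loadings")
}

#' Percent of total variance explained by an eigenvalue
#'
#' For correlation-matrix PCA the total variance equals the number of
#' variables, so the share of component k is 100 * lambda_k / n_variables.
#'
#' @param lambda Eigenvalue(s) of the correlation matrix.
#' @param n_vars Number of variables.
#' @return Percent variance, same length as \code{lambda}.
#' @export
percent_variance <- function(lambda, n_vars) {
  if (n_vars < 1) stop("n_vars must be positive")
  100 * lambda / n_vars
}

#' Varimax rotation with Kaiser normalization
#'
#' Orthogonally rotates retained loadings to maximize the varimax simplicity
#' criterion; with Kaiser normalization rows are divided by the square root
#' of their communality before rotation and restored afterwards, so
#' communalities are preserved exactly. Single-factor solutions are returned
#' unchanged with a note. Each rotated factor is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param fl A \code{factor_loadings} object (or bare loading matrix).
#' @param kaiser_normalize Apply Kaiser row normalization (default TRUE).
#' @param tol,max_iter Convergence controls of the rotation sweeps.
#' @return The input with rotated \code{loadings}, \code{rotated = TRUE} and
#'   the rotation matrix in \code{rotmat}.
#' @export
varimax_rotate <- function(fl, kaiser_normalize = TRUE, tol = 1e-10,
                           max_iter = 1000L) {
  L <- if (inherits(fl, "factor_loadings")) fl$loadings else as.matrix(fl)
  if (ncol(L) < 2L) {
    message("single factor: rotation is a no-op")
    if (inherits(fl, "factor_loadings")) return(fl) else return(L)
  }
  v <- stats::varimax(L, normalize = kaiser_normalize, eps = tol)
  Lr <- L %*% v$rotmat
  for (j in seq_len(ncol(Lr))) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) Lr[, j] <- -Lr[, j]
  }
  dimnames(Lr) <- dimnames(L)
  if (inherits(fl, "factor_loadings")) {
    fl$loadings <- Lr
    fl$rotated <- TRUE
    fl$rotmat <- v$rotmat
    fl
  } else Lr
}

#' Varimax simplicity criterion
#'
#' Sum over factors of the variance of squared loadings (raw criterion, on
#' Kaiser-normalized rows when requested). Exposed for oracle checks of the
#' rotation.
#'
#' @param L Loading matrix.
#' @param kaiser_normalize Normalize rows to unit communality first.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(L, kaiser_normalize = TRUE) {
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    L <- L / h
  }
  n <- nrow(L)
  sum(apply(L^2, 2L, function(c2) sum((c2 - mean(c2))^2))) / n
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO = sum of squared off-diagonal correlations over that sum plus the sum
#' of squared off-diagonal partial correlations (anti-image correlations
#' derived from the inverse correlation matrix).
#'
#' @param R Symmetric positive-definite correlation matrix.
#' @return KMO value in (0, 1].
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  S <- tryCatch(solve(R), error = function(e) stop("singular correlation matrix"))
  Q <- -S / sqrt(outer(diag(S), diag(S)))
  off <- row(R) != col(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  if (r2 + q2 < 1e-12) warning("near-identity correlation matrix: KMO ill-conditioned")
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' chi2 = -(n - 1 - (2p + 5)/6) * ln det(R), df = p(p-1)/2, upper-tail
#' chi-square p value; tests whether the correlation matrix is an identity.
#'
#' @param R Correlation matrix (positive definite).
#' @param n Sample count used to form R (must exceed the variable count).
#' @return List: \code{chi2}, \code{df}, \code{p}.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n <= p) stop("need n > number of variables")
  d <- det(R)
  if (d <= 0) stop("correlation matrix is not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Classify loadings as strong / moderate / none
#'
#' Absolute loadings above 0.70 are strong; between 0.5 and 0.7 inclusive,
#' moderate; below 0.5, none.
#'
#' @param loadings Numeric matrix or vector of loadings.
#' @return Character labels, same shape.
#' @export
classify_loadings <- function(loadings) {
  a <- abs(loadings)
  lab <- ifelse(a > 0.70, "strong", ifelse(a >= 0.5, "moderate", "none"))
  if (is.matrix(loadings)) dim(lab) <- dim(loadings)
  if (!is.null(dimnames(loadings))) dimnames(lab) <- dimnames(loadings)
  lab
}

#' Loadings table in the conventional layout
#'
#' Variables x factors with eigenvalue, percent-variance and
#' cumulative-percent footer rows, as printed in water-quality factor
#' analyses.
#'
#' @param fl A \code{factor_loadings} object.
#' @return Data frame ready to write as CSV.
#' @export
loadings_table <- function(fl) {
  stopifnot(inherits(fl, "factor_loadings"))
  k <- ncol(fl$loadings)
  body <- data.frame(variable = rownames(fl$loadings),
                     round(fl$loadings, 2), check.names = FALSE)
  foot <- data.frame(variable = c("Eigenvalues", "% of Variance",
                                  "Cumulative %"),
                     rbind(round(fl$eigenvalues[seq_len(k)], 2),
                           round(fl$percent_variance, 2),
                           round(fl$cumulative_percent, 2)),
                     check.names = FALSE)
  names(foot) <- names(body)
  rbind(body, foot)
}
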