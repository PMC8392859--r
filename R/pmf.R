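#' Measurement uncertainty for the PMF receptor model
#'
#' Standard receptor-model convention: above the method detection limit,
#' u = sqrt((EF * x)^2 + (0.5 * MDL)^2); at or below the MDL,
#' u = 5/6 * MDL. EF is the dimensionless error fraction of the measurement.
#'
#' @param x Concentration (parameter units), non-negative.
#' @param mdl Method detection limit (same units), >= 0.
#' @param ef Error fraction, >= 0.
#' @return Uncertainty u, same units as x. Vectorized over \code{x}.
#' @export
build_uncertainty <- function(x, mdl, ef) {
  if (any(mdl < 0) || any(ef < 0)) stop("MDL and EF must be non-negative")
  u <- ifelse(x > mdl, sqrt((ef * x)^2 + (0.5 * mdl)^2), 5 / 6 * mdl)
  if (any(u <= 0 & x > 0)) {
    stop("zero uncertainty for a positive concentration is ill-posed")
  }
  u
}

#' Uncertainty matrix from per-parameter MDL/EF
#'
#' Applies [build_uncertainty()] column-wise. When \code{mdl} is NULL each
#' parameter's MDL defaults to 1\% of its median; when \code{ef} is a scalar
#' it applies to every parameter.
#'
#' @param X Samples x parameters non-negative matrix.
#' @param mdl Named vector of MDLs, or NULL for the 1\%-of-median default.
#' @param ef Named vector or scalar error fraction (default 0.1).
#' @return Matrix of uncertainties, same shape as X, with attributes
#'   \code{mdl} and \code{ef} recording the values used.
#' @export
uncertainty_matrix <- function(X, mdl = NULL, ef = 0.1) {
  p <- colnames(X)
  if (is.null(mdl)) {
    mdl <- apply(X, 2L, function(col) 0.01 * stats::median(col, na.rm = TRUE))
  }
  if (length(ef) == 1L && is.null(names(ef))) ef <- stats::setNames(rep(ef, ncol(X)), p)
  U <- X
  for (j in seq_len(ncol(X))) {
    U[, j] <- build_uncertainty(X[, j], mdl[[p[j]]], ef[[p[j]]])
  }
  attr(U, "mdl") <- mdl
  attr(U, "ef") <- ef
  U
}

## ---- internal: exact per-row non-negative least squares ----
## Solves, for every row i, min_{x >= 0} 0.5 x' A_i x - b_i' x  (the normal
## form of a weighted NNLS subproblem) by enumerating active sets with a KKT
## check -- exact for convex A_i, vectorized over rows for subproblem
## dimension <= 3 (Cramer solves), per-row solve() beyond that.
nnls_rows <- function(A, b) {
  n <- nrow(b); p <- ncol(b)
  x <- matrix(0, n, p)
  solved <- rep(FALSE, n)
  scale <- pmax(apply(abs(b), 1L, max), 1e-300)
  tol <- 1e-12

  subsets <- unlist(lapply(p:0, function(s) {
    if (s == 0L) list(integer(0)) else
      apply(utils::combn(p, s), 2L, identity, simplify = FALSE)
  }), recursive = FALSE)

  for (S in subsets) {
    todo <- which(!solved)
    if (!length(todo)) break
    s <- length(S)
    if (s == 0L) {
      ok <- apply(b[todo, , drop = FALSE] <= tol * scale[todo], 1L, all)
      solved[todo[ok]] <- TRUE
      next
    }
    xs <- if (s == 1L) {
      matrix(b[todo, S] / A[todo, S, S], ncol = 1L)
    } else if (s == 2L) {
      a11 <- A[todo, S[1], S[1]]; a22 <- A[todo, S[2], S[2]]
      a12 <- A[todo, S[1], S[2]]
      b1 <- b[todo, S[1]]; b2 <- b[todo, S[2]]
      dt <- a11 * a22 - a12^2
      cbind((b1 * a22 - b2 * a12) / dt, (a11 * b2 - a12 * b1) / dt)
    } else if (s == 3L) {
      a11 <- A[todo, S[1], S[1]]; a12 <- A[todo, S[1], S[2]]
      a13 <- A[todo, S[1], S[3]]; a22 <- A[todo, S[2], S[2]]
      a23 <- A[todo, S[2], S[3]]; a33 <- A[todo, S[3], S[3]]
      b1 <- b[todo, S[1]]; b2 <- b[todo, S[2]]; b3 <- b[todo, S[3]]
      dt <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
        a13 * (a12 * a23 - a22 * a13)
      x1 <- (b1 * (a22 * a33 - a23^2) - a12 * (b2 * a33 - a23 * b3) +
               a13 * (b2 * a23 - a22 * b3)) / dt
      x2 <- (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a23 * a13) +
               a13 * (a12 * b3 - b2 * a13)) / dt
      x3 <- (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13) +
               b1 * (a12 * a23 - a22 * a13)) / dt
      cbind(x1, x2, x3)
    } else {
      t(vapply(todo, function(i) {
        tryCatch(solve(A[i, S, S], b[i, S]),
                 error = function(e) rep(NA_real_, s))
      }, numeric(s)))
    }
    feas <- rowSums(!is.finite(xs)) == 0L &
      apply(xs, 1L, min) >= -tol * scale[todo]
    if (s < p) {
      out <- setdiff(seq_len(p), S)
      grad_ok <- rep(TRUE, length(todo))
      for (j in out) {
        g <- -b[todo, j]
        for (k in seq_len(s)) g <- g + A[todo, j, S[k]] * xs[, k]
        grad_ok <- grad_ok & !is.na(g) & g >= -tol * scale[todo]
      }
      feas <- feas & grad_ok
    }
    hit <- todo[feas]
    if (length(hit)) {
      x[hit, S] <- pmax(xs[feas, , drop = FALSE], 0)
      solved[hit] <- TRUE
    }
  }
  left <- which(!solved)
  for (i in left) {   # numerically degenerate rows: ridge fallback
    x[i, ] <- pmax(solve(A[i, , ] + diag(1e-8 * max(diag(A[i, , ])), p),
                         b[i, ]), 0)
  }
  x
}

## non-negative double SVD initialization (Boutsidis & Gallopoulos): a
## deterministic, data-adapted starting point that avoids the rank-collapsed
## local minima random initializations can fall into on badly column-scaled
## concentration matrices
nndsvd_init <- function(X, p) {
  sv <- svd(X, nu = p, nv = p)
  G <- matrix(0, nrow(X), p)
  F <- matrix(0, p, ncol(X))
  u1 <- abs(sv$u[, 1]); v1 <- abs(sv$v[, 1])
  G[, 1] <- sqrt(sv$d[1]) * u1
  F[1, ] <- sqrt(sv$d[1]) * v1
  for (k in seq_len(p)[-1]) {
    u <- sv$u[, k]; v <- sv$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      sig <- nup * nvp
      G[, k] <- sqrt(sv$d[k] * sig) * up / nup
      F[k, ] <- sqrt(sv$d[k] * sig) * vp / nvp
    } else if (nun * nvn > 0) {
      sig <- nun * nvn
      G[, k] <- sqrt(sv$d[k] * sig) * un / nun
      F[k, ] <- sqrt(sv$d[k] * sig) * vn / nvn
    }
  }
  floor_g <- 1e-6 * max(G); floor_f <- 1e-6 * max(F)
  G[G < floor_g] <- floor_g
  F[F < floor_f] <- floor_f
  list(G = G, F = F)
}

## build the n x p x p array of normal matrices A_i = M' diag(w_i) M for
## row-wise subproblems, from the n x m weight matrix and m x p design M
normal_arrays <- function(W, M) {
  p <- ncol(M)
  A <- array(0, c(nrow(W), p, p))
  for (k in seq_len(p)) {
    for (l in k:p) {
      v <- W %*% (M[, k] * M[, l])
      A[, k, l] <- v
      A[, l, k] <- v
    }
  }
  A
}

#' Fit a positive matrix factorization receptor model
#'
#' Decomposes a non-negative samples x parameters concentration matrix X
#' into non-negative factor contributions G (samples x p) and factor
#' profiles F (p x parameters), X = G F + E, by minimizing the
#' uncertainty-weighted objective Q = sum(((X - G F) / U)^2). The solver
#' alternates exact uncertainty-weighted non-negative least squares updates
#' of G (per sample) and F (per parameter) — each half-step is an exact
#' block minimization, so Q is non-increasing across iterations. The first
#' of the \code{n_starts} initializations is a deterministic non-negative
#' double-SVD start; the rest are seeded random draws. The lowest-Q
#' solution is kept.
#'
#' Output is normalized so every factor's mean contribution over samples is
#' 1, pushing units into F (profiles read directly as mean concentration
#' contributions); factors are ordered by total explained concentration,
#' descending.
#'
#' @param X Non-negative numeric matrix (no NAs; pre-screen bounded
#'   variables such as pH — they do not fit source semantics).
#' @param U Positive uncertainty matrix, same shape (default: all ones,
#'   i.e. unweighted least squares).
#' @param p Number of factors, 1 <= p < min(dim(X)).
#' @param n_starts Number of random initializations.
#' @param seed Integer seed controlling all initializations.
#' @param tol Relative Q-change convergence tolerance per run.
#' @param max_iter Maximum iterations per run.
#' @return A \code{pmf_fit} list: \code{G}, \code{F}, \code{residuals},
#'   \code{Q}, \code{p}, \code{converged}, \code{best_start},
#'   \code{q_trace} (per-iteration Q of the best run), \code{iterations}.
#' @export
fit_pmf <- function(X, U = NULL, p = 3L, n_starts = 10L, seed = 1L,
                    tol = 1e-8, max_iter = 2000L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  if (any(X < 0)) stop("X must be non-negative (pre-screen pH-like variables)")
  if (p < 1L || p >= min(dim(X))) stop("need 1 <= p < min(samples, parameters)")
  if (is.null(U)) U <- matrix(1, nrow(X), ncol(X))
  U <- as.matrix(U)
  if (any(U <= 0)) stop("all uncertainties must be positive")
  W <- 1 / U^2
  WX <- W * X
  eps <- 1e-12

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      init <- nndsvd_init(X, p)
      G <- init$G; F <- init$F
    } else {
      set.seed(run_seeds[s])
      scale0 <- sqrt(mean(X) / p)
      G <- matrix(stats::runif(nrow(X) * p, 0.1, 1) * scale0, nrow(X), p)
      F <- matrix(stats::runif(p * ncol(X), 0.1, 1) * scale0, p, ncol(X))
    }
    q_trace <- numeric(0)
    q_prev <- Inf
    q_floor <- 1e-14 * sum(WX * X)   # residuals at roundoff level
    converged <- FALSE
    beta <- 1                        # extrapolation step, grown on success
    for (it in seq_len(max_iter)) {
      G_old <- G; F_old <- F
      G <- nnls_rows(normal_arrays(W, t(F)), WX %*% t(F))
      F <- t(nnls_rows(normal_arrays(t(W), G), t(crossprod(G, WX))))
      q <- sum(W * (X - G %*% F)^2)
      # monotone-safe extrapolation along the last step (accelerates the
      # slow alternating-least-squares tail; accepted only when Q drops)
      Ge <- pmax(G + beta * (G - G_old), 0)
      Fe <- pmax(F + beta * (F - F_old), 0)
      qe <- sum(W * (X - Ge %*% Fe)^2)
      if (qe < q) {
        G <- Ge; F <- Fe; q <- qe
        beta <- min(beta * 1.5, 50)
      } else {
        beta <- max(beta / 2, 1)
      }
      q_trace <- c(q_trace, q)
      if (q <= q_floor ||
          (is.finite(q_prev) && abs(q_prev - q) <= tol * max(q_prev, eps))) {
        converged <- TRUE
        break
      }
      q_prev <- q
    }
    if (is.null(best) || q < best$Q) {
      best <- list(G = G, F = F, Q = q, q_trace = q_trace,
                   converged = converged, best_start = s,
                   iterations = length(q_trace))
    }
  }
  if (!best$converged) {
    warning("PMF did not reach the Q tolerance within max_iter; ",
            "returning best solution found")
  }

  # normalization: mean contribution of each factor = 1, units pushed into F
  G <- best$G; F <- best$F
  scale <- colMeans(G)
  scale[scale <= 0] <- 1   # a dead factor keeps its (zero) scale
  G <- sweep(G, 2L, scale, "/")
  F <- sweep(F, 1L, scale, "*")
  ord <- order(rowSums(F), decreasing = TRUE)
  G <- G[, ord, drop = FALSE]
  F <- F[ord, , drop = FALSE]
  rownames(F) <- colnames(G) <- paste0("Factor", seq_len(p))
  colnames(F) <- colnames(X)

  structure(list(G = G, F = F, residuals = X - G %*% F, Q = best$Q,
                 p = p, converged = best$converged,
                 best_start = best$best_start, q_trace = best$q_trace,
                 iterations = best$iterations, U = U),
            class = "pmf_fit")
}

#' Percentage contributions from a concentration-contribution matrix
#'
#' Row-normalizes mean concentration contributions (parameters x factors)
#' to percentages summing to 100 per parameter.
#'
#' @param conc Parameters x factors non-negative matrix.
#' @return Matrix of percentages, same shape; rows with zero total are NA.
#' @export
contribution_percentages <- function(conc) {
  conc <- as.matrix(conc)
  tot <- rowSums(conc)
  pct <- sweep(conc, 1L, tot, "/") * 100
  pct[tot == 0, ] <- NA_real_
  pct
}

#' Source apportionment table from a fitted PMF model
#'
#' For each parameter j and factor k: the mean over samples of
#' g_ik * f_kj (concentration contribution, parameter units), the
#' percentage share of that mean, and the squared Pearson correlation
#' between the observed and reconstructed series of parameter j.
#'
#' @param model A \code{pmf_fit}.
#' @param X The matrix the model was fitted to.
#' @return Data frame: parameter, one concentration column and one
#'   percentage column per factor, and \code{r2}.
#' @export
apportion <- function(model, X) {
  stopifnot(inherits(model, "pmf_fit"))
  X <- as.matrix(X)
  p <- model$p
  conc <- sapply(seq_len(p), function(k) {
    colMeans(outer(model$G[, k], model$F[k, ]))
  })
  rownames(conc) <- colnames(X)
  pct <- contribution_percentages(conc)
  recon <- model$G %*% model$F
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    r2_per_variable(X[, j], recon[, j])
  }, numeric(1))
  out <- data.frame(parameter = colnames(X), conc, pct, r2 = r2,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("parameter",
                  paste0("conc_f", seq_len(p)),
                  paste0("pct_f", seq_len(p)), "r2")
  rownames(out) <- NULL
  out
}

#' Squared Pearson correlation of observed vs reconstructed series
#'
#' @param observed Observed values (>= 3, non-constant).
#' @param reconstructed Reconstructed values, same length.
#' @return R-squared in [0, 1]; NA with a warning when either series is
#'   constant.
#' @export
r2_per_variable <- function(observed, reconstructed) {
  ok <- !is.na(observed) & !is.na(reconstructed)
  if (sum(ok) < 3L) stop("need at least 3 paired values")
  if (stats::sd(observed[ok]) == 0 || stats::sd(reconstructed[ok]) == 0) {
    warning("constant series: R^2 undefined")
    return(NA_real_)
  }
  stats::cor(observed[ok], reconstructed[ok])^2
}

#' Best-permutation cosine similarity between fitted and true profiles
#'
#' Matches fitted factors to reference factors by searching all factor
#' permutations for the one maximizing the mean row-wise cosine similarity.
#' By default both profile matrices are first column-normalized to
#' per-parameter shares (each parameter's contributions divided by that
#' parameter's total across factors, the same normalization as percentage
#' contribution tables) so that every parameter weighs equally regardless
#' of its measurement units; otherwise the raw-unit cosine is dominated by
#' large-unit parameters such as coliform counts. Used to score
#' source-recovery experiments.
#'
#' @param F_fit Fitted profile matrix (p x parameters).
#' @param F_true Reference profile matrix, same shape (columns matched by
#'   name when both are named).
#' @param normalize "share" (default) or "none".
#' @return List: \code{perm} (ordering of fitted factors), \code{cosine}
#'   (per matched factor), \code{mean_cosine}.
#' @export
match_profiles <- function(F_fit, F_true, normalize = c("share", "none")) {
  normalize <- match.arg(normalize)
  if (!is.null(colnames(F_fit)) && !is.null(colnames(F_true))) {
    common <- intersect(colnames(F_true), colnames(F_fit))
    F_fit <- F_fit[, common, drop = FALSE]
    F_true <- F_true[, common, drop = FALSE]
  }
  p <- nrow(F_true)
  stopifnot(nrow(F_fit) == p)
  if (normalize == "share") {
    col_share <- function(M) {
      tot <- colSums(M)
      tot[tot == 0] <- 1
      sweep(M, 2L, tot, "/")
    }
    F_fit <- col_share(F_fit)
    F_true <- col_share(F_true)
  }
  cos_row <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- perms_of(p)
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    pr <- perms[i, ]
    cs <- vapply(seq_len(p), function(k) cos_row(F_fit[pr[k], ], F_true[k, ]),
                 numeric(1))
    if (is.null(best) || mean(cs) > best$mean_cosine) {
      best <- list(perm = pr, cosine = cs, mean_cosine = mean(cs))
    }
  }
  best
}

perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
  dimnames(out) <- NULL
  out
}
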