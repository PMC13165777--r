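## Multi-stage blind source separation: sliding-window PCA over spatially
## ordered traces, correlation-based retention, global PCA capped at ten
## modes, SOBI joint diagonalization, and per-component cleanup. Every stage
## stores the operators needed to back-project selected components.

#' Plan sliding windows over the trace index
#'
#' Window width follows the adaptive rule
#' `width = min(max(floor(M / 3), 5), M)`; starts advance by a stride of 3
#' traces and the final window is shifted left so it ends at trace `M`
#' (duplicate starts after clamping are dropped).
#'
#' @param M number of traces.
#' @param stride stride in traces (default 3).
#' @return list with `starts` (1-based), `width`, `M`.
#' @export
plan_windows <- function(M, stride = 3L) {
  stopifnot(M >= 1L)
  width <- min(max(floor(M / 3), 5L), M)
  last <- M - width + 1L
  starts <- unique(c(seq(1L, last, by = stride), last))
  list(starts = as.integer(starts), width = as.integer(width), M = as.integer(M))
}

## eigen-PCA of row signals: rows of Z are variables, columns time
.row_pca <- function(Z, k) {
  C <- Z %*% t(Z) / ncol(Z)
  e <- eigen(C, symmetric = TRUE)
  k <- min(k, nrow(Z))
  V <- e$vectors[, seq_len(k), drop = FALSE]
  list(loadings = V,
       components = t(V) %*% Z,
       evar = pmax(e$values, 0)[seq_len(k)] / max(sum(pmax(e$values, 0)), 1e-300))
}

#' Sliding-window PCA of episode traces
#'
#' Traces are z-scored over time, then each planned window of spatially
#' adjacent traces is reduced to its top `n_pcs` principal-component time
#' courses. Zero-variance traces are excluded from their windows with a
#' notice. Component loadings per window are stored for back-projection.
#'
#' @param traces `M x T` numeric matrix (spatially ordered; see
#'   [order_triangles]), or an `episode`.
#' @param plan window plan from [plan_windows] (default: computed from `M`).
#' @param n_pcs principal components per window (default 2).
#' @return A `window_pca` component set: `components` (`K x T`), `meta`
#'   (window and PC of each component), `windows` (trace indices and
#'   loadings), `trace_center`/`trace_scale`, `evar`, `M`, `stage`.
#' @export
window_pca <- function(traces, plan = NULL, n_pcs = 2L) {
  if (inherits(traces, "episode")) traces <- traces$signals
  X <- as.matrix(traces)
  M <- nrow(X)
  if (is.null(plan)) plan <- plan_windows(M)
  ctr <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  zero_var <- sdv == 0
  if (any(zero_var))
    message(sprintf("%d zero-variance trace(s) excluded from window PCA",
                    sum(zero_var)))
  scl <- ifelse(zero_var, 1, sdv)
  Z <- (X - ctr) / scl

  comps <- list(); meta <- list(); windows <- list(); evar <- list()
  for (w in seq_along(plan$starts)) {
    idx <- plan$starts[w]:(plan$starts[w] + plan$width - 1L)
    idx <- idx[!zero_var[idx]]
    if (length(idx) < 2L) next
    p <- .row_pca(Z[idx, , drop = FALSE], n_pcs)
    windows[[length(windows) + 1L]] <- list(trace_idx = idx,
                                            loadings = p$loadings)
    wid <- length(windows)
    for (j in seq_len(ncol(p$loadings))) {
      comps[[length(comps) + 1L]] <- p$components[j, ]
      meta[[length(meta) + 1L]] <- c(window = wid, pc = j)
      evar[[length(evar) + 1L]] <- p$evar[j]
    }
  }
  if (length(comps) == 0L)
    stop("window PCA produced no components (all windows degenerate)",
         call. = FALSE)
  structure(list(components = do.call(rbind, comps),
                 meta = do.call(rbind, meta),
                 windows = windows,
                 trace_center = ctr, trace_scale = scl,
                 evar = unlist(evar), M = M,
                 stage = "window_pca"),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set [%s]: %d components x %d samples\n",
              x$stage, nrow(x$components), ncol(x$components)))
  invisible(x)
}

#' Correlation-based retention of coherent components
#'
#' The representative component maximises the mean absolute Pearson
#' correlation with all others; components whose absolute correlation with
#' the representative strictly exceeds `threshold` are retained (the
#' representative always is). A single component is returned unchanged.
#'
#' @param cs a `window_pca` component set (or plain matrix of components).
#' @param threshold correlation threshold (default 0.5).
#' @return The component set with non-coherent components dropped; kept
#'   indices in attribute `selection`.
#' @export
correlation_select <- function(cs, threshold = 0.5) {
  X <- if (inherits(cs, "component_set")) cs$components else as.matrix(cs)
  K <- nrow(X)
  if (K < 2L) return(cs)
  C <- abs(suppressWarnings(stats::cor(t(X))))
  C[!is.finite(C)] <- 0
  mean_abs <- (rowSums(C) - 1) / (K - 1)
  rep_i <- which.max(mean_abs)
  keep <- which(C[rep_i, ] > threshold | seq_len(K) == rep_i)
  if (inherits(cs, "component_set")) {
    cs$components <- X[keep, , drop = FALSE]
    cs$meta <- cs$meta[keep, , drop = FALSE]
    cs$evar <- cs$evar[keep]
    attr(cs, "selection") <- list(kept = keep, representative = rep_i,
                                  mean_abs_cor = mean_abs)
    cs
  } else {
    structure(X[keep, , drop = FALSE],
              selection = list(kept = keep, representative = rep_i))
  }
}

#' Global PCA of retained components
#'
#' Reduces the retained window components to at most `max_k` orthogonal
#' modes (components z-scored over time first); the projection operator is
#' stored so that SOBI sources can be back-projected.
#'
#' @param cs a `component_set` (or `K x T` matrix).
#' @param max_k component cap (default 10).
#' @return A `global_pca` component set with `components`, `loadings`,
#'   `in_center`, `in_scale`, `evar`, and `parent` (the input set).
#' @export
global_pca <- function(cs, max_k = 10L) {
  X <- if (inherits(cs, "component_set")) cs$components else as.matrix(cs)
  stopifnot(nrow(X) >= 1L)
  ctr <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  scl <- ifelse(sdv == 0, 1, sdv)
  Z <- (X - ctr) / scl
  p <- .row_pca(Z, min(nrow(X), max_k))
  structure(list(components = p$components,
                 loadings = p$loadings,
                 in_center = ctr, in_scale = scl,
                 evar = p$evar,
                 parent = if (inherits(cs, "component_set")) cs else NULL,
                 stage = "global_pca"),
            class = "component_set")
}

## Jacobi joint approximate diagonalization of symmetric matrices
joint_diagonalize <- function(Ms, tol = 1e-8, max_sweeps = 100L) {
  m <- nrow(Ms[[1L]])
  V <- diag(m)
  off <- function(Ms) sum(vapply(Ms, function(M) sum(M^2) - sum(diag(M)^2),
                                 numeric(1)))
  off_trace <- off(Ms)
  sweeps <- 0L
  converged <- m < 2L
  while (!converged && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    rotated <- FALSE
    for (p in 1:(m - 1L)) for (q in (p + 1L):m) {
      g1 <- vapply(Ms, function(M) M[p, p] - M[q, q], numeric(1))
      g2 <- vapply(Ms, function(M) M[p, q] + M[q, p], numeric(1))
      a <- sum(g1 * g1); b <- sum(g1 * g2); d <- sum(g2 * g2)
      lam <- (a + d) / 2 + sqrt(((a - d) / 2)^2 + b^2)
      v <- c(lam - d, b)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-300) next
      v <- v / nv
      if (v[1L] < 0) v <- -v
      cth <- sqrt((1 + v[1L]) / 2)
      sth <- v[2L] / (2 * cth)
      if (abs(sth) < tol) next
      rotated <- TRUE
      for (k in seq_along(Ms)) {
        M <- Ms[[k]]
        rp <- cth * M[p, ] + sth * M[q, ]
        rq <- -sth * M[p, ] + cth * M[q, ]
        M[p, ] <- rp; M[q, ] <- rq
        cp <- cth * M[, p] + sth * M[, q]
        cq <- -sth * M[, p] + cth * M[, q]
        M[, p] <- cp; M[, q] <- cq
        Ms[[k]] <- M
      }
      vp <- cth * V[, p] + sth * V[, q]
      vq <- -sth * V[, p] + cth * V[, q]
      V[, p] <- vp; V[, q] <- vq
    }
    off_trace <- c(off_trace, off(Ms))
    if (!rotated) converged <- TRUE
  }
  list(V = V, converged = converged, sweeps = sweeps, off = off_trace)
}

#' Second-order blind identification (SOBI)
#'
#' Whitens the (row-centred) input and jointly diagonalizes its symmetrized
#' time-lagged covariance matrices with Jacobi rotation sweeps, separating
#' temporally structured sources such as the cardiac pulse. Sources have
#' unit variance; the stored unmixing and mixing operators satisfy
#' `unmixing %*% mixing = I`.
#'
#' @param X `k x T` matrix (typically the global-PCA components).
#' @param lags covariance lags in samples (default `1:20`, i.e. up to 1 s
#'   at 20 FPS).
#' @param tol Jacobi rotation tolerance.
#' @param max_sweeps maximum Jacobi sweeps; on non-convergence the best
#'   iterate is returned with a warning flag.
#' @return A `sobi` component set: `sources` (`m x T`, also exposed as
#'   `components`), `mixing` (`k x m`), `unmixing` (`m x k`), `row_means`,
#'   `converged`, `sweeps`, `off_criterion`.
#' @export
sobi <- function(X, lags = 1:20, tol = 1e-8, max_sweeps = 100L) {
  if (inherits(X, "component_set")) {
    parent <- X
    X <- X$components
  } else parent <- NULL
  X <- as.matrix(X)
  k <- nrow(X); T_ <- ncol(X)
  stopifnot(k >= 2L, T_ > max(lags))
  mu <- rowMeans(X)
  Xc <- X - mu
  C0 <- Xc %*% t(Xc) / T_
  e <- eigen(C0, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  E <- e$vectors[, keep, drop = FALSE]
  dvals <- e$values[keep]
  W0 <- diag(1 / sqrt(dvals), nrow = length(dvals)) %*% t(E)
  Z <- W0 %*% Xc
  Ms <- lapply(lags, function(tau) {
    A <- Z[, 1:(T_ - tau), drop = FALSE]
    B <- Z[, (1 + tau):T_, drop = FALSE]
    M <- A %*% t(B) / (T_ - tau)
    (M + t(M)) / 2
  })
  jd <- joint_diagonalize(Ms, tol = tol, max_sweeps = max_sweeps)
  if (!jd$converged)
    warning(sprintf("SOBI did not converge in %d sweeps; returning best iterate",
                    max_sweeps))
  S <- t(jd$V) %*% Z
  unmixing <- t(jd$V) %*% W0
  mixing <- E %*% diag(sqrt(dvals), nrow = length(dvals)) %*% jd$V
  structure(list(components = S, sources = S,
                 mixing = mixing, unmixing = unmixing,
                 row_means = mu, parent = parent,
                 converged = jd$converged, sweeps = jd$sweeps,
                 off_criterion = jd$off, stage = "sobi"),
            class = "component_set")
}

#' Clean SOBI components
#'
#' Applies, per component, harmonic suppression, time-point outlier zeroing
#' (`tau = 4`) and a 0.8-3 Hz bandpass.
#'
#' @param sources `m x T` matrix or a `sobi` component set.
#' @param fs sampling rate (Hz).
#' @param tau outlier threshold (default 4).
#' @param band passband (Hz).
#' @param sigma,alpha harmonic-notch parameters.
#' @return Cleaned object of the same type.
#' @export
cleanup_components <- function(sources, fs, tau = 4, band = c(0.8, 3.0),
                               sigma = 0.1, alpha = 0.7) {
  is_set <- inherits(sources, "component_set")
  S <- if (is_set) sources$components else as.matrix(sources)
  for (i in seq_len(nrow(S))) {
    x <- harmonic_suppress(S[i, ], fs, sigma = sigma, alpha = alpha,
                           band = band)
    S[i, ] <- as.numeric(zero_timepoint_outliers(x, fs, tau = tau,
                                                 band = band))
  }
  if (is_set) {
    sources$components <- S
    sources$sources <- S
    sources
  } else S
}
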