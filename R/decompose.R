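#' Truncated principal component analysis of a CSD matrix
#'
#' Singular value decomposition of the depths x time CSD matrix, truncated
#' to the `K` largest singular values: the best rank-K approximation in
#' Frobenius norm. Columns of the eigenimage matrix are orthonormal spatial
#' profiles; rows of the eigensequence matrix are orthonormal time courses.
#' Signs are fixed so each eigenimage's largest-magnitude entry is positive.
#'
#' @param csd a [csd_estimate()] (or plain matrix).
#' @param K number of components to retain, `1 <= K <= min(dim)`.
#' @return An object of class `pca_result` with `eigenimages` (depths x K),
#'   `singular_values` (length K), `eigensequences` (K x time), plus all
#'   singular values (`all_singular_values`) for energy accounting.
#' @export
pca_truncate <- function(csd, K) {
  x <- if (inherits(csd, "csd_estimate")) csd$values else as.matrix(csd)
  if (!is.numeric(K) || K < 1 || K > min(dim(x))) {
    stop("invalid parameter: `K` must be in 1..min(dim)")
  }
  K <- as.integer(K)
  sv <- svd(x)
  u <- sv$u[, seq_len(K), drop = FALSE]
  v <- t(sv$v[, seq_len(K), drop = FALSE])      # K x Nt, rows eigensequences
  for (k in seq_len(K)) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) {
      u[, k] <- -u[, k]
      v[k, ] <- -v[k, ]
    }
  }
  structure(
    list(eigenimages = u, singular_values = sv$d[seq_len(K)],
         eigensequences = v, K = K, all_singular_values = sv$d,
         grid = if (inherits(csd, "csd_estimate")) csd$grid else NULL,
         dt = if (inherits(csd, "csd_estimate")) csd$dt else NA_real_),
    class = "pca_result")
}

#' Reconstruct the rank-K approximation from a PCA result
#' @param pca a [pca_result][pca_truncate()].
#' @return The depths x time matrix `U_K diag(d_K) V_K`.
#' @export
pca_reconstruct <- function(pca) {
  pca$eigenimages %*% (pca$singular_values * pca$eigensequences)
}

## ---- infomax score functions -------------------------------------------

# super-Gaussian (logistic) source model: log-density and score
logp_super <- function(u) -abs(u) - 2 * log1p(exp(-abs(u)))
phi_super <- function(u) -tanh(u / 2)
# sub-Gaussian (quartic) source model: cubic-dominant score
logp_sub <- function(u) -u^4 / 4
phi_sub <- function(u) -u^3

# Joint infomax objective and gradient over the unmixing matrix W.
#
# The truncated data factor as X_K = Ut %*% Vt (conditioned so both factors
# have unit RMS; the scalar `scale2` restores amplitudes). For any
# invertible W the pair S = W t(Ut), T = solve(t(W)) %*% Vt satisfies
# t(S) %*% T == Ut %*% Vt exactly, so every W is an exact linear
# re-representation of the PCA subspace. The objective is the weighted sum
# of the spatial and temporal infomax log-likelihoods,
#   alpha  * [ mean log p_s(S) + log|det W| ]
# + (1-alpha) * [ mean log p_t(T) - log|det W| ],
# with a heavy-tailed (logistic) source model over space and a light-tailed
# (quartic) model over time.
stica_value_grad <- function(par, ut_t, vt, alpha) {
  k <- as.integer(sqrt(length(par)))
  w <- matrix(par, k, k)
  dt_w <- determinant(w, logarithm = TRUE)
  if (dt_w$modulus < -200 || !is.finite(dt_w$modulus)) {
    return(list(value = -1e10, grad = -par))
  }
  w_inv <- solve(w)
  w_inv_t <- t(w_inv)
  n_s <- ncol(ut_t); n_t <- ncol(vt)
  s <- w %*% ut_t
  tt <- w_inv_t %*% vt
  val <- 0
  grad <- matrix(0, k, k)
  if (alpha > 0) {
    val <- val + alpha * (mean(colSums(logp_super(s))) +
                            as.numeric(dt_w$modulus))
    gs <- (phi_super(s) %*% t(ut_t)) / n_s
    grad <- grad + alpha * (gs + w_inv_t)
  }
  if (alpha < 1) {
    val <- val + (1 - alpha) * (mean(colSums(logp_sub(tt))) -
                                  as.numeric(dt_w$modulus))
    gm <- (phi_sub(tt) %*% t(vt)) / n_t + w       # gradient w.r.t. M = W^-T
    grad <- grad + (1 - alpha) * (-(w_inv_t %*% t(gm) %*% w_inv_t))
  }
  list(value = val, grad = as.vector(grad))
}

# symmetric fixed-point ICA on whitened rows (independent cross-check
# backend): classic one-unit update with symmetric decorrelation
ica_fixedpoint <- function(z, fun = c("tanh", "pow3"), seed = 1,
                           maxit = 1000, tol = 1e-9) {
  fun <- match.arg(fun)
  k <- nrow(z); n <- ncol(z)
  g <- switch(fun, tanh = function(u) tanh(u), pow3 = function(u) u^3)
  gp <- switch(fun, tanh = function(u) 1 - tanh(u)^2,
               pow3 = function(u) 3 * u^2)
  sym_decor <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-15)), k) %*%
      t(e$vectors) %*% w
  }
  w <- with_local_seed(seed, random_orthogonal(k))
  for (it in seq_len(maxit)) {
    u <- w %*% z
    w_new <- (g(u) %*% t(z)) / n - diag(rowMeans(gp(u)), k) %*% w
    w_new <- sym_decor(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) break
  }
  w
}

#' Independent component analysis of a PCA-truncated CSD
#'
#' Decomposes the retained PCA subspace into `K` spatial profile / time
#' course product components by maximum-entropy (infomax) unmixing.
#' `spatial_ica()` assumes statistically independent, heavy-tailed spatial
#' maps; `temporal_ica()` independent, light-tailed time courses;
#' `spatiotemporal_ica()` maximizes an `alpha`-weighted combination of the
#' spatial and temporal entropies, with `alpha = 1` and `alpha = 0`
#' degenerating to the pure spatial and temporal objectives. The exact
#' infomax log-likelihood is maximized over the unconstrained unmixing
#' matrix by BFGS with analytic gradients, restarted from `restarts` random
#' orthogonal initializations (seeds derived from `seed`); the best
#' objective wins, so results are reproducible given (input, K, alpha,
#' seed). Components are ordered by the variance of their rank-1
#' spatiotemporal maps and sign-normalized so each spatial profile's
#' largest-magnitude entry is positive. The component maps always sum to
#' the PCA-truncated data exactly, whatever the unmixing.
#'
#' @param pca a [pca_result][pca_truncate()].
#' @param K number of components; must equal the PCA truncation order.
#' @param seed integer seed for the restart schedule.
#' @param alpha spatial-entropy weight in [0, 1] (spatiotemporal only).
#' @param restarts number of random restarts.
#' @param maxit BFGS iteration cap per restart.
#' @param backend "infomax" (default) or "fixedpoint", a symmetric
#'   fixed-point iteration on the whitened factors kept as an independent
#'   cross-check (spatial and temporal modes only).
#' @return An object of class `ica_result`: `spatial` (K x depths,
#'   unit-norm rows), `temporal` (K x time, carrying the amplitudes),
#'   `unmixing`, `mode`, `alpha`, `objective`, `seed`.
#' @export
spatial_ica <- function(pca, K = pca$K, seed = 1, restarts = 5,
                        maxit = 2000, backend = c("infomax", "fixedpoint")) {
  stica_fit(pca, K, alpha = 1, seed = seed, restarts = restarts,
            maxit = maxit, backend = match.arg(backend), mode = "spatial")
}

#' @rdname spatial_ica
#' @export
temporal_ica <- function(pca, K = pca$K, seed = 1, restarts = 5,
                         maxit = 2000, backend = c("infomax", "fixedpoint")) {
  stica_fit(pca, K, alpha = 0, seed = seed, restarts = restarts,
            maxit = maxit, backend = match.arg(backend), mode = "temporal")
}

#' @rdname spatial_ica
#' @export
spatiotemporal_ica <- function(pca, K = pca$K, alpha = 0.5, seed = 1,
                               restarts = 5, maxit = 2000) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must be in [0, 1]")
  }
  stica_fit(pca, K, alpha = alpha, seed = seed, restarts = restarts,
            maxit = maxit, backend = "infomax", mode = "spatiotemporal")
}

stica_fit <- function(pca, K, alpha, seed, restarts, maxit, backend,
                      mode) {
  stopifnot(inherits(pca, "pca_result"))
  if (K != pca$K) {
    stop("`K` must equal the PCA truncation order; re-run pca_truncate()")
  }
  d <- pca$singular_values
  if (any(d < 1e-10 * d[1])) {
    stop("PCA subspace is numerically degenerate (singular value ratio < ",
         "1e-10); reduce K")
  }
  u <- pca$eigenimages                       # Nest x K
  v <- pca$eigensequences                    # K x Nt
  # split the singular values symmetrically and condition both factors to
  # unit RMS; `scale2` restores the amplitude on output
  ut <- u %*% diag(sqrt(d), K)
  vt <- diag(sqrt(d), K) %*% v
  r_u <- sqrt(mean(ut^2)); r_v <- sqrt(mean(vt^2))
  r0 <- sqrt(r_u * r_v)
  ut <- ut * sqrt(r_v / r_u) / r0
  vt <- vt * sqrt(r_u / r_v) / r0
  scale2 <- r0^2

  if (backend == "fixedpoint") {
    if (!mode %in% c("spatial", "temporal")) {
      stop("fixed-point backend supports spatial and temporal modes only")
    }
    # The fixed-point iteration unmixes the *whitened* factor (orthonormal
    # eigenimages/eigensequences); translate its orthogonal W into the
    # conditioned parameterization through the diagonal change of basis
    # between the whitened and the conditioned factor.
    if (mode == "spatial") {
      z <- sqrt(nrow(u)) * t(u)              # K x Nest, unit-variance rows
      w_fp <- ica_fixedpoint(z, fun = "tanh", seed = seed)
      dd <- diag(t(ut) %*% u)                # t(ut) = diag(dd) %*% t(u)
      w_use <- w_fp %*% diag(1 / dd, K)
    } else {
      z <- sqrt(ncol(v)) * v                 # K x Nt, unit-variance rows
      w_fp <- ica_fixedpoint(z, fun = "pow3", seed = seed)
      dd <- diag(vt %*% t(v))                # vt = diag(dd) %*% v
      m_use <- w_fp %*% diag(1 / dd, K)      # T = M vt reproduces W_fp v
      w_use <- t(solve(m_use))               # M = W^-T
    }
    obj <- stica_value_grad(as.vector(w_use), t(ut), vt, alpha)$value
    fit <- list(par = as.vector(w_use), value = obj, convergence = 0L)
  } else {
    best <- NULL
    for (r in seq_len(restarts)) {
      w0 <- with_local_seed(derive_seed(seed, r), random_orthogonal(K))
      res <- tryCatch(
        stats::optim(as.vector(w0),
                     fn = function(p) -stica_value_grad(p, t(ut), vt,
                                                        alpha)$value,
                     gr = function(p) -stica_value_grad(p, t(ut), vt,
                                                        alpha)$grad,
                     method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) {
      stop("ICA failed to converge from any restart; inspect the input ",
           "for degeneracy or increase `maxit`")
    }
    fit <- list(par = best$par, value = -best$value,
                convergence = best$convergence)
  }

  w <- matrix(fit$par, K, K)
  s_raw <- w %*% t(ut)                       # K x Nest
  t_raw <- solve(t(w)) %*% vt                # K x Nt; M = W^-T acting on vt
  # order by rank-1 map variance, fix signs, normalize spatial rows
  s_norm <- sqrt(rowSums(s_raw^2))
  t_norm <- sqrt(rowSums(t_raw^2))
  ord <- order(s_norm * t_norm, decreasing = TRUE)
  spatial <- matrix(0, K, ncol(s_raw))
  temporal <- matrix(0, K, ncol(t_raw))
  for (i in seq_len(K)) {
    k <- ord[i]
    sgn <- sign(s_raw[k, which.max(abs(s_raw[k, ]))])
    if (sgn == 0) sgn <- 1
    spatial[i, ] <- sgn * s_raw[k, ] / s_norm[k]
    temporal[i, ] <- sgn * scale2 * s_norm[k] * t_raw[k, ]
  }
  structure(
    list(spatial = spatial, temporal = temporal,
         unmixing = w[ord, , drop = FALSE], mode = mode, alpha = alpha,
         objective = fit$value, seed = seed, K = K,
         converged = fit$convergence == 0L,
         grid = pca$grid, dt = pca$dt, backend = backend),
    class = "ica_result")
}

#' Rank-1 spatiotemporal maps of the components
#'
#' Expands each independent component into its depths x time matrix (outer
#' product of spatial profile and time course). The maps sum exactly to the
#' PCA-truncated data the decomposition represents.
#'
#' @param ica an [ica_result][spatial_ica()].
#' @return A list of class `component_maps`; each element is a matrix with
#'   attributes `profile` and `course`.
#' @export
components_to_maps <- function(ica) {
  stopifnot(inherits(ica, "ica_result"))
  maps <- lapply(seq_len(ica$K), function(k) {
    m <- outer(ica$spatial[k, ], ica$temporal[k, ])
    attr(m, "profile") <- ica$spatial[k, ]
    attr(m, "course") <- ica$temporal[k, ]
    m
  })
  structure(maps, class = "component_maps", grid = ica$grid, dt = ica$dt)
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> K = %d of %d; leading singular values: %s\n",
              x$K, length(x$all_singular_values),
              paste(signif(x$singular_values, 3), collapse = ", ")))
  invisible(x)
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> mode %s (alpha %g), K = %d, objective %.6g\n",
              x$mode, x$alpha, x$K, x$objective))
  invisible(x)
}
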