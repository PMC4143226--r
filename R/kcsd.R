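#' Current source density estimate
#'
#' Depth profile of current source density over time. Sign convention:
#' positive values are sources (current entering the extracellular medium),
#' negative values are sinks.
#'
#' @param grid strictly increasing estimation depths in um.
#' @param values numeric matrix (grid points x time samples).
#' @param lambda ridge parameter used for the estimate (NA when not
#'   applicable, e.g. coarse-grained reference maps).
#' @param dt sampling interval in ms.
#' @return An object of class `csd_estimate`.
#' @export
csd_estimate <- function(grid, values, lambda = NA_real_, dt = NA_real_) {
  grid <- as.numeric(grid)
  values <- as.matrix(values)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  if (nrow(values) != length(grid)) {
    stop("`values` must have one row per grid point")
  }
  structure(list(grid = grid, values = values, lambda = lambda, dt = dt),
            class = "csd_estimate")
}

#' @export
print.csd_estimate <- function(x, ...) {
  cat(sprintf("<csd_estimate> %d depths x %d samples (lambda %s)\n",
              length(x$grid), ncol(x$values),
              if (is.na(x$lambda)) "-" else format(x$lambda)))
  invisible(x)
}

#' Basis configuration for kernel CSD
#'
#' The 1D kernel CSD estimator represents the source density along the probe
#' as a combination of basis profiles, each assumed constant on discs of
#' radius `disc_radius` orthogonal to the probe (the source is unknown away
#' from the measurement line, so a cylindrical symmetry of this lateral
#' extent is imposed). Basis centers are spaced equally over `span`, which
#' must cover the electrode span.
#'
#' Defaults: Gaussian bases, `n_bases` three per contact, width equal to the
#' inter-contact spacing, disc radius 150 um, estimation span 0-2700 um on
#' 100 grid points.
#'
#' @param array an [electrode_array()]; used to derive defaults.
#' @param n_bases number of basis profiles M (must be >= number of contacts).
#' @param type "gaussian" or "step".
#' @param width basis width in um (Gaussian standard deviation; ignored for
#'   step bases, whose width is set to tile the span disjointly).
#' @param disc_radius lateral disc radius R in um.
#' @param span length-2 depth interval for basis centers and estimation.
#' @param n_grid number of estimation grid points.
#' @return An object of class `basis_config`.
#' @export
basis_config <- function(array = NULL, n_bases = NULL,
                         type = c("gaussian", "step"), width = NULL,
                         disc_radius = 150, span = c(0, 2700), n_grid = 100) {
  type <- match.arg(type)
  if (!is.null(array)) {
    stopifnot(inherits(array, "electrode_array"))
    if (is.null(n_bases)) n_bases <- 3L * length(array$depths)
    if (is.null(width)) {
      width <- if (length(array$depths) > 1) min(diff(array$depths)) else 50
    }
  }
  if (is.null(n_bases) || is.null(width)) {
    stop("`n_bases` and `width` are required when no array is given")
  }
  stopifnot_scalar(disc_radius, "disc_radius", positive = TRUE)
  stopifnot_scalar(width, "width", positive = TRUE)
  if (length(span) != 2L || span[2] <= span[1]) stop("invalid `span`")
  structure(list(n_bases = as.integer(n_bases), type = type, width = width,
                 disc_radius = disc_radius, span = as.numeric(span),
                 n_grid = as.integer(n_grid)),
            class = "basis_config")
}

validate_basis_vs_array <- function(config, array) {
  if (config$n_bases < length(array$depths)) {
    stop("`n_bases` must be at least the number of contacts")
  }
  if (config$span[1] > min(array$depths) || config$span[2] < max(array$depths)) {
    stop("basis `span` must cover the electrode span")
  }
  invisible(TRUE)
}

#' Build the CSD basis set
#'
#' Places `n_bases` basis profiles with equally spaced centers over the
#' configured span. Gaussian bases are unnormalized (`exp(-(x-c)^2/2w^2)`);
#' step bases are indicators on disjoint intervals tiling the span.
#'
#' @param config a [basis_config()].
#' @param array an [electrode_array()] (validates span/count constraints).
#' @return A list with `centers`, `type`, `width` and an evaluator
#'   `value(x, i)` giving basis `i` at depths `x`.
#' @export
build_basis <- function(config, array) {
  stopifnot(inherits(config, "basis_config"))
  validate_basis_vs_array(config, array)
  m <- config$n_bases
  if (config$type == "gaussian") {
    centers <- seq(config$span[1], config$span[2], length.out = m)
    w <- config$width
    value <- function(x, i) exp(-(x - centers[i])^2 / (2 * w^2))
  } else {
    h <- diff(config$span) / m
    centers <- config$span[1] + h * (seq_len(m) - 0.5)
    w <- h
    value <- function(x, i) {
      as.numeric(x >= centers[i] - h / 2 & x < centers[i] + h / 2)
    }
  }
  list(centers = centers, type = config$type, width = w, value = value)
}

# potential kernel of a disc source at depth-distance h, unit volume density:
# (1/2sigma) (sqrt(h^2 + R^2) - |h|); nA/um^3 * um -> mV with sigma in S/m
disc_potential_kernel <- function(h, disc_radius, sigma) {
  (sqrt(h^2 + disc_radius^2) - abs(h)) / (2 * sigma)
}

#' Potential profiles of the basis elements
#'
#' For each basis profile, computes the potential it generates at each
#' contact, assuming the source is constant on discs of the configured
#' radius: a 1D adaptive quadrature of the disc-source forward kernel
#' against the basis shape (relative tolerance 1e-10).
#'
#' @param basis result of [build_basis()].
#' @param config a [basis_config()].
#' @param array an [electrode_array()].
#' @param sigma conductivity in S/m.
#' @return Matrix (n_bases x contacts) of potentials.
#' @export
basis_potentials <- function(basis, config, array, sigma) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  m <- length(basis$centers)
  depths <- array$depths
  out <- matrix(0, m, length(depths))
  r <- config$disc_radius
  for (i in seq_len(m)) {
    if (basis$type == "gaussian") {
      lo <- basis$centers[i] - 10 * basis$width
      hi <- basis$centers[i] + 10 * basis$width
    } else {
      lo <- basis$centers[i] - basis$width / 2
      hi <- basis$centers[i] + basis$width / 2
    }
    for (j in seq_along(depths)) {
      z <- depths[j]
      res <- tryCatch(
        stats::integrate(function(x) {
          basis$value(x, i) * disc_potential_kernel(z - x, r, sigma)
        }, lower = lo, upper = hi, rel.tol = 1e-10, subdivisions = 400L),
        error = function(e) NULL
      )
      if (is.null(res)) stop("quadrature failed for basis potential")
      out[i, j] <- res$value
    }
  }
  out
}

# cache of assembled kernel matrices, keyed by geometry + config + sigma
.kcsd_cache <- new.env(parent = emptyenv())

#' Assemble the kCSD kernel matrices
#'
#' Precomputes, for a given electrode geometry, conductivity and basis
#' configuration: the basis potentials `B` at the contacts, the contact
#' kernel `K = B'B` (symmetric positive semidefinite), and the cross-kernel
#' `K_cross` linking estimation depths to contacts. Results are cached so
#' repeated reconstructions with the same geometry are cheap.
#'
#' @inheritParams basis_potentials
#' @param use_cache reuse a previously assembled engine when possible.
#' @return An object of class `kcsd_engine`.
#' @export
kcsd_engine <- function(array, sigma, config = basis_config(array),
                        use_cache = TRUE) {
  stopifnot(inherits(array, "electrode_array"), inherits(config, "basis_config"))
  key <- paste(
    paste(format(array$depths, digits = 12), collapse = ","),
    paste(format(array$lateral, digits = 12), collapse = ","),
    format(sigma, digits = 12), config$n_bases, config$type,
    format(config$width, digits = 12), format(config$disc_radius, digits = 12),
    paste(format(config$span, digits = 12), collapse = ","), config$n_grid,
    sep = "|")
  if (use_cache && !is.null(.kcsd_cache[[key]])) return(.kcsd_cache[[key]])
  basis <- build_basis(config, array)
  b_pot <- basis_potentials(basis, config, array, sigma)     # M x Ne
  grid <- seq(config$span[1], config$span[2], length.out = config$n_grid)
  b_tilde <- vapply(seq_along(basis$centers),
                    function(i) basis$value(grid, i),
                    numeric(length(grid)))                   # Ngrid x M
  eng <- structure(
    list(array = array, sigma = sigma, config = config, basis = basis,
         b_pot = b_pot,
         K = crossprod(b_pot),                               # Ne x Ne
         K_cross = b_tilde %*% b_pot,                        # Ngrid x Ne
         grid = grid),
    class = "kcsd_engine")
  if (use_cache) .kcsd_cache[[key]] <- eng
  eng
}

#' Kernel CSD reconstruction with ridge regularization
#'
#' Estimates current source density on the configured depth grid from
#' laminar potentials via kernel ridge regression: the CSD at the estimation
#' depths equals the cross-kernel applied to `(K + lambda I)^(-1) V`,
#' columnwise over time. At `lambda = 0` on noise-free, basis-consistent
#' data the estimate interpolates the measurements (minimum-norm solution);
#' positive `lambda` trades fidelity for smoothness and is the standard
#' defence against overfitting measurement noise.
#'
#' @param recording a [potential_recording()].
#' @param config a [basis_config()] (defaults derived from the array).
#' @param lambda a non-negative ridge penalty, or "auto" to select by
#'   leave-one-contact-out cross-validation over `lambdas`.
#' @param lambdas candidate grid used when `lambda = "auto"`; `NULL` uses a
#'   logarithmic grid scaled to the kernel's diagonal (the penalty only
#'   acts relative to the kernel spectrum).
#' @param engine optional precomputed [kcsd_engine()].
#' @return A [csd_estimate()].
#' @export
reconstruct_csd <- function(recording, config = NULL, lambda = "auto",
                            lambdas = NULL, engine = NULL) {
  stopifnot(inherits(recording, "potential_recording"))
  if (is.null(engine)) {
    if (is.null(config)) config <- basis_config(recording$array)
    engine <- kcsd_engine(recording$array, recording$sigma, config)
  }
  if (identical(lambda, "auto")) {
    lambda <- choose_lambda(recording, engine = engine, lambdas = lambdas)
  }
  stopifnot_scalar(lambda, "lambda")
  if (lambda < 0) stop("`lambda` must be >= 0")
  n_el <- nrow(engine$K)
  kr <- engine$K + lambda * diag(n_el)
  sol <- tryCatch(solve(kr, recording$values), error = function(e) NULL)
  if (is.null(sol)) {
    stop("singular kernel system at lambda = ", lambda,
         "; use a positive ridge penalty")
  }
  csd_estimate(engine$grid, engine$K_cross %*% sol, lambda = lambda,
               dt = recording$dt)
}

#' Select the ridge penalty by leave-one-contact-out cross-validation
#'
#' For each candidate penalty, each contact in turn is withheld, the
#' potential there is predicted from the remaining contacts through the
#' kernel, and the squared prediction error is accumulated over contacts and
#' time. The candidate with the smallest total error wins; ties break toward
#' the smaller penalty.
#'
#' @inheritParams reconstruct_csd
#' @param lambdas candidate penalties (at least one); `NULL` for the
#'   kernel-scaled default grid.
#' @return The selected penalty (scalar).
#' @export
choose_lambda <- function(recording, config = NULL, lambdas = NULL,
                          engine = NULL) {
  stopifnot(inherits(recording, "potential_recording"))
  if (is.null(engine)) {
    if (is.null(config)) config <- basis_config(recording$array)
    engine <- kcsd_engine(recording$array, recording$sigma, config)
  }
  if (is.null(lambdas)) {
    lambdas <- mean(diag(engine$K)) * 10^seq(-10, 0, length.out = 21)
  }
  if (length(lambdas) < 1L) stop("at least one candidate is required")
  n_el <- nrow(engine$K)
  if (n_el < 3L) stop("insufficient data: need at least 3 contacts for CV")
  lambdas <- sort(as.numeric(lambdas))
  if (length(lambdas) == 1L) return(lambdas)
  err <- vapply(lambdas, function(lam) {
    tot <- 0
    for (i in seq_len(n_el)) {
      ki <- engine$K[-i, -i, drop = FALSE] + lam * diag(n_el - 1L)
      pred <- engine$K[i, -i, drop = FALSE] %*%
        tryCatch(solve(ki, recording$values[-i, , drop = FALSE]),
                 error = function(e) matrix(NA_real_, n_el - 1L,
                                            ncol(recording$values)))
      tot <- tot + sum((pred - recording$values[i, ])^2)
    }
    tot
  }, numeric(1))
  err[!is.finite(err)] <- Inf
  lambdas[which.min(err)]   # which.min takes the first (smallest) on ties
}

#' Traditional (finite-difference) CSD
#'
#' The classical estimator: minus conductivity times the second central
#' difference of the potential along depth, defined at interior contacts of
#' an equally spaced array. Boundary contacts are excluded.
#'
#' @param recording a [potential_recording()] with >= 3 equally spaced
#'   contacts.
#' @return A [csd_estimate()] on the interior contact depths.
#' @export
traditional_csd <- function(recording) {
  stopifnot(inherits(recording, "potential_recording"))
  z <- recording$array$depths
  if (length(z) < 3L) stop("need at least 3 contacts")
  h <- diff(z)
  if (max(h) - min(h) > 1e-6 * mean(h)) {
    stop("invalid geometry: contacts must be equally spaced")
  }
  h <- mean(h)
  v <- recording$values
  n <- nrow(v)
  csd <- -recording$sigma *
    (v[1:(n - 2), , drop = FALSE] - 2 * v[2:(n - 1), , drop = FALSE] +
       v[3:n, , drop = FALSE]) / h^2
  csd_estimate(z[2:(n - 1)], csd, lambda = NA_real_, dt = recording$dt)
}
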