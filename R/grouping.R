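#' Pearson correlation of two spatiotemporal matrices
#'
#' Flattens both matrices over (space x time) and returns the Pearson
#' correlation coefficient, the similarity measure used to score how well a
#' signed combination of components reproduces a population's activity.
#'
#' @param a,b numeric matrices of equal dimensions, neither constant.
#' @return A scalar in [-1, 1].
#' @export
correlation_similarity <- function(a, b) {
  a <- if (inherits(a, "csd_estimate")) a$values else as.matrix(a)
  b <- if (inherits(b, "csd_estimate")) b$values else as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (stats::sd(as.vector(a)) == 0 || stats::sd(as.vector(b)) == 0) {
    stop("undefined correlation: constant input")
  }
  stats::cor(as.vector(a), as.vector(b))
}

# precompute centered, flattened component vectors and their Gram matrix so
# that the correlation of any signed combination with a reference is O(K^2)
grouping_precompute <- function(maps, references) {
  k <- length(maps)
  mc <- vapply(maps, function(m) {
    v <- as.vector(m); v - mean(v)
  }, numeric(length(as.vector(maps[[1]]))))
  gram <- crossprod(mc)                           # K x K
  refs <- lapply(references, function(r) {
    v <- if (inherits(r, "csd_estimate")) as.vector(r$values) else
      as.vector(as.matrix(r))
    v - mean(v)
  })
  list(k = k, mc = mc, gram = gram, refs = refs,
       ref_ss = vapply(refs, function(v) sum(v^2), numeric(1)))
}

# correlation of the beta-weighted combination with reference i;
# beta all zero -> score 0 by convention (the "empty" assignment: a
# population that no combination describes better than silence)
combo_score <- function(beta, pre, i) {
  if (all(beta == 0)) return(0)
  num <- sum(beta * crossprod(pre$mc, pre$refs[[i]]))
  den <- sqrt(drop(t(beta) %*% pre$gram %*% beta) * pre$ref_ss[i])
  if (den == 0) return(0)
  num / den
}

# all sign/membership vectors over `idx` as a matrix (3^m or 2^m columns)
beta_grid <- function(m, signed) {
  vals <- if (signed) c(-1, 0, 1) else c(0, 1)
  as.matrix(expand.grid(rep(list(vals), m)))
}

#' Assign independent components to populations
#'
#' Exhaustive signed-subset search: components are distributed among the
#' reference populations (each component used by at most one population,
#' or left unused) with per-component coefficients in {-1, 0, +1}, so the
#' arbitrary sign of an independent component cannot affect the result.
#' Populations are processed in order of decreasing reference signal power
#' and each receives, from the components still available, the signed
#' subset maximizing the Pearson correlation between the summed component
#' maps and its reference activity (a lexicographic optimum across
#' populations). Ties break toward fewer components, then toward lower
#' component indices.
#'
#' @param maps a [component_maps][components_to_maps()] list (or plain list
#'   of matrices), at most `max_k` components.
#' @param references named list of population reference activities
#'   ([csd_estimate()]s or matrices) on the same grid as the maps.
#' @param betas "signed" ({-1, 0, +1}, default) or "binary" ({0, 1},
#'   provided for sensitivity analysis).
#' @param max_k exhaustive-search bound on the number of components.
#' @return An object of class `population_assignment`: a `coefficients`
#'   tibble (population x component), a `scores` tibble with each
#'   population's correlation `m`, and the population order used.
#' @export
assign_components <- function(maps, references, betas = c("signed", "binary"),
                              max_k = 12) {
  betas <- match.arg(betas)
  k <- length(maps)
  if (k == 0) stop("no components to assign")
  if (k > max_k) {
    stop(sprintf(
      "combinatorial limit: %d components exceeds max_k = %d; consider a %s",
      k, max_k, "greedy pre-selection or raising max_k"))
  }
  if (is.null(names(references))) {
    names(references) <- paste0("pop", seq_along(references))
  }
  pre <- grouping_precompute(maps, references)
  pop_order <- order(pre$ref_ss, decreasing = TRUE)
  available <- seq_len(k)
  coef_mat <- matrix(0, length(references), k,
                     dimnames = list(names(references), NULL))
  scores <- numeric(length(references))
  for (p in pop_order) {
    m <- length(available)
    if (m == 0) { scores[p] <- 0; next }
    grid <- beta_grid(m, signed = betas == "signed")
    g_sub <- drop(crossprod(pre$mc, pre$refs[[p]]))[available]
    gram_sub <- pre$gram[available, available, drop = FALSE]
    num <- drop(grid %*% g_sub)
    quad <- rowSums((grid %*% gram_sub) * grid)
    sc <- ifelse(quad > 0, num / sqrt(quad * pre$ref_ss[p]), 0)
    best <- max(sc)
    cand <- which(sc >= best - 1e-12)
    nz <- rowSums(grid[cand, , drop = FALSE] != 0)
    cand <- cand[nz == min(nz)]
    if (length(cand) > 1L) {
      keys <- apply(grid[cand, , drop = FALSE], 1, paste, collapse = ",")
      cand <- cand[order(keys)][1]
    }
    best_beta <- grid[cand[1], ]
    beta_full <- rep(0, k)
    beta_full[available] <- best_beta
    coef_mat[p, ] <- beta_full
    scores[p] <- max(best, 0)
    available <- setdiff(available, which(beta_full != 0))
  }
  structure(
    list(
      coefficients = tibble::as_tibble(coef_mat, .name_repair = ~paste0(
        "IC", seq_len(k))) |>
        dplyr::mutate(population = names(references), .before = 1),
      scores = tibble::tibble(
        population = names(references),
        score = scores,
        n_components = rowSums(coef_mat != 0),
        reference_power = pre$ref_ss),
      betas = betas,
      population_order = names(references)[pop_order]),
    class = "population_assignment")
}

#' @export
print.population_assignment <- function(x, ...) {
  cat("<population_assignment>\n")
  print(x$scores)
  invisible(x)
}

#' Relate matched components to a population's principal components
#'
#' Computes the PCA of a reference population's activity and reports the
#' absolute Pearson correlation between each matched component map and each
#' of the top principal-component rank-1 maps, with greedy one-to-one
#' matching (largest correlation first). This quantifies the finding that
#' independent components of the total signal recover the principal
#' components of single-population activity, not the full population
#' pattern.
#'
#' @param matched_maps list of component maps assigned to the population.
#' @param reference the population's reference activity ([csd_estimate()]
#'   or matrix); must not be degenerate.
#' @param n_pc number of principal components to compare against (default:
#'   number of matched maps).
#' @return A tibble with columns `component`, `pc`, `correlation`, plus the
#'   reference singular values as an attribute.
#' @export
population_pca_match <- function(matched_maps, reference,
                                 n_pc = length(matched_maps)) {
  x <- if (inherits(reference, "csd_estimate")) reference$values else
    as.matrix(reference)
  if (stats::sd(as.vector(x)) == 0) stop("degenerate reference")
  n_pc <- min(n_pc, min(dim(x)))
  sv <- svd(x)
  pc_maps <- lapply(seq_len(n_pc), function(k) {
    sv$d[k] * outer(sv$u[, k], sv$v[, k])
  })
  n_c <- length(matched_maps)
  cors <- matrix(NA_real_, n_c, n_pc)
  for (i in seq_len(n_c)) {
    for (j in seq_len(n_pc)) {
      cors[i, j] <- abs(correlation_similarity(matched_maps[[i]],
                                               pc_maps[[j]]))
    }
  }
  # greedy one-to-one matching, strongest pair first
  pairs <- list()
  tmp <- cors
  for (s in seq_len(min(n_c, n_pc))) {
    ij <- arrayInd(which.max(tmp), dim(tmp))
    pairs[[s]] <- tibble::tibble(component = ij[1], pc = ij[2],
                                 correlation = cors[ij[1], ij[2]])
    tmp[ij[1], ] <- -Inf
    tmp[, ij[2]] <- -Inf
  }
  out <- dplyr::bind_rows(pairs) |> dplyr::arrange(.data$pc)
  attr(out, "singular_values") <- sv$d
  out
}
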