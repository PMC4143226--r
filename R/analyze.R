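#' Full population-recovery analysis of one dataset
#'
#' Runs the complete pipeline on a ground-truth dataset: kernel CSD
#' reconstruction of the total LFP, per-population reference CSDs
#' reconstructed from each population's own LFP (same kernel and ridge
#' penalty, mirroring how reference activity would be represented in an
#' experiment), PCA truncation to `K`, spatial ICA, expansion into rank-1
#' component maps, and exhaustive signed assignment of components to
#' populations.
#'
#' @param dataset a `ground_truth_dataset`.
#' @param K PCA/ICA model order (default 5).
#' @param lambda ridge penalty, or "auto" for leave-one-out CV on the total
#'   LFP; the selected value is reused for the population references.
#' @param config optional [basis_config()] (defaults from the array).
#' @param ica_seed seed for the ICA restart schedule.
#' @param mode ICA flavor: "spatial" (default, the recommended pipeline),
#'   "temporal" or "spatiotemporal".
#' @param alpha entropy weight when `mode = "spatiotemporal"`.
#' @return An object of class `lampop_analysis`: the CSD estimate, PCA,
#'   ICA, component maps, references, assignment and per-population
#'   recovery scores.
#' @export
analyze_dataset <- function(dataset, K = 5, lambda = "auto", config = NULL,
                            ica_seed = 1, mode = c("spatial", "temporal",
                                                   "spatiotemporal"),
                            alpha = 0.5) {
  stopifnot(inherits(dataset, "ground_truth_dataset"))
  mode <- match.arg(mode)
  if (is.null(config)) config <- basis_config(dataset$array)
  engine <- kcsd_engine(dataset$array, dataset$sigma, config)
  if (identical(lambda, "auto")) {
    lambda <- choose_lambda(dataset$lfp, engine = engine)
  }
  csd <- reconstruct_csd(dataset$lfp, lambda = lambda, engine = engine)
  references <- lapply(dataset$populations, function(p) {
    reconstruct_csd(p$lfp, lambda = lambda, engine = engine)
  })
  pca <- pca_truncate(csd, K)
  ica <- switch(mode,
                spatial = spatial_ica(pca, K, seed = ica_seed),
                temporal = temporal_ica(pca, K, seed = ica_seed),
                spatiotemporal = spatiotemporal_ica(pca, K, alpha = alpha,
                                                    seed = ica_seed))
  maps <- components_to_maps(ica)
  assignment <- assign_components(maps, references)
  structure(
    list(csd = csd, pca = pca, ica = ica, maps = maps,
         references = references, assignment = assignment,
         scores = assignment$scores, lambda = lambda, K = K, mode = mode),
    class = "lampop_analysis")
}

#' Component maps assigned to one population
#'
#' @param analysis a [lampop_analysis][analyze_dataset()].
#' @param population population name.
#' @return List of that population's signed component maps.
#' @export
matched_maps <- function(analysis, population) {
  stopifnot(inherits(analysis, "lampop_analysis"))
  coefs <- analysis$assignment$coefficients
  row <- coefs[coefs$population == population, , drop = FALSE]
  if (nrow(row) == 0) stop(sprintf("unknown population '%s'", population))
  beta <- as.numeric(row[1, -1])
  idx <- which(beta != 0)
  lapply(idx, function(i) beta[i] * analysis$maps[[i]])
}

#' @export
print.lampop_analysis <- function(x, ...) {
  cat(sprintf("<lampop_analysis> K = %d, lambda = %.3g, mode = %s\n",
              x$K, x$lambda, x$mode))
  print(x$scores)
  invisible(x)
}
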