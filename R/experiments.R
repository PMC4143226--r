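#' Robustness experiments
#'
#' Scripted, seeded sweeps that quantify how population recovery degrades
#' with measurement noise, electrode count, relative population depth and
#' ICA model order. Each sweep repeats the full pipeline (`repetitions`
#' times per factor level) with a fresh noise draw and a fresh ICA restart
#' schedule per repetition, and records every run in a tidy table:
#' one row per (level, population, repetition) carrying the recovery score
#' and the seeds that produced it. A population whose best signed
#' combination of components does not beat silence scores 0.
#'
#' @name experiments
#' @param scenario a `lampop_scenario` (see [default_scenario()]).
#' @param repetitions repetitions per factor level (>= 1).
#' @param seed base seed; all per-repetition seeds derive from it.
#' @param K ICA model order.
#' @param lambdas candidate ridge penalties for per-dataset CV (NULL for the kernel-scaled default grid).
#' @return An object of class `experiment_result`: a tibble with columns
#'   `<factor>`, `population`, `repetition`, `score`, `seed`, with the
#'   factor name and scenario stored as attributes. `summary()`/`glance()`
#'   give per-level means and standard deviations.
NULL

experiment_result <- function(rows, factor_name, scenario) {
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("experiment_result", class(out)),
            factor_name = factor_name, scenario = scenario)
}

# One pipeline run on a prepared dataset; returns per-population scores.
# Each repetition runs ICA from a single random initialization (the
# repetitions themselves play the role of restarts), so the reported
# standard deviation reflects the run-to-run variability of the stochastic
# decomposition, as in repeated-ICA protocols.
pipeline_scores <- function(dataset, K, ica_seed, engine, lambdas) {
  lambda <- choose_lambda(dataset$lfp, engine = engine, lambdas = lambdas)
  csd <- reconstruct_csd(dataset$lfp, lambda = lambda, engine = engine)
  refs <- lapply(dataset$populations, function(p) {
    reconstruct_csd(p$lfp, lambda = lambda, engine = engine)
  })
  pca <- pca_truncate(csd, K)
  ica <- spatial_ica(pca, K, seed = ica_seed, restarts = 1)
  assignment <- assign_components(components_to_maps(ica), refs)
  stats::setNames(assignment$scores$score, assignment$scores$population)
}

default_lambdas <- function() NULL   # kernel-scaled grid in choose_lambda()

#' @rdname experiments
#' @param levels noise levels in percent of the pooled LFP standard
#'   deviation (>= 0).
#' @export
run_noise_sweep <- function(scenario, levels = c(0, 10, 25, 50, 100),
                            repetitions = 10, seed = 1, K = 5,
                            lambdas = default_lambdas()) {
  stopifnot(inherits(scenario, "lampop_scenario"))
  if (any(levels < 0)) stop("noise levels must be >= 0")
  base <- realize_scenario(scenario)
  engine <- kcsd_engine(base$array, base$sigma, basis_config(base$array))
  rows <- list()
  for (li in seq_along(levels)) {
    for (rep_i in seq_len(repetitions)) {
      rs <- derive_seed(seed, li, rep_i)
      ds <- if (levels[li] > 0) add_noise(base, levels[li], seed = rs) else base
      sc <- pipeline_scores(ds, K, ica_seed = derive_seed(rs, 1),
                            engine = engine, lambdas = lambdas)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        noise_percent = levels[li], population = names(sc),
        repetition = rep_i, score = unname(sc), seed = rs)
    }
  }
  experiment_result(rows, "noise_percent", scenario)
}

#' @rdname experiments
#' @param counts electrode counts to retain (each between 2 and the full
#'   array size); references are recomputed from the same subsampled
#'   contacts.
#' @param noise_percent noise level applied at every count (default 0).
#' @export
run_electrode_sweep <- function(scenario, counts = c(26, 21, 16, 13, 8, 6),
                                repetitions = 10, seed = 1, K = 5,
                                noise_percent = 0,
                                lambdas = default_lambdas()) {
  stopifnot(inherits(scenario, "lampop_scenario"))
  base <- realize_scenario(scenario)
  rows <- list()
  for (ci in seq_along(counts)) {
    n <- counts[ci]
    sub_total_clean <- subsample_electrodes(base$lfp_clean, n)
    engine <- kcsd_engine(sub_total_clean$array, base$sigma,
                          basis_config(sub_total_clean$array))
    sub_pops <- lapply(base$populations, function(p) {
      list(spec = p$spec, sources = p$sources,
           lfp = subsample_electrodes(p$lfp, n))
    })
    for (rep_i in seq_len(repetitions)) {
      rs <- derive_seed(seed, ci, rep_i)
      ds <- base
      ds$populations <- sub_pops
      ds$array <- sub_total_clean$array
      ds$lfp_clean <- sub_total_clean
      ds$lfp <- sub_total_clean
      ds$noise_percent <- 0
      if (noise_percent > 0) ds <- add_noise(ds, noise_percent, seed = rs)
      sc <- pipeline_scores(ds, K, ica_seed = derive_seed(rs, 1),
                            engine = engine, lambdas = lambdas)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_electrodes = n, population = names(sc),
        repetition = rep_i, score = unname(sc), seed = rs)
    }
  }
  experiment_result(rows, "n_electrodes", scenario)
}

#' @rdname experiments
#' @param shifts downward depth translations in um applied to `population`.
#' @param population name of the population to shift (default: the first
#'   one in the scenario, the superficial pyramidal-like population).
#' @export
run_shift_sweep <- function(scenario, shifts = c(0, 100, 200, 300),
                            population = NULL, repetitions = 10, seed = 1,
                            K = 5, noise_percent = 0,
                            lambdas = default_lambdas()) {
  stopifnot(inherits(scenario, "lampop_scenario"))
  if (is.null(population)) population <- scenario$specs[[1]]$name
  base <- realize_scenario(scenario)
  engine <- kcsd_engine(base$array, base$sigma, basis_config(base$array))
  rows <- list()
  for (si in seq_along(shifts)) {
    shifted <- if (shifts[si] == 0) base else
      shift_population(base, population, shifts[si])
    for (rep_i in seq_len(repetitions)) {
      rs <- derive_seed(seed, si, rep_i)
      ds <- if (noise_percent > 0) {
        add_noise(shifted, noise_percent, seed = rs)
      } else shifted
      sc <- pipeline_scores(ds, K, ica_seed = derive_seed(rs, 1),
                            engine = engine, lambdas = lambdas)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        shift_um = shifts[si], population = names(sc),
        repetition = rep_i, score = unname(sc), seed = rs)
    }
  }
  experiment_result(rows, "shift_um", scenario)
}

#' @rdname experiments
#' @param k_values ICA model orders to try. The model-order sweep applies a
#'   baseline noise level (default 10 percent): with noise the data matrix
#'   has full rank, so orders above the ground-truth rank remain
#'   well-posed, as they are in recordings.
#' @export
run_k_sweep <- function(scenario, k_values = c(1, 2, 3, 4, 5, 6, 7, 8),
                        repetitions = 10, seed = 1, noise_percent = 10,
                        lambdas = default_lambdas()) {
  stopifnot(inherits(scenario, "lampop_scenario"))
  base <- realize_scenario(scenario)
  engine <- kcsd_engine(base$array, base$sigma, basis_config(base$array))
  rows <- list()
  for (ki in seq_along(k_values)) {
    for (rep_i in seq_len(repetitions)) {
      rs <- derive_seed(seed, ki, rep_i)
      ds <- if (noise_percent > 0) add_noise(base, noise_percent, seed = rs)
      else base
      sc <- pipeline_scores(ds, k_values[ki], ica_seed = derive_seed(rs, 1),
                            engine = engine, lambdas = lambdas)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        K = k_values[ki], population = names(sc),
        repetition = rep_i, score = unname(sc), seed = rs)
    }
  }
  experiment_result(rows, "K", scenario)
}

#' @export
summary.experiment_result <- function(object, ...) {
  fac <- attr(object, "factor_name")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object),
                    dplyr::across(dplyr::all_of(c(fac, "population")))),
    mean_score = mean(.data$score),
    sd_score = if (dplyr::n() > 1) stats::sd(.data$score) else 0,
    n = dplyr::n(), .groups = "drop")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> factor: %s, %d rows\n",
              attr(x, "factor_name"), nrow(x)))
  print(summary(x), n = 20)
  invisible(x)
}
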