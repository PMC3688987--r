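#' Run the full network-feature analysis on a study
#'
#' Convenience wrapper chaining the pipeline stages: temporal-concatenation
#' group ICA at dimension `d`, dual regression per subject, feature extraction
#' (amplitudes and network matrices over all components), and cross-subject
#' behaviour correlation with BH-FDR for the scalar features. Spatial-map
#' inference is exposed separately through [permutation_fwe()] because of its
#' cost; [spatial_map_inference()] runs it per component.
#'
#' @param datasets list of [masked_dataset()].
#' @param behavior per-subject scores, aligned with `datasets` (a numeric
#'   vector or a data frame with a `score` column).
#' @param d ICA dimensionality.
#' @param labels optional per-component `"signal"`/`"artifact"` labels applied
#'   after variance ranking; all components enter the regressions and the
#'   partial-correlation estimation, artifact elements are discarded only at
#'   the inference step.
#' @param lambda,tau ICOV/gICOV regularization parameters.
#' @param q FDR level for the scalar analyses.
#' @param seed seed for the ICA initialisation.
#' @return list of class `rsn_analysis`: `group_maps`, `decompositions`,
#'   `amplitudes` (subjects x d), `netmats` (per method), and tibbles
#'   `amplitude_results`, `netmat_results`.
#' @export
run_rsn_analysis <- function(datasets, behavior, d, labels = NULL, lambda = 10,
                             tau = 0.5, q = 0.05, seed = 1) {
  if (is.data.frame(behavior)) behavior <- behavior$score
  stopifnot(length(behavior) == length(datasets))
  cm <- group_ica(datasets, d = d, seed = seed, labels = labels)
  decomps <- lapply(datasets, dual_regression, group_maps = cm)
  amps <- do.call(rbind, lapply(decomps, `[[`, "amplitudes"))
  ts_list <- lapply(decomps, `[[`, "timeseries_raw")
  netmats <- list(
    CORR = lapply(ts_list, netmat_corr),
    ICOV = lapply(ts_list, netmat_icov, lambda = lambda))
  covs <- lapply(ts_list, function(x) {
    xn <- normalize_columns(as.matrix(x), "component timeseries")
    crossprod(xn) / (nrow(xn) - 1)
  })
  netmats$GICOV <- netmat_gicov(covs, lambda = lambda, tau = tau)
  amp_res <- amplitude_behavior(amps, behavior, labels = cm$labels, q = q)
  nm_res <- do.call(rbind, lapply(netmats, netmat_behavior, behavior = behavior,
                                  labels = cm$labels, q = q))
  structure(list(group_maps = cm, decompositions = decomps, amplitudes = amps,
                 netmats = netmats, amplitude_results = amp_res,
                 netmat_results = nm_res, behavior = behavior, q = q),
            class = "rsn_analysis")
}

#' @export
print.rsn_analysis <- function(x, ...) {
  cat(sprintf("<rsn_analysis> %d subjects, %d components (%d signal)\n",
              length(x$decompositions), x$group_maps$d,
              sum(x$group_maps$labels == "signal")))
  cat(sprintf("  amplitude: %d/%d significant at FDR %.2g\n",
              sum(x$amplitude_results$significant_fdr),
              nrow(x$amplitude_results), x$q))
  cat(sprintf("  netmat edges: %d/%d significant at FDR %.2g\n",
              sum(x$netmat_results$significant_fdr),
              nrow(x$netmat_results), x$q))
  invisible(x)
}

#' Spatial-map-versus-behaviour inference for one component
#'
#' Stacks one component's subject spatial maps (beta or z), optionally smooths
#' them with an additional Gaussian kernel, and runs TFCE max-statistic
#' permutation inference against the behavioural score.
#'
#' @param decompositions list of `subject_decomposition` objects.
#' @param component component index.
#' @param behavior per-subject scores.
#' @param grid the study [voxel_grid()].
#' @param use_z use the z-transformed maps instead of the raw beta maps?
#' @param smooth_fwhm additional smoothing FWHM in mm (0 = none).
#' @param ... passed to [permutation_fwe()] (`n_perm`, `alpha`, `seed`,
#'   `two_sided`, ...).
#' @return A `spatial_inference` object (see [permutation_fwe()]).
#' @export
spatial_map_inference <- function(decompositions, component, behavior, grid,
                                  use_z = FALSE, smooth_fwhm = 0, ...) {
  maps <- do.call(rbind, lapply(decompositions, function(dc) {
    m <- if (use_z) dc$z_maps else dc$beta_maps
    m[component, ]
  }))
  if (smooth_fwhm > 0) maps <- smooth_masked_dataset(maps, smooth_fwhm, grid)
  permutation_fwe(maps, behavior, grid, ...)
}
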