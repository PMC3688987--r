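# Run code with a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stop-signal reaction time
#'
#' SSRT under the race model's mean method: the mean Go-trial reaction time
#' minus the (staircase-converged) stop-signal delay.
#'
#' @param mean_go_rt mean reaction time of Go trials, ms.
#' @param mean_ssd mean stop-signal delay, ms.
#' @return `mean_go_rt - mean_ssd`, ms. Vectorised.
#' @examples
#' compute_ssrt(450, 200) # 250
#' @export
compute_ssrt <- function(mean_go_rt, mean_ssd) {
  if (!is.numeric(mean_go_rt) || !is.numeric(mean_ssd) ||
      !all(is.finite(mean_go_rt)) || !all(is.finite(mean_ssd)))
    stop("both inputs must be finite numbers", call. = FALSE)
  mean_go_rt - mean_ssd
}

#' Generate compact network blob maps on a voxel grid
#'
#' Places `d_true` spatially compact Gaussian blobs (truncated below 5% of
#' their peak) at random centres, rejecting placements whose normalised
#' spatial overlap with any already-placed component exceeds `max_overlap`.
#' Per-component "effect masks" -- the voxels above half of the blob peak --
#' are returned alongside; these are the voxel sets where subject-level map
#' deviations can be coupled to behaviour.
#'
#' @param grid_dims integer(3) grid dimensions.
#' @param d_true number of components (>= 2).
#' @param blob_fwhm blob FWHM in voxel units.
#' @param seed RNG seed; output is a pure function of the arguments.
#' @param max_overlap maximum pairwise normalised dot product between maps.
#' @return list with `maps` (n_voxels x d_true, full-grid mask), `effect_masks`
#'   (list of in-mask voxel index vectors) and `grid` (a [voxel_grid()]).
#' @export
make_group_maps <- function(grid_dims, d_true, blob_fwhm = 3, seed = 1,
                            max_overlap = 0.3) {
  grid_dims <- as.integer(grid_dims)
  if (d_true < 2) stop("`d_true` must be >= 2", call. = FALSE)
  sigma <- blob_fwhm / (2 * sqrt(2 * log(2)))
  margin <- ceiling(blob_fwhm / 2)
  lo <- rep(1 + margin, 3L)
  hi <- grid_dims - margin
  if (any(hi < lo))
    stop("grid too small for the requested blob size", call. = FALSE)
  grid <- voxel_grid(grid_dims, voxel_size = c(2, 2, 2))
  coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                  y = seq_len(grid_dims[2]),
                                  z = seq_len(grid_dims[3])))
  v <- nrow(coords)
  maps <- with_local_seed(seed, {
    out <- matrix(0, v, d_true)
    for (i in seq_len(d_true)) {
      placed <- FALSE
      for (attempt in seq_len(500L)) {
        ctr <- vapply(1:3, function(a) {
          if (lo[a] >= hi[a]) lo[a] else sample(seq(lo[a], hi[a]), 1L)
        }, numeric(1))
        d2 <- colSums((t(coords) - ctr)^2)
        m <- exp(-d2 / (2 * sigma^2))
        m[m < 0.05] <- 0
        if (sum(m > 0) < 2) next
        ok <- TRUE
        if (i > 1) {
          for (j in seq_len(i - 1L)) {
            ov <- sum(m * out[, j]) / sqrt(sum(m^2) * sum(out[, j]^2))
            if (ov >= max_overlap) { ok <- FALSE; break }
          }
        }
        if (ok) { out[, i] <- m; placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("grid too small to place %d blobs with overlap < %.2f",
                     d_true, max_overlap), call. = FALSE)
    }
    out
  })
  effect_masks <- lapply(seq_len(d_true), function(i)
    which(maps[, i] > 0.5 * max(maps[, i])))
  list(maps = maps, effect_masks = effect_masks, grid = grid)
}

#' Ground truth for a simulated resting-state study
#'
#' Defines the generative model: smooth nonnegative group network maps mixed
#' linearly into voxel timeseries, network timecourses drawn from a structured
#' inter-network precision matrix, subject network amplitudes linearly coupled
#' to a behavioural score (plus subject-level amplitude dispersion, so the
#' planted amplitude-behaviour correlation is a tunable quantity rather than
#' +/-1), localized behaviour-coupled spatial-map deviations, and i.i.d.
#' Gaussian sensor noise.
#'
#' Couplings act on the standardized behaviour score; the emitted `behavior`
#' column is an affine SSRT-like transform (mean 220 ms, sd 30 ms), which
#' leaves all Pearson-correlation analyses unchanged.
#'
#' @param n_subjects number of subjects.
#' @param grid_dims integer(3) grid dimensions.
#' @param d_true number of networks.
#' @param blob_fwhm blob FWHM, voxels.
#' @param base_amplitudes positive baseline network amplitudes `alpha_i`.
#' @param amplitude_slopes coupling `beta_i` of amplitude to the standardized
#'   score; negative values plant the "higher amplitude, faster inhibition"
#'   direction. The planted correlation is
#'   `beta_i / sqrt(beta_i^2 + amplitude_noise_sd^2)`.
#' @param amplitude_noise_sd sd of subject-level amplitude dispersion.
#' @param spatial_slopes coupling `gamma_i` of map weight to the standardized
#'   score on each component's effect-mask voxels.
#' @param precision d x d symmetric positive-definite inter-network precision
#'   matrix; `NULL` gives a chain (tridiagonal) structure with off-diagonal
#'   -0.35, i.e. direct links only between neighbouring networks.
#' @param noise_sd sd of the i.i.d. Gaussian sensor noise.
#' @param seed integer seed; the truth is a pure function of the arguments.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_subjects = 30, grid_dims = c(16, 16, 8),
                             d_true = 5, blob_fwhm = 3,
                             base_amplitudes = rep(1, d_true),
                             amplitude_slopes = c(rep(-0.15, 3), rep(0, d_true - 3)),
                             amplitude_noise_sd = 0.26,
                             spatial_slopes = c(rep(-0.08, 2), rep(0, d_true - 2)),
                             precision = NULL, noise_sd = 1, seed = 1) {
  stopifnot(n_subjects >= 3, d_true >= 2,
            length(base_amplitudes) == d_true,
            length(amplitude_slopes) == d_true,
            length(spatial_slopes) == d_true,
            all(base_amplitudes > 0), amplitude_noise_sd >= 0, noise_sd >= 0)
  if (is.null(precision)) {
    precision <- diag(d_true)
    for (i in seq_len(d_true - 1)) {
      precision[i, i + 1] <- -0.35
      precision[i + 1, i] <- -0.35
    }
  }
  precision <- as.matrix(precision)
  if (!isTRUE(all.equal(precision, t(precision), tolerance = 1e-10)))
    stop("precision must be symmetric", call. = FALSE)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision must be positive definite", call. = FALSE)

  gm <- make_group_maps(grid_dims, d_true, blob_fwhm = blob_fwhm, seed = seed)
  for (i in seq_len(d_true))
    stopifnot(all(gm$maps[gm$effect_masks[[i]], i] > 0))

  z <- with_local_seed(seed + 1L, as.numeric(scale(stats::rnorm(n_subjects))))
  behavior <- 220 + 30 * z
  # deterministic-part positivity check (spec invariant); the amplitude jitter
  # is checked again at simulation time
  realized <- outer(z, amplitude_slopes) +
    matrix(base_amplitudes, n_subjects, d_true, byrow = TRUE)
  if (any(realized <= 0))
    stop("realized subject amplitudes alpha_i + beta_i * b_s are not all positive",
         call. = FALSE)

  structure(list(
    group_maps = gm$maps, effect_masks = gm$effect_masks, grid = gm$grid,
    n_subjects = n_subjects, d_true = d_true,
    behavior = behavior, behavior_z = z,
    base_amplitudes = base_amplitudes, amplitude_slopes = amplitude_slopes,
    amplitude_noise_sd = amplitude_noise_sd, spatial_slopes = spatial_slopes,
    precision = precision, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d subjects, %d networks on %s grid, noise sd %g\n",
              x$n_subjects, x$d_true, paste(x$grid$dims, collapse = "x"), x$noise_sd))
  cat(sprintf("  planted amplitude correlations: %s\n",
              paste(sprintf("%.2f", x$amplitude_slopes /
                              sqrt(x$amplitude_slopes^2 + x$amplitude_noise_sd^2)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate one subject's 4D timeseries
#'
#' Draws network timecourses from the truth's inter-network precision, rescales
#' each column to the subject's realized amplitude (exactly, by sample sd),
#' perturbs the group maps on the effect-mask voxels by `gamma_i * z_s`, mixes
#' `data = T %*% t(maps_s)` and adds i.i.d. Gaussian noise.
#'
#' @param truth a [simulation_truth()].
#' @param subject_index subject number in `1..n_subjects`.
#' @param n_timepoints number of volumes (> `d_true`).
#' @param seed base seed; the subject uses `seed + subject_index` so subjects
#'   are independent yet individually reproducible.
#' @param tr repetition time, seconds.
#' @param drift_amplitude optional amplitude of an added low-frequency
#'   sinusoid (for exercising the high-pass filter); 0 disables.
#' @param drift_period period of the drift sinusoid, seconds.
#' @return list with `dataset` (a [masked_dataset()]), `timeseries` (the true
#'   `n_timepoints x d_true` timecourses), `true_amplitudes`, and `maps`
#'   (the subject's true spatial maps, voxels x d_true).
#' @export
simulate_subject <- function(truth, subject_index, n_timepoints = 230,
                             seed = truth$seed, tr = 2,
                             drift_amplitude = 0, drift_period = 200) {
  stopifnot(inherits(truth, "simulation_truth"),
            subject_index >= 1, subject_index <= truth$n_subjects)
  d <- truth$d_true
  if (n_timepoints <= d) stop("`n_timepoints` must exceed `d_true`", call. = FALSE)
  z_s <- truth$behavior_z[subject_index]
  with_local_seed(seed + subject_index, {
    eta <- stats::rnorm(d, sd = truth$amplitude_noise_sd)
    target_sd <- truth$base_amplitudes + truth$amplitude_slopes * z_s + eta
    if (any(target_sd <= 0))
      stop(sprintf("non-positive realized amplitude for component %d of subject %d",
                   which(target_sd <= 0)[1], subject_index), call. = FALSE)
    Sigma <- solve(truth$precision)
    L <- chol(Sigma)
    T_s <- matrix(stats::rnorm(n_timepoints * d), n_timepoints, d) %*% L
    T_s <- sweep(T_s, 2L, colMeans(T_s))
    sds <- apply(T_s, 2L, stats::sd)
    T_s <- sweep(T_s, 2L, target_sd / sds, "*")
    maps_s <- truth$group_maps
    for (i in seq_len(d)) {
      idx <- truth$effect_masks[[i]]
      maps_s[idx, i] <- maps_s[idx, i] + truth$spatial_slopes[i] * z_s
    }
    data <- T_s %*% t(maps_s)
    if (truth$noise_sd > 0)
      data <- data + truth$noise_sd *
        matrix(stats::rnorm(length(data)), nrow(data), ncol(data))
    if (drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      drift <- drift_amplitude * sin(2 * pi * (seq_len(n_timepoints) - 1) * tr /
                                       drift_period + phase)
      data <- data + drift
    }
    list(dataset = masked_dataset(data, truth$grid, tr = tr,
                                  subject_id = sprintf("sub-%02d", subject_index)),
         timeseries = T_s, true_amplitudes = target_sd, maps = maps_s)
  })
}

#' Simulate a full multi-subject study
#'
#' @inheritParams simulate_subject
#' @param truth a [simulation_truth()].
#' @param keep_truth_series keep each subject's true timecourses and maps
#'   (memory permitting)?
#' @return list with `datasets` (list of [masked_dataset()]), `behavior`
#'   (tibble: subject_id, score), `truth`, and, if requested,
#'   `true_timeseries`, `true_amplitudes` (subjects x d matrix), `true_maps`.
#' @export
simulate_study <- function(truth, n_timepoints = 230, seed = truth$seed, tr = 2,
                           drift_amplitude = 0, drift_period = 200,
                           keep_truth_series = FALSE) {
  subs <- lapply(seq_len(truth$n_subjects), function(s)
    simulate_subject(truth, s, n_timepoints = n_timepoints, seed = seed, tr = tr,
                     drift_amplitude = drift_amplitude, drift_period = drift_period))
  out <- list(
    datasets = lapply(subs, `[[`, "dataset"),
    behavior = tibble::tibble(
      subject_id = vapply(subs, function(s) s$dataset$subject_id, character(1)),
      score = truth$behavior),
    true_amplitudes = do.call(rbind, lapply(subs, `[[`, "true_amplitudes")),
    truth = truth)
  if (keep_truth_series) {
    out$true_timeseries <- lapply(subs, `[[`, "timeseries")
    out$true_maps <- lapply(subs, `[[`, "maps")
  }
  out
}

#' Write a simulated study to disk
#'
#' Writes one 4D NIfTI per subject, the mask, `behavior.tsv`
#' (subject_id, score) and `truth.json` with the generator parameters.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- study$truth$grid
  write_volumes(grid$mask * 1L, file.path(dir, "mask.nii.gz"), grid,
                datatype = "uint8")
  for (ds in study$datasets)
    write_volumes(ds$data, file.path(dir, paste0(ds$subject_id, ".nii.gz")),
                  grid, tr = ds$tr)
  utils::write.table(study$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- study$truth
  truth_json <- list(
    n_subjects = tr$n_subjects, d_true = tr$d_true, grid_dims = tr$grid$dims,
    base_amplitudes = tr$base_amplitudes, amplitude_slopes = tr$amplitude_slopes,
    amplitude_noise_sd = tr$amplitude_noise_sd, spatial_slopes = tr$spatial_slopes,
    precision = tr$precision, noise_sd = tr$noise_sd, seed = tr$seed,
    behavior = tr$behavior)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  } else {
    saveRDS(truth_json, file.path(dir, "truth.rds"))
  }
  invisible(dir)
}
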