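#' Pipeline configuration
#'
#' All tunable parameters of the three-step segmentation with their defaults:
#' noise sampling box 25 x 50 pixels, four fuzzy clusters with fuzziness 2,
#' 50-pixel area filter, disk element of radius 2; stopping criterion and
#' iteration caps for the clustering; adaptive region-growing stop rule
#' unless `srg_stop_delta` is set. Values can be overridden by arguments or
#' loaded from a YAML file with [read_pipeline_config()] (explicit arguments
#' win over file values).
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    noise_box_rows = 25L,
    noise_box_cols = 50L,
    noise_clamp_g = FALSE,
    noise_tail_tol = 1e-6,
    noise_max_iter = 200L,
    fcm_clusters = 4L,
    fcm_fuzziness = 2,
    fcm_epsilon = 1e-5,
    fcm_max_iter = 100L,
    fcm_seed = 1L,
    fcm_backend = "fcm",
    srg_stop_delta = NULL,
    srg_connectivity = 4L,
    label_connectivity = 8L,
    disk_radius = 2L,
    min_area = 50L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- defaults
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are config names.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals[names(list(...))] <- list(...)
  do.call(pipeline_config, vals)
}

#' Run the full segmentation pipeline
#'
#' Executes the three-step method end to end: per-slice statistical noise
#' subtraction ([fit_noise()], [apply_threshold()]), fuzzy C-means
#' ventilation clustering with the negligible class discarded
#' ([fcm_cluster()], [refine_mask()]), and semiautomatic airway removal with
#' templated morphological cleanup ([remove_airways()]); then quantifies the
#' ventilated lung volume ([compute_vlv()]). Clustering runs over the pixels
#' inside the union of the per-slice initial masks across the whole volume.
#'
#' The run log records every stage's parameters and timing, so a run is
#' fully reproducible from its log.
#'
#' @param stack an `image_stack` (or a NIfTI path, read via [read_stack()]).
#' @param seeds list of [seed_spec()] objects, a path to a JSON sidecar, or
#'   `NULL`. With no seeds the airway stage warns and applies the
#'   morphological cleanup only.
#' @param config a [pipeline_config()].
#' @param keep_intermediates keep the initial and refined masks in the result.
#' @return a list of class `pipeline_result`: `mask` (final `mask_stack`),
#'   `labels` (per-slice integer class maps on the refined mask), `vlv`
#'   ([compute_vlv()] result), `noise_fits`, `cluster_model`, `airway`
#'   (removed-airway `mask_stack`), `log`, and (optionally) `initial`,
#'   `refined`.
#' @export
run_pipeline <- function(stack, seeds = NULL, config = pipeline_config(),
                         keep_intermediates = FALSE) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"), inherits(config, "pipeline_config"))
  if (is.character(seeds)) seeds <- read_seed_specs(seeds)
  if (is.null(seeds)) seeds <- list()
  log <- list()
  stage <- function(name, params, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log[[name]] <<- list(params = params,
                         elapsed_s = proc.time()[["elapsed"]] - t0)
    res
  }

  fits <- stage("noise_subtraction",
                config[c("noise_box_rows", "noise_box_cols", "noise_clamp_g",
                         "noise_tail_tol")], {
    fit_noise(stack, box_rows = config$noise_box_rows,
              box_cols = config$noise_box_cols,
              clamp_g = config$noise_clamp_g,
              tail_tol = config$noise_tail_tol,
              max_iter = config$noise_max_iter)
  })
  initial <- apply_threshold(stack, fits)

  refined_out <- stage("ventilation_clustering",
                       config[c("fcm_clusters", "fcm_fuzziness", "fcm_epsilon",
                                "fcm_max_iter", "fcm_seed", "fcm_backend")], {
    vals <- masked_values(stack, initial)
    model <- fcm_cluster(vals, C = config$fcm_clusters,
                         m = config$fcm_fuzziness,
                         epsilon = config$fcm_epsilon,
                         max_iter = config$fcm_max_iter,
                         seed = config$fcm_seed,
                         backend = config$fcm_backend)
    c(refine_mask(stack, initial, model), list(model = model))
  })

  if (!length(seeds)) {
    warning("no airway seed specs supplied: applying morphological cleanup only",
            call. = FALSE)
  }
  sigmas <- vapply(fits, function(f) f$sigma, numeric(1L))
  removal <- stage("airway_removal",
                   c(config[c("srg_stop_delta", "srg_connectivity",
                              "label_connectivity", "disk_radius", "min_area")],
                     list(n_seeds = length(seeds))), {
    remove_airways(stack, refined_out$mask, specs = seeds,
                   stop_delta = config$srg_stop_delta, sigmas = sigmas,
                   se = disk_element(config$disk_radius),
                   min_area = config$min_area,
                   grow_connectivity = config$srg_connectivity,
                   label_connectivity = config$label_connectivity)
  })

  vlv <- compute_vlv(removal$mask)
  out <- list(mask = removal$mask, labels = refined_out$labels, vlv = vlv,
              noise_fits = fits, cluster_model = refined_out$model,
              airway = removal$airway, log = log)
  if (keep_intermediates) {
    out$initial <- initial
    out$refined <- refined_out$mask
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  taus <- vapply(x$noise_fits, function(f) f$tau, integer(1L))
  cat(sprintf("  thresholds: %s\n", paste(taus, collapse = " ")))
  cat(sprintf("  cluster centres: %s\n",
              paste(sprintf("%.4g", x$cluster_model$centers), collapse = ", ")))
  cat(sprintf("  VLV: %.3f L\n", x$vlv$total_l))
  for (nm in names(x$log)) {
    cat(sprintf("  stage %s: %.2fs\n", nm, x$log[[nm]]$elapsed_s))
  }
  invisible(x)
}
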