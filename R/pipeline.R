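# End-to-end orchestration: frames in, motion-class maps, read-out fields,
# velocity gradients, danger zones and MSTd pattern responses out, plus the
# disk-writing run front-end with its YAML config and JSON manifest.

#' Run the full motion model on a frame stack
#'
#' Drives all stages per frame pair: Gabor filtering and initial motion,
#' the V1 cascade (with MT feedback from the previous pair), MT integration
#' and soft competition, per-cell read-out and classification, the 3-frame
#' temporal consistency filter, and - optionally - MSTd pattern matching
#' and velocity gradients.
#'
#' @param frames a [frame_stack()] (or `H x W x T` array).
#' @param params a [motion_model_params()]. A `NULL` `theta_motion` is
#'   calibrated with [calibrate_motion_threshold()].
#' @param mstd compute MSTd pattern responses.
#' @param gradients compute velocity-gradient fields.
#' @param feedback include MT-to-V1 feedback.
#' @param keep_fields retain the per-frame V1/MT likelihood arrays in the
#'   result (memory-hungry for large videos).
#' @return object of class `"crowd_motion"`: list with `readout` (list of
#'   [read_out_field()] per frame pair), `labels` (MT-resolution label
#'   matrices), `class_maps` (stabilized frame-resolution maps),
#'   `danger` (logical maps), `gradients`, `mstd` (per-pair normalized
#'   pattern responses), `templates`, `params`, `theta_motion`, and - when
#'   `keep_fields` - `z3_v1`, `z3_mt`.
#' @export
run_pipeline <- function(frames, params = motion_model_params(),
                         mstd = TRUE, gradients = TRUE, feedback = TRUE,
                         keep_fields = FALSE) {
  frames <- as_frame_stack(frames)
  H <- dim(frames)[1]; W <- dim(frames)[2]
  grid <- grid_from_params(params)
  theta <- params$theta_motion
  if (is.null(theta)) theta <- calibrate_motion_threshold(params)

  v1 <- run_v1(frames, params, feedback = feedback)
  z3_mt <- v1$z3_mt
  if (is.null(z3_mt)) {
    z3_mt <- lapply(v1$z3_v1, mt_frame, params = params)
  }
  np <- length(z3_mt)

  readout <- vector("list", np)
  labels <- vector("list", np)
  for (t in seq_len(np)) {
    readout[[t]] <- read_out_field(z3_mt[[t]], grid, theta,
                                   params$max_motions)
    labels[[t]] <- classify_motions(readout[[t]])
  }
  class_maps <- stabilize_and_upsample(labels, c(H, W))

  danger <- vector("list", np)
  for (t in seq_len(np)) {
    sp_up <- upsample_matrix(readout[[t]]$speed_max, c(H, W))
    danger[[t]] <- danger_zones(class_maps[[t]], sp_up, params$theta_slow)
  }

  grads <- NULL
  if (gradients) grads <- lapply(readout, velocity_gradients)

  mstd_out <- NULL
  templates <- NULL
  if (mstd) {
    dmt <- dim(z3_mt[[1]])
    templates <- build_templates(dmt[1], dmt[2], grid$directions, params)
    r1 <- NULL
    mstd_out <- vector("list", np)
    for (t in seq_len(np)) {
      r1 <- mstd_integrate(z3_mt[[t]], templates, r1, params)
      mstd_out[[t]] <- mstd_normalize(r1, params)
      mstd_out[[t]]$r1 <- r1
    }
  }

  out <- list(readout = readout, labels = labels, class_maps = class_maps,
              danger = danger, gradients = grads, mstd = mstd_out,
              templates = templates, params = params, theta_motion = theta,
              frame_size = c(H, W))
  if (keep_fields) {
    out$z3_v1 <- v1$z3_v1
    out$z3_mt <- z3_mt
  }
  class(out) <- "crowd_motion"
  out
}

# Nearest-neighbor upsampling of a matrix to frame resolution.
upsample_matrix <- function(m, size_hw) {
  H <- size_hw[1]; W <- size_hw[2]
  iy <- pmin(pmax(round((seq_len(H) - 1) / (H / nrow(m))) + 1, 1), nrow(m))
  ix <- pmin(pmax(round((seq_len(W) - 1) / (W / ncol(m))) + 1, 1), ncol(m))
  m[iy, ix, drop = FALSE]
}

#' @export
print.crowd_motion <- function(x, ...) {
  np <- length(x$readout)
  last <- x$class_maps[[np]]
  cat(sprintf("<crowd_motion> %d frame pairs, frames %d x %d px\n",
              np, x$frame_size[1], x$frame_size[2]))
  cat(sprintf(
    "  last stabilized map: %.1f%% none, %.1f%% single, %.1f%% multiple\n",
    100 * mean(last == "none"), 100 * mean(last == "single"),
    100 * mean(last == "multiple")
  ))
  if (!is.null(x$mstd)) {
    disp <- x$mstd[[np]]$display
    best <- arrayInd(which.max(disp), dim(disp))
    cat(sprintf("  dominant MSTd pattern: delta = %d deg at anchor %d\n",
                x$templates$deltas[best[2]], best[1]))
  }
  invisible(x)
}

#' Summarize a pipeline result
#'
#' Per-frame fractions of the three motion classes (over stabilized
#' frame-resolution maps) and the danger-pixel fraction.
#'
#' @param object a `"crowd_motion"` result.
#' @param ... unused.
#' @return data frame with one row per frame pair.
#' @export
summary.crowd_motion <- function(object, ...) {
  np <- length(object$class_maps)
  do.call(rbind, lapply(seq_len(np), function(t) {
    m <- object$class_maps[[t]]
    data.frame(
      frame = t,
      frac_none = mean(m == "none"),
      frac_single = mean(m == "single"),
      frac_multiple = mean(m == "multiple"),
      frac_danger = mean(object$danger[[t]])
    )
  }))
}

#' Run configuration
#'
#' All run settings in one YAML-serializable list: input/output paths, the
#' model parameters, thresholds, stage toggles and seed.
#'
#' @param input input frame directory or pattern (may be `NULL` for
#'   in-memory runs).
#' @param output output directory.
#' @param params a [motion_model_params()].
#' @param mstd,gradients,feedback stage toggles.
#' @param seed integer seed recorded for reproducibility.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, output = "results",
                       params = motion_model_params(), mstd = TRUE,
                       gradients = TRUE, feedback = TRUE, seed = 1) {
  structure(list(input = input, output = output, params = unclass(params),
                 mstd = mstd, gradients = gradients, feedback = feedback,
                 seed = seed),
            class = "run_config")
}

#' Read / write run configurations as YAML
#'
#' `write_run_config()` and `read_run_config()` round-trip losslessly.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- raw$params
  p$speeds <- as.numeric(p$speeds)
  p$directions <- as.numeric(p$directions)
  params <- do.call(motion_model_params, p)
  run_config(input = raw$input, output = raw$output, params = params,
             mstd = raw$mstd, gradients = raw$gradients,
             feedback = raw$feedback, seed = raw$seed)
}

#' Run the pipeline from a config and write the artifact bundle
#'
#' Loads the input frames, runs [run_pipeline()], and writes: per-frame
#' class-map PNGs and danger-map PNGs, gradient renderings, the MSTd
#' pattern CSV, MT velocity-field CSV, the per-frame summary CSV, and a
#' JSON manifest with the config (and its hash), seed and package version.
#' Identical config and seed reproduce identical outputs.
#'
#' @param config a [run_config()] with a valid `input`.
#' @param frames optionally, an in-memory [frame_stack()] overriding
#'   `config$input`.
#' @return the `"crowd_motion"` result, invisibly; side effect: files
#'   under `config$output`.
#' @export
run_pipeline_to_disk <- function(config, frames = NULL) {
  if (is.null(frames)) {
    if (is.null(config$input)) stop("config has no input")
    frames <- load_frames(config$input)
  }
  out_dir <- config$output
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- do.call(motion_model_params, config$params)
  res <- withCallingHandlers(
    run_pipeline(frames, params, mstd = config$mstd,
                 gradients = config$gradients, feedback = config$feedback),
    error = function(e) stop("pipeline stage failed: ", conditionMessage(e))
  )
  np <- length(res$class_maps)
  wd <- max(4, nchar(np))
  for (t in seq_len(np)) {
    write_map_png(encode_class_map(res$class_maps[[t]]),
                  file.path(out_dir, sprintf("class_%0*d.png", wd, t)))
    write_map_png(res$danger[[t]],
                  file.path(out_dir, sprintf("danger_%0*d.png", wd, t)))
    if (!is.null(res$gradients)) {
      render_gradient_field(res$gradients[[t]],
                            file.path(out_dir,
                                      sprintf("gradient_%0*d.png", wd, t)))
    }
  }
  if (!is.null(res$mstd)) {
    mstd_to_csv(res$mstd, res$templates, file.path(out_dir, "mstd.csv"))
  }
  utils::write.csv(summary(res), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    config = unclass(config),
    config_hash = fnv1a32(as.character(cfg_json)),
    seed = config$seed,
    theta_motion = res$theta_motion,
    n_frames = n_frames(frames),
    package_version = as.character(utils::packageVersion("crowdmotion"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
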