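#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for a full evaluation run:
#' phantom simulation, cut detection, repositioning quantification, screw
#' quantification and evaluation. Accepts a YAML file path or a named list;
#' unknown keys are rejected. All module defaults mirror the published
#' hyperparameter sets (coarse/fine registration scales, Hough knobs,
#' segmenter spec).
#'
#' @param config Path to a YAML file or a named list of overrides.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    out = NULL,
    simulate = TRUE,
    inputs = list(),
    phantom = list(),
    backends = list(cuts = "oracle", pelvis = "oracle"),
    coarse_registration = list(),
    fine_registration = list(),
    hough = list(),
    head_axis = c(0, 0, 1),
    hu_threshold = 2500
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (nm in names(defaults))  # modifyList drops NULL-valued keys
    if (!nm %in% names(cfg)) cfg[nm] <- list(defaults[[nm]])
  cfg <- cfg[names(defaults)]
  cfg$inputs <- cfg$inputs[!vapply(cfg$inputs, is.null, logical(1))]
  check_block <- function(block, fn, label) {
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad))
      stop("unknown keys in ", label, ": ", paste(bad, collapse = ", "))
  }
  check_block(cfg$phantom, phantom_config, "phantom")
  check_block(cfg$coarse_registration, registration_params, "coarse_registration")
  check_block(cfg$fine_registration, registration_params, "fine_registration")
  check_block(cfg$hough, hough_params, "hough")
  if (!all(cfg$backends$cuts %in% c("oracle", "network")) ||
      !all(cfg$backends$pelvis %in% c("oracle", "network")))
    stop("backends must be 'oracle' or 'network'")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path Output YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage_run <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
  message(sprintf("stage %-12s %6.1f s", stage,
                  proc.time()[["elapsed"]] - t0))
  res
}

plane_to_list <- function(p) list(center = p$center, normal = p$normal)

#' Run the full postoperative evaluation pipeline
#'
#' Executes simulate, detect-cuts, reposition, screws and evaluate in
#' order, writing each stage's outputs (when `out` is set) before the next
#' stage begins. With oracle backends the whole run is deterministic for a
#' fixed seed. Currently the pipeline consumes simulated phantoms (with
#' full ground truth); pass trained segmenter handles via `cut_model` /
#' `pelvis_model` to exercise the network backends.
#'
#' @param config A [pipeline_config()], YAML path or named list.
#' @param cut_model,pelvis_model Optional trained segmenters for the
#'   network backends.
#' @return The evaluation report (named list), invisibly also written to
#'   `<out>/report.json` together with per-stage artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), cut_model = NULL,
                         pelvis_model = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out <- cfg$out
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit <- function(name, writer) if (!is.null(out)) writer(file.path(out, name))

  # -- simulate / ingest ------------------------------------------------
  sim <- stage_run("simulate", {
    if (cfg$simulate) {
      ph_args <- utils::modifyList(cfg$phantom, list(seed = cfg$seed))
      make_phantom(do.call(phantom_config, ph_args))
    } else {
      if (is.null(cfg$inputs[["pre"]]) || is.null(cfg$inputs[["post"]]))
        stop("simulate is disabled and pre/post CT paths are missing")
      list(pre = read_volume(cfg$inputs$pre),
           post = read_volume(cfg$inputs$post),
           truth = NULL)
    }
  })
  if (cfg$simulate) {
    emit("pre.nii.gz", function(p) write_volume(sim$pre, p))
    emit("post.nii.gz", function(p) write_volume(sim$post, p))
    emit("cut_labels.nii.gz", function(p) write_volume(sim$truth$cut_labels, p))
    emit("fragment_label.nii.gz",
         function(p) write_volume(sim$truth$fragment_label, p))
    emit("truth.json", function(p) jsonlite::write_json(list(
      planes = lapply(sim$truth$planes, plane_to_list),
      fragment_transform = unclass(sim$truth$fragment_transform),
      global_transform = unclass(sim$truth$global_transform),
      screws = lapply(sim$truth$screws, function(s)
        s[c("direction", "entry", "length", "radius")]),
      seed = sim$truth$seed), p, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"))
  }

  # -- detect-cuts ------------------------------------------------------
  det <- stage_run("detect-cuts", detect_planes(
    sim$post, backend = cfg$backends$cuts, truth = sim$truth,
    model = cut_model))
  emit("planes.json", function(p) jsonlite::write_json(
    list(planes = lapply(det$planes, function(x)
      if (is.null(x)) NULL else plane_to_list(x)), failed = det$failed),
    p, auto_unbox = TRUE, digits = NA, null = "null"))

  # -- reposition -------------------------------------------------------
  repo <- stage_run("reposition", {
    if (any(det$failed)) stop("cannot reposition: undetected cut plane(s)")
    pelvis_mask <- if (cfg$backends$pelvis == "oracle") {
      if (is.null(sim$truth)) stop("oracle pelvis backend requires phantom truth")
      sim$truth$pre_bone_mask
    } else {
      if (is.null(pelvis_model)) stop("network pelvis backend requires a model")
      segment_with_network(pelvis_model, sim$pre)
    }
    post_mask <- if (cfg$backends$pelvis == "oracle") sim$truth$post_bone_mask
                 else NULL
    quantify_repositioning(
      sim$pre, sim$post, det$planes, pelvis_mask,
      coarse_params = do.call(registration_params, cfg$coarse_registration),
      fine_params = do.call(fine_registration_params, cfg$fine_registration),
      post_bone_mask = post_mask)
  })
  emit("transforms.json", function(p) jsonlite::write_json(
    list(T1 = unclass(repo$T1), T2 = unclass(repo$T2),
         total = unclass(repo$total), report = repo$report),
    p, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"))

  # -- screws -----------------------------------------------------------
  screws <- stage_run("screws", quantify_screws(
    sim$post, params = do.call(hough_params, cfg$hough),
    head_axis = cfg$head_axis, hu_threshold = cfg$hu_threshold))
  emit("screws.json", function(p) jsonlite::write_json(
    lapply(screws, unclass), p, auto_unbox = TRUE, digits = NA))

  # -- evaluate ---------------------------------------------------------
  report <- stage_run("evaluate", {
    rep <- list(seed = cfg$seed, n_screws_detected = length(screws))
    if (!is.null(sim$truth)) {
      tr <- sim$truth
      plane_err <- lapply(1:4, function(j) {
        est <- det$planes[[j]]; ref <- tr$planes[[j]]
        list(normal_angle_deg = normal_angle(est$normal, ref$normal),
             center_offset_mm = abs(sum((est$center - ref$center) * ref$normal)))
      })
      surf <- fragment_surface_points(tr)
      rep$planes <- plane_err
      rep$registration <- list(
        coarse_mae_mm = registration_errors(surf, repo$T1, tr$global_transform),
        fragment_mae_mm = registration_errors(surf, repo$total,
                                              tr$fragment_transform),
        coarse_converged = repo$report$coarse$converged,
        fine_converged = repo$report$fine$converged)
      se <- screw_errors(screws, tr$screws)
      rep$screws <- list(mean_entry_mm = se$mean_head_mm,
                         mean_axis_deg = se$mean_axis_deg,
                         n_matched = nrow(se$pairs),
                         n_truth = length(tr$screws))
    }
    rep
  })
  emit("report.json", function(p) write_report(report, p))
  invisible(report)
}
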