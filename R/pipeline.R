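#' Run configuration
#'
#' Builds/validates the configuration driving [run_pipeline()]. A config is
#' a named list with blocks `phantom` (or explicit `paths` to a mask, point
#' clouds and landmarks), `material`, `mesh`, `solver` and `evaluate`;
#' missing entries fall back to the documented defaults. YAML or JSON files
#' are accepted.
#'
#' @param x a named list, a path to a YAML/JSON file, or `NULL` (defaults).
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(x = NULL) {
  cfg <- if (is.null(x)) list()
  else if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    if (grepl("\\.json$", x, ignore.case = TRUE)) jsonlite::read_json(x)
    else yaml::read_yaml(x)
  } else x
  cfg$mesh <- utils::modifyList(list(max_edge = 5, min_voxels = 1), cfg$mesh %||% list())
  cfg$solver <- utils::modifyList(list(duration = 30, increments = 10,
                                       rtol = 1e-6, atol = 1e-10,
                                       max_iter = 25),
                                  cfg$solver %||% list())
  cfg$evaluate <- utils::modifyList(list(fine_ground_truth = FALSE,
                                         fine_max_edge = 2.5,
                                         denominator = "measured"),
                                    cfg$evaluate %||% list())
  if (is.null(cfg$phantom)) cfg$phantom <- list()
  if (!is.null(cfg$paths)) {
    for (p in unlist(cfg$paths))
      if (!file.exists(p)) stop("config-validation error: missing input ", p)
  }
  cfg$seed <- cfg$seed %||% 1L
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full retraction-simulation pipeline
#'
#' Phantom (or file inputs) -> octree mesh + enrichment -> tracked
#' boundary conditions -> hyper-viscoelastic XFEM solve -> dense field +
#' predicted image -> metrics. Each stage logs its parameters and wall
#' time; artifacts (mesh `.vtu`, BC CSV, DOF archive JSON, predicted image,
#' metrics JSON/CSV) are written to `out_dir`.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param verbose print stage progress.
#' @return list with the phantom, enriched mesh, bc set, solved field,
#'   dense field, predicted image/mask and (when ground truth is available)
#'   the [metrics_report()].
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, verbose = TRUE) {
  cfg <- run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("[%s] done in %.1f s", name, proc.time()[3] - t0)
    out
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  phargs <- cfg$phantom
  phargs$seed <- phargs$seed %||% cfg$seed
  phantom <- stage("phantom", generate_phantom(do.call(phantom_config, phargs)))
  material <- material_from_config(cfg$material)

  enr <- stage("mesh", {
    mesh <- build_octree_hex_mesh(phantom$mask, max_edge = cfg$mesh$max_edge,
                                  min_voxels = cfg$mesh$min_voxels)
    say("  %d nodes, %d elements", nrow(mesh$nodes), nrow(mesh$elems))
    classify_and_enrich(mesh, phantom$crack)
  })
  bcs <- stage("bcs", phantom_bcs(phantom, enr))
  field <- stage("solve", {
    idata <- integration_data(enr, material)
    solve_retraction(idata, bcs, duration = cfg$solver$duration,
                     increments = cfg$solver$increments,
                     rtol = cfg$solver$rtol, atol = cfg$solver$atol,
                     max_iter = cfg$solver$max_iter)
  })
  warped <- stage("warp", {
    dense <- dense_displacement_field(field, phantom$intensity)
    list(dense = dense,
         image = warp_image_backward(phantom$intensity, field),
         mask = warp_image_backward(phantom$mask, field, background = 0))
  })

  metrics <- NULL
  if (isTRUE(cfg$evaluate$fine_ground_truth)) {
    metrics <- stage("evaluate", {
      fenr <- classify_and_enrich(
        build_octree_hex_mesh(phantom$mask,
                              max_edge = cfg$evaluate$fine_max_edge),
        phantom$crack)
      fbcs <- phantom_bcs(phantom, fenr)
      ffield <- solve_retraction(integration_data(fenr, material), fbcs,
                                 duration = cfg$solver$duration,
                                 increments = cfg$solver$increments)
      lm <- ground_truth_displacements(phantom, ffield)
      pre <- lm_coords(lm, "pre")
      lm <- landmark_set(lm$id, pre,
                         predicted = pre + displacement_at(enr, field$dofs, pre),
                         measured = lm_coords(lm, "measured"))
      truth_mask <- warp_image_backward(phantom$mask, ffield, background = 0)
      metrics_report(lm, mask_predicted = vol3d(warped$mask$data > 0.5,
                                                warped$mask$spacing,
                                                warped$mask$origin),
                     mask_measured = vol3d(truth_mask$data > 0.5,
                                           truth_mask$spacing,
                                           truth_mask$origin),
                     denominator = cfg$evaluate$denominator)
    })
  }

  if (!is.null(out_dir)) {
    stage("write", {
      write_mesh_vtu(enr, file.path(out_dir, "mesh.vtu"),
                     displacements = nodal_displacements(field))
      write.csv(bcs$crack_face_bcs, file.path(out_dir, "bcs.csv"),
                row.names = FALSE)
      jsonlite::write_json(list(dofs = field$dofs, ndof = length(field$dofs),
                                duration = field$duration,
                                increments = field$increments),
                           file.path(out_dir, "dofs.json"), digits = NA)
      write_volume(warped$image, file.path(out_dir, "predicted.nii.gz"))
      if (!is.null(metrics)) {
        write.csv(metrics$per_landmark,
                  file.path(out_dir, "metrics_landmarks.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
          list(forecast_error_mm = metrics$forecast_error$mean,
               forecast_error_mm_r1 = metrics$forecast_error$mean.r1,
               accuracy_pct = metrics$accuracy$mean,
               accuracy_pct_r1 = metrics$accuracy$mean.r1,
               tre_initial_mm = metrics$tre_initial,
               tre_updated_mm = metrics$tre_updated,
               dsc_pct = metrics$dsc),
          file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
      }
      invisible(NULL)
    })
  }
  list(config = cfg, phantom = phantom, enr = enr, bcs = bcs, field = field,
       dense = warped$dense, predicted = warped$image,
       predicted_mask = warped$mask, metrics = metrics)
}
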