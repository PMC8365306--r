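# End-to-end synthetic experiment: phantom -> brain shift -> projection ->
# mesh -> volume-conduction solve -> recording synthesis/extraction ->
# validation statistics, over the comparison grid of projection methods x
# CSF depths. "Recorded" voltages are synthesized from a designated
# ground-truth model (true electrode positions, 0 mm CSF) plus noise, so
# parameter recovery is measurable.

#' Configuration of a synthetic validation run
#'
#' Defaults encode the study conditions: an 8 x 8 grid of 2.3 mm contacts
#' at 10 mm pitch, biphasic 1.2 ms pulses sampled at 12,207 Hz, bipolar
#' stimulation between two neighbouring contacts, CSF depths of 0, 1 and
#' 2 mm, and brain shift of a few millimetres (within the range of reported
#' median projection distances).
#'
#' @param grid_shape electrode grid (rows x cols).
#' @param pitch_mm contact spacing.
#' @param gray_thickness_mm,white_thickness_mm slab phantom layers.
#' @param extent_mm lateral phantom size.
#' @param shift a [shift_model()]; default 4 mm inward with 0.5 mm jitter.
#' @param artifact_elongation,artifact_n_voxels,artifact_axis_sd_deg CT
#'   artifact synthesis parameters (axis wobble in degrees).
#' @param stim_pair cathode/anode labels (default B4/B3).
#' @param stim_amplitude_mA stimulation amplitude I0 (default 3.50 mA).
#' @param n_pulses pulses per synthesized recording.
#' @param noise_sd_v recording noise SD (volts).
#' @param drift_v_per_s linear baseline drift (volts/s).
#' @param methods projection methods to run.
#' @param csf_depths_mm CSF depths to run (subset of 0, 1, 2).
#' @param h_fine,h_coarse mesh sizing (mm).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(grid_shape = c(8, 8), pitch_mm = 10,
                       gray_thickness_mm = 25, white_thickness_mm = 20,
                       extent_mm = c(200, 200),
                       shift = shift_model(4, 0.3, seed = 101L),
                       artifact_elongation = 4, artifact_n_voxels = 60,
                       artifact_axis_sd_deg = 5,
                       stim_pair = c("B4", "B3"), stim_amplitude_mA = 3.50,
                       n_pulses = 1000, noise_sd_v = 1e-3,
                       drift_v_per_s = 0.01,
                       methods = c("hermes", "principal_axis", "dykstra"),
                       csf_depths_mm = c(0, 1, 2),
                       h_fine = 2.5, h_coarse = 15, seed = 1L) {
  if (length(methods) < 1 || length(csf_depths_mm) < 1)
    stop("at least one method and one CSF depth required", call. = FALSE)
  structure(
    list(grid_shape = grid_shape, pitch_mm = pitch_mm,
         gray_thickness_mm = gray_thickness_mm,
         white_thickness_mm = white_thickness_mm, extent_mm = extent_mm,
         shift = shift, artifact_elongation = artifact_elongation,
         artifact_n_voxels = artifact_n_voxels,
         artifact_axis_sd_deg = artifact_axis_sd_deg,
         stim_pair = stim_pair, stim_amplitude_mA = stim_amplitude_mA,
         n_pulses = n_pulses, noise_sd_v = noise_sd_v,
         drift_v_per_s = drift_v_per_s, methods = methods,
         csf_depths_mm = csf_depths_mm, h_fine = h_fine,
         h_coarse = h_coarse, seed = as.integer(seed)),
    class = "run_config"
  )
}

# Per-contact artifact axes: inward normal with isotropic angular wobble.
artifact_axes <- function(electrodes, sd_deg, seed) {
  n <- nrow(electrodes$normals)
  with_seed(seed, {
    ax <- -electrodes$normals
    pert <- matrix(stats::rnorm(3 * n, sd = tan(sd_deg * pi / 180)), n, 3)
    pert <- pert - rowSums(pert * ax) * ax   # tangential wobble
    normalize_rows(ax + pert)
  })
}

# Mesh + stiffness for one CSF depth on the slab phantom. The silicone
# sheet and CSF film cover the nominal grid footprint (method-independent,
# so a depth's mesh is shared by all projection methods).
build_depth_model <- function(config, geometry, depth_mm) {
  half_w <- (config$grid_shape[2] - 1) * config$pitch_mm / 2 + 5
  half_h <- (config$grid_shape[1] - 1) * config$pitch_mm / 2 + 5
  csf <- if (depth_mm > 0) {
    slab_surface(c(-half_h, half_h), c(-half_w, half_w), 0, depth_mm,
                 nx = 8, ny = 8, name = "csf")
  } else NULL
  sheet <- slab_surface(c(-half_h, half_h), c(-half_w, half_w), depth_mm,
                        depth_mm + 0.5, nx = 8, ny = 8, name = "sheet")
  mesh <- tetrahedralize(
    geometry, sheet = sheet, csf = csf,
    sizing = list(h_fine = config$h_fine, h_coarse = config$h_coarse,
                  fine_xy = rbind(c(-half_h - 5, half_h + 5),
                                  c(-half_w - 5, half_w + 5)))
  )
  K <- assemble(mesh, conductivity_table())
  list(mesh = mesh, K = K, depth_mm = depth_mm)
}

# Solve one model for the configured bipolar pair and return per-contact
# voltages.
solve_model <- function(model, disks, config, tol = 1e-8) {
  mesh <- embed_electrodes(model$mesh, disks)
  stim <- stim_config(config$stim_pair[1], config$stim_pair[2],
                      config$stim_amplitude_mA)
  rhs <- make_rhs(mesh, stim)
  sol <- solve_fem(model$K, rhs, tol = tol)
  v <- electrode_voltage(sol, mesh, names(disks))
  list(voltages = v, solution = sol, mesh = mesh)
}

#' Prepare the shared context of a synthetic validation run
#'
#' Builds the phantom and electrode set (with brain shift and CT-like
#' artifacts), solves the ground-truth model (true contact positions, 0 mm
#' CSF), synthesizes the "recorded" pulse trains from the ground-truth
#' passive-contact voltages plus drift and noise, and extracts the recorded
#' quasi-static voltages.
#'
#' @param config a [run_config()].
#' @return a `run_context` list used by [run_condition()] / [run_grid()].
#' @export
prepare_context <- function(config) {
  geometry <- make_layered_slab_head(
    extent_mm = config$extent_mm,
    gray_thickness_mm = config$gray_thickness_mm,
    white_thickness_mm = config$white_thickness_mm
  )
  es <- place_grid(geometry, config$grid_shape, config$pitch_mm)
  es <- apply_brain_shift(es, config$shift)
  axes <- artifact_axes(es, config$artifact_axis_sd_deg,
                        seed = config$seed + 7L)
  es <- synthesize_artifacts(es, axes, config$artifact_elongation,
                             config$artifact_n_voxels,
                             seed = config$seed + 11L)
  passive <- setdiff(es$labels, config$stim_pair)
  # ground truth: true positions on the surface, 0 mm CSF
  truth <- projection_result("hermes", es$labels, es$true_centroids,
                             es$true_centroids)
  cg <- geometry$surfaces$closed_gray
  true_disks <- build_disks(truth, cg)
  model0 <- build_depth_model(config, geometry, 0)
  gt <- solve_model(model0, true_disks, config)
  rec <- synthesize_recording(
    gt$voltages[passive], n_pulses = config$n_pulses,
    noise_sd = config$noise_sd_v, drift_v_per_s = config$drift_v_per_s,
    stim_amplitude_mA = config$stim_amplitude_mA,
    stim_pair = config$stim_pair, seed = config$seed + 23L
  )
  v_rec <- extract_voltages(rec)$voltages
  structure(
    list(config = config, geometry = geometry, electrodes = es,
         passive = passive, truth_voltages = gt$voltages,
         recording = rec, v_rec = v_rec,
         depth_models = list(`0` = model0)),
    class = "run_context"
  )
}

context_depth_model <- function(context, depth_mm) {
  key <- as.character(depth_mm)
  if (is.null(context$depth_models[[key]])) {
    context$depth_models[[key]] <-
      build_depth_model(context$config, context$geometry, depth_mm)
  }
  context
}

#' Run one condition of the comparison grid
#'
#' Executes the full chain for one projection method and CSF depth:
#' project the shifted contacts to the closed-gray surface, offset by the
#' CSF depth, build disks, solve the volume-conduction model, and compare
#' the simulated passive-contact voltages against the synthesized
#' recordings.
#'
#' @param config a [run_config()].
#' @param method projection method (`"rigid"` uses the clipped-tissue
#'   variant and ignores `depth_mm`).
#' @param depth_mm CSF depth (0, 1 or 2 mm).
#' @param context optional shared [prepare_context()] output (built on the
#'   fly if absent); pass it when running several conditions.
#' @return a `condition_report`: list with the projection, simulated and
#'   recorded voltages (raw and normalized to 1 mA), absolute errors and a
#'   [regression_report()]. For a non-converged Dykstra run, the report
#'   carries `converged = FALSE` and no voltages.
#' @export
run_condition <- function(config, method, depth_mm = 0, context = NULL) {
  if (is.null(context)) context <- prepare_context(config)
  es <- context$electrodes
  cg <- context$geometry$surfaces$closed_gray
  if (method == "rigid") {
    clipped <- clip_gray_for_rigid(context$geometry, es)
    proj <- rigid_localize(es)
    # the voxel clip quantizes the cut plane: rest the contacts and the
    # sheet exactly on the clipped tissue top so the silicone stays coupled
    # to the conductive domain
    np <- nearest_surface_point(clipped$surfaces$closed_gray,
                                proj$projected_centroids)
    z_e <- stats::median(np$point[, 3])
    centers <- proj$projected_centroids
    centers[, 3] <- z_e
    half_w <- (config$grid_shape[2] - 1) * config$pitch_mm / 2 + 5
    half_h <- (config$grid_shape[1] - 1) * config$pitch_mm / 2 + 5
    sheet <- slab_surface(c(-half_h, half_h), c(-half_w, half_w), z_e,
                          z_e + 0.5, nx = 8, ny = 8, name = "sheet")
    disks <- lapply(seq_along(es$labels), function(i) {
      build_disk(centers[i, ], c(0, 0, 1), es$contact_diameter_mm,
                 es$labels[i])
    })
    names(disks) <- es$labels
    mesh <- tetrahedralize(
      clipped, sheet = sheet,
      sizing = list(h_fine = config$h_fine, h_coarse = config$h_coarse,
                    fine_xy = rbind(c(-half_h - 5, half_h + 5),
                                    c(-half_w - 5, half_w + 5)),
                    z_breaks = z_e)
    )
    K <- assemble(mesh, conductivity_table())
    model <- list(mesh = mesh, K = K, depth_mm = 0)
  } else {
    proj <- project_electrodes(es, cg, method)
    if (!proj$converged) {
      return(structure(
        list(method = method, depth_mm = depth_mm, projection = proj,
             converged = FALSE),
        class = "condition_report"
      ))
    }
    proj <- offset_csf(proj, cg, depth_mm)
    disks <- build_disks(proj, cg)
    context <- context_depth_model(context, depth_mm)
    model <- context$depth_models[[as.character(depth_mm)]]
  }
  sim <- solve_model(model, disks, config)
  v_sim <- sim$voltages[context$passive]
  v_rec <- context$v_rec
  err <- absolute_error(v_rec, v_sim)
  I0 <- config$stim_amplitude_mA
  reg <- regression_report(normalize_to_unit_current(v_sim[names(v_rec)], I0),
                           normalize_to_unit_current(v_rec, I0))
  structure(
    list(method = method, depth_mm = depth_mm, projection = proj,
         converged = TRUE, v_sim = v_sim, v_rec = v_rec,
         abs_error = err, regression = reg,
         median_abs_error = unname(attr(err, "summary")["median"])),
    class = "condition_report"
  )
}

#' @export
print.condition_report <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<condition %s @ %g mm CSF: projection did not converge>\n",
                x$method, x$depth_mm))
  } else {
    cat(sprintf(
      "<condition %s @ %g mm CSF: median |err| %.3g mV, slope %.3f, r %.3f>\n",
      x$method, x$depth_mm, 1000 * x$median_abs_error, x$regression$slope,
      x$regression$pearson_r))
  }
  invisible(x)
}

#' Run the full comparison grid
#'
#' All requested projection methods at all CSF depths (plus the rigid model
#' if listed), with pairwise Wilcoxon signed-rank comparisons of the
#' absolute-error distributions across depths (Holm-corrected) per method.
#'
#' @param config a [run_config()].
#' @param context optional prepared context.
#' @return a `grid_report`: list with `conditions` (per-condition reports),
#'   `summary` (data.frame: method, depth, median/IQR absolute error,
#'   slope, r) and `depth_comparisons` (per method, Holm-adjusted Wilcoxon
#'   p values between consecutive depths).
#' @export
run_grid <- function(config, context = NULL) {
  if (is.null(context)) context <- prepare_context(config)
  conditions <- list()
  for (method in config$methods) {
    depths <- if (method == "rigid") 0 else config$csf_depths_mm
    for (d in depths) {
      key <- sprintf("%s_%g", method, d)
      if (method != "rigid") context <- context_depth_model(context, d)
      conditions[[key]] <- run_condition(config, method, d, context)
    }
  }
  ok <- vapply(conditions, function(x) isTRUE(x$converged), logical(1))
  summary <- do.call(rbind, lapply(conditions[ok], function(x) {
    s <- attr(x$abs_error, "summary")
    data.frame(method = x$method, depth_mm = x$depth_mm,
               median_abs_error_v = unname(s["median"]),
               iqr_low_v = unname(s["q1"]), iqr_high_v = unname(s["q3"]),
               slope = x$regression$slope, pearson_r = x$regression$pearson_r,
               n = x$regression$n)
  }))
  rownames(summary) <- NULL
  depth_comparisons <- list()
  for (method in setdiff(config$methods, "rigid")) {
    keys <- sprintf("%s_%g", method, config$csf_depths_mm)
    keys <- keys[keys %in% names(conditions)[ok]]
    if (length(keys) < 2) next
    pairs <- utils::combn(keys, 2)
    p <- apply(pairs, 2, function(kk) {
      d1 <- conditions[[kk[1]]]$abs_error
      d2 <- conditions[[kk[2]]]$abs_error
      wilcoxon_signed_rank(d1 - d2[names(d1)])$p_value
    })
    cmp <- holm_bonferroni(p)
    cmp$pair <- apply(pairs, 2, paste, collapse = " vs ")
    depth_comparisons[[method]] <- cmp
  }
  structure(
    list(conditions = conditions, summary = summary,
         depth_comparisons = depth_comparisons,
         non_converged = names(conditions)[!ok]),
    class = "grid_report"
  )
}

#' @export
print.grid_report <- function(x, ...) {
  cat("<grid_report>\n")
  print(x$summary)
  if (length(x$non_converged))
    cat("non-converged conditions:", paste(x$non_converged, collapse = ", "),
        "\n")
  invisible(x)
}
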