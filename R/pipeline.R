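#' Package defaults for vessel hemodynamics runs
#'
#' All physiology-derived defaults live in one documented YAML file
#' shipped with the package (`inst/defaults/defaults.yaml`): blood density
#' and the Carreau-Yasuda constants, the 1 s cycle with systolic peak at
#' 0.14 s, the 140/80 mmHg pressure envelope, the 1e-5 residual target
#' and the four snapshot report times. `hemoflow_defaults()` returns the
#' parsed list.
#'
#' @return A named list of defaults.
#' @export
hemoflow_defaults <- function() {
  yaml::read_yaml(system.file("defaults", "defaults.yaml",
                              package = "hemoflow", mustWork = TRUE))
}

#' Probe set
#'
#' Named probe points on the mesh, analogous to the per-plane data points
#' used when reporting pressure waveforms in true/false-lumen studies
#' (e.g. points P5, P9, P10, P13 on the ascending and descending planes).
#' Coordinates are in metres; probes must lie inside the fluid domain at
#' run time.
#'
#' @param name Character vector of probe names.
#' @param x,y Probe coordinates, m.
#' @return A tibble of class `probe_set`.
#' @export
probe_set <- function(name, x, y) {
  stopifnot(length(name) == length(x), length(x) == length(y))
  out <- tibble::tibble(name = as.character(name), x = x, y = y)
  class(out) <- unique(c("probe_set", class(out)))
  out
}

#' Run configuration
#'
#' Assembles and validates everything an end-to-end case needs. Any
#' missing required field raises an error naming it.
#'
#' @param vessel A [vessel_spec()] (or preset name `"pre_ad"` /
#'   `"post_ad"`).
#' @param resolution Cells across the reference diameter.
#' @param inlet A [waveform_spec()] (velocity or pressure) for transient
#'   runs, or a single mean velocity in m/s for steady runs.
#' @param outlet A [waveform_spec()] with unit mmHg, or a constant outlet
#'   pressure in mmHg.
#' @param rheology A [rheology_params()].
#' @param solver A [solver_config()].
#' @param probes Optional [probe_set()].
#' @param mode `"transient"` or `"steady"`.
#' @param n_samples Samples per cycle for synthesized waveforms.
#' @param seed Integer seed for waveform jitter.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vessel, resolution = 16L, inlet = NULL, outlet = 0,
                       rheology = rheology_params(),
                       solver = solver_config(),
                       probes = NULL,
                       mode = c("transient", "steady"),
                       n_samples = 200L, seed = 1L) {
  mode <- match.arg(mode)
  if (missing(vessel) || is.null(vessel)) {
    stop("run_config: missing required field `vessel`", call. = FALSE)
  }
  if (is.character(vessel)) vessel <- vessel_preset(vessel)
  stopifnot(inherits(vessel, "vessel_spec"))
  if (is.null(inlet)) {
    stop("run_config: missing required field `inlet`", call. = FALSE)
  }
  if (mode == "transient" && !inherits(inlet, "waveform_spec")) {
    stop("run_config: transient mode needs a waveform_spec `inlet`",
         call. = FALSE)
  }
  if (!is.null(probes)) stopifnot(inherits(probes, "probe_set"))
  structure(list(vessel = vessel, resolution = as.integer(resolution),
                 inlet = inlet, outlet = outlet, rheology = rheology,
                 solver = solver, probes = probes, mode = mode,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level keys `vessel` (either
#' `preset: pre_ad|post_ad` or the [vessel_spec()] fields), `resolution`,
#' `mode`, `inlet` / `outlet` (waveform-spec fields plus `unit`, or a
#' number), `rheology`, `solver`, `probes` (list of `{name, x_mm, y_mm}`)
#' and `seed`. Omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  vessel <- if (!is.null(cfg$vessel$preset)) {
    vessel_preset(cfg$vessel$preset)
  } else if (!is.null(cfg$vessel)) {
    vs <- cfg$vessel
    if (!is.null(vs$tears)) vs$tears <- do.call(rbind.data.frame, vs$tears)
    do.call(vessel_spec, vs)
  } else NULL
  mk_spec <- function(x, default_unit) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x)) return(x)
    do.call(waveform_spec, utils::modifyList(list(unit = default_unit), x))
  }
  rheo <- if (is.null(cfg$rheology)) rheology_params() else
    do.call(rheology_params, cfg$rheology)
  solv <- if (is.null(cfg$solver)) solver_config() else
    do.call(solver_config, cfg$solver)
  probes <- if (!is.null(cfg$probes)) {
    pr <- dplyr::bind_rows(lapply(cfg$probes, tibble::as_tibble))
    probe_set(pr$name, pr$x_mm / 1000, pr$y_mm / 1000)
  } else NULL
  run_config(vessel = vessel,
             resolution = cfg$resolution %||% 16L,
             inlet = mk_spec(cfg$inlet, "m/s"),
             outlet = mk_spec(cfg$outlet, "mmHg") %||% 0,
             rheology = rheo, solver = solv, probes = probes,
             mode = cfg$mode %||% "transient",
             n_samples = cfg$n_samples %||% 200L,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate probe pressures from a flow series
#'
#' Bilinearly interpolates the cell-centre pressure field at each probe
#' for every stored time step, converts to mmHg at the output boundary,
#' and summarizes each probe by its minimum, mean and maximum over the
#' reported cycle.
#'
#' @param series A `flow_series` from [solve_transient()].
#' @param probes A [probe_set()].
#' @param mesh The mesh; defaults to the one stored in the series.
#' @return A list: `waveforms` (named list of mmHg [waveform()]s) and
#'   `stats` (tibble `probe, p_min, p_mean, p_max` in mmHg).
#' @export
probe_pressure <- function(series, probes, mesh = series$mesh) {
  stopifnot(inherits(series, "flow_series"), inherits(probes, "probe_set"))
  traces <- purrr::map(seq_len(nrow(probes)), function(k) {
    vals <- vapply(series$states, function(s) {
      interp_cell_field(s$p, mesh, probes$x[k], probes$y[k])
    }, numeric(1))
    waveform(Pa_to_mmHg(vals), period = series$period, unit = "mmHg",
             time_s = series$times - series$times[1])
  })
  names(traces) <- probes$name
  stats <- purrr::map_dfr(seq_along(traces), function(k) {
    v <- traces[[k]]$value
    tibble::tibble(probe = probes$name[k], p_min = min(v),
                   p_mean = mean(v), p_max = max(v))
  })
  list(waveforms = traces, stats = stats)
}

interp_cell_field <- function(P, mesh, x, y) {
  if (x < mesh$x0 || x > mesh$x0 + mesh$nx * mesh$dx ||
      y < mesh$y0 || y > mesh$y0 + mesh$ny * mesh$dy) {
    stop(sprintf("probe (%.4g, %.4g) lies outside the fluid domain", x, y),
         call. = FALSE)
  }
  xc <- mesh_xc(mesh); yc <- mesh_yc(mesh)
  i <- findInterval(x, xc); j <- findInterval(y, yc)
  ic <- min(max(i, 1L), mesh$nx); jc <- min(max(j, 1L), mesh$ny)
  ic2 <- min(ic + 1L, mesh$nx); jc2 <- min(jc + 1L, mesh$ny)
  # probe must sit in a fluid cell
  icell <- min(max(as.integer(round((x - mesh$x0) / mesh$dx + 0.5)), 1L),
               mesh$nx)
  jcell <- min(max(as.integer(round((y - mesh$y0) / mesh$dy + 0.5)), 1L),
               mesh$ny)
  if (!mesh$fluid[icell, jcell]) {
    stop(sprintf("probe (%.4g, %.4g) lies outside the fluid domain", x, y),
         call. = FALSE)
  }
  corners <- rbind(c(ic, jc), c(ic2, jc), c(ic, jc2), c(ic2, jc2))
  ok <- mesh$fluid[corners]
  if (!all(ok)) return(P[icell, jcell])
  tx <- if (ic2 > ic) (x - xc[ic]) / (xc[ic2] - xc[ic]) else 0
  ty <- if (jc2 > jc) (y - yc[jc]) / (yc[jc2] - yc[jc]) else 0
  tx <- min(max(tx, 0), 1); ty <- min(max(ty, 0), 1)
  (1 - tx) * (1 - ty) * P[ic, jc] + tx * (1 - ty) * P[ic2, jc] +
    (1 - tx) * ty * P[ic, jc2] + tx * ty * P[ic2, jc2]
}

#' Run a full case end to end
#'
#' Orchestrates geometry, waveform synthesis, the flow solve, wall shear
#' stress extraction, the four risk indices, probe traces and the export
#' bundle. Reruns with the same configuration are bitwise reproducible
#' (the solver has no unseeded randomness; waveform jitter is seeded).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for the artifact bundle, or `NULL` to
#'   skip writing files.
#' @return A list of class `hemoflow_case`: `mesh`, `series`, `wss`,
#'   `indices`, `probes` (traces and stats, when configured), `summary`
#'   (the machine-readable run summary), and `paths` of written files.
#' @export
run_case <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  mesh <- build_vessel(config$vessel, config$resolution)
  aud <- mesh_audit(mesh)
  if (!aud$ok) {
    stop(paste("stage geometry:", paste(aud$problems, collapse = "; ")),
         call. = FALSE)
  }
  if (config$mode == "steady") {
    p_out <- if (is.numeric(config$outlet)) mmHg_to_Pa(config$outlet[1]) else 0
    state <- solve_steady(mesh, inlet_velocity = config$inlet,
                          outlet_pressure = p_out,
                          rheology = config$rheology,
                          config = config$solver)
    series <- as_flow_series(state, mesh)
    series$period <- 1
  } else {
    inlet_w <- synthesize_pulse(config$inlet, n_samples = config$n_samples,
                                seed = config$seed)
    outlet_w <- if (inherits(config$outlet, "waveform_spec")) {
      synthesize_pulse(config$outlet, n_samples = config$n_samples,
                       seed = config$seed)
    } else config$outlet
    series <- solve_transient(mesh, inlet_w, outlet_w,
                              rheology = config$rheology,
                              config = config$solver)
  }
  wss <- wall_shear_stress(series, mesh, config$rheology)
  idx <- hemodynamic_indices(wss)
  pr <- if (!is.null(config$probes) && config$mode == "transient") {
    probe_pressure(series, config$probes, mesh)
  } else NULL
  mb <- mass_balance(series$states[[length(series$states)]], mesh)
  summary <- list(
    vessel_kind = config$vessel$kind,
    mode = config$mode,
    cells = sum(mesh$fluid),
    mass_balance = list(relative_imbalance = mb$relative_imbalance),
    indices = list(tawss_max = max(idx$tawss), tawss_mean = mean(idx$tawss),
                   osi_max = max(idx$osi), rrt_max = max(idx$rrt),
                   ecap_max = max(idx$ecap)),
    wss_max = max(sqrt(wss$wss_x^2 + wss$wss_y^2)),
    probes = if (!is.null(pr)) {
      lapply(split(pr$stats, pr$stats$probe), function(r) {
        list(min_mmHg = r$p_min, mean_mmHg = r$p_mean, max_mmHg = r$p_max)
      })
    } else NULL
  )
  case <- structure(list(mesh = mesh, series = series, wss = wss,
                         indices = idx, probes = pr, summary = summary,
                         paths = character(0)),
                    class = "hemoflow_case")
  if (!is.null(out_dir)) case$paths <- export_bundle(case, out_dir)
  case
}

#' @export
print.hemoflow_case <- function(x, ...) {
  cat(sprintf("<hemoflow_case> %s, %d cells, TAWSS max %.3g Pa, OSI max %.3g\n",
              x$summary$vessel_kind, x$summary$cells,
              x$summary$indices$tawss_max, x$summary$indices$osi_max))
  invisible(x)
}

#' Export a case's artifact bundle
#'
#' Writes the stable artifact set to `directory` (created if needed):
#' `mesh.vtk`, `wss_series.csv`, `index_maps.csv`, `index_maps.vtk`,
#' per-probe `probe_<name>.csv` traces and the machine-readable
#' `summary.json`. Existing files are overwritten, so re-exporting the
#' same case reproduces identical bytes.
#'
#' @param case A `hemoflow_case` from [run_case()].
#' @param directory Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
export_bundle <- function(case, directory) {
  stopifnot(inherits(case, "hemoflow_case"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2) != 0) {
    stop("output directory is not writable: ", directory, call. = FALSE)
  }
  paths <- c(
    mesh = file.path(directory, "mesh.vtk"),
    wss = file.path(directory, "wss_series.csv"),
    idx_csv = file.path(directory, "index_maps.csv"),
    idx_vtk = file.path(directory, "index_maps.vtk"),
    summary = file.path(directory, "summary.json"))
  write_mesh_vtk(case$mesh, paths[["mesh"]])
  write_wss_csv(case$wss, paths[["wss"]])
  readr::write_csv(tibble::as_tibble(case$indices), paths[["idx_csv"]])
  write_index_maps_vtk(case$indices, paths[["idx_vtk"]])
  if (!is.null(case$probes)) {
    for (nm in names(case$probes$waveforms)) {
      p <- file.path(directory, paste0("probe_", nm, ".csv"))
      write_waveform_csv(case$probes$waveforms[[nm]], p)
      paths[nm] <- p
    }
  }
  jsonlite::write_json(case$summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = 12, pretty = TRUE)
  invisible(paths)
}

#' Check a run summary against the shipped schema
#'
#' Structural validation of `summary.json`: required fields, types and
#' ranges as documented in `inst/schema/summary-schema.json`.
#'
#' @param summary A list (parsed JSON) or path to a `summary.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  need <- c("vessel_kind", "mode", "cells", "mass_balance", "indices",
            "wss_max")
  miss <- setdiff(need, names(summary))
  if (length(miss)) {
    stop("summary missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!summary$vessel_kind %in% c("straight", "arch", "dissected")) {
    stop("summary: invalid vessel_kind", call. = FALSE)
  }
  idx <- summary$indices
  for (f in c("tawss_max", "osi_max", "rrt_max", "ecap_max")) {
    if (is.null(idx[[f]]) || !is.numeric(idx[[f]]) || idx[[f]] < 0) {
      stop("summary: invalid indices$", f, call. = FALSE)
    }
  }
  if (idx$osi_max > 0.5) stop("summary: osi_max exceeds 0.5", call. = FALSE)
  invisible(TRUE)
}

#' Validate a computed flow-rate waveform against a reference CSV
#'
#' Reads a reference flow-rate trace (mL/s) from a waveform CSV, resamples
#' both waveforms to a common grid and reports the relative-L2 percent
#' difference together with the per-sample residuals, the standard check
#' of a computed aortic flow waveform against published measurement data.
#'
#' @param case_flow A [waveform()] with unit `"mL/s"` (e.g. from
#'   [flow_rate_from_velocity()]).
#' @param reference_csv Path to a waveform CSV with unit `"mL/s"`.
#' @return A list: `percent_difference`, and `aligned` (tibble `time_s,
#'   case, reference, residual`).
#' @export
validate_against_reference <- function(case_flow, reference_csv) {
  stopifnot(inherits(case_flow, "waveform"))
  if (!identical(wf_unit(case_flow), "mL/s")) {
    stop("`case_flow` must be a flow-rate waveform in mL/s", call. = FALSE)
  }
  ref <- read_waveform_csv(reference_csv)
  if (!identical(wf_unit(ref), "mL/s")) {
    stop("reference CSV must carry the unit tag mL/s", call. = FALSE)
  }
  n <- max(nrow(case_flow), nrow(ref))
  a <- resample_waveform(case_flow, n)
  b <- resample_waveform(ref, n)
  list(percent_difference = waveform_percent_difference(case_flow, ref),
       aligned = tibble::tibble(time_s = a$time_s, case = a$value,
                                reference = b$value,
                                residual = a$value - b$value))
}

#' Export flow-field snapshots as a VTK time series
#'
#' Writes one legacy-VTK file per stored state (cell data: pressure in Pa,
#' cell-centre velocity components) plus a `.series` JSON index, the
#' layout time-series readers expect.
#'
#' @param series A `flow_series`.
#' @param directory Output directory.
#' @param basename File stem for the snapshots.
#' @return Paths of written files, invisibly.
#' @export
write_flow_vtk_series <- function(series, directory, basename = "flow") {
  stopifnot(inherits(series, "flow_series"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  mesh <- series$mesh
  idx <- which(mesh$fluid, arr.ind = TRUE)
  files <- character(0)
  for (k in seq_along(series$states)) {
    s <- series$states[[k]]
    path <- file.path(directory, sprintf("%s_%04d.vtk", basename, k))
    write_mesh_vtk(mesh, path)
    ucc <- (s$u[1:mesh$nx, , drop = FALSE] +
              s$u[2:(mesh$nx + 1L), , drop = FALSE]) / 2
    vcc <- (s$v[, 1:mesh$ny, drop = FALSE] +
              s$v[, 2:(mesh$ny + 1L), drop = FALSE]) / 2
    con <- file(path, "a")
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", s$p[idx]), con)
    writeLines(c("VECTORS velocity double"), con)
    writeLines(sprintf("%.9g %.9g 0", ucc[idx], vcc[idx]), con)
    close(con)
    files <- c(files, path)
  }
  series_json <- file.path(directory, paste0(basename, ".vtk.series"))
  jsonlite::write_json(
    list(`file-series-version` = "1.0",
         files = purrr::map2(basename(files), series$times,
                             function(f, t) list(name = f, time = t))),
    series_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, series_json))
}
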