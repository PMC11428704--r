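#' Specify a synthetic vessel geometry
#'
#' Describes one of three desk-scale vessel archetypes used in aortic
#' hemodynamics studies, all in millimetres:
#' \describe{
#'   \item{straight}{A straight tube (axisymmetric by default) or planar
#'     channel, optionally linearly tapered between the inlet and outlet
#'     diameters.}
#'   \item{arch}{A planar curved channel following a circular arc of the
#'     given bend angle, with the centerline arc length set by `length`.}
#'   \item{dissected}{A planar two-lumen channel: a true lumen (bottom),
#'     an impermeable septum (intimal flap) and a false lumen (top). The
#'     false lumen is sealed at the inlet and communicates with the true
#'     lumen only through intimal tears, mimicking a dissected aorta; both
#'     lumens are open at the outlet.}
#' }
#' Lumen diameters may be a single value or a length-2 vector
#' `(inlet, outlet)` for a linear taper.
#'
#' @param kind `"straight"`, `"arch"` or `"dissected"`.
#' @param inlet_diameter,outlet_diameter Vessel diameter at the inlet and
#'   outlet, mm (straight/arch kinds). `outlet_diameter` defaults to the
#'   inlet value.
#' @param length Centerline length, mm.
#' @param bend_angle Arch bend angle, degrees (arch only).
#' @param axisymmetric Straight kind only: treat the geometry as a body of
#'   revolution (circular tube) rather than a planar channel.
#' @param true_lumen_diameter,false_lumen_diameter Dissected kind: lumen
#'   heights, mm; scalar or `(inlet, outlet)`.
#' @param septum_thickness Dissected kind: intimal flap thickness, mm.
#' @param tears Dissected kind: a data frame (or 2-column matrix) with
#'   columns `position` and `opening` in mm, giving the centre and width of
#'   each intimal tear along the vessel axis. At least one tear is required
#'   so that the false lumen is connected to the inlet flow.
#' @return An object of class `vessel_spec`.
#' @seealso [vessel_preset()], [build_vessel()]
#' @export
vessel_spec <- function(kind = c("straight", "arch", "dissected"),
                        inlet_diameter = 20, outlet_diameter = inlet_diameter,
                        length = 100, bend_angle = 180,
                        axisymmetric = (kind == "straight"),
                        true_lumen_diameter = NULL,
                        false_lumen_diameter = NULL,
                        septum_thickness = 2,
                        tears = NULL) {
  kind <- match.arg(kind)
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  chk_pos(length, "length")
  spec <- list(kind = kind, length = length)
  if (kind %in% c("straight", "arch")) {
    chk_pos(inlet_diameter, "inlet_diameter")
    chk_pos(outlet_diameter, "outlet_diameter")
    spec$inlet_diameter <- inlet_diameter
    spec$outlet_diameter <- outlet_diameter
  }
  if (kind == "straight") {
    spec$axisymmetric <- isTRUE(axisymmetric)
  } else {
    spec$axisymmetric <- FALSE
  }
  if (kind == "arch") {
    if (!is.finite(bend_angle) || bend_angle <= 0 || bend_angle > 360) {
      stop("`bend_angle` must lie in (0, 360] degrees", call. = FALSE)
    }
    spec$bend_angle <- bend_angle
  }
  if (kind == "dissected") {
    if (is.null(true_lumen_diameter) || is.null(false_lumen_diameter)) {
      stop("dissected vessels need `true_lumen_diameter` and `false_lumen_diameter`",
           call. = FALSE)
    }
    chk_pos(true_lumen_diameter, "true_lumen_diameter")
    chk_pos(false_lumen_diameter, "false_lumen_diameter")
    chk_pos(septum_thickness, "septum_thickness")
    spec$true_lumen_diameter <- rep_len(true_lumen_diameter, 2L)
    spec$false_lumen_diameter <- rep_len(false_lumen_diameter, 2L)
    spec$septum_thickness <- septum_thickness
    if (is.null(tears) || NROW(tears) < 1L) {
      stop("dissected vessels require at least one intimal tear", call. = FALSE)
    }
    tears <- as.data.frame(tears)
    if (ncol(tears) < 2L) stop("`tears` needs columns position, opening",
                               call. = FALSE)
    names(tears)[1:2] <- c("position", "opening")
    chk_pos(tears$position, "tears$position")
    chk_pos(tears$opening, "tears$opening")
    if (any(tears$position - tears$opening / 2 <= 0) ||
        any(tears$position + tears$opening / 2 >= length)) {
      stop("tear lies outside the vessel domain", call. = FALSE)
    }
    spec$tears <- tears
  }
  structure(spec, class = "vessel_spec")
}

#' Vessel presets for the aneurysm / dissection study conditions
#'
#' `"pre_ad"` is the pre-dissection aneurysmal aorta analogue: a straight
#' tapered tube from a 52.79 mm ascending diameter to a 28.44 mm
#' descending diameter. `"post_ad"` is the post-dissection analogue: a
#' two-lumen channel whose true lumen tapers 23.17 to 20.18 mm and false
#' lumen 44.55 to 19.11 mm (ascending to descending values), separated by
#' a 2 mm intimal flap with a single proximal entry tear.
#'
#' @param name `"pre_ad"` or `"post_ad"`.
#' @param length Centerline length in mm (default 300, an adult
#'   ascending-to-descending aortic path at desk scale).
#' @return A [vessel_spec()].
#' @export
vessel_preset <- function(name = c("pre_ad", "post_ad"), length = 300) {
  name <- match.arg(name)
  switch(name,
    pre_ad = vessel_spec("straight", inlet_diameter = 52.79,
                         outlet_diameter = 28.44, length = length),
    post_ad = vessel_spec("dissected",
                          true_lumen_diameter = c(23.17, 20.18),
                          false_lumen_diameter = c(44.55, 19.11),
                          septum_thickness = 2,
                          tears = data.frame(position = 0.15 * length,
                                             opening = 0.08 * length),
                          length = length)
  )
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf("<vessel_spec> kind=%s length=%g mm%s\n", x$kind, x$length,
              if (isTRUE(x$axisymmetric)) " (axisymmetric)" else ""))
  invisible(x)
}

# linear taper helper; x_m along the axis in metres, result in metres
taper_m <- function(d_mm_pair, x_m, length_mm) {
  frac <- pmin(pmax(x_m / (length_mm / 1000), 0), 1)
  (d_mm_pair[1] + (d_mm_pair[2] - d_mm_pair[1]) * frac) / 1000
}

#' Build a structured mesh for a vessel specification
#'
#' Discretizes the vessel on a uniform structured grid of square cells
#' (spacing set by `resolution` cells across the reference diameter: the
#' inlet diameter for straight/arch vessels, the inlet true-lumen diameter
#' for dissected ones). Curved or tapered walls are represented by the
#' stair-step fluid mask; boundary faces are tagged `inlet`, `outlet`,
#' `wall`, `septum` or (on the symmetry axis) `axis`. Coordinates are
#' stored in metres.
#'
#' @param spec A [vessel_spec()].
#' @param resolution Cells across the reference diameter; at least 8.
#' @return An object of class `vessel_mesh`: a list with grid dimensions
#'   `nx, ny`, spacings `dx, dy` (m), origin `x0, y0`, logical matrices
#'   `fluid` and `septum`, inlet/outlet openness per row, the boundary-face
#'   table `faces`, and the originating `spec` and `resolution`.
#' @export
build_vessel <- function(spec, resolution) {
  stopifnot(inherits(spec, "vessel_spec"))
  resolution <- as.integer(resolution)
  if (resolution < 8L) stop("`resolution` must be >= 8", call. = FALSE)
  switch(spec$kind,
         straight = build_straight(spec, resolution),
         dissected = build_dissected(spec, resolution),
         arch = build_arch(spec, resolution))
}

new_vessel_mesh <- function(spec, resolution, nx, ny, dx, dy, x0, y0,
                            fluid, septum, inlet_open, outlet_open,
                            axisymmetric) {
  m <- structure(
    list(kind = spec$kind, axisymmetric = axisymmetric,
         nx = nx, ny = ny, dx = dx, dy = dy, x0 = x0, y0 = y0,
         fluid = fluid, septum = septum,
         inlet_open = inlet_open, outlet_open = outlet_open,
         spec = spec, resolution = resolution),
    class = "vessel_mesh")
  m$faces <- boundary_faces(m)
  m
}

mesh_xc <- function(mesh) mesh$x0 + mesh$dx * (seq_len(mesh$nx) - 0.5)
mesh_yc <- function(mesh) mesh$y0 + mesh$dy * (seq_len(mesh$ny) - 0.5)

build_straight <- function(spec, resolution) {
  d_pair <- c(spec$inlet_diameter, spec$outlet_diameter)
  L <- spec$length / 1000
  dy <- (spec$inlet_diameter / 1000) / resolution
  dx <- dy
  nx <- max(4L, as.integer(round(L / dx)))
  xc <- dx * (seq_len(nx) - 0.5)
  rad <- taper_m(d_pair, xc, spec$length) / 2
  if (spec$axisymmetric) {
    ny <- as.integer(ceiling(max(rad) / dy - 1e-9))
    yc <- dy * (seq_len(ny) - 0.5)
    fluid <- outer(rad, yc, function(r, y) y < r)
  } else {
    h <- 2 * max(rad)
    ny <- as.integer(ceiling(h / dy - 1e-9))
    yc <- dy * (seq_len(ny) - 0.5)
    ctr <- h / 2
    fluid <- outer(rad, yc, function(r, y) abs(y - ctr) < r)
  }
  inlet_open <- fluid[1, ]
  outlet_open <- fluid[nx, ]
  new_vessel_mesh(spec, resolution, nx, ny, dx, dy, 0, 0, fluid,
                  septum = matrix(FALSE, nx, ny),
                  inlet_open, outlet_open, spec$axisymmetric)
}

build_dissected <- function(spec, resolution) {
  L <- spec$length / 1000
  dy <- (spec$true_lumen_diameter[1] / 1000) / resolution
  dx <- dy
  s <- spec$septum_thickness / 1000
  if (s < dy) {
    stop("resolution too coarse to resolve the septum (need >= 1 cell)",
         call. = FALSE)
  }
  nx <- max(4L, as.integer(round(L / dx)))
  xc <- dx * (seq_len(nx) - 0.5)
  ht <- taper_m(spec$true_lumen_diameter, xc, spec$length)
  hf <- taper_m(spec$false_lumen_diameter, xc, spec$length)
  if (min(ht) < 3 * dy || min(hf) < 3 * dy) {
    stop("resolution too coarse: each lumen needs >= 3 cells across",
         call. = FALSE)
  }
  H <- max(ht + s + hf)
  ny <- as.integer(ceiling(H / dy - 1e-9))
  yc <- dy * (seq_len(ny) - 0.5)
  in_true <- outer(ht, yc, function(h, y) y < h)
  in_false <- matrix(FALSE, nx, ny)
  in_band <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    in_false[i, ] <- yc > ht[i] + s & yc < ht[i] + s + hf[i]
    in_band[i, ] <- yc >= ht[i] & yc <= ht[i] + s
  }
  tear_col <- rep(FALSE, nx)
  for (k in seq_len(nrow(spec$tears))) {
    p <- spec$tears$position[k] / 1000
    o <- spec$tears$opening[k] / 1000
    tear_col <- tear_col | (abs(xc - p) <= o / 2)
  }
  fluid <- in_true | in_false | (in_band & tear_col)
  septum <- in_band & !tear_col
  # inlet feeds the true lumen only; the false lumen is sealed proximally
  inlet_open <- in_true[1, ]
  outlet_open <- fluid[nx, ]
  new_vessel_mesh(spec, resolution, nx, ny, dx, dy, 0, 0, fluid, septum,
                  inlet_open, outlet_open, axisymmetric = FALSE)
}

build_arch <- function(spec, resolution) {
  theta <- spec$bend_angle * pi / 180
  L <- spec$length / 1000
  rc <- L / theta
  dy <- (spec$inlet_diameter / 1000) / resolution
  dx <- dy
  d_pair <- c(spec$inlet_diameter, spec$outlet_diameter)
  # bounding box of the annular band over the bend
  phi_s <- seq(0, theta, length.out = 721)
  wid <- taper_m(d_pair, rc * phi_s, spec$length)
  ro <- rc + max(wid) / 2
  xs <- c((rc - wid / 2) * cos(phi_s), (rc + wid / 2) * cos(phi_s), 0)
  ys <- c((rc - wid / 2) * sin(phi_s), (rc + wid / 2) * sin(phi_s), 0)
  x0 <- min(xs) - dx
  y0 <- min(ys) - dy
  nx <- as.integer(ceiling((max(xs) - x0) / dx)) + 1L
  ny <- as.integer(ceiling((max(ys) - y0) / dy)) + 1L
  xc <- x0 + dx * (seq_len(nx) - 0.5)
  yc <- y0 + dy * (seq_len(ny) - 0.5)
  xg <- matrix(xc, nx, ny)
  yg <- matrix(yc, nx, ny, byrow = TRUE)
  rho <- sqrt(xg^2 + yg^2)
  phi <- atan2(yg, xg) %% (2 * pi)
  w_here <- taper_m(d_pair, rc * phi, spec$length)
  fluid <- phi >= 0 & phi <= theta & abs(rho - rc) < w_here / 2
  m <- new_vessel_mesh(spec, resolution, nx, ny, dx, dy, x0, y0, fluid,
                       septum = matrix(FALSE, nx, ny),
                       inlet_open = rep(FALSE, ny),
                       outlet_open = rep(FALSE, ny),
                       axisymmetric = FALSE)
  # retag faces near the end planes as inlet (phi = 0) / outlet (phi = theta)
  f <- m$faces
  fphi <- atan2(f$y, f$x) %% (2 * pi)
  frho <- sqrt(f$x^2 + f$y^2)
  tol <- 1.2 * max(dx, dy) / pmax(frho, rc / 2)
  f$tag[f$tag == "wall" & (fphi < tol | fphi > 2 * pi - tol)] <- "inlet"
  f$tag[f$tag == "wall" & abs(fphi - theta) < tol] <- "outlet"
  m$faces <- f
  m
}

# Boundary faces of the fluid region: one row per (cell, side) where the
# neighbouring location is solid or outside the grid.
boundary_faces <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  fl <- mesh$fluid
  sp <- mesh$septum
  xc <- mesh_xc(mesh); yc <- mesh_yc(mesh)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nx, ny)
    is <- seq_len(nx) + di
    js <- seq_len(ny) + dj
    ok_i <- is >= 1L & is <= nx
    ok_j <- js >= 1L & js <= ny
    out[ok_i, ok_j] <- m[is[ok_i], js[ok_j]]
    out
  }
  rows <- list()
  sides <- list(W = c(-1L, 0L), E = c(1L, 0L), S = c(0L, -1L), N = c(0L, 1L))
  for (sd in names(sides)) {
    di <- sides[[sd]][1]; dj <- sides[[sd]][2]
    nb_fluid <- pad(fl, di, dj)
    nb_septum <- pad(sp, di, dj)
    hit <- fl & !nb_fluid
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    i <- idx[, 1]; j <- idx[, 2]
    off_grid <- (i + di < 1L) | (i + di > nx) | (j + dj < 1L) | (j + dj > ny)
    tag <- rep("wall", nrow(idx))
    tag[nb_septum[hit]] <- "septum"
    if (sd == "W") tag[off_grid & mesh$inlet_open[j]] <- "inlet"
    if (sd == "E") tag[off_grid & mesh$outlet_open[j]] <- "outlet"
    if (sd == "S" && mesh$axisymmetric) tag[off_grid] <- "axis"
    fx <- xc[i] + di * mesh$dx / 2
    fy <- yc[j] + dj * mesh$dy / 2
    rows[[sd]] <- tibble::tibble(i = i, j = j, side = sd, tag = tag,
                                 x = fx, y = fy)
  }
  dplyr::bind_rows(rows)
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh> %s %dx%d grid (%d fluid cells), h=%.3g mm%s\n",
              x$kind, x$nx, x$ny, sum(x$fluid), x$dx * 1000,
              if (x$axisymmetric) ", axisymmetric" else ""))
  cat("  boundary faces:",
      paste(sprintf("%s=%d", names(table(x$faces$tag)), table(x$faces$tag)),
            collapse = " "), "\n")
  invisible(x)
}

#' Audit mesh validity
#'
#' Checks the structural invariants every generated mesh must satisfy:
#' positive cell spacing (all cell Jacobians are then strictly positive on
#' the uniform grid), a non-empty fluid region, the presence of inlet and
#' outlet faces, a single tag per boundary face, and connectivity of every
#' fluid cell to the inlet (which guarantees that dissected lumens
#' communicate through at least one tear).
#'
#' @param mesh A [vessel_mesh][build_vessel()].
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
mesh_audit <- function(mesh) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  probs <- character()
  if (!(mesh$dx > 0 && mesh$dy > 0)) probs <- c(probs, "non-positive spacing")
  if (!any(mesh$fluid)) probs <- c(probs, "empty fluid region")
  tags <- mesh$faces$tag
  if (!"inlet" %in% tags) probs <- c(probs, "no inlet faces")
  if (!"outlet" %in% tags) probs <- c(probs, "no outlet faces")
  if (anyNA(tags)) probs <- c(probs, "untagged boundary face")
  dup <- duplicated(mesh$faces[, c("i", "j", "side")])
  if (any(dup)) probs <- c(probs, "boundary face tagged more than once")
  # connectivity: flood fill from inlet cells through the fluid mask
  reach <- matrix(FALSE, mesh$nx, mesh$ny)
  inlet_faces <- mesh$faces[mesh$faces$tag == "inlet", ]
  reach[cbind(inlet_faces$i, inlet_faces$j)] <- TRUE
  reach <- reach & mesh$fluid
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-mesh$nx, ]
    grown[-mesh$nx, ] <- grown[-mesh$nx, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -mesh$ny]
    grown[, -mesh$ny] <- grown[, -mesh$ny] | reach[, -1]
    grown <- grown & mesh$fluid
    if (identical(grown, reach)) break
    reach <- grown
  }
  if (any(mesh$fluid & !reach)) {
    probs <- c(probs, "fluid cells not connected to the inlet")
  }
  list(ok = length(probs) == 0L, problems = probs)
}

#' Refine a vessel mesh
#'
#' Splits every cell `factor` times per direction by regenerating the mesh
#' from its specification at `factor * resolution`. Tags are recomputed on
#' the refined boundary, so they cover the same geometric curves;
#' refinement is compositional (refining twice by 2 equals refining once
#' by 4, with identical node coordinates).
#'
#' @param mesh A [vessel_mesh][build_vessel()].
#' @param factor Integer refinement factor, at least 2.
#' @return The refined `vessel_mesh`.
#' @export
refine <- function(mesh, factor) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) {
    stop("`factor` must be an integer >= 2", call. = FALSE)
  }
  build_vessel(mesh$spec, mesh$resolution * factor)
}

#' Mesh-convergence report
#'
#' Summarizes a refinement ladder the way aortic CFD mesh studies do:
#' one row per refinement level with the cell count, the maximum wall
#' shear stress, maximum pressure and maximum velocity magnitude of the
#' associated solution, plus the relative change of each quantity from the
#' previous (coarser) level. All solutions must come from the same vessel
#' specification.
#'
#' @param solutions A list; each element is a list with components `mesh`
#'   (a [vessel_mesh][build_vessel()]) and `result` (a `flow_state` from
#'   [solve_steady()] or a `flow_series` from [solve_transient()]).
#' @param rheology The [rheology_params()] used for the solves (needed to
#'   evaluate wall shear stress).
#' @return A tibble with columns `level`, `cells`, `wss_max`, `p_max`,
#'   `v_max` and `rel_change_*` columns.
#' @export
mesh_convergence_report <- function(solutions, rheology = rheology_params()) {
  if (length(solutions) < 2L) {
    stop("need at least two refinement levels", call. = FALSE)
  }
  specs <- lapply(solutions, function(s) s$mesh$spec)
  if (!all(vapply(specs[-1], identical, logical(1), specs[[1]]))) {
    stop("all solutions must share the same vessel spec", call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_along(solutions), function(k) {
    mesh <- solutions[[k]]$mesh
    res <- solutions[[k]]$result
    series <- if (inherits(res, "flow_series")) res else
      as_flow_series(res, mesh)
    wss <- wall_shear_stress(series, mesh, rheology)
    vmax <- max(vapply(series$states, function(s) {
      max(speed_cc(s, mesh)[mesh$fluid])
    }, numeric(1)))
    pmax <- max(vapply(series$states, function(s) max(s$p[mesh$fluid]),
                       numeric(1)))
    tibble::tibble(level = k, cells = sum(mesh$fluid),
                   wss_max = max(sqrt(wss$wss_x^2 + wss$wss_y^2)),
                   p_max = pmax, v_max = vmax)
  })
  rows <- dplyr::arrange(rows, .data$cells)
  rel <- function(x) c(NA_real_, abs(diff(x)) / pmax(abs(x[-length(x)]), 1e-300))
  dplyr::mutate(rows,
                rel_change_wss = rel(.data$wss_max),
                rel_change_p = rel(.data$p_max),
                rel_change_v = rel(.data$v_max))
}

#' Export a mesh to legacy VTK
#'
#' Writes the fluid cells as an ASCII legacy-VTK unstructured grid of
#' quadrilaterals with cell-data arrays `region` (1 fluid) and the
#' boundary tags summarized as integer markers on cells adjacent to each
#' boundary type.
#'
#' @param mesh A [vessel_mesh][build_vessel()].
#' @param path Output file path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  idx <- which(mesh$fluid, arr.ind = TRUE)
  nc <- nrow(idx)
  # nodes of each quad (corner grid), deduplicated
  corner_id <- function(i, j) (j - 1L) * (mesh$nx + 1L) + i  # 1-based
  c1 <- corner_id(idx[, 1], idx[, 2])
  c2 <- corner_id(idx[, 1] + 1L, idx[, 2])
  c3 <- corner_id(idx[, 1] + 1L, idx[, 2] + 1L)
  c4 <- corner_id(idx[, 1], idx[, 2] + 1L)
  used <- sort(unique(c(c1, c2, c3, c4)))
  remap <- integer(max(used)); remap[used] <- seq_along(used) - 1L
  gi <- (used - 1L) %% (mesh$nx + 1L)
  gj <- (used - 1L) %/% (mesh$nx + 1L)
  px <- mesh$x0 + gi * mesh$dx
  py <- mesh$y0 + gj * mesh$dy
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hemoflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", length(used))), con)
  writeLines(sprintf("%.9g %.9g 0", px, py), con)
  writeLines(sprintf("CELLS %d %d", nc, 5L * nc), con)
  writeLines(sprintf("4 %d %d %d %d", remap[c1], remap[c2], remap[c3],
                     remap[c4]), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(rep("9", nc), con)  # VTK_QUAD
  writeLines(sprintf("CELL_DATA %d", nc), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(rep("1", nc), con)
  invisible(path)
}
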