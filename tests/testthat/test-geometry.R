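test_that("straight channel meshes have the documented shape and tags", {
  spec <- vessel_spec("straight", inlet_diameter = 20, length = 100,
                      axisymmetric = FALSE)
  m <- build_vessel(spec, 10)
  expect_equal(c(m$nx, m$ny), c(50L, 10L))
  expect_setequal(unique(m$faces$tag), c("inlet", "outlet", "wall"))
  expect_true(mesh_audit(m)$ok)
  # axisymmetric variant meshes the radius and tags the axis
  ma <- build_vessel(vessel_spec("straight", inlet_diameter = 20,
                                 length = 100), 10)
  expect_equal(ma$ny, 5L)
  expect_true("axis" %in% ma$faces$tag)
})

test_that("the tapered aneurysm preset respects the measured diameters", {
  m <- build_vessel(vessel_preset("pre_ad"), 16)
  expect_true(m$axisymmetric)
  xc <- m$x0 + m$dx * (seq_len(m$nx) - 0.5)
  # local wall-to-wall distance within one cell width of the linear taper
  for (i in c(1L, round(m$nx / 2), m$nx)) {
    d_here <- 2 * sum(m$fluid[i, ]) * m$dy
    frac <- min(max(xc[i] / 0.3, 0), 1)
    d_spec <- (52.79 + (28.44 - 52.79) * frac) / 1000
    expect_lt(abs(d_here - d_spec), 2 * m$dy)
  }
  expect_true(mesh_audit(m)$ok)
})

test_that("dissected specs enforce tears and septum resolution", {
  expect_error(vessel_spec("dissected", length = 60,
                           true_lumen_diameter = 8,
                           false_lumen_diameter = 6, tears = NULL),
               "tear")
  expect_error(vessel_spec("dissected", length = 60,
                           true_lumen_diameter = 8,
                           false_lumen_diameter = 6,
                           tears = data.frame(position = 59, opening = 6)),
               "outside")
  spec <- vessel_spec("dissected", length = 60, true_lumen_diameter = 8,
                      false_lumen_diameter = 6, septum_thickness = 0.5,
                      tears = data.frame(position = 15, opening = 6))
  expect_error(build_vessel(spec, 10), "septum")
  # a resolvable spec separates the lumens except at the tear
  spec2 <- vessel_spec("dissected", length = 60, true_lumen_diameter = 8,
                       false_lumen_diameter = 6, septum_thickness = 1.5,
                       tears = data.frame(position = 15, opening = 6))
  m <- build_vessel(spec2, 10)
  expect_true(any(m$septum))
  expect_true("septum" %in% m$faces$tag)
  expect_true(mesh_audit(m)$ok)
  # the post-dissection preset builds and audits cleanly
  mp <- build_vessel(vessel_preset("post_ad"), 30)
  expect_true(mesh_audit(mp)$ok)
})

test_that("refinement is compositional and preserves the geometry", {
  spec <- vessel_spec("straight", inlet_diameter = 20, length = 100,
                      axisymmetric = FALSE)
  m <- build_vessel(spec, 10)
  m2 <- refine(m, 2)
  expect_equal(c(m2$nx, m2$ny), c(100L, 20L))
  expect_setequal(unique(m2$faces$tag), unique(m$faces$tag))
  expect_identical(refine(refine(m, 2), 2)$fluid, refine(m, 4)$fluid)
  expect_equal(refine(refine(m, 2), 2)$dx, refine(m, 4)$dx)
  expect_error(refine(m, 1), "factor")
})

test_that("randomized specs always produce valid meshes", {
  withr::with_seed(99, {
    for (rep in 1:8) {
      kind <- sample(c("straight", "arch", "dissected"), 1)
      spec <- switch(kind,
        straight = vessel_spec("straight",
                               inlet_diameter = stats::runif(1, 10, 50),
                               outlet_diameter = stats::runif(1, 10, 50),
                               length = stats::runif(1, 50, 200),
                               axisymmetric = sample(c(TRUE, FALSE), 1)),
        arch = vessel_spec("arch", inlet_diameter = stats::runif(1, 15, 30),
                           length = stats::runif(1, 100, 200),
                           bend_angle = stats::runif(1, 60, 270)),
        dissected = vessel_spec("dissected", length = 80,
                                true_lumen_diameter = stats::runif(1, 8, 15),
                                false_lumen_diameter = stats::runif(1, 6, 15),
                                septum_thickness = 2,
                                tears = data.frame(
                                  position = stats::runif(1, 20, 60),
                                  opening = stats::runif(1, 5, 10))))
      m <- build_vessel(spec, sample(8:14, 1))
      aud <- mesh_audit(m)
      expect_true(aud$ok, info = paste(kind, paste(aud$problems,
                                                   collapse = "; ")))
    }
  })
})

test_that("convergence report tracks refinement ladders", {
  lad <- steady_tube_ladder()
  rep2 <- mesh_convergence_report(lad$levels[1:2], lad$rheology)
  expect_equal(nrow(rep2), 2L)
  expect_true(all(diff(rep2$cells) > 0))
  expect_true(is.na(rep2$rel_change_wss[1]))
  # duplicated levels: zero relative change
  dup <- mesh_convergence_report(list(lad$levels[[1]], lad$levels[[1]]),
                                 lad$rheology)
  expect_equal(dup$rel_change_wss[2], 0)
  expect_equal(dup$rel_change_p[2], 0)
  # a single level is rejected, as are mismatched specs
  expect_error(mesh_convergence_report(lad$levels[1], lad$rheology),
               "two refinement levels")
  other <- list(mesh = build_vessel(vessel_spec("straight",
                                                inlet_diameter = 10,
                                                length = 50), 8),
                result = lad$levels[[1]]$result)
  expect_error(mesh_convergence_report(list(lad$levels[[1]], other),
                                       lad$rheology), "same vessel spec")
})

test_that("mesh VTK export writes a well-formed unstructured grid", {
  m <- build_vessel(vessel_spec("straight", inlet_diameter = 20,
                                length = 40, axisymmetric = FALSE), 8)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(m, path)
  lines <- readLines(path)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  npts <- as.integer(strsplit(lines[5], " ")[[1]][2])
  expect_equal(npts, (m$nx + 1L) * (m$ny + 1L))
  expect_true(any(grepl("^CELL_TYPES", lines)))
})
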