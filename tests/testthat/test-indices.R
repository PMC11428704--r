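test_that("TAWSS averages the magnitude over the cycle", {
  s_const <- series_from_fun(function(t) rep(2, length(t)),
                             function(t) rep(0, length(t)), 100)
  expect_equal(tawss(s_const)$tawss, 2)
  # alternating +3/-3 square wave: magnitude is constant
  s_sq <- series_from_fun(function(t) ifelse(t < 0.5, 3, -3),
                          function(t) rep(0, length(t)), 100)
  expect_equal(tawss(s_sq)$tawss, 3)
  # sampled sinusoid: mean of |A sin| is 2A/pi
  A <- 1.7
  s_sin <- series_from_fun(function(t) A * sin(2 * pi * t),
                           function(t) rep(0, length(t)), 400)
  expect_equal(tawss(s_sin)$tawss, 2 * A / pi, tolerance = 1e-4)
  expect_error(wss_series(data.frame(point_id = 1, arc_length_m = 0,
                                     time_s = 0, wss_x = 1, wss_y = 0)),
               "2 time samples")
})

test_that("OSI endpoints and intermediate values are correct", {
  s_uni <- series_from_fun(function(t) rep(2, length(t)),
                           function(t) rep(0, length(t)), 100)
  expect_identical(osi(s_uni)$osi, 0)
  s_rev <- series_from_fun(function(t) ifelse(t < 0.5, 3, -3),
                           function(t) rep(0, length(t)), 100)
  expect_identical(osi(s_rev)$osi, 0.5)
  # partially reversing signal pinned by the fine-grid oracle
  fx <- function(t) 0.5 + sin(2 * pi * t)
  fy <- function(t) rep(0, length(t))
  ref <- indices_fine_oracle(fx, fy)
  s <- series_from_fun(fx, fy, 400)
  expect_equal(osi(s)$osi, ref$osi, tolerance = 5e-4)
  expect_equal(tawss(s)$tawss, ref$tawss, tolerance = 5e-4)
})

test_that("RRT and ECAP follow their defining formulas with capping", {
  maps <- tibble::tibble(point_id = 1:3, arc_length_m = 0:2 / 1000,
                         tawss = c(2, 4, 2), osi = c(0, 0.25, 0.5))
  out <- ecap(rrt(maps))
  expect_equal(out$rrt[1], 0.5)        # 1 / ((1 - 0) * 2)
  expect_equal(out$rrt[2], 0.5)        # 1 / ((1 - 0.5) * 4)
  expect_equal(out$rrt[3], 1e3)        # singular: capped
  expect_identical(out$degenerate, c(FALSE, FALSE, TRUE))
  expect_equal(out$ecap, c(0, 0.0625, 0.25))
  # zero TAWSS flags ECAP
  z <- ecap(tibble::tibble(tawss = 0, osi = 0))
  expect_identical(z$ecap, 0)
  expect_true(z$degenerate)
  # elementwise: order preserved
  expect_identical(out$point_id, 1:3)
})

test_that("index identities hold and are time-reversal invariant", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      tr <- ground_truth(target_tawss = stats::runif(1, 0.5, 8),
                         target_osi = stats::runif(1, 0, 0.45),
                         seed = rep)
      s <- make_wss_series(tr, n_points = 6, n_steps = 64)
      s <- add_noise(s, 0.02, seed = rep + 100)
      maps <- hemodynamic_indices(s)
      ok <- !maps$degenerate
      expect_true(all(maps$osi >= 0 & maps$osi <= 0.5))
      expect_equal(maps$rrt[ok] * maps$tawss[ok] * (1 - 2 * maps$osi[ok]),
                   rep(1, sum(ok)), tolerance = 1e-10)
      expect_equal(maps$ecap * maps$tawss, maps$osi, tolerance = 1e-12)
      # triangle inequality: TAWSS >= |mean WSS vector|
      tw <- tawss(s)
      mv <- dplyr::summarise(dplyr::group_by(s, point_id),
                             m = sqrt(mean(wss_x)^2 + mean(wss_y)^2))
      expect_true(all(tw$tawss >= mv$m - 1e-12))
      # reversing the sampling order leaves all indices unchanged
      srev <- wss_series(dplyr::arrange(tibble::as_tibble(s),
                                        point_id, dplyr::desc(time_s)),
                         period = 1)
      expect_equal(hemodynamic_indices(srev)$osi, maps$osi)
      expect_equal(hemodynamic_indices(srev)$tawss, maps$tawss)
    }
  })
})

test_that("index error decreases as the time sampling is refined", {
  A <- 2
  errs <- sapply(c(24, 96, 384), function(n) {
    s <- series_from_fun(function(t) A * sin(2 * pi * t),
                         function(t) rep(0, length(t)), n)
    abs(tawss(s)$tawss - 2 * A / pi)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("snapshots interpolate the stored samples at the report times", {
  tr <- ground_truth(target_tawss = 2, target_osi = 0.1, seed = 2)
  s <- make_wss_series(tr, n_points = 3, n_steps = 100)
  snaps <- wss_snapshots(s)
  expect_equal(sort(unique(snaps$time_s)), c(0.01, 0.14, 0.35, 0.59))
  expect_equal(nrow(snaps), 3 * 4)
  # interpolated value between two samples matches hand interpolation
  one <- dplyr::filter(tibble::as_tibble(s), point_id == 1)
  mag <- sqrt(one$wss_x^2 + one$wss_y^2)
  tq <- 0.1234
  i0 <- findInterval(tq, one$time_s)
  w <- (tq - one$time_s[i0]) / 0.01
  by_hand <- (1 - w) * mag[i0] + w * mag[i0 + 1]
  got <- wss_snapshots(s, tq)
  expect_equal(got$wss_mag[got$point_id == 1], by_hand, tolerance = 1e-12)
  expect_error(wss_snapshots(s, 1.5), "within the period")
})

test_that("WSS series CSV round-trips", {
  tr <- ground_truth(seed = 4)
  s <- make_wss_series(tr, n_points = 4, n_steps = 32)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wss_csv(s, path)
  back <- read_wss_csv(path)
  expect_equal(back$wss_x, s$wss_x, tolerance = 1e-12)
  expect_equal(attr(back, "period"), 1, tolerance = 1e-9)
  expect_equal(hemodynamic_indices(back)$osi, hemodynamic_indices(s)$osi)
})

test_that("index maps export as VTK point data", {
  tr <- ground_truth(seed = 5)
  maps <- hemodynamic_indices(make_wss_series(tr, n_points = 5,
                                              n_steps = 32))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_index_maps_vtk(maps, path)
  lines <- readLines(path)
  expect_true(any(grepl("SCALARS TAWSS", lines)))
  expect_true(any(grepl("SCALARS ECAP", lines)))
})
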