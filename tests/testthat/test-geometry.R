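test_that("to_physical applies the confocal pixel calibration to coordinates", {
  su <- bdml_scale_unit(0.105, 0.105, 0.5, 1, "micrometer", "second")
  d <- minimal_doc(scale_unit = su)
  d <- add_object(d, "nucleus")
  d <- add_component(d, 0)
  d <- add_measurement(d, last_component_id(d), "nucleus",
                       bdml_point(c(100, 200, 10)))
  p <- to_physical(d)
  expect_equal(components(p)[[1]]$measurements[[1]]$entity$xyz,
               c(10.5, 21.0, 5.0))
  # scale factors collapse to 1 afterwards
  expect_identical(p$body$scale_unit$x_scale, 1)
  expect_identical(p$body$scale_unit$t_scale, 1)
})

test_that("to_physical at unit scales is the identity and is always idempotent", {
  d <- chain_doc(3)
  expect_true(bdml_equal(to_physical(d), d))
  su <- bdml_scale_unit(0.9, 0.9, 1.0, 2.5, "micrometer", "second")
  d2 <- gen_expression_spheres(n_generations = 2, frames_per_cell = 2, seed = 3)$doc
  d2$body$scale_unit <- su
  p1 <- suppressWarnings(to_physical(d2))  # anisotropic z vs xy on spheres
  expect_true(bdml_equal(to_physical(p1), p1))
  # times and feature values scale too
  expect_equal(component_times(p1), component_times(d2) * 2.5)
})

test_that("feature values scale by their own feature_scale", {
  d <- chain_doc(2)  # GFP values 1, 2 at feature_scale 1
  idx <- match("GFP", vapply(d$body$features, `[[`, "", "feature_name"))
  d$body$features[[idx]]$feature_scale <- 2
  p <- to_physical(d)
  vals <- vapply(components(p), function(cp)
    cp$measurements[[1]]$properties[[1]]$feature_val, 0)
  expect_equal(vals, c(2, 4))
  expect_identical(p$body$features[[idx]]$feature_scale, 1)
})

test_that("polyline_length matches closed forms and a brute-force oracle", {
  square <- bdml_line(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                            c(0, 1, 0), c(0, 0, 0)))
  expect_identical(polyline_length(square), 4)
  expect_identical(polyline_length(bdml_line(rbind(c(0, 0, 0), c(3, 4, 0)))), 5)
  set.seed(42)
  for (i in 1:50) {
    m <- matrix(runif(30, -10, 10), ncol = 3)
    su <- bdml_scale_unit(runif(1, 0.1, 3), runif(1, 0.1, 3), runif(1, 0.1, 3),
                          1, "micrometer", "second")
    # independent segment-wise oracle
    expected <- 0
    for (k in 1:(nrow(m) - 1)) {
      a <- m[k, ] * c(su$x_scale, su$y_scale, su$z_scale)
      b <- m[k + 1, ] * c(su$x_scale, su$y_scale, su$z_scale)
      expected <- expected + sqrt(sum((b - a)^2))
    }
    got <- polyline_length(bdml_line(m), su)
    expect_equal(got, expected, tolerance = 1e-12)
    # invariant under vertex-order reversal
    expect_equal(polyline_length(bdml_line(m[nrow(m):1, ]), su), got,
                 tolerance = 1e-12)
  }
})

test_that("is_closed_chain detects exactly-joined endpoints", {
  square <- bdml_line(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                            c(0, 1, 0), c(0, 0, 0)))
  expect_true(is_closed_chain(square))
  expect_false(is_closed_chain(bdml_line(rbind(c(0, 0, 0), c(1, 0, 0)))))
  expect_error(is_closed_chain(bdml_point(c(0, 0, 0))), class = "bdml_wrong-kind")
})

test_that("measure_size matches the closed forms of each entity kind", {
  expect_equal(measure_size(bdml_sphere(c(0, 0, 0), 1)), 4 * pi / 3)
  expect_equal(measure_size(bdml_circle(c(5, 5, 5), 2)), 4 * pi)
  expect_equal(measure_size(bdml_face(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))), 0.5)
  expect_identical(measure_size(bdml_point(c(1, 2, 3))), 0)
  # sizes are never negative; degenerate faces have zero area
  expect_identical(
    measure_size(bdml_face(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)))), 0)
})

test_that("radii scale by x_scale, warning when scales are anisotropic", {
  iso <- bdml_scale_unit(2, 2, 2, 1, "micrometer", "second")
  expect_equal(measure_size(bdml_sphere(c(0, 0, 0), 1), iso), 4 / 3 * pi * 8)
  aniso <- bdml_scale_unit(2, 1, 1, 1, "micrometer", "second")
  expect_warning(v <- measure_size(bdml_sphere(c(0, 0, 0), 1), aniso),
                 "anisotropic-radius")
  expect_equal(v, 4 / 3 * pi * 8)
  # circles only care about x vs y
  circ_su <- bdml_scale_unit(2, 2, 7, 1, "micrometer", "second")
  expect_no_warning(measure_size(bdml_circle(c(0, 0, 0), 1), circ_su))
})

test_that("centroid equals the brute-force mean of representative points", {
  d <- minimal_doc()
  d <- add_object(d, "m")
  d <- add_component(d, 3)
  cid <- last_component_id(d)
  d <- add_measurement(d, cid, "m", bdml_point(c(2, 4, 6)))
  cen <- centroid(components(d)[[1]])
  expect_equal(c(cen$x, cen$y, cen$z, cen$t), c(2, 4, 6, 3))

  d2 <- minimal_doc()
  d2 <- add_object(d2, "m")
  d2 <- add_component(d2, 0)
  cid <- last_component_id(d2)
  d2 <- add_measurement(d2, cid, "m", bdml_sphere(c(0, 0, 0), 1))
  d2 <- add_measurement(d2, cid, "m", bdml_sphere(c(2, 0, 0), 1))
  cen2 <- centroid(components(d2)[[1]])
  expect_equal(c(cen2$x, cen2$y, cen2$z), c(1, 0, 0))

  # random component against an independently computed mean
  set.seed(7)
  d3 <- gen_random_document(31, n_components = 1)
  cp <- components(d3)[[1]]
  su <- d3$body$scale_unit
  reps <- sapply(cp$measurements, function(ms) {
    e <- ms$entity
    switch(e$kind, point = e$xyz, line = colMeans(e$coords),
           face = colMeans(e$coords), e$center)
  })
  expected <- rowMeans(reps) * c(su$x_scale, su$y_scale, su$z_scale)
  got <- centroid(cp, su)
  expect_equal(c(got$x, got$y, got$z), unname(expected), tolerance = 1e-12)
})

test_that("isotropic rescaling acts linearly on lengths and cubically on volumes", {
  m <- matrix(runif(15, 0, 10), ncol = 3)
  for (s in c(0.5, 2, 3.7)) {
    su <- bdml_scale_unit(s, s, s, 1, "micrometer", "second")
    expect_equal(polyline_length(bdml_line(m), su),
                 s * polyline_length(bdml_line(m)), tolerance = 1e-12)
    expect_equal(measure_size(bdml_sphere(c(0, 0, 0), 2), su),
                 s^3 * measure_size(bdml_sphere(c(0, 0, 0), 2)), tolerance = 1e-12)
  }
})

test_that("z_scale = 0 flattens all physical z coordinates to zero", {
  g <- gen_worm_track2d(n_frames = 3, seed = 1)
  p <- to_physical(g$doc)
  for (cp in components(p))
    expect_true(all(cp$measurements[[1]]$entity$coords[, 3] == 0))
  tab <- coordinates_table(g$doc)
  expect_true(all(tab$z == 0))
})

test_that("component_summary reports physical times, centroids and sizes", {
  d <- chain_doc(3)
  s <- component_summary(d)
  expect_identical(nrow(s), 3L)
  expect_identical(s$component_id, component_ids(d))
  expect_equal(s$centroid_x, c(1, 2, 3))
  expect_identical(s$total_size, rep(0, 3))  # points have zero size
})
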