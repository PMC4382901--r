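test_that("molecule generator emits one component per frame with all molecules", {
  g <- gen_molecule_points(n_molecules = 3, n_frames = 5, seed = 1)
  expect_length(components(g$doc), 5)
  for (cp in components(g$doc)) expect_length(cp$measurements, 3)
  su <- g$doc$body$scale_unit
  expect_identical(su$xyz_unit, "meter")
  expect_identical(c(su$x_scale, su$y_scale, su$z_scale, su$t_scale),
                   c(1, 1, 1, 1))
  expect_identical(g$doc$summary$basedon, "simulation")
})

test_that("zero diffusion freezes molecule coordinates across frames", {
  g <- gen_molecule_points(n_molecules = 4, n_frames = 6, diffusion_step = 0,
                           seed = 2)
  first <- t(vapply(components(g$doc)[[1]]$measurements,
                    function(ms) ms$entity$xyz, numeric(3)))
  for (cp in components(g$doc))
    expect_identical(t(vapply(cp$measurements, function(ms) ms$entity$xyz,
                              numeric(3))), first)
})

test_that("molecule positions stay inside the rod-shaped cell volume", {
  g <- gen_molecule_points(n_molecules = 20, n_frames = 20,
                           diffusion_step = 3e-7, cell_length = 2e-6,
                           cell_radius = 5e-7, seed = 3)
  pos <- g$truth$positions
  half <- 1e-6; R <- 5e-7
  inside <- apply(pos, c(1, 2), function(p) {
    if (abs(p[1]) <= half) sqrt(p[2]^2 + p[3]^2) <= R + 1e-12
    else sqrt((abs(p[1]) - half)^2 + p[2]^2 + p[3]^2) <= R + 1e-12
  })
  expect_true(all(inside))
})

test_that("mean squared displacement follows the Brownian closed form", {
  g <- gen_molecule_points(n_molecules = 1000, n_frames = 10, seed = 4)
  pos <- g$truth$positions
  t <- 9
  disp <- pos[10, , ] - pos[1, , ]
  msd <- mean(rowSums(disp^2))
  expect_equal(msd, 3 * g$truth$diffusion_step^2 * t, tolerance = 0.1)
})

test_that("dividing-nuclei contours are closed chains under the printed calibration", {
  g <- gen_dividing_nuclei(n_generations = 3, frames_per_cell = 3, seed = 5)
  su <- g$doc$body$scale_unit
  expect_identical(c(su$x_scale, su$y_scale, su$z_scale), c(0.105, 0.105, 0.5))
  expect_identical(su$xyz_unit, "micrometer")
  for (cp in components(g$doc))
    expect_true(is_closed_chain(cp$measurements[[1]]$entity))
  expect_identical(g$truth$n_branches, 7L)
  expect_identical(g$truth$n_divisions, 3L)
})

test_that("planted contour perimeters respect the inscribed-polygon bound", {
  nv <- 24
  g <- gen_dividing_nuclei(n_generations = 2, vertices_per_contour = nv,
                           frames_per_cell = 2, seed = 6)
  comps <- components(g$doc)
  for (i in seq_along(comps)) {
    r <- g$truth$components$radius[i]
    len <- polyline_length(comps[[i]]$measurements[[1]]$entity)
    # inscribed regular n-gon perimeter: 2 n r sin(pi/n) <= 2 pi r
    expect_equal(len, 2 * nv * r * sin(pi / nv), tolerance = 1e-9)
    expect_lte(2 * pi * r - len, 2 * pi * r * (1 - sin(pi / nv) / (pi / nv)) + 1e-9)
  }
})

test_that("microtubule segments start exactly on the pronucleus surface", {
  g <- gen_pronucleus_microtubules(n_microtubules = 8, n_frames = 4, seed = 7)
  comps <- components(g$doc)
  for (f in seq_along(comps)) {
    ms <- comps[[f]]$measurements
    expect_length(ms, 1 + 8)  # one sphere plus the segments
    sph <- ms[[1]]$entity
    expect_identical(sph$kind, "sphere")
    expect_equal(sph$center, g$truth$centers[f, ], tolerance = 1e-12)
    for (k in 2:length(ms)) {
      v <- ms[[k]]$entity$coords[1, ]
      expect_equal(sqrt(sum((v - sph$center)^2)), sph$radius, tolerance = 1e-9)
    }
  }
})

test_that("the split layout yields two set members with matched frame times", {
  g <- gen_pronucleus_microtubules(n_microtubules = 5, n_frames = 3,
                                   layout = "separate_components", seed = 8)
  expect_s3_class(g$doc$body, "bdml_set")
  expect_length(g$parts, 2)
  expect_identical(g$doc$body$entries$bdml_id,
                   vapply(g$parts, function(p) p$info$bdml_id, "",
                          USE.NAMES = FALSE))
  expect_identical(component_times(g$parts$pronucleus),
                   component_times(g$parts$microtubules))
  for (cp in components(g$parts$microtubules)) expect_length(cp$measurements, 5)
})

test_that("noiseless GFP dynamics are exactly linear along every track", {
  g <- gen_expression_spheres(n_generations = 2, frames_per_cell = 4,
                              intensity_slope = 0.7, noise_sd = 0, seed = 9)
  fu <- vapply(g$doc$body$features, `[[`, "", "feature_unit")
  expect_identical(fu, "a.u.")
  su <- g$doc$body$scale_unit
  expect_identical(c(su$x_scale, su$y_scale, su$z_scale), c(0.9, 0.9, 1.0))
  tracks <- extract_tracks(build_lineage(g$doc))
  for (tr in tracks) {
    ts <- feature_timeseries(g$doc, tr, "GFP")
    if (nrow(ts) < 2) next
    slopes <- diff(ts$value) / diff(ts$time)
    expect_equal(slopes, rep(0.7, nrow(ts) - 1), tolerance = 1e-9)
  }
})

test_that("the planted GFP slope is recovered from a noisy 50-frame track", {
  g <- gen_expression_spheres(n_generations = 1, frames_per_cell = 50,
                              intensity_slope = 1, noise_sd = 0.1, seed = 10)
  tr <- extract_tracks(build_lineage(g$doc))[[1]]
  ts <- feature_timeseries(g$doc, tr, "GFP")
  fit <- stats::lm(value ~ time, data = ts)
  est <- stats::coef(fit)[["time"]]
  se <- summary(fit)$coefficients["time", "Std. Error"]
  expect_lt(abs(est - 1), 3 * se)
})

test_that("worm tracks are flat open centerlines of exactly constant length", {
  g <- gen_worm_track2d(n_frames = 10, body_points = 30, seed = 11)
  su <- g$doc$body$scale_unit
  expect_identical(c(su$x_scale, su$y_scale, su$z_scale), c(4.1, 4.1, 0))
  lens <- vapply(components(g$doc), function(cp) {
    e <- cp$measurements[[1]]$entity
    expect_false(is_closed_chain(e))
    expect_true(all(e$coords[, 3] == 0))
    polyline_length(e)
  }, 0)
  expect_equal(lens, rep(g$truth$length_px, 10), tolerance = 1e-6)
})

test_that("every generator output is semantically valid and schema-conformant", {
  outs <- list(
    gen_molecule_points(n_molecules = 2, n_frames = 3, seed = 1)$doc,
    gen_dividing_nuclei(n_generations = 2, frames_per_cell = 2, seed = 1)$doc,
    gen_pronucleus_microtubules(n_microtubules = 3, n_frames = 2, seed = 1)$doc,
    gen_expression_spheres(n_generations = 2, frames_per_cell = 2, seed = 1)$doc,
    gen_worm_track2d(n_frames = 3, body_points = 5, seed = 1)$doc
  )
  schema <- bdml_schema()
  for (d in outs) {
    expect_true(validate_bdml(d)$is_valid)
    x <- write_bdml(d)
    expect_true(xml2::xml_validate(xml2::read_xml(charToRaw(x)), schema))
  }
})

test_that("generators are byte-deterministic given parameters and seed", {
  pairs <- list(
    c1 = list(gen_molecule_points(3, 3, seed = 13), gen_molecule_points(3, 3, seed = 13)),
    c2 = list(gen_dividing_nuclei(2, 12, 2, seed = 13), gen_dividing_nuclei(2, 12, 2, seed = 13)),
    c3 = list(gen_expression_spheres(2, 2, noise_sd = 0.5, seed = 13),
              gen_expression_spheres(2, 2, noise_sd = 0.5, seed = 13)),
    c4 = list(gen_worm_track2d(3, 8, seed = 13), gen_worm_track2d(3, 8, seed = 13))
  )
  for (p in pairs)
    expect_identical(write_bdml(p[[1]]$doc), write_bdml(p[[2]]$doc))
  # and different seeds give different documents
  expect_false(identical(write_bdml(gen_worm_track2d(3, 8, seed = 1)$doc),
                         write_bdml(gen_worm_track2d(3, 8, seed = 2)$doc)))
})

test_that("generator parameter validation rejects nonsense", {
  expect_error(gen_molecule_points(n_molecules = 0), class = "bdml_invalid-params")
  expect_error(gen_dividing_nuclei(vertices_per_contour = 2),
               class = "bdml_invalid-params")
  expect_error(gen_worm_track2d(body_points = 1), class = "bdml_invalid-params")
  expect_error(gen_expression_spheres(noise_sd = -1), class = "bdml_invalid-params")
})
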