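test_that("constructor-built and generator documents validate with zero errors", {
  docs <- list(
    chain_doc(4),
    gen_dividing_nuclei(n_generations = 2, frames_per_cell = 2, seed = 1)$doc,
    gen_expression_spheres(n_generations = 2, frames_per_cell = 2, seed = 1)$doc,
    gen_worm_track2d(n_frames = 3, seed = 1)$doc,
    gen_molecule_points(n_molecules = 3, n_frames = 3, seed = 1)$doc
  )
  for (d in docs) {
    rep <- validate_bdml(d)
    expect_true(rep$is_valid)
    expect_identical(nrow(rep$violations), 0L)
  }
})

test_that("two components sharing a time yield exactly one TIME-DUPLICATE", {
  d <- chain_doc(3, times = c(5, 8, 11))
  d$body$components[[2]]$time <- 5
  d$body$components[[2]]$prev_ids <- character()
  rep <- validate_bdml(d)
  expect_identical(sum(rep$violations$code == "TIME-DUPLICATE"), 1L)
  expect_false(rep$is_valid)
})

test_that("dangling ontology references warn without invalidating the document", {
  d <- chain_doc(2)
  d$summary$datatype_ref <- "missing-term"
  rep <- validate_bdml(d)
  expect_true("ONTOREF-UNKNOWN" %in% rep$violations$code)
  expect_identical(
    rep$violations$severity[rep$violations$code == "ONTOREF-UNKNOWN"], "warning")
  expect_true(rep$is_valid)
})

test_that("unresolved backward links downgrade to warnings in series parts", {
  d <- chain_doc(3, times = 5:7)
  d$body$components[[1]]$prev_ids <- "c9999"  # lives in the previous file
  expect_false(validate_bdml(d)$is_valid)
  rep <- validate_bdml(d, series_part = TRUE)
  expect_true(rep$is_valid)
  expect_true("PREV-UNKNOWN" %in% rep$violations$code)
})

test_that("single-fault injection is detected with the correct code for all 13 codes", {
  # documents rich enough for every mutation (>= 2 components, measurements,
  # feature properties)
  seeds_with_props <- Filter(function(s) {
    d <- gen_random_document(s, n_components = 5)
    any(vapply(components(d), function(cp)
      any(vapply(cp$measurements, function(ms) length(ms$properties) > 0, TRUE)),
      TRUE))
  }, 1:20)[1:5]
  for (s in seeds_with_props) {
    d <- gen_random_document(s, n_components = 5)
    for (code in violation_codes()) {
      xml <- inject_violation(d, code, seed = s + 100)
      rep <- validate_bdml(read_bdml(xml))
      expect_true(code %in% rep$violations$code,
                  info = sprintf("code %s, seed %d", code, s))
    }
  }
})

test_that("the injector is deterministic given document, code and seed", {
  d <- gen_random_document(4, n_components = 6)
  for (code in c("TIME-DUPLICATE", "ENTITY-MALFORMED", "PREV-FORWARD"))
    expect_identical(inject_violation(d, code, seed = 7),
                     inject_violation(d, code, seed = 7))
})

test_that("injection on insufficient material raises not-applicable", {
  d <- chain_doc(1)  # single component, no way to duplicate a time
  expect_error(inject_violation(d, "TIME-DUPLICATE"),
               class = "bdml_not-applicable")
  d2 <- minimal_doc()
  d2 <- add_object(d2, "m")
  d2 <- add_component(d2, 0)
  d2 <- add_measurement(d2, last_component_id(d2), "m", bdml_point(c(0, 0, 0)))
  expect_error(inject_violation(d2, "FEATURE-UNKNOWN"),
               class = "bdml_not-applicable")
})

test_that("validation is pure and reports are exportable as JSON lines", {
  d <- read_bdml(inject_violation(chain_doc(3), "UNIT-ENUM"))
  r1 <- validate_bdml(d)
  r2 <- validate_bdml(d)
  expect_identical(r1, r2)
  lines <- report_jsonl(r1)
  expect_length(lines, nrow(r1$violations))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_named(parsed, c("code", "path", "message", "severity"),
               ignore.order = TRUE)
})
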