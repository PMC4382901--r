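test_that("new documents carry a fresh v4 UUID and format version 0.2", {
  d <- minimal_doc()
  expect_match(d$info$bdml_id,
               "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
  expect_identical(d$info$bdml_version, "0.2")
  expect_length(d$ontology, 0)
  expect_length(components(d), 0)
  d2 <- minimal_doc()
  expect_false(identical(d$info$bdml_id, d2$info$bdml_id))
})

test_that("contact, unit and enum preconditions are enforced at construction", {
  expect_error(bdml_contact("Name", "", "Lab"), class = "bdml_invalid-contact")
  expect_error(bdml_contact("Name", "not-an-email", "Lab"),
               class = "bdml_invalid-contact")
  expect_error(bdml_scale_unit(xyz_unit = "parsec"), class = "bdml_invalid-unit")
  expect_error(bdml_scale_unit(t_unit = "fortnight"), class = "bdml_invalid-unit")
  expect_error(bdml_scale_unit(x_scale = -1), class = "bdml_invalid-unit")
  expect_error(bdml_summary("d", "t", "o", basedon = "hearsay"))
  expect_error(bdml_feature("f", feature_scale = 0), class = "bdml_invalid-unit")
})

test_that("the unit vocabularies have the documented sizes and members", {
  u <- bdml_units()
  expect_length(u, 34)
  expect_false(anyDuplicated(u) > 0)
  expect_true(all(c("a.u.", "p.d.u.", "micrometer", "meter", "liter") %in% u))
  tu <- bdml_time_units()
  expect_length(tu, 9)
  expect_identical(tu[c(1, 9)], c("nanosecond", "year"))
})

test_that("components must be separated in time and link strictly backwards", {
  d <- chain_doc(1)
  expect_length(components(d), 1)
  expect_identical(components(d)[[1]]$prev_ids, character(0))
  expect_error(add_component(d, 0), class = "bdml_duplicate-time")
  expect_error(add_component(d, 5, prev_ids = "nonexistent"),
               class = "bdml_unknown-prev")
  # same-time and forward links are rejected too
  d <- add_component(d, 5)
  id5 <- last_component_id(d)
  expect_error(add_component(d, 3, prev_ids = id5), class = "bdml_unknown-prev")
})

test_that("entity constructors reject malformed geometry", {
  expect_error(bdml_line(rbind(c(0, 0, 0))), class = "bdml_malformed-entity")
  expect_error(bdml_face(matrix(runif(12), 4)), class = "bdml_malformed-entity")
  expect_error(bdml_sphere(c(0, 0, 0), 0), class = "bdml_malformed-entity")
  expect_error(bdml_circle(c(0, 0, 0), -2), class = "bdml_malformed-entity")
  expect_error(bdml_point(c(1, 2)), class = "bdml_malformed-entity")
})

test_that("measurements check their object and feature references", {
  d <- chain_doc(1)
  cid <- component_ids(d)[1]
  d2 <- add_measurement(d, cid, "cell", bdml_sphere(c(0, 0, 0), 1))
  expect_length(components(d2)[[1]]$measurements, 2)
  expect_error(add_measurement(d, cid, "nucleus", bdml_point(c(0, 0, 0))),
               class = "bdml_unknown-object")
  expect_error(add_measurement(d, cid, "cell", bdml_point(c(0, 0, 0)),
                               properties = c(RFP = 1)),
               class = "bdml_unknown-feature")
})

test_that("constructor-built random documents always satisfy every invariant", {
  for (s in 1:25) {
    d <- gen_random_document(s)
    rep <- validate_bdml(d)
    expect_true(rep$is_valid, info = paste("seed", s))
    expect_identical(sum(rep$violations$severity == "error"), 0L)
    # ids unique, links acyclic by construction
    expect_false(anyDuplicated(component_ids(d)) > 0)
    expect_s3_class(build_lineage(d), "bdml_lineage")
  }
})
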