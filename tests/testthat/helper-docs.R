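# shared fixture builders (all fixtures are built in code)

minimal_doc <- function(scale_unit = bdml_scale_unit(1, 1, 1, 1, "meter", "second")) {
  new_document(
    summary = bdml_summary("minimal test document", "test dynamics",
                           "Caenorhabditis elegans", basedon = "experiment"),
    contact = bdml_contact("Test Person", "test@example.org", "Test Lab"),
    methods = bdml_methods(source_uri = "https://example.org/src"),
    scale_unit = scale_unit
  )
}

# a small document with one object, one feature and n chained components,
# each holding one point measurement
chain_doc <- function(n = 3, times = seq_len(n) - 1) {
  doc <- minimal_doc()
  doc <- add_object(doc, "cell")
  doc <- add_feature(doc, bdml_feature("GFP", 1, "a.u."))
  prev <- character()
  for (i in seq_len(n)) {
    doc <- add_component(doc, time = times[i], prev_ids = prev)
    prev <- last_component_id(doc)
    doc <- add_measurement(doc, prev, "cell", bdml_point(c(i, 2 * i, 0)),
                           properties = c(GFP = i))
  }
  doc
}

# binary division over components: root chain then two child chains, each
# child extending `tail_len` components after the branch point
division_doc <- function(tail_len = 2) {
  doc <- minimal_doc()
  doc <- add_object(doc, "cell")
  doc <- add_component(doc, 0, component_id = "A")
  doc <- add_measurement(doc, "A", "cell", bdml_point(c(0, 0, 0)))
  t <- 1
  for (child in c("B", "C")) {
    prev <- "A"
    for (k in seq_len(tail_len)) {
      id <- paste0(child, k)
      doc <- add_component(doc, t, prev_ids = prev, component_id = id)
      doc <- add_measurement(doc, id, "cell", bdml_point(c(t, 0, 0)))
      prev <- id
      t <- t + 1
    }
  }
  doc
}
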