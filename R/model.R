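# In-memory document model for BDML 0.2.
#
# A BDML document carries six top-level slots -- info, ontology, summary,
# contact, methods and a body that is exactly one of data / series / set.
# Constructors enforce the local invariants of each element so that any
# document assembled through them is semantically valid; document-wide
# checks live in validate_bdml().

# ---- metadata elements ----------------------------------------------------

#' Create the info element of a BDML document
#'
#' Every BDML file carries a unique identifier (`bdmlID`, an RFC-4122 UUID)
#' so files can be shared and cross-referenced without central coordination,
#' plus explicit license information.
#'
#' @param bdml_id UUID string; defaults to a freshly generated version-4 UUID.
#' @param license Non-empty license text (e.g. a Creative Commons license name).
#' @param title Optional free-text title.
#' @param release_date Optional ISO-8601 date string.
#' @return An object of class `bdml_info`.
#' @export
bdml_info <- function(bdml_id = uuid4(), license = "CC BY 4.0",
                      title = NULL, release_date = NULL) {
  if (!is_uuid(bdml_id))
    stop_bdml("invalid-document", sprintf("bdmlID '%s' is not an RFC-4122 UUID", bdml_id))
  if (!is_nonempty_string(license))
    stop_bdml("invalid-document", "license must be a non-empty string")
  structure(
    list(bdml_id = bdml_id, title = title, license = license,
         release_date = release_date, bdml_version = "0.2"),
    class = "bdml_info"
  )
}

#' Create an ontology term
#'
#' Associates a local identifier used inside the document with a term from an
#' external ontology source (for example the NCBI taxonomy). Elements that
#' accept an `ontology_ref` argument refer back to the `id` given here.
#'
#' @param id Local identifier, unique within the document's ontology section.
#' @param term The term text.
#' @param ontology_id Accession identifier in the source ontology.
#' @param ontology_uri Unique identifier (URI) of the ontology source.
#' @return An object of class `bdml_ontology_term`.
#' @export
bdml_ontology_term <- function(id, term, ontology_id, ontology_uri) {
  for (f in c(id, term, ontology_id, ontology_uri))
    if (!is_nonempty_string(f))
      stop_bdml("invalid-document", "all ontology term fields must be non-empty strings")
  structure(
    list(id = id, term = term, ontology_id = ontology_id,
         ontology_uri = ontology_uri),
    class = "bdml_ontology_term"
  )
}

#' Create the summary element
#'
#' A concise description of the quantitative data: the biological process
#' targeted (`datatype`), the organism (named per NCBI taxonomy), and whether
#' the data derive from an experimental measurement or a computer simulation.
#'
#' @param description Free-text description.
#' @param datatype Term naming the biological process observed.
#' @param organism Organism name (NCBI taxonomy nomenclature).
#' @param basedon Either `"experiment"` or `"simulation"`.
#' @param local_id Optional author-internal identifier.
#' @param references Character vector of publication/database citations.
#' @param datatype_ref,organism_ref Optional ontology term ids (see
#'   [bdml_ontology_term()]).
#' @return An object of class `bdml_summary`.
#' @export
bdml_summary <- function(description, datatype, organism,
                         basedon = c("experiment", "simulation"),
                         local_id = NULL, references = character(),
                         datatype_ref = NULL, organism_ref = NULL) {
  basedon <- match.arg(basedon)
  for (f in c(description, datatype, organism))
    if (!is_nonempty_string(f))
      stop_bdml("invalid-document", "summary description/datatype/organism must be non-empty")
  structure(
    list(description = description, datatype = datatype, organism = organism,
         local_id = local_id, basedon = basedon,
         references = as.character(references),
         datatype_ref = datatype_ref, organism_ref = organism_ref),
    class = "bdml_summary"
  )
}

#' Create the contact element
#'
#' Contact name, e-mail address and affiliation of the corresponding author
#' are mandatory in every BDML file.
#'
#' @param name Person name.
#' @param email E-mail address (must contain an `@` with non-empty sides).
#' @param affiliation Institution text.
#' @return An object of class `bdml_contact`.
#' @export
bdml_contact <- function(name, email, affiliation) {
  for (f in list(name, email, affiliation))
    if (!is_nonempty_string(f))
      stop_bdml("invalid-contact", "contact name, email and affiliation must all be non-empty")
  if (!grepl("^[^@[:space:]]+@[^@[:space:]]+$", email))
    stop_bdml("invalid-contact", sprintf("'%s' is not a plausible e-mail address", email))
  structure(list(name = name, email = email, affiliation = affiliation),
            class = "bdml_contact")
}

#' Create the methods element
#'
#' Describes how the quantitative data were produced, through two URIs: one
#' pointing at the original sources (microscopic images for a measurement,
#' model files for a simulation) and one at a description of the
#' data-processing procedure. Both links are stored as opaque URIs.
#'
#' @param source_uri Optional URI to the original sources.
#' @param procedure_uri Optional URI to the processing procedure.
#' @param notes Optional free text.
#' @return An object of class `bdml_methods`.
#' @export
bdml_methods <- function(source_uri = NULL, procedure_uri = NULL, notes = NULL) {
  for (u in c(source_uri, procedure_uri))
    if (!is.null(u) && !is_uri(u))
      stop_bdml("invalid-document", sprintf("'%s' is not a syntactically valid URI", u))
  structure(list(source_uri = source_uri, procedure_uri = procedure_uri,
                 notes = notes),
            class = "bdml_methods")
}

#' Create the scaleUnit element
#'
#' Maps stored coordinates and frame indices to physical positions and times.
#' Experimental data are typically recorded in pixel coordinates and regular
#' time frames; the per-axis scale factors convert them to the named units.
#' Setting all scale factors to 1.0 stores physical values directly, and
#' `z_scale = 0` marks two-dimensional data.
#'
#' @param x_scale,y_scale,z_scale,t_scale Non-negative scale factors.
#' @param xyz_unit Spatial unit, one of [bdml_units()].
#' @param t_unit Time unit, one of [bdml_time_units()].
#' @return An object of class `bdml_scale_unit`.
#' @export
#' @examples
#' # confocal stack: 0.105 um/px in x and y, 0.5 um z-step, 1 s frames
#' bdml_scale_unit(0.105, 0.105, 0.5, 1, "micrometer", "second")
bdml_scale_unit <- function(x_scale = 1, y_scale = 1, z_scale = 1,
                            t_scale = 1, xyz_unit = "micrometer",
                            t_unit = "second") {
  for (s in list(x_scale, y_scale, z_scale, t_scale))
    if (!is_scalar_num(s) || s < 0)
      stop_bdml("invalid-unit", "scale factors must be single non-negative numbers")
  if (!is_string(xyz_unit) || !(xyz_unit %in% bdml_units()))
    stop_bdml("invalid-unit", sprintf("'%s' is not a valid spatial unit", xyz_unit))
  if (!is_string(t_unit) || !(t_unit %in% bdml_time_units()))
    stop_bdml("invalid-unit", sprintf("'%s' is not a valid time unit", t_unit))
  structure(
    list(x_scale = as.numeric(x_scale), y_scale = as.numeric(y_scale),
         z_scale = as.numeric(z_scale), t_scale = as.numeric(t_scale),
         xyz_unit = xyz_unit, t_unit = t_unit),
    class = "bdml_scale_unit"
  )
}

#' Declare an object type
#'
#' Object types name the biological objects whose dynamics are recorded
#' (e.g. `"nucleus"`, `"microtubule"`); measurements refer to them by name.
#'
#' @param object_name Unique object type name.
#' @param ontology_ref Optional ontology term id.
#' @return An object of class `bdml_object`.
#' @export
bdml_object <- function(object_name, ontology_ref = NULL) {
  if (!is_nonempty_string(object_name))
    stop_bdml("invalid-document", "object_name must be a non-empty string")
  structure(list(object_name = object_name, ontology_ref = ontology_ref),
            class = "bdml_object")
}

#' Declare a feature type
#'
#' Features attach per-object scalar values to measurements (e.g. total GFP
#' signal); each declares its own scale factor and unit, so stored raw values
#' convert to physical values the same way coordinates do.
#'
#' @param feature_name Unique feature name.
#' @param feature_scale Positive scale factor applied to stored values.
#' @param feature_unit Unit name, one of [bdml_units()] (fluorescence data
#'   conventionally uses `"a.u."`).
#' @param ontology_ref Optional ontology term id.
#' @return An object of class `bdml_feature`.
#' @export
bdml_feature <- function(feature_name, feature_scale = 1,
                         feature_unit = "a.u.", ontology_ref = NULL) {
  if (!is_nonempty_string(feature_name))
    stop_bdml("invalid-document", "feature_name must be a non-empty string")
  if (!is_scalar_num(feature_scale) || feature_scale <= 0)
    stop_bdml("invalid-unit", "feature_scale must be a single positive number")
  if (!is_string(feature_unit) || !(feature_unit %in% bdml_units()))
    stop_bdml("invalid-unit", sprintf("'%s' is not a valid feature unit", feature_unit))
  structure(
    list(feature_name = feature_name, feature_scale = as.numeric(feature_scale),
         feature_unit = feature_unit, ontology_ref = ontology_ref),
    class = "bdml_feature"
  )
}

# ---- geometric entities ---------------------------------------------------

as_xyz <- function(v, what) {
  v <- suppressWarnings(as.numeric(v))
  if (length(v) != 3L || anyNA(v) || !all(is.finite(v)))
    stop_bdml("malformed-entity", sprintf("%s must be a finite (x, y, z) triple", what))
  unname(v)
}

as_xyz_matrix <- function(m, what) {
  if (is.numeric(m) && is.null(dim(m))) m <- matrix(m, ncol = 3, byrow = TRUE)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L || anyNA(m) || !all(is.finite(m)))
    stop_bdml("malformed-entity", sprintf("%s must be an n x 3 matrix of finite coordinates", what))
  dimnames(m) <- NULL
  m
}

new_entity <- function(kind, payload) {
  structure(c(list(kind = kind), payload),
            class = c(paste0("bdml_", kind), "bdml_entity"))
}

#' Geometric entities
#'
#' BDML describes the spatial extent of an object with five geometric
#' primitives: a point (one 3D coordinate), a line (a polyline of two or more
#' connected vertices; a closed polygonal chain when the first and last
#' vertex coincide), a circle and a sphere (centre plus strictly positive
#' radius) and a face (a closed triangle given by exactly three vertices).
#' Complex shapes are built by combining entities across measurements.
#'
#' Stored coordinates are raw (typically pixel) values; [to_physical()]
#' applies the document's scale factors.
#'
#' @param xyz A numeric (x, y, z) triple.
#' @param coords An n x 3 coordinate matrix (or a length-3n vector, filled
#'   row-wise); `bdml_line()` needs at least two rows, `bdml_face()` exactly
#'   three.
#' @param center Numeric (x, y, z) centre.
#' @param radius Strictly positive radius, in the same raw units as the
#'   coordinates.
#' @return An object of class `bdml_entity` with a `kind` field in
#'   `c("point", "line", "circle", "sphere", "face")`.
#' @name bdml_entity
#' @examples
#' bdml_point(c(1, 2, 3))
#' bdml_line(rbind(c(0, 0, 0), c(3, 4, 0)))
#' bdml_sphere(center = c(0, 0, 0), radius = 2.5)
NULL

#' @rdname bdml_entity
#' @export
bdml_point <- function(xyz) {
  new_entity("point", list(xyz = as_xyz(xyz, "point")))
}

#' @rdname bdml_entity
#' @export
bdml_line <- function(coords) {
  m <- as_xyz_matrix(coords, "line")
  if (nrow(m) < 2L)
    stop_bdml("malformed-entity", "a line needs at least 2 vertices")
  new_entity("line", list(coords = m))
}

#' @rdname bdml_entity
#' @export
bdml_circle <- function(center, radius) {
  if (!is_scalar_num(radius) || radius <= 0)
    stop_bdml("malformed-entity", "circle radius must be strictly positive")
  new_entity("circle", list(center = as_xyz(center, "circle center"),
                            radius = as.numeric(radius)))
}

#' @rdname bdml_entity
#' @export
bdml_sphere <- function(center, radius) {
  if (!is_scalar_num(radius) || radius <= 0)
    stop_bdml("malformed-entity", "sphere radius must be strictly positive")
  new_entity("sphere", list(center = as_xyz(center, "sphere center"),
                            radius = as.numeric(radius)))
}

#' @rdname bdml_entity
#' @export
bdml_face <- function(coords) {
  m <- as_xyz_matrix(coords, "face")
  if (nrow(m) != 3L)
    stop_bdml("malformed-entity",
              sprintf("a face is a closed polygonal chain with exactly 3 vertices, got %d", nrow(m)))
  new_entity("face", list(coords = m))
}

# normalize user-supplied properties into a list of (feature_ref, feature_val)
as_properties <- function(properties) {
  if (is.null(properties) || length(properties) == 0) return(list())
  if (is.numeric(properties)) {
    if (is.null(names(properties)) || any(!nzchar(names(properties))))
      stop_bdml("invalid-document", "numeric properties must be named by feature")
    return(unname(Map(function(n, v) list(feature_ref = n, feature_val = as.numeric(v)),
                      names(properties), properties)))
  }
  lapply(properties, function(p) {
    if (!is.list(p) || !is_nonempty_string(p$feature_ref) || !is_scalar_num(p$feature_val))
      stop_bdml("invalid-document", "each property needs a feature_ref and a numeric feature_val")
    list(feature_ref = p$feature_ref, feature_val = as.numeric(p$feature_val))
  })
}

new_measurement <- function(object_ref, entity, properties = list()) {
  structure(list(object_ref = object_ref, entity = entity,
                 properties = as_properties(properties)),
            class = "bdml_measurement")
}

# ---- document assembly ----------------------------------------------------

new_data_section <- function(scale_unit) {
  structure(list(scale_unit = scale_unit, objects = list(),
                 features = list(), components = list()),
            class = "bdml_data")
}

#' Create a series or set body
#'
#' Large datasets can be split over multiple BDML files. A *series* indexes
#' parts of one dataset cut into consecutive time windows; a *set* bundles
#' related but separate experiments or simulations (for example all
#' measurements behind one published work). Either body replaces the data
#' element of the index document and lists each part's `bdmlID` together with
#' a locator (file name or URI).
#'
#' @param bdml_ids Character vector of the parts' UUID identifiers (distinct).
#' @param locators Character vector of file names/URIs, same length.
#' @return An object of class `bdml_series` or `bdml_set`.
#' @export
bdml_series <- function(bdml_ids, locators) {
  new_index_body("series", bdml_ids, locators)
}

#' @rdname bdml_series
#' @export
bdml_set <- function(bdml_ids, locators) {
  new_index_body("set", bdml_ids, locators)
}

new_index_body <- function(kind, bdml_ids, locators) {
  bdml_ids <- as.character(bdml_ids); locators <- as.character(locators)
  if (length(bdml_ids) == 0L)
    stop_bdml("invalid-document", sprintf("a %s needs at least one entry", kind))
  if (length(bdml_ids) != length(locators))
    stop_bdml("invalid-document", "bdml_ids and locators must have the same length")
  if (anyDuplicated(bdml_ids))
    stop_bdml("invalid-document", sprintf("%s entries must have distinct bdmlIDs", kind))
  structure(list(entries = data.frame(bdml_id = bdml_ids, locator = locators,
                                      stringsAsFactors = FALSE)),
            class = paste0("bdml_", kind))
}

#' Create a new BDML document
#'
#' Assembles a complete document with a freshly generated version-4 UUID as
#' its identifier, format version 0.2, an empty ontology section and an empty
#' component list. Populate it with [add_object()], [add_feature()],
#' [add_component()] and [add_measurement()].
#'
#' @param summary A [bdml_summary()].
#' @param contact A [bdml_contact()].
#' @param methods A [bdml_methods()].
#' @param scale_unit A [bdml_scale_unit()].
#' @param license License text for the info element.
#' @param title Optional document title.
#' @param body Optional replacement body ([bdml_series()] / [bdml_set()]);
#'   by default an empty data section using `scale_unit`.
#' @return An object of class `bdml_document`.
#' @export
#' @examples
#' doc <- new_document(
#'   summary = bdml_summary("tracked nuclei", "cell division", "C. elegans",
#'                          basedon = "experiment"),
#'   contact = bdml_contact("A. Author", "author@lab.org", "Some Institute"),
#'   methods = bdml_methods(source_uri = "https://example.org/images"),
#'   scale_unit = bdml_scale_unit(0.105, 0.105, 0.5, 1, "micrometer", "second")
#' )
#' doc$info$bdml_version
new_document <- function(summary, contact, methods = bdml_methods(),
                         scale_unit = bdml_scale_unit(),
                         license = "CC BY 4.0", title = NULL, body = NULL) {
  stopifnot(inherits(summary, "bdml_summary"), inherits(contact, "bdml_contact"),
            inherits(methods, "bdml_methods"))
  if (is.null(body)) {
    stopifnot(inherits(scale_unit, "bdml_scale_unit"))
    body <- new_data_section(scale_unit)
  }
  structure(
    list(info = bdml_info(license = license, title = title),
         ontology = list(), summary = summary, contact = contact,
         methods = methods, body = body),
    class = "bdml_document"
  )
}

require_data_body <- function(doc) {
  stopifnot(inherits(doc, "bdml_document"))
  if (!inherits(doc$body, "bdml_data"))
    stop_bdml("invalid-document", "this operation needs a document with a data body")
  doc
}

#' Add an ontology term to a document
#'
#' @param doc A `bdml_document`.
#' @param term A [bdml_ontology_term()].
#' @return The modified document.
#' @export
add_ontology_term <- function(doc, term) {
  stopifnot(inherits(doc, "bdml_document"), inherits(term, "bdml_ontology_term"))
  if (term$id %in% vapply(doc$ontology, `[[`, "", "id"))
    stop_bdml("invalid-document", sprintf("ontology term id '%s' already declared", term$id))
  doc$ontology <- c(doc$ontology, list(term))
  doc
}

#' Declare object and feature types on a document
#'
#' @param doc A `bdml_document` with a data body.
#' @param object A [bdml_object()] (or a bare name string).
#' @param feature A [bdml_feature()].
#' @return The modified document.
#' @export
add_object <- function(doc, object) {
  doc <- require_data_body(doc)
  if (is.character(object)) object <- bdml_object(object)
  stopifnot(inherits(object, "bdml_object"))
  if (object$object_name %in% object_names(doc))
    stop_bdml("invalid-document",
              sprintf("object '%s' already declared", object$object_name))
  doc$body$objects <- c(doc$body$objects, list(object))
  doc
}

#' @rdname add_object
#' @export
add_feature <- function(doc, feature) {
  doc <- require_data_body(doc)
  stopifnot(inherits(feature, "bdml_feature"))
  if (feature$feature_name %in% feature_names(doc))
    stop_bdml("invalid-document",
              sprintf("feature '%s' already declared", feature$feature_name))
  doc$body$features <- c(doc$body$features, list(feature))
  doc
}

object_names <- function(doc) vapply(doc$body$objects, `[[`, "", "object_name")
feature_names <- function(doc) vapply(doc$body$features, `[[`, "", "feature_name")

#' Component accessors
#'
#' `components()` returns the list of components of a data-bodied document,
#' `component_ids()` their identifiers and `component_times()` their stored
#' (unscaled) time values, all in document order. `last_component_id()`
#' returns the identifier minted by the most recent [add_component()] call.
#'
#' @param doc A `bdml_document` with a data body.
#' @return A list, character vector or numeric vector, respectively.
#' @export
components <- function(doc) require_data_body(doc)$body$components

#' @rdname components
#' @export
component_ids <- function(doc)
  vapply(components(doc), `[[`, "", "component_id")

#' @rdname components
#' @export
component_times <- function(doc)
  vapply(components(doc), `[[`, 0, "time")

#' @rdname components
#' @export
last_component_id <- function(doc) attr(doc, "component_id")

#' Add a component (one time point) to a document
#'
#' A component collects everything observed at a single time point. Each
#' component must be separated in time (no two components may share a time
#' value) and carries a unique identifier. Backward links (`prev_ids`) tie a
#' component to components at strictly earlier times: one link continues a
#' track, several encode object fusion, and shared targets encode division.
#'
#' @param doc A `bdml_document` with a data body.
#' @param time Non-negative time value (frame index or elapsed time;
#'   interpreted through the document's `t_scale`).
#' @param name Optional component name.
#' @param prev_ids Character vector of earlier components' identifiers.
#' @param component_id Optional explicit identifier; auto-generated when `NULL`.
#' @return The modified document; the new component's identifier is available
#'   via [last_component_id()].
#' @export
add_component <- function(doc, time, name = NULL, prev_ids = character(),
                          component_id = NULL) {
  doc <- require_data_body(doc)
  if (!is_scalar_num(time) || time < 0)
    stop_bdml("invalid-document", "time must be a single non-negative number")
  ids <- component_ids(doc)
  times <- component_times(doc)
  if (any(times == time))
    stop_bdml("duplicate-time",
              sprintf("a component at time %s already exists; components must be separated in time", fmt_num(time)))
  prev_ids <- as.character(prev_ids)
  for (p in prev_ids) {
    j <- match(p, ids)
    if (is.na(j))
      stop_bdml("unknown-prev", sprintf("prevID '%s' does not match any component", p))
    if (times[j] >= time)
      stop_bdml("unknown-prev",
                sprintf("prevID '%s' must reference a strictly earlier time", p))
  }
  if (is.null(component_id)) {
    k <- length(ids) + 1L
    repeat {
      component_id <- sprintf("c%04d", k)
      if (!(component_id %in% ids)) break
      k <- k + 1L
    }
  } else if (component_id %in% ids) {
    stop_bdml("invalid-document", sprintf("componentID '%s' already in use", component_id))
  }
  comp <- structure(
    list(component_id = component_id, component_name = name,
         time = as.numeric(time), prev_ids = prev_ids, measurements = list()),
    class = "bdml_component"
  )
  doc$body$components <- c(doc$body$components, list(comp))
  attr(doc, "component_id") <- component_id
  doc
}

#' Add a measurement to a component
#'
#' A measurement records the spatial extent of one object at the component's
#' time point: a reference to a declared object type, one geometric entity,
#' and optional feature values (e.g. fluorescence intensity) referring to
#' declared features.
#'
#' @param doc A `bdml_document` with a data body.
#' @param component_id Identifier of an existing component.
#' @param object_ref Name of a declared object type (see [add_object()]).
#' @param entity A geometric entity (see [bdml_point()] and friends).
#' @param properties Feature values: either a named numeric vector
#'   (`c(GFP = 12.5)`) or a list of `list(feature_ref =, feature_val =)`.
#' @return The modified document.
#' @export
add_measurement <- function(doc, component_id, object_ref, entity,
                            properties = NULL) {
  doc <- require_data_body(doc)
  idx <- match(component_id, component_ids(doc))
  if (is.na(idx))
    stop_bdml("invalid-document", sprintf("no component with id '%s'", component_id))
  if (!is_nonempty_string(object_ref) || !(object_ref %in% object_names(doc)))
    stop_bdml("unknown-object",
              sprintf("objectRef '%s' does not name a declared object", object_ref %||% ""))
  if (!inherits(entity, "bdml_entity"))
    stop_bdml("malformed-entity", "entity must be a bdml_entity")
  props <- as_properties(properties)
  declared <- feature_names(doc)
  for (p in props)
    if (!(p$feature_ref %in% declared))
      stop_bdml("unknown-feature",
                sprintf("featureRef '%s' does not name a declared feature", p$feature_ref))
  m <- new_measurement(object_ref, entity, props)
  doc$body$components[[idx]]$measurements <-
    c(doc$body$components[[idx]]$measurements, list(m))
  doc
}

# ---- printing -------------------------------------------------------------

#' @export
print.bdml_document <- function(x, ...) {
  cat("<bdml_document> BDML", x$info$bdml_version, "\n")
  cat("  bdmlID:  ", x$info$bdml_id, "\n", sep = "")
  cat("  organism:", x$summary$organism, "| basedon:", x$summary$basedon, "\n")
  if (inherits(x$body, "bdml_data")) {
    su <- x$body$scale_unit
    cat(sprintf("  scale: (%s, %s, %s) %s, t %s %s\n",
                fmt_num(su$x_scale), fmt_num(su$y_scale), fmt_num(su$z_scale),
                su$xyz_unit, fmt_num(su$t_scale), su$t_unit))
    cat(sprintf("  %d object type(s), %d feature(s), %d component(s)\n",
                length(x$body$objects), length(x$body$features),
                length(x$body$components)))
  } else {
    kind <- if (inherits(x$body, "bdml_series")) "series" else "set"
    cat(sprintf("  %s of %d part(s)\n", kind, nrow(x$body$entries)))
  }
  invisible(x)
}

#' @export
print.bdml_entity <- function(x, ...) {
  cat("<bdml_entity>", x$kind, "\n")
  if (x$kind %in% c("circle", "sphere"))
    cat("  center:", paste(fmt_num(x$center), collapse = " "),
        " radius:", fmt_num(x$radius), "\n")
  else if (x$kind == "point")
    cat("  xyz:", paste(fmt_num(x$xyz), collapse = " "), "\n")
  else
    cat(" ", nrow(x$coords), "vertices\n")
  invisible(x)
}
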