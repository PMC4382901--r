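# Semantic validation beyond the XML Schema: document-wide referential
# integrity, closed enumerations and temporal consistency. All breaches are
# collected (no fail-fast) into a machine-readable report, so one run gives
# a complete, stable diagnosis.

#' The closed set of semantic violation codes
#'
#' @return Character vector of the 13 codes reported by [validate_bdml()].
#' @export
violation_codes <- function() {
  c("UUID-FORMAT", "CONTACT-REQUIRED", "UNIT-ENUM", "SCALE-NEGATIVE",
    "TIME-DUPLICATE", "PREV-UNKNOWN", "PREV-FORWARD", "OBJECT-UNKNOWN",
    "FEATURE-UNKNOWN", "ONTOREF-UNKNOWN", "ENTITY-MALFORMED",
    "COMPONENT-EMPTY", "BASEDON-ENUM")
}

empty_violations <- function() {
  data.frame(code = character(), path = character(), message = character(),
             severity = character(), stringsAsFactors = FALSE)
}

#' Semantic validation of a BDML document
#'
#' Checks everything the XML Schema cannot express: the `bdmlID` UUID format
#' (`UUID-FORMAT`); presence of contact name, e-mail and affiliation
#' (`CONTACT-REQUIRED`; e-mail syntax is checked only loosely); membership
#' of the spatial, temporal and feature units in the format's closed
#' vocabularies (`UNIT-ENUM`); non-negative scale factors
#' (`SCALE-NEGATIVE`); pairwise distinct component times (`TIME-DUPLICATE`);
#' backward links that resolve (`PREV-UNKNOWN`) and point strictly backwards
#' in time (`PREV-FORWARD`); object and feature references that resolve
#' (`OBJECT-UNKNOWN`, `FEATURE-UNKNOWN`); ontology references that resolve
#' (`ONTOREF-UNKNOWN`); well-formed geometric entities -- at least two line
#' vertices, exactly three face vertices, strictly positive radii
#' (`ENTITY-MALFORMED`); at least one measurement per component
#' (`COMPONENT-EMPTY`); and the experiment/simulation enumeration
#' (`BASEDON-ENUM`).
#'
#' Every code is reported at severity `"error"` except `ONTOREF-UNKNOWN`,
#' which is a warning: the ontology section is optional in BDML 0.2 and
#' ontology annotations are commonly attached only at database registration
#' time, so a dangling reference should not block data exchange. In a
#' document known to be one part of a series, unresolved backward links are
#' downgraded to warnings as well, since a track may legitimately continue
#' from the previous file (`series_part = TRUE`).
#'
#' Nothing is thrown: all breaches are reported together.
#'
#' @param doc A `bdml_document` (typically from [read_bdml()] with or
#'   without schema checking).
#' @param series_part Treat the document as one part of a series.
#' @return A `bdml_report`: list with `violations` (data frame with columns
#'   code, path, message, severity) and `is_valid` (`TRUE` iff no
#'   error-severity violations).
#' @export
validate_bdml <- function(doc, series_part = FALSE) {
  stopifnot(inherits(doc, "bdml_document"))
  v <- list()
  add <- function(code, path, message, severity = "error") {
    v[[length(v) + 1L]] <<- data.frame(code = code, path = path,
                                       message = message, severity = severity,
                                       stringsAsFactors = FALSE)
  }

  if (!is_uuid(doc$info$bdml_id %||% ""))
    add("UUID-FORMAT", "/bdml/info/bdmlID",
        sprintf("bdmlID '%s' is not an RFC-4122 UUID", doc$info$bdml_id %||% ""))
  if (!is_nonempty_string(doc$info$license %||% NULL))
    add("CONTACT-REQUIRED", "/bdml/info/license", "license must be non-empty")

  ct <- doc$contact
  for (f in c("name", "email", "affiliation"))
    if (!is_nonempty_string(ct[[f]] %||% NULL))
      add("CONTACT-REQUIRED", paste0("/bdml/contact/", f),
          sprintf("contact %s is required and must be non-empty", f))
  if (is_nonempty_string(ct$email %||% NULL) &&
      !grepl("^[^@[:space:]]+@[^@[:space:]]+$", ct$email))
    add("CONTACT-REQUIRED", "/bdml/contact/email",
        sprintf("'%s' is not a plausible e-mail address", ct$email))

  if (!((doc$summary$basedon %||% "") %in% BDML_BASEDON))
    add("BASEDON-ENUM", "/bdml/summary/basedon",
        sprintf("basedon must be 'experiment' or 'simulation', got '%s'",
                doc$summary$basedon %||% ""))

  onto_ids <- vapply(doc$ontology, function(t) t$id %||% "", "")
  check_ref <- function(ref, path) {
    if (!is.null(ref) && !(ref %in% onto_ids))
      add("ONTOREF-UNKNOWN", path,
          sprintf("ontologyRef '%s' matches no ontologyTerm id", ref),
          severity = "warning")
  }
  check_ref(doc$summary$datatype_ref, "/bdml/summary/datatype")
  check_ref(doc$summary$organism_ref, "/bdml/summary/organism")

  if (inherits(doc$body, "bdml_data")) {
    su <- doc$body$scale_unit
    for (f in c("x_scale", "y_scale", "z_scale", "t_scale")) {
      s <- su[[f]]
      if (!is_scalar_num(s %||% NaN) || s < 0)
        add("SCALE-NEGATIVE", paste0("/bdml/data/scaleUnit/", f),
            sprintf("scale factor %s must be a non-negative number", f))
    }
    if (!((su$xyz_unit %||% "") %in% bdml_units()))
      add("UNIT-ENUM", "/bdml/data/scaleUnit/xyzUnit",
          sprintf("'%s' is not a predefined spatial unit", su$xyz_unit %||% ""))
    if (!((su$t_unit %||% "") %in% bdml_time_units()))
      add("UNIT-ENUM", "/bdml/data/scaleUnit/tUnit",
          sprintf("'%s' is not a predefined time unit", su$t_unit %||% ""))

    obj_names <- vapply(doc$body$objects, function(o) o$object_name %||% "", "")
    feat_names <- vapply(doc$body$features, function(f) f$feature_name %||% "", "")
    for (i in seq_along(doc$body$objects))
      check_ref(doc$body$objects[[i]]$ontology_ref,
                sprintf("/bdml/data/object[%d]", i))
    for (i in seq_along(doc$body$features)) {
      ft <- doc$body$features[[i]]
      fpath <- sprintf("/bdml/data/feature[%d]", i)
      check_ref(ft$ontology_ref, fpath)
      if (!((ft$feature_unit %||% "") %in% bdml_units()))
        add("UNIT-ENUM", paste0(fpath, "/featureUnit"),
            sprintf("'%s' is not a predefined feature unit", ft$feature_unit %||% ""))
      if (!is_scalar_num(ft$feature_scale %||% NaN) || ft$feature_scale <= 0)
        add("SCALE-NEGATIVE", paste0(fpath, "/featureScale"),
            "featureScale must be strictly positive")
    }

    comps <- doc$body$components
    ids <- vapply(comps, function(cp) cp$component_id %||% "", "")
    times <- vapply(comps, function(cp) (cp$time %||% NA_real_)[1L], 0)
    dup_t <- unique(times[duplicated(times) & !is.na(times)])
    for (t in dup_t)
      add("TIME-DUPLICATE", "/bdml/data",
          sprintf("components %s share time value %s; components must be separated in time",
                  paste(ids[which(times == t)], collapse = ", "), fmt_num(t)))

    for (i in seq_along(comps)) {
      cp <- comps[[i]]
      cpath <- sprintf("/bdml/data/component[%d]", i)
      if (length(cp$measurements) == 0L)
        add("COMPONENT-EMPTY", cpath,
            sprintf("component '%s' has no measurement; at least one is required", ids[i]))
      for (p in cp$prev_ids) {
        j <- match(p, ids)
        if (is.na(j))
          add("PREV-UNKNOWN", cpath,
              sprintf("prevID '%s' matches no component", p),
              severity = if (series_part) "warning" else "error")
        else if (!is.na(times[j]) && !is.na(times[i]) && times[j] >= times[i])
          add("PREV-FORWARD", cpath,
              sprintf("prevID '%s' (t=%s) does not precede component '%s' (t=%s)",
                      p, fmt_num(times[j]), ids[i], fmt_num(times[i])))
      }
      for (k in seq_along(cp$measurements)) {
        ms <- cp$measurements[[k]]
        mpath <- sprintf("%s/measurement[%d]", cpath, k)
        if (!((ms$object_ref %||% "") %in% obj_names))
          add("OBJECT-UNKNOWN", mpath,
              sprintf("objectRef '%s' is not a declared object", ms$object_ref %||% ""))
        for (pr in ms$properties)
          if (!((pr$feature_ref %||% "") %in% feat_names))
            add("FEATURE-UNKNOWN", mpath,
                sprintf("featureRef '%s' is not a declared feature", pr$feature_ref %||% ""))
        e <- ms$entity
        bad <- switch(e$kind %||% "unknown",
          point = length(e$xyz %||% numeric()) != 3L,
          line = is.null(e$coords) || nrow(e$coords) < 2L,
          face = is.null(e$coords) || nrow(e$coords) != 3L,
          circle = ,
          sphere = !is_scalar_num(e$radius %||% NaN) || e$radius <= 0 ||
                   length(e$center %||% numeric()) != 3L,
          TRUE)
        if (isTRUE(bad))
          add("ENTITY-MALFORMED", mpath,
              sprintf("%s entity is malformed (line needs >= 2 vertices, face exactly 3, radius > 0)",
                      e$kind %||% "unknown"))
      }
    }
  }

  violations <- if (length(v) > 0L) do.call(rbind, v) else empty_violations()
  structure(
    list(violations = violations,
         is_valid = !any(violations$severity == "error")),
    class = "bdml_report"
  )
}

#' @export
print.bdml_report <- function(x, ...) {
  if (nrow(x$violations) == 0L) {
    cat("<bdml_report> valid: no violations\n")
    return(invisible(x))
  }
  cat(sprintf("<bdml_report> %s: %d violation(s)\n",
              if (x$is_valid) "valid (warnings only)" else "INVALID",
              nrow(x$violations)))
  for (i in seq_len(nrow(x$violations)))
    cat(sprintf("  [%s] %-16s %s: %s\n", x$violations$severity[i],
                x$violations$code[i], x$violations$path[i],
                x$violations$message[i]))
  invisible(x)
}

#' @export
as.data.frame.bdml_report <- function(x, ...) x$violations

#' Export a validation report as JSON lines
#'
#' Writes one JSON object per violation (fields code, path, message,
#' severity), a convenient stable format for CI pipelines.
#'
#' @param report A `bdml_report`.
#' @param path Output file; when `NULL` the lines are returned.
#' @return The JSON lines, invisibly when written to a file.
#' @export
report_jsonl <- function(report, path = NULL) {
  stopifnot(inherits(report, "bdml_report"))
  lines <- vapply(seq_len(nrow(report$violations)), function(i) {
    jsonlite::toJSON(as.list(report$violations[i, ]), auto_unbox = TRUE)
  }, "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# ---- one-fault injection --------------------------------------------------

#' Inject a single semantic fault into a valid document
#'
#' Takes a semantically valid document, introduces exactly one breach of the
#' named violation code, and returns the mutated document serialized to XML.
#' The mutation site is chosen with a seeded generator, so the same document,
#' code and seed always give byte-identical output. This is the ground-truth
#' harness behind the validator's completeness guarantee: for every code,
#' `validate_bdml(read_bdml(inject_violation(d, code)))` must report that
#' code.
#'
#' @param doc A valid, data-bodied `bdml_document`.
#' @param code One of [violation_codes()].
#' @param seed Integer seed selecting the mutation site.
#' @return XML text containing exactly one introduced fault.
#' @export
inject_violation <- function(doc, code, seed = 1L) {
  doc <- require_data_body(doc)
  code <- match.arg(code, violation_codes())
  na <- function(why) stop_bdml("not-applicable",
    sprintf("cannot inject %s: %s", code, why))
  with_seed(seed, {
    comps <- doc$body$components
    n <- length(comps)
    pick <- function(k) if (k == 1L) 1L else sample.int(k, 1L)
    # indices of components that have at least one measurement
    with_ms <- which(vapply(comps, function(cp) length(cp$measurements) > 0L, TRUE))

    doc <- switch(code,
      "UUID-FORMAT" = { doc$info$bdml_id <- "not-a-uuid"; doc },
      "CONTACT-REQUIRED" = { doc$contact$email <- ""; doc },
      "UNIT-ENUM" = { doc$body$scale_unit$xyz_unit <- "furlong"; doc },
      "SCALE-NEGATIVE" = { doc$body$scale_unit$x_scale <- -1; doc },
      "TIME-DUPLICATE" = {
        if (n < 2L) na("needs at least two components")
        i <- pick(n - 1L)
        doc$body$components[[i + 1L]]$time <- comps[[i]]$time
        # dropping the mutated component's own backward links keeps the
        # time clash the only introduced breach
        doc$body$components[[i + 1L]]$prev_ids <- character()
        doc
      },
      "PREV-UNKNOWN" = {
        if (n < 1L) na("needs a component")
        i <- pick(n)
        doc$body$components[[i]]$prev_ids <-
          c(comps[[i]]$prev_ids, "no-such-component")
        doc
      },
      "PREV-FORWARD" = {
        if (n < 2L) na("needs at least two components")
        ord <- order(vapply(comps, `[[`, 0, "time"))
        i <- ord[1L]; j <- ord[pick(n - 1L) + 1L]
        doc$body$components[[i]]$prev_ids <-
          c(comps[[i]]$prev_ids, comps[[j]]$component_id)
        doc
      },
      "OBJECT-UNKNOWN" = {
        if (length(with_ms) == 0L) na("needs a measurement")
        i <- with_ms[pick(length(with_ms))]
        k <- pick(length(comps[[i]]$measurements))
        doc$body$components[[i]]$measurements[[k]]$object_ref <- "undeclared-object"
        doc
      },
      "FEATURE-UNKNOWN" = {
        hit <- NULL
        for (i in with_ms) for (k in seq_along(comps[[i]]$measurements))
          if (length(comps[[i]]$measurements[[k]]$properties) > 0L)
            hit <- rbind(hit, c(i, k))
        if (is.null(hit)) na("document carries no feature properties")
        r <- hit[pick(nrow(hit)), ]
        doc$body$components[[r[1]]]$measurements[[r[2]]]$properties[[1L]]$feature_ref <-
          "undeclared-feature"
        doc
      },
      "ONTOREF-UNKNOWN" = { doc$summary$datatype_ref <- "no-such-term"; doc },
      "ENTITY-MALFORMED" = {
        if (length(with_ms) == 0L) na("needs a measurement")
        i <- with_ms[pick(length(with_ms))]
        k <- pick(length(comps[[i]]$measurements))
        e <- comps[[i]]$measurements[[k]]$entity
        bad <- switch(e$kind,
          circle = ,
          sphere = new_entity(e$kind, list(center = e$center, radius = -abs(e$radius))),
          face = new_entity("face", list(coords = rbind(e$coords, e$coords[1L, ] + 1))),
          # points and lines become a one-vertex line
          new_entity("line", list(coords = matrix(c(0, 0, 0), 1L)))
        )
        doc$body$components[[i]]$measurements[[k]]$entity <- bad
        doc
      },
      "COMPONENT-EMPTY" = {
        if (length(with_ms) == 0L) na("needs a component with measurements")
        i <- with_ms[pick(length(with_ms))]
        doc$body$components[[i]]$measurements <- list()
        doc
      },
      "BASEDON-ENUM" = { doc$summary$basedon <- "hearsay"; doc }
    )
    write_bdml(doc, check = FALSE)
  })
}
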