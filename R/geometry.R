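# Scale conversion and geometric summaries over the five entity types.
#
# Stored coordinates are raw values (typically pixel coordinates and frame
# indices); the document's scaleUnit maps them to physical positions and
# times. Radii scale by the x factor: a circle or sphere cannot be scaled
# anisotropically and remain a circle or sphere, so mixed pixel scales
# trigger a warning. Circles are interpreted as lying in the plane
# z = center_z.

check_entity_kind <- function(entity, kind) {
  if (!inherits(entity, "bdml_entity") || !identical(entity$kind, kind))
    stop_bdml("wrong-kind", sprintf("expected a %s entity", kind))
  entity
}

scale_xyz <- function(m, su) {
  m[, 1L] <- m[, 1L] * su$x_scale
  m[, 2L] <- m[, 2L] * su$y_scale
  m[, 3L] <- m[, 3L] * su$z_scale
  m
}

warn_anisotropic <- function(su, kind) {
  aniso <- su$x_scale != su$y_scale ||
    (kind == "sphere" && su$x_scale != su$z_scale)
  if (aniso)
    warning(sprintf(
      "anisotropic-radius: scales (%s, %s, %s) are anisotropic; the %s radius is scaled by x_scale only",
      fmt_num(su$x_scale), fmt_num(su$y_scale), fmt_num(su$z_scale), kind),
      call. = FALSE)
  invisible(su)
}

scale_entity <- function(e, su) {
  switch(e$kind,
    point = new_entity("point", list(xyz = drop(scale_xyz(rbind(e$xyz), su)))),
    line = ,
    face = new_entity(e$kind, list(coords = scale_xyz(e$coords, su))),
    circle = ,
    sphere = {
      warn_anisotropic(su, e$kind)
      new_entity(e$kind, list(center = drop(scale_xyz(rbind(e$center), su)),
                              radius = e$radius * su$x_scale))
    })
}

#' Convert a document to physical coordinates
#'
#' Multiplies every stored coordinate by the per-axis scale factors
#' (x by `x_scale`, y by `y_scale`, z by `z_scale`), every radius by
#' `x_scale`, every component time by `t_scale`, and every stored feature
#' value by its feature's `feature_scale`. All scale factors in the result
#' are then set to 1, making the operation idempotent: applying it twice is
#' the same as applying it once. Units are unchanged -- the result expresses
#' positions directly in `xyz_unit` and times in `t_unit`.
#'
#' With `z_scale = 0` (the format's marker for two-dimensional data) all
#' physical z coordinates become 0. Anisotropic scales trigger an
#' `anisotropic-radius` warning for every circle or sphere, whose radius is
#' scaled by `x_scale` alone.
#'
#' @param doc A data-bodied `bdml_document`.
#' @return The converted document, with unit scale factors.
#' @export
#' @examples
#' \dontrun{
#' phys <- to_physical(doc)   # coordinates now in micrometers, say
#' }
to_physical <- function(doc) {
  doc <- require_data_body(doc)
  su <- doc$body$scale_unit
  fscale <- vapply(doc$body$features, `[[`, 0, "feature_scale")
  names(fscale) <- vapply(doc$body$features, `[[`, "", "feature_name")
  doc$body$components <- lapply(doc$body$components, function(cp) {
    cp$time <- cp$time * su$t_scale
    cp$measurements <- lapply(cp$measurements, function(ms) {
      ms$entity <- scale_entity(ms$entity, su)
      ms$properties <- lapply(ms$properties, function(pr) {
        s <- fscale[[pr$feature_ref]] %||% 1
        pr$feature_val <- pr$feature_val * s
        pr
      })
      ms
    })
    cp
  })
  doc$body$scale_unit$x_scale <- 1
  doc$body$scale_unit$y_scale <- 1
  doc$body$scale_unit$z_scale <- 1
  doc$body$scale_unit$t_scale <- 1
  doc$body$features <- lapply(doc$body$features, function(f) {
    f$feature_scale <- 1
    f
  })
  doc
}

#' Physical length of a polyline
#'
#' Sum of Euclidean segment lengths of a line entity after applying the
#' per-axis scale factors. With `z_scale = 0` this is the planar length of
#' two-dimensional data.
#'
#' @param line A line entity ([bdml_line()]).
#' @param scale A [bdml_scale_unit()]; defaults to unit scales.
#' @return Length in `xyz_unit`.
#' @export
#' @examples
#' polyline_length(bdml_line(rbind(c(0, 0, 0), c(3, 4, 0))))  # 5
polyline_length <- function(line, scale = bdml_scale_unit()) {
  check_entity_kind(line, "line")
  m <- scale_xyz(line$coords, scale)
  d <- diff(m)
  sum(sqrt(rowSums(d * d)))
}

#' Is a line a closed polygonal chain?
#'
#' A closed polygonal chain joins its start and end point: the first and
#' last vertex must be exactly equal. Nuclear contours are stored this way.
#'
#' @param line A line entity.
#' @return `TRUE` iff first vertex equals last vertex exactly.
#' @export
is_closed_chain <- function(line) {
  check_entity_kind(line, "line")
  m <- line$coords
  all(m[1L, ] == m[nrow(m), ])
}

#' Kind-specific physical size of an entity
#'
#' Returns the natural scalar size of each entity kind, in physical units:
#' a point has size 0; a line its [polyline_length()]; a circle its area
#' \eqn{\pi r^2}; a sphere its volume \eqn{(4/3)\pi r^3}; a face its
#' triangle area computed with the cross-product formula. Radii are scaled
#' by `x_scale` (with an `anisotropic-radius` warning when the scales are
#' mixed).
#'
#' @param entity A `bdml_entity`.
#' @param scale A [bdml_scale_unit()]; defaults to unit scales.
#' @return A non-negative number.
#' @export
#' @examples
#' measure_size(bdml_sphere(c(0, 0, 0), 1))  # 4 * pi / 3
measure_size <- function(entity, scale = bdml_scale_unit()) {
  stopifnot(inherits(entity, "bdml_entity"))
  switch(entity$kind,
    point = 0,
    line = polyline_length(entity, scale),
    circle = {
      warn_anisotropic(scale, "circle")
      r <- entity$radius * scale$x_scale
      pi * r^2
    },
    sphere = {
      warn_anisotropic(scale, "sphere")
      r <- entity$radius * scale$x_scale
      4 / 3 * pi * r^3
    },
    face = {
      m <- scale_xyz(entity$coords, scale)
      u <- m[2L, ] - m[1L, ]
      v <- m[3L, ] - m[1L, ]
      cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
              u[3L] * v[1L] - u[1L] * v[3L],
              u[1L] * v[2L] - u[2L] * v[1L])
      0.5 * sqrt(sum(cr^2))
    })
}

# representative raw point of an entity (vertex mean / centre)
entity_rep_point <- function(e) {
  switch(e$kind,
    point = e$xyz,
    line = ,
    face = colMeans(e$coords),
    circle = ,
    sphere = e$center)
}

#' Physical centroid of a component
#'
#' Unweighted mean of the entity representative points of all measurements
#' in the component -- a point is its own representative, a line or face is
#' represented by its vertex mean, a circle or sphere by its centre -- mapped
#' to physical units along with the component time. This is a summary
#' convention of this package (the format itself defines no centroid).
#'
#' @param component A `bdml_component`.
#' @param scale A [bdml_scale_unit()].
#' @return A named list with `x`, `y`, `z` (in `xyz_unit`), `t` (in
#'   `t_unit`), and the unit names; class `bdml_physical_point`.
#' @export
centroid <- function(component, scale = bdml_scale_unit()) {
  stopifnot(inherits(component, "bdml_component"))
  if (length(component$measurements) == 0L)
    stop_bdml("invalid-document", "component has no measurements")
  reps <- t(vapply(component$measurements,
                   function(ms) entity_rep_point(ms$entity), numeric(3)))
  mu <- drop(scale_xyz(rbind(colMeans(reps)), scale))
  structure(
    list(x = mu[1L], y = mu[2L], z = mu[3L],
         t = component$time * scale$t_scale,
         xyz_unit = scale$xyz_unit, t_unit = scale$t_unit),
    class = "bdml_physical_point"
  )
}

#' @export
print.bdml_physical_point <- function(x, ...) {
  cat(sprintf("(%s, %s, %s) %s at t = %s %s\n",
              fmt_num(x$x), fmt_num(x$y), fmt_num(x$z), x$xyz_unit,
              fmt_num(x$t), x$t_unit))
  invisible(x)
}

#' Per-component physical summary table
#'
#' One row per component: identifier, physical time, centroid coordinates
#' and the summed [measure_size()] of its measurements, all in physical
#' units. Suitable for CSV export with [utils::write.csv()].
#'
#' @param doc A data-bodied `bdml_document`.
#' @return A data frame with columns component_id, time_physical,
#'   centroid_x/y/z, n_measurements and total_size.
#' @export
component_summary <- function(doc) {
  doc <- require_data_body(doc)
  su <- doc$body$scale_unit
  rows <- lapply(components(doc), function(cp) {
    cen <- if (length(cp$measurements) > 0L) centroid(cp, su) else
      list(x = NA_real_, y = NA_real_, z = NA_real_)
    sz <- if (length(cp$measurements) > 0L)
      sum(vapply(cp$measurements, function(ms)
        suppressWarnings(measure_size(ms$entity, su)), 0)) else NA_real_
    data.frame(component_id = cp$component_id,
               time_physical = cp$time * su$t_scale,
               centroid_x = cen$x, centroid_y = cen$y, centroid_z = cen$z,
               n_measurements = length(cp$measurements),
               total_size = sz, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
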