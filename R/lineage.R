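# Lineage reconstruction from backward component links.
#
# Every prevID entry induces one directed edge from the earlier component
# to the later one; because links must point strictly backwards in time the
# resulting graph is acyclic by construction. Tracks are maximal unbranched
# chains; a node with out-degree >= 2 is a division, in-degree >= 2 a
# fusion.

#' Build the lineage graph of a document
#'
#' One node per component (with its stored time), one directed edge per
#' backward link, oriented from the earlier component to the later one.
#' The document must be free of link errors (unresolved or forward-pointing
#' prevIDs); acyclicity then holds automatically and is double-checked.
#'
#' @param doc A data-bodied `bdml_document`.
#' @return A `bdml_lineage`: list with `nodes` (data frame: id, time) and
#'   `edges` (data frame: from, to).
#' @export
build_lineage <- function(doc) {
  doc <- require_data_body(doc)
  rep <- validate_bdml(doc)
  linkbad <- rep$violations$code %in% c("PREV-UNKNOWN", "PREV-FORWARD", "TIME-DUPLICATE")
  if (any(linkbad & rep$violations$severity == "error"))
    stop_bdml("invalid-links",
              paste("document has link errors:",
                    paste(unique(rep$violations$code[linkbad]), collapse = ", ")))
  comps <- components(doc)
  nodes <- data.frame(id = component_ids(doc), time = component_times(doc),
                      stringsAsFactors = FALSE)
  el <- do.call(rbind, lapply(comps, function(cp) {
    if (length(cp$prev_ids) == 0L) return(NULL)
    data.frame(from = cp$prev_ids, to = cp$component_id, stringsAsFactors = FALSE)
  }))
  edges <- el %||% data.frame(from = character(), to = character(),
                              stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes$id)
    if (!igraph::is_dag(g))
      stop_bdml("invalid-links", "prevID links form a cycle")
  }
  structure(list(nodes = nodes, edges = edges), class = "bdml_lineage")
}

#' @export
print.bdml_lineage <- function(x, ...) {
  cat(sprintf("<bdml_lineage> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

out_neighbors <- function(g) split(g$edges$to, factor(g$edges$from, levels = g$nodes$id))
in_neighbors <- function(g) split(g$edges$from, factor(g$edges$to, levels = g$nodes$id))

#' Extract tracks from a lineage graph
#'
#' A track is a maximal unbranched chain of components: it is cut at every
#' branch point, so a division ends the parent's track and starts one new
#' track per child (track identity follows neither child), and a fusion
#' ends all incoming tracks. Every component belongs to exactly one track,
#' times increase strictly along each track, and the ordering is
#' deterministic (by start time, then component id).
#'
#' @param g A `bdml_lineage`.
#' @return A list of character vectors of component ids.
#' @export
extract_tracks <- function(g) {
  stopifnot(inherits(g, "bdml_lineage"))
  if (nrow(g$nodes) == 0L) return(list())
  outs <- out_neighbors(g)
  ins <- in_neighbors(g)
  outdeg <- lengths(outs)
  indeg <- lengths(ins)
  # a track starts where the chain cannot be extended backwards:
  # no unique predecessor, or the predecessor branches
  starts <- vapply(g$nodes$id, function(v) {
    if (indeg[[v]] != 1L) return(TRUE)
    outdeg[[ins[[v]]]] >= 2L
  }, TRUE)
  times <- stats::setNames(g$nodes$time, g$nodes$id)
  sid <- g$nodes$id[starts]
  sid <- sid[order(times[sid], sid)]
  lapply(sid, function(v) {
    chain <- v
    repeat {
      nxt <- outs[[v]]
      if (length(nxt) != 1L) break        # end or division
      if (indeg[[nxt]] != 1L) break       # child is a fusion point
      chain <- c(chain, nxt)
      v <- nxt
    }
    chain
  })
}

#' Classify lineage events
#'
#' Scans the lineage graph for the four event kinds: *division* (out-degree
#' at least 2 -- one component linked forward by several later ones),
#' *fusion* (in-degree at least 2 -- a component carrying several prevIDs),
#' *appearance* (no incoming link at a time later than the dataset start)
#' and *disappearance* (no outgoing link before the dataset end). A node may
#' generate several events (e.g. both fuse and divide).
#'
#' @param g A `bdml_lineage`.
#' @return A data frame with columns kind, component_id, time, ordered by
#'   time then id.
#' @export
classify_events <- function(g) {
  stopifnot(inherits(g, "bdml_lineage"))
  empty <- data.frame(kind = character(), component_id = character(),
                      time = numeric(), stringsAsFactors = FALSE)
  if (nrow(g$nodes) == 0L) return(empty)
  outdeg <- lengths(out_neighbors(g))
  indeg <- lengths(in_neighbors(g))
  t0 <- min(g$nodes$time)
  t1 <- max(g$nodes$time)
  ev <- list(empty)
  addev <- function(kind, ids) {
    if (length(ids) == 0L) return()
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, component_id = ids,
      time = g$nodes$time[match(ids, g$nodes$id)], stringsAsFactors = FALSE)
  }
  addev("division", g$nodes$id[outdeg[g$nodes$id] >= 2L])
  addev("fusion", g$nodes$id[indeg[g$nodes$id] >= 2L])
  addev("appearance", g$nodes$id[indeg[g$nodes$id] == 0L & g$nodes$time > t0])
  addev("disappearance", g$nodes$id[outdeg[g$nodes$id] == 0L & g$nodes$time < t1])
  out <- do.call(rbind, ev)
  out[order(out$time, out$component_id, out$kind), , drop = FALSE]
}

#' Feature values along a track
#'
#' For each component of the track, in order, reports the physical time
#' (stored time times `t_scale`) and the summed physical feature value
#' (stored value times the feature's `feature_scale`) over all measurements
#' of that component carrying the feature. Components without the feature
#' yield `NA` -- a gap marker -- so interrupted recordings stay visible.
#'
#' @param doc A data-bodied `bdml_document`.
#' @param track Character vector of component ids (from [extract_tracks()]).
#' @param feature_name Name of a declared feature.
#' @return A data frame with columns component_id, time and value.
#' @export
feature_timeseries <- function(doc, track, feature_name) {
  doc <- require_data_body(doc)
  if (!(feature_name %in% feature_names(doc)))
    stop_bdml("unknown-feature",
              sprintf("feature '%s' is not declared", feature_name))
  stopifnot(is.character(track), length(track) > 0L)
  fidx <- match(feature_name, feature_names(doc))
  fscale <- doc$body$features[[fidx]]$feature_scale
  t_scale <- doc$body$scale_unit$t_scale
  ids <- component_ids(doc)
  rows <- lapply(track, function(cid) {
    i <- match(cid, ids)
    if (is.na(i))
      stop_bdml("invalid-document", sprintf("track references unknown component '%s'", cid))
    cp <- doc$body$components[[i]]
    vals <- unlist(lapply(cp$measurements, function(ms) {
      vapply(Filter(function(p) p$feature_ref == feature_name, ms$properties),
             `[[`, 0, "feature_val")
    }))
    data.frame(component_id = cid, time = cp$time * t_scale,
               value = if (length(vals) == 0L) NA_real_ else sum(vals) * fscale,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a lineage as Newick tree strings
#'
#' Serializes a fusion-free lineage graph as parenthesized Newick trees, one
#' string per root component. Node labels are component ids and branch
#' lengths are physical time differences between a component and its
#' predecessor (stored time difference times `t_scale`). Lineages containing
#' fusions are not trees; export those with [lineage_edges()] instead.
#'
#' @param g A `bdml_lineage` without fusion nodes.
#' @param t_scale Time scale factor applied to branch lengths.
#' @return Character vector of Newick strings (each ending in `;`).
#' @export
lineage_newick <- function(g, t_scale = 1) {
  stopifnot(inherits(g, "bdml_lineage"))
  indeg <- lengths(in_neighbors(g))
  if (any(indeg >= 2L))
    stop_bdml("invalid-links",
              "lineage contains fusion nodes and cannot be written as trees")
  outs <- out_neighbors(g)
  times <- stats::setNames(g$nodes$time, g$nodes$id)
  rec <- function(v, parent_time) {
    kids <- outs[[v]]
    kids <- kids[order(times[kids], kids)]
    bl <- fmt_num((times[[v]] - parent_time) * t_scale)
    if (length(kids) == 0L) return(sprintf("%s:%s", v, bl))
    sprintf("(%s)%s:%s",
            paste(vapply(kids, rec, "", parent_time = times[[v]]), collapse = ","),
            v, bl)
  }
  roots <- g$nodes$id[indeg[g$nodes$id] == 0L]
  roots <- roots[order(times[roots], roots)]
  vapply(roots, function(r) {
    kids <- outs[[r]]
    kids <- kids[order(times[kids], kids)]
    if (length(kids) == 0L) sprintf("%s;", r)
    else sprintf("(%s)%s;",
                 paste(vapply(kids, rec, "", parent_time = times[[r]]), collapse = ","),
                 r)
  }, "", USE.NAMES = FALSE)
}

#' Lineage edge list
#'
#' The lineage as a plain edge table (columns from, to, with the endpoints'
#' stored times), the general-purpose export that also covers graphs with
#' fusions.
#'
#' @param g A `bdml_lineage`.
#' @return A data frame with columns from, to, time_from, time_to.
#' @export
lineage_edges <- function(g) {
  stopifnot(inherits(g, "bdml_lineage"))
  e <- g$edges
  e$time_from <- g$nodes$time[match(e$from, g$nodes$id)]
  e$time_to <- g$nodes$time[match(e$to, g$nodes$id)]
  e
}
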