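# Seeded synthetic-data generators.
#
# Each generator emits a complete, semantically valid BDML document with the
# structure of one canonical data shape -- single-molecule point tracks in a
# rod-shaped bacterium, dividing nuclei outlined as closed polygonal chains,
# a pronucleus sphere with radiating microtubule segments, nuclei as spheres
# carrying a GFP intensity feature over a division lineage, and a 2D worm
# centerline -- together with the planted ground truth, so downstream
# modules can be tested by parameter recovery. All randomness flows through
# one seeded stream per call (R's default Mersenne-Twister); the same
# parameters and seed reproduce the document byte for byte.
#
# Because each component must own a unique time value, simultaneous objects
# share a single component per frame and keep their identity through
# distinct object type names. Where truly separate simultaneous components
# are wanted (the pronucleus/microtubule split layout), the generator emits
# two documents bundled in a set instead.

synth_contact <- function() {
  bdml_contact("Synthetic Data Generator", "synth@bdmlr.invalid", "bdmlr package")
}

synth_methods <- function(what) {
  bdml_methods(source_uri = paste0("urn:bdmlr:synth:", what),
               procedure_uri = "urn:bdmlr:synth:procedure")
}

check_count <- function(x, name, min = 1) {
  if (!is_scalar_num(x) || x < min || x != trunc(x))
    stop_bdml("invalid-params",
              sprintf("%s must be an integer >= %s", name, fmt_num(min)))
  as.integer(x)
}

check_pos <- function(x, name, strict = TRUE) {
  if (!is_scalar_num(x) || (strict && x <= 0) || (!strict && x < 0))
    stop_bdml("invalid-params",
              sprintf("%s must be a %s number", name,
                      if (strict) "positive" else "non-negative"))
  as.numeric(x)
}

# ---- single-molecule Brownian points in a rod-shaped cell -----------------

# reflect a proposed position back into the spherocylinder (capsule) of
# half-length `half_len` and radius `R`, axis along x
reflect_capsule <- function(p, half_len, R) {
  for (i in 1:20) {
    if (abs(p[1L]) <= half_len) {
      r <- sqrt(p[2L]^2 + p[3L]^2)
      if (r <= R) return(p)
      p[2:3] <- p[2:3] * (2 * R - r) / r
    } else {
      cx <- c(sign(p[1L]) * half_len, 0, 0)
      d <- p - cx
      dn <- sqrt(sum(d^2))
      if (dn <= R) return(p)
      p <- cx + d * (2 * R - dn) / dn
    }
  }
  p
}

#' Simulate single-molecule point trajectories in a rod-shaped cell
#'
#' Brownian point particles diffuse inside a spherocylindrical (rod-shaped)
#' volume -- a cylinder of length `cell_length` capped by hemispheres of
#' radius `cell_radius`, the classic approximation of an *E. coli* cell --
#' with reflective boundaries. Each axis displacement per frame is drawn
#' from a centered normal with standard deviation `diffusion_step`, so the
#' planted mean squared displacement after `t` frames is
#' \eqn{3\,\sigma^2 t} (boundary reflections bend this only when steps
#' approach the cell size). Every frame becomes one component holding one
#' point measurement per molecule; molecule identity is carried by one
#' object type per molecule, and consecutive frames are chained with
#' backward links. Coordinates are stored directly in meters (all scale
#' factors 1).
#'
#' @param n_molecules Number of molecules (default 50).
#' @param n_frames Number of frames (default 20).
#' @param diffusion_step Per-axis step standard deviation in meters
#'   (default 10 nm).
#' @param cell_length Cylinder length in meters (default 2 um).
#' @param cell_radius Cell radius in meters (default 0.5 um).
#' @param seed Integer seed.
#' @return A list with `doc` (the `bdml_document`) and `truth` (planted
#'   parameters and the full `n_frames x n_molecules x 3` position array).
#' @export
gen_molecule_points <- function(n_molecules = 50, n_frames = 20,
                                diffusion_step = 1e-8, cell_length = 2e-6,
                                cell_radius = 5e-7, seed = 1L) {
  n_molecules <- check_count(n_molecules, "n_molecules")
  n_frames <- check_count(n_frames, "n_frames")
  diffusion_step <- check_pos(diffusion_step, "diffusion_step", strict = FALSE)
  cell_length <- check_pos(cell_length, "cell_length")
  cell_radius <- check_pos(cell_radius, "cell_radius")
  with_seed(seed, {
    half_len <- cell_length / 2
    pos <- array(0, c(n_frames, n_molecules, 3L))
    # uniform start positions in the cylindrical part
    for (m in seq_len(n_molecules)) {
      th <- stats::runif(1, 0, 2 * pi)
      r <- cell_radius * sqrt(stats::runif(1))
      pos[1L, m, ] <- c(stats::runif(1, -half_len, half_len),
                        r * cos(th), r * sin(th))
    }
    if (n_frames > 1L) for (f in 2:n_frames) for (m in seq_len(n_molecules)) {
      prop <- pos[f - 1L, m, ] + stats::rnorm(3, 0, diffusion_step)
      pos[f, m, ] <- reflect_capsule(prop, half_len, cell_radius)
    }

    doc <- new_document(
      summary = bdml_summary(
        "simulated single-molecule diffusion inside a rod-shaped cell",
        "single-molecule dynamics", "Escherichia coli", basedon = "simulation"),
      contact = synth_contact(), methods = synth_methods("molecule-points"),
      scale_unit = bdml_scale_unit(1, 1, 1, 1, "meter", "second"))
    mol_names <- sprintf("molecule_%03d", seq_len(n_molecules))
    for (nm in mol_names) doc <- add_object(doc, nm)
    prev <- character()
    for (f in seq_len(n_frames)) {
      doc <- add_component(doc, time = f - 1, prev_ids = prev)
      cid <- last_component_id(doc)
      for (m in seq_len(n_molecules))
        doc <- add_measurement(doc, cid, mol_names[m], bdml_point(pos[f, m, ]))
      prev <- cid
    }
    list(doc = doc,
         truth = list(positions = pos, diffusion_step = diffusion_step,
                      cell_length = cell_length, cell_radius = cell_radius,
                      msd_expected = function(t) 3 * diffusion_step^2 * t))
  })
}

# ---- shared binary-division scaffolding -----------------------------------

# heap-indexed binary tree over `n_generations` generations: branch b has
# children 2b and 2b+1; generation g holds branches 2^(g-1) .. 2^g - 1.
# Each branch lives `frames_per_cell` frames; generation g occupies global
# frames (g-1)*F .. g*F - 1. Branch b's components get time
# frame + b / 2^n_generations, which is unique across the document yet keeps
# children strictly after their parent.
division_tree <- function(n_generations, frames_per_cell) {
  n_branches <- as.integer(2^n_generations - 1)
  off <- function(b) b / 2^n_generations
  list(
    n_branches = n_branches,
    generation = function(b) as.integer(floor(log2(b))) + 1L,
    parent = function(b) if (b == 1L) NA_integer_ else b %/% 2L,
    frames = function(b) {
      g <- floor(log2(b)) + 1
      (g - 1) * frames_per_cell + seq_len(frames_per_cell) - 1
    },
    time_of = function(b, frame) frame + off(b),
    n_divisions = as.integer(2^(n_generations - 1) - 1)
  )
}

# seeded 2D layout: each division pushes the two children apart
branch_centers <- function(n_generations, spread = 40) {
  centers <- matrix(NA_real_, 2L^n_generations - 1L, 2L)
  centers[1L, ] <- c(100, 100)
  if (n_generations > 1L) for (b in 2L:(2L^n_generations - 1L)) {
    g <- floor(log2(b)) + 1
    side <- if (b %% 2L == 0L) -1 else 1
    axis <- 1L + (g %% 2L)  # alternate split axis per generation
    d <- c(0, 0)
    d[axis] <- side * spread / 2^(g - 1)
    centers[b, ] <- centers[b %/% 2L, ] + d + stats::rnorm(2, 0, 1)
  }
  centers
}

#' Generate dividing nuclei outlined by closed polygonal chains
#'
#' Emulates nuclear division dynamics extracted from DIC microscopy of an
#' early *C. elegans* embryo: each nucleus contour is a closed polygonal
#' chain (first vertex repeated as the last) inscribed in a circle whose
#' radius shrinks linearly over the cell's life, as chromatin condenses
#' before division. Cells divide in a perfect binary tree over
#' `n_generations` generations; every cell-frame is one component, backward
#' links chain a cell's frames and tie each daughter's first component to
#' its mother's last, planting the division topology in the link structure.
#' (Component times of simultaneous cells are offset by distinct sub-frame
#' fractions, respecting the one-time-per-component rule.) Coordinates are
#' pixels under the confocal calibration 0.105 x 0.105 x 0.5 micrometers
#' per voxel, times in seconds.
#'
#' @param n_generations Number of generations (default 3, i.e. 7 branches
#'   and 3 divisions).
#' @param vertices_per_contour Distinct polygon vertices per contour,
#'   at least 3 (default 36).
#' @param frames_per_cell Frames each cell is observed (default 3).
#' @param seed Integer seed.
#' @return A list with `doc` and `truth` (branch table, per-component
#'   planted radii and centers, expected division count).
#' @export
gen_dividing_nuclei <- function(n_generations = 3, vertices_per_contour = 36,
                                frames_per_cell = 3, seed = 1L) {
  n_generations <- check_count(n_generations, "n_generations")
  vertices_per_contour <- check_count(vertices_per_contour, "vertices_per_contour", min = 3)
  frames_per_cell <- check_count(frames_per_cell, "frames_per_cell")
  with_seed(seed, {
    tree <- division_tree(n_generations, frames_per_cell)
    centers <- branch_centers(n_generations)
    r0 <- 30  # pixels; ~3.2 um at 0.105 um/px
    doc <- new_document(
      summary = bdml_summary(
        "nuclear division dynamics, contours as closed polygonal chains",
        "cell division dynamics", "Caenorhabditis elegans",
        basedon = "experiment"),
      contact = synth_contact(), methods = synth_methods("dividing-nuclei"),
      scale_unit = bdml_scale_unit(0.105, 0.105, 0.5, 1, "micrometer", "second"))
    doc <- add_object(doc, "nucleus")

    ang <- seq(0, 2 * pi, length.out = vertices_per_contour + 1L)[-(vertices_per_contour + 1L)]
    truth_rows <- list()
    last_comp <- rep(NA_character_, tree$n_branches)
    for (b in seq_len(tree$n_branches)) {
      g <- tree$generation(b)
      r_start <- r0 * 0.75^(g - 1)
      frames <- tree$frames(b)
      par <- tree$parent(b)
      prev <- if (is.na(par)) character() else last_comp[par]
      for (j in seq_along(frames)) {
        shrink <- if (frames_per_cell == 1L) 0 else (j - 1) / (frames_per_cell - 1)
        r <- r_start * (1 - 0.4 * shrink)
        t <- tree$time_of(b, frames[j])
        doc <- add_component(doc, time = t,
                             name = sprintf("branch_%d", b), prev_ids = prev)
        cid <- last_component_id(doc)
        xy <- cbind(centers[b, 1L] + r * cos(ang), centers[b, 2L] + r * sin(ang), 10)
        contour <- bdml_line(rbind(xy, xy[1L, , drop = FALSE]))  # closed chain
        doc <- add_measurement(doc, cid, "nucleus", contour)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          component_id = cid, branch = b, generation = g, time = t,
          radius = r, cx = centers[b, 1L], cy = centers[b, 2L],
          stringsAsFactors = FALSE)
        prev <- cid
      }
      last_comp[b] <- prev
    }
    truth <- list(
      components = do.call(rbind, truth_rows),
      n_branches = tree$n_branches, n_divisions = tree$n_divisions,
      division_component_ids = last_comp[seq_len(max(0L, as.integer(2^(n_generations - 1) - 1)))],
      vertices_per_contour = vertices_per_contour,
      parent = vapply(seq_len(tree$n_branches), tree$parent, 1L))
    list(doc = doc, truth = truth)
  })
}

# ---- pronucleus + microtubules --------------------------------------------

#' Generate a migrating pronucleus with radiating microtubules
#'
#' Emulates simulated nuclear migration in a *C. elegans* embryo: one
#' pronucleus sphere drifting along a planted linear path, with microtubule
#' line segments radiating outward from its surface (each segment's first
#' vertex lies exactly on the sphere). With `layout = "one_component"` the
#' sphere and all segments share one component per frame (identity through
#' the two object types); with `layout = "separate_components"` the
#' pronucleus and the microtubules are written as two documents bundled in
#' a set, the reading of "separate components" that keeps every component's
#' time unique within its file. Units are meters with all scale factors 1.
#'
#' @param n_microtubules Number of microtubule segments (default 20).
#' @param n_frames Number of frames (default 10).
#' @param layout `"one_component"` or `"separate_components"`.
#' @param seed Integer seed.
#' @return A list with `doc`, `truth` (drift path, radius, directions,
#'   lengths) and, for the split layout, `parts` (the two member documents;
#'   `doc` is then the set index).
#' @export
gen_pronucleus_microtubules <- function(n_microtubules = 20, n_frames = 10,
                                        layout = c("one_component", "separate_components"),
                                        seed = 1L) {
  n_microtubules <- check_count(n_microtubules, "n_microtubules")
  n_frames <- check_count(n_frames, "n_frames")
  layout <- match.arg(layout)
  with_seed(seed, {
    radius <- 5e-6
    start <- c(1e-5, 2.5e-5, 2.5e-5)
    velocity <- c(1.5e-6, 2e-7, 0)
    centers <- t(vapply(seq_len(n_frames) - 1,
                        function(f) start + f * velocity, numeric(3)))
    # fixed astral directions; lengths resampled per frame
    u <- matrix(stats::rnorm(3 * n_microtubules), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    lens <- matrix(stats::runif(n_frames * n_microtubules, 2e-6, 1e-5),
                   nrow = n_frames)

    mk_doc <- function(what) new_document(
      summary = bdml_summary(
        paste("simulated pronuclear migration driven by microtubules:", what),
        "nuclear migration", "Caenorhabditis elegans", basedon = "simulation"),
      contact = synth_contact(),
      methods = synth_methods("pronucleus-microtubules"),
      scale_unit = bdml_scale_unit(1, 1, 1, 1, "meter", "second"))

    add_sphere <- function(doc, cid, f)
      add_measurement(doc, cid, "pronucleus", bdml_sphere(centers[f, ], radius))
    add_mts <- function(doc, cid, f) {
      for (m in seq_len(n_microtubules)) {
        a <- centers[f, ] + radius * u[m, ]
        bnd <- centers[f, ] + (radius + lens[f, m]) * u[m, ]
        doc <- add_measurement(doc, cid, "microtubule", bdml_line(rbind(a, bnd)))
      }
      doc
    }

    truth <- list(centers = centers, radius = radius, directions = u,
                  lengths = lens, velocity = velocity)
    if (layout == "one_component") {
      doc <- mk_doc("sphere and segments in one component per frame")
      doc <- add_object(doc, "pronucleus")
      doc <- add_object(doc, "microtubule")
      prev <- character()
      for (f in seq_len(n_frames)) {
        doc <- add_component(doc, time = f - 1, prev_ids = prev)
        cid <- last_component_id(doc)
        doc <- add_sphere(doc, cid, f)
        doc <- add_mts(doc, cid, f)
        prev <- cid
      }
      list(doc = doc, truth = truth)
    } else {
      sph <- mk_doc("pronucleus part of a two-document set")
      sph <- add_object(sph, "pronucleus")
      mts <- mk_doc("microtubule part of a two-document set")
      mts <- add_object(mts, "microtubule")
      prev_s <- character(); prev_m <- character()
      for (f in seq_len(n_frames)) {
        sph <- add_component(sph, time = f - 1, prev_ids = prev_s)
        sph <- add_sphere(sph, last_component_id(sph), f)
        prev_s <- last_component_id(sph)
        mts <- add_component(mts, time = f - 1, prev_ids = prev_m)
        mts <- add_mts(mts, last_component_id(mts), f)
        prev_m <- last_component_id(mts)
      }
      index <- mk_doc("set index for the two-part split layout")
      index$body <- bdml_set(c(sph$info$bdml_id, mts$info$bdml_id),
                             c("pronucleus.bdml", "microtubules.bdml"))
      list(doc = index, parts = list(pronucleus = sph, microtubules = mts),
           truth = truth)
    }
  })
}

# ---- nuclei as spheres with a GFP intensity feature -----------------------

#' Generate dividing nuclei with a GFP intensity feature
#'
#' Emulates single-cell gene expression dynamics in a dividing *C. elegans*
#' embryo: each nucleus is a sphere whose total GFP--histone signal is
#' recorded as a feature value growing linearly in time,
#' `base + slope * t + noise`, with independent Gaussian noise of standard
#' deviation `noise_sd`. The division lineage over `n_generations`
#' generations is planted in the backward links exactly as in
#' [gen_dividing_nuclei()]. Coordinates are pixels under the calibration
#' 0.9 x 0.9 x 1.0 micrometers per voxel, the feature is declared in
#' arbitrary units (`"a.u."`), times in seconds.
#'
#' @param n_generations Number of generations (default 3).
#' @param frames_per_cell Frames per cell (default 5).
#' @param intensity_slope Planted linear growth rate per frame (default 1).
#' @param intensity_base Intensity at time 0 (default 10).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return A list with `doc` and `truth` (planted slope/base/noise, tree
#'   structure and per-component noiseless values).
#' @export
gen_expression_spheres <- function(n_generations = 3, frames_per_cell = 5,
                                   intensity_slope = 1, intensity_base = 10,
                                   noise_sd = 0, seed = 1L) {
  n_generations <- check_count(n_generations, "n_generations")
  frames_per_cell <- check_count(frames_per_cell, "frames_per_cell")
  noise_sd <- check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (!is_scalar_num(intensity_slope) || !is_scalar_num(intensity_base))
    stop_bdml("invalid-params", "intensity_slope and intensity_base must be numbers")
  with_seed(seed, {
    tree <- division_tree(n_generations, frames_per_cell)
    centers <- branch_centers(n_generations, spread = 60)
    doc <- new_document(
      summary = bdml_summary(
        "nuclear division with single-cell GFP-histone expression dynamics",
        "gene expression dynamics", "Caenorhabditis elegans",
        basedon = "experiment"),
      contact = synth_contact(), methods = synth_methods("expression-spheres"),
      scale_unit = bdml_scale_unit(0.9, 0.9, 1.0, 1, "micrometer", "second"))
    doc <- add_object(doc, "nucleus")
    doc <- add_feature(doc, bdml_feature("GFP", feature_scale = 1,
                                         feature_unit = "a.u."))
    truth_rows <- list()
    last_comp <- rep(NA_character_, tree$n_branches)
    for (b in seq_len(tree$n_branches)) {
      g <- tree$generation(b)
      r <- 12 * 0.8^(g - 1)
      par <- tree$parent(b)
      prev <- if (is.na(par)) character() else last_comp[par]
      for (frame in tree$frames(b)) {
        t <- tree$time_of(b, frame)
        value_true <- intensity_base + intensity_slope * t
        value <- value_true + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
        doc <- add_component(doc, time = t,
                             name = sprintf("branch_%d", b), prev_ids = prev)
        cid <- last_component_id(doc)
        doc <- add_measurement(doc, cid, "nucleus",
                               bdml_sphere(c(centers[b, ], 15), r),
                               properties = c(GFP = value))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          component_id = cid, branch = b, time = t,
          value_true = value_true, value = value, stringsAsFactors = FALSE)
        prev <- cid
      }
      last_comp[b] <- prev
    }
    truth <- list(
      components = do.call(rbind, truth_rows),
      intensity_slope = intensity_slope, intensity_base = intensity_base,
      noise_sd = noise_sd, n_branches = tree$n_branches,
      n_divisions = tree$n_divisions,
      parent = vapply(seq_len(tree$n_branches), tree$parent, 1L))
    list(doc = doc, truth = truth)
  })
}

# ---- 2D worm centerline ---------------------------------------------------

#' Generate a crawling worm centerline in 2D
#'
#' Emulates behavioral tracking of an adult *C. elegans* from 2D time-lapse
#' images: per frame one open polyline traces the body centerline as a
#' unit-speed curve -- every segment has the same length, so total arc
#' length is exactly constant across frames -- whose tangent angle
#' undulates sinusoidally around a slowly drifting heading, with the phase
#' advancing each frame to propagate the crawling wave. All stored z
#' coordinates are 0 and the z scale factor is 0, the format's marker for
#' two-dimensional data; x and y are pixels at 4.1 micrometers per pixel.
#'
#' @param n_frames Number of frames (default 20).
#' @param body_points Centerline vertices per frame, at least 2 (default 50).
#' @param undulation_amplitude Tangent-angle amplitude in radians
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list with `doc` and `truth` (segment length, planted arc
#'   length in pixels, heading series).
#' @export
gen_worm_track2d <- function(n_frames = 20, body_points = 50,
                             undulation_amplitude = 0.5, seed = 1L) {
  n_frames <- check_count(n_frames, "n_frames")
  body_points <- check_count(body_points, "body_points", min = 2)
  undulation_amplitude <- check_pos(undulation_amplitude, "undulation_amplitude",
                                    strict = FALSE)
  with_seed(seed, {
    ds <- 5          # pixels per segment; 49 segments * 5 px * 4.1 um ~ 1 mm
    n_waves <- 1.5   # undulation wavelengths along the body
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(n_frames - 1, 0, 0.15)))
    head_pos <- matrix(0, n_frames, 2L)
    head_pos[1L, ] <- c(500, 500)
    if (n_frames > 1L) for (f in 2:n_frames)
      head_pos[f, ] <- head_pos[f - 1L, ] +
        2 * ds * c(cos(heading[f]), sin(heading[f]))

    doc <- new_document(
      summary = bdml_summary(
        "2D behavioral tracking of an adult worm centerline",
        "behavioral dynamics", "Caenorhabditis elegans",
        basedon = "experiment"),
      contact = synth_contact(), methods = synth_methods("worm-track2d"),
      scale_unit = bdml_scale_unit(4.1, 4.1, 0, 1, "micrometer", "second"))
    doc <- add_object(doc, "worm")
    prev <- character()
    for (f in seq_len(n_frames)) {
      k <- seq_len(body_points - 1L)
      theta <- heading[f] +
        undulation_amplitude * sin(2 * pi * n_waves * k / body_points + 0.8 * f)
      pts <- matrix(0, body_points, 3L)
      pts[1L, 1:2] <- head_pos[f, ]
      for (i in k)
        pts[i + 1L, 1:2] <- pts[i, 1:2] + ds * c(cos(theta[i]), sin(theta[i]))
      doc <- add_component(doc, time = f - 1, prev_ids = prev)
      cid <- last_component_id(doc)
      doc <- add_measurement(doc, cid, "worm", bdml_line(pts))
      prev <- cid
    }
    list(doc = doc,
         truth = list(segment_px = ds, body_points = body_points,
                      length_px = (body_points - 1L) * ds,
                      length_um = (body_points - 1L) * ds * 4.1,
                      heading = heading))
  })
}

# ---- randomized valid documents (property-test corpus) --------------------

rand_word <- function(n = 8) paste(sample(letters, n, replace = TRUE), collapse = "")

rand_entity <- function() {
  kind <- sample(BDML_ENTITY_KINDS, 1L)
  rp <- function(n) round(matrix(stats::runif(3 * n, -100, 100), ncol = 3L), 3)
  switch(kind,
    point = bdml_point(drop(rp(1L))),
    line = bdml_line(rp(sample(2:8, 1L))),
    circle = bdml_circle(drop(rp(1L)), round(stats::runif(1, 0.1, 20), 3)),
    sphere = bdml_sphere(drop(rp(1L)), round(stats::runif(1, 0.1, 20), 3)),
    face = bdml_face(rp(3L)))
}

#' Generate a randomized valid BDML document
#'
#' Draws a structurally varied but semantically valid document: random
#' metadata, optionally a populated ontology section with references to it,
#' random object and feature declarations, components at strictly
#' increasing times carrying randomly chosen entities of all five kinds,
#' random feature properties and random backward links (including
#' occasional divisions and fusions). Built entirely through the model
#' constructors, so validity holds by construction. This is the corpus
#' behind the serialization round-trip and validator soundness properties.
#'
#' @param seed Integer seed.
#' @param n_components Number of components (default drawn in 1..12).
#' @return A `bdml_document`.
#' @export
gen_random_document <- function(seed = 1L, n_components = NULL) {
  with_seed(seed, {
    if (is.null(n_components)) n_components <- sample(1:12, 1L)
    n_components <- check_count(n_components, "n_components")
    n_onto <- sample(0:2, 1L)
    onto_ids <- if (n_onto > 0) sprintf("term%02d", seq_len(n_onto)) else character()
    doc <- new_document(
      summary = bdml_summary(
        description = paste("randomized document", rand_word()),
        datatype = rand_word(), organism = "Caenorhabditis elegans",
        basedon = sample(BDML_BASEDON, 1L),
        local_id = if (stats::runif(1) < 0.5) rand_word(5) else NULL,
        references = if (stats::runif(1) < 0.5) sprintf("doi:10.0/%s", rand_word(5)) else character(),
        datatype_ref = if (n_onto > 0 && stats::runif(1) < 0.5) onto_ids[1L] else NULL),
      contact = bdml_contact(rand_word(), paste0(rand_word(5), "@", rand_word(5), ".org"),
                             rand_word(12)),
      methods = bdml_methods(
        source_uri = if (stats::runif(1) < 0.7) paste0("https://example.org/", rand_word()) else NULL,
        procedure_uri = if (stats::runif(1) < 0.5) paste0("urn:proc:", rand_word()) else NULL,
        notes = if (stats::runif(1) < 0.3) paste("notes with <markup> &", rand_word()) else NULL),
      scale_unit = bdml_scale_unit(
        round(stats::runif(1, 0.05, 5), 3), round(stats::runif(1, 0.05, 5), 3),
        if (stats::runif(1) < 0.2) 0 else round(stats::runif(1, 0.05, 5), 3),
        round(stats::runif(1, 0.1, 60), 3),
        xyz_unit = sample(c("meter", "micrometer", "p.d.u."), 1L),
        t_unit = sample(bdml_time_units(), 1L)),
      title = if (stats::runif(1) < 0.5) rand_word(10) else NULL)
    for (id in onto_ids)
      doc <- add_ontology_term(doc, bdml_ontology_term(
        id, rand_word(), sprintf("ONT:%04d", sample(9999, 1L)),
        "https://example.org/ontology"))
    objs <- sprintf("object_%s", letters[seq_len(sample(1:3, 1L))])
    for (o in objs)
      doc <- add_object(doc, bdml_object(o,
        ontology_ref = if (n_onto > 0 && stats::runif(1) < 0.3) sample(onto_ids, 1L) else NULL))
    feats <- if (stats::runif(1) < 0.7) sprintf("feature_%s", letters[seq_len(sample(1:2, 1L))]) else character()
    for (f in feats)
      doc <- add_feature(doc, bdml_feature(f,
        feature_scale = round(stats::runif(1, 0.1, 10), 3),
        feature_unit = sample(c("a.u.", "mole", "item"), 1L)))
    times <- round(cumsum(stats::runif(n_components, 0.5, 3)), 3)
    ids <- character()
    for (i in seq_len(n_components)) {
      prev <- if (i > 1L && stats::runif(1) < 0.7)
        sample(ids, sample(1:min(2L, length(ids)), 1L)) else character()
      doc <- add_component(doc, time = times[i],
                           name = if (stats::runif(1) < 0.3) rand_word(6) else NULL,
                           prev_ids = prev)
      ids <- c(ids, last_component_id(doc))
      for (k in seq_len(sample(1:3, 1L))) {
        props <- if (length(feats) > 0L && stats::runif(1) < 0.6)
          stats::setNames(round(stats::runif(1, 0, 50), 3), sample(feats, 1L)) else NULL
        doc <- add_measurement(doc, ids[i], sample(objs, 1L), rand_entity(),
                               properties = props)
      }
    }
    attr(doc, "component_id") <- NULL
    doc
  })
}
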