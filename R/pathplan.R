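#' Print-path configuration
#'
#' Parameters of the toolpath generator. The slow-start scheme prints the
#' first `slow_speed * slow_time` mm of every stroke (each transition from a
#' non-printing to a printing state) at `slow_speed`, compensating the
#' pneumatic extrusion start-up lag; the remainder runs at `speed`. The
#' overlap distance `overlap_d2` is the gap between the infill short edges and
#' the perimeter frame.
#'
#' @param speed Normal print speed, mm/s (default 12).
#' @param slow_speed Slow-start speed, mm/s (default 1).
#' @param slow_time Slow-start duration t0, s (default 0.1; 0 disables).
#' @param layer_thickness Layer height, mm (default 0.2).
#' @param fill_spacing Spacing between neighboring infill lines, mm
#'   (default 0.8).
#' @param frame_offset Spacing between the outer frame and the fill pattern,
#'   mm (default 0.5).
#' @param overlap_d2 Distance from the infill short edge to the frame, mm
#'   (default 0.3, inside the recommended 0.2-0.3 mm window);
#'   must be <= `frame_offset`.
#' @param nozzle_diameter Nozzle inner diameter, mm (default 0.25).
#' @param travel_speed Non-printing travel speed, mm/s (default 30).
#' @return An object of class `path_config`.
#' @export
path_config <- function(speed = 12, slow_speed = 1, slow_time = 0.1,
                        layer_thickness = 0.2, fill_spacing = 0.8,
                        frame_offset = 0.5, overlap_d2 = 0.3,
                        nozzle_diameter = 0.25, travel_speed = 30) {
  vals <- c(speed = speed, slow_speed = slow_speed,
            layer_thickness = layer_thickness, fill_spacing = fill_spacing,
            frame_offset = frame_offset, nozzle_diameter = nozzle_diameter,
            travel_speed = travel_speed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all path-config speeds and lengths must be finite and > 0")
  if (!is.finite(slow_time) || slow_time < 0)
    stop("slow_time must be finite and >= 0")
  if (!is.finite(overlap_d2) || overlap_d2 < 0)
    stop("overlap_d2 must be finite and >= 0")
  if (overlap_d2 > frame_offset)
    stop("overlap_d2 must not exceed frame_offset")
  structure(list(speed = speed, slow_speed = slow_speed, slow_time = slow_time,
                 layer_thickness = layer_thickness,
                 fill_spacing = fill_spacing, frame_offset = frame_offset,
                 overlap_d2 = overlap_d2, nozzle_diameter = nozzle_diameter,
                 travel_speed = travel_speed),
            class = "path_config")
}

empty_segments <- function() {
  data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
             x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
             speed_mm_s = numeric(0), extruding = logical(0),
             slow_start = logical(0), layer = integer(0))
}

seg_row <- function(p0, p1, speed, extruding, slow_start, layer) {
  data.frame(x0 = p0[1], y0 = p0[2], z0 = p0[3],
             x1 = p1[1], y1 = p1[2], z1 = p1[3],
             speed_mm_s = speed, extruding = extruding,
             slow_start = slow_start, layer = as.integer(layer))
}

new_tool_path <- function(segments, config) {
  rownames(segments) <- NULL
  structure(list(segments = segments, config = config), class = "tool_path")
}

#' @export
print.tool_path <- function(x, ...) {
  s <- x$segments
  len <- segment_lengths(x)
  cat(sprintf(
    "Toolpath: %d segments, %d layer(s); printed %.2f mm, travel %.2f mm, %d slow-start stroke(s)\n",
    nrow(s), if (nrow(s)) max(s$layer) else 0L,
    sum(len[s$extruding]), sum(len[!s$extruding]), sum(s$slow_start)))
  invisible(x)
}

#' Segment lengths of a toolpath, mm
#'
#' @param path A `tool_path`.
#' @return Numeric vector of per-segment lengths.
#' @export
segment_lengths <- function(path) {
  s <- path$segments
  sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 + (s$z1 - s$z0)^2)
}

# a printed stroke from p0 to p1; first slow_len mm at slow speed when the
# stroke begins a printing resumption
stroke_segments <- function(p0, p1, config, layer, resume = TRUE) {
  len <- sqrt(sum((p1 - p0)^2))
  slow_len <- config$slow_speed * config$slow_time
  if (!resume || slow_len == 0) {
    return(seg_row(p0, p1, config$speed, TRUE, FALSE, layer))
  }
  if (len <= slow_len)
    stop("stroke length (", len, " mm) must exceed the slow-start length (",
         slow_len, " mm)")
  mid <- p0 + (p1 - p0) * slow_len / len
  rbind(seg_row(p0, mid, config$slow_speed, TRUE, TRUE, layer),
        seg_row(mid, p1, config$speed, TRUE, FALSE, layer))
}

#' Plan a single printed line
#'
#' One straight stroke of the design length along +x, with the slow-start
#' scheme applied at the stroke start: the first `slow_speed * slow_time` mm
#' run at the slow speed and the remainder at the normal speed, so the total
#' path length equals the design length.
#'
#' @param length Design line length, mm; must exceed the slow-start length.
#' @param config A [path_config()].
#' @return A `tool_path`.
#' @examples
#' plan_line(15, path_config())
#' @export
plan_line <- function(length, config = path_config()) {
  stopifnot(inherits(config, "path_config"))
  if (!is.finite(length) || length <= config$slow_speed * config$slow_time)
    stop("length must exceed the slow-start distance ",
         config$slow_speed * config$slow_time, " mm")
  z <- config$layer_thickness
  segs <- stroke_segments(c(0, 0, z), c(length, 0, z), config, layer = 1L)
  new_tool_path(segs, config)
}

# serpentine infill for a rectangular region; axis = "x" (lines along x) or
# "y"; returns printed segments (one continuous stroke, slow start on entry)
serpentine_fill <- function(width, depth, z, config, layer, axis) {
  d2 <- config$overlap_d2
  off <- config$frame_offset
  sp <- config$fill_spacing
  if (axis == "x") {
    span <- depth - 2 * off
    n_lines <- floor(span / sp) + 1L
    ys <- off + (seq_len(n_lines) - 1L) * sp
    x_lo <- d2; x_hi <- width - d2
    pts <- list()
    for (i in seq_len(n_lines)) {
      fwd <- i %% 2L == 1L
      pts[[length(pts) + 1L]] <- c(if (fwd) x_lo else x_hi, ys[i], z)
      pts[[length(pts) + 1L]] <- c(if (fwd) x_hi else x_lo, ys[i], z)
    }
  } else {
    span <- width - 2 * off
    n_lines <- floor(span / sp) + 1L
    xs <- off + (seq_len(n_lines) - 1L) * sp
    y_lo <- d2; y_hi <- depth - d2
    pts <- list()
    for (i in seq_len(n_lines)) {
      fwd <- i %% 2L == 1L
      pts[[length(pts) + 1L]] <- c(xs[i], if (fwd) y_lo else y_hi, z)
      pts[[length(pts) + 1L]] <- c(xs[i], if (fwd) y_hi else y_lo, z)
    }
  }
  segs <- empty_segments()
  prev <- NULL
  for (i in seq_along(pts)) {
    if (!is.null(prev) && !isTRUE(all.equal(prev, pts[[i]]))) {
      segs <- rbind(segs, stroke_segments(prev, pts[[i]], config, layer,
                                          resume = nrow(segs) == 0))
    }
    prev <- pts[[i]]
  }
  segs
}

#' Plan a grid- or solid-filled rectangular prism
#'
#' Per layer: the perimeter frame is printed first, then the infill. Infill
#' short edges stop at the overlap distance `overlap_d2` from the frame; the
#' first infill line sits `frame_offset` from the frame. For the `grid`
#' pattern the fill orientation alternates 0/90 degrees between layers;
#' `solid` keeps one orientation. Every transition from travel to printing
#' starts with a slow-start segment.
#'
#' @param width,depth Part footprint, mm; each must exceed
#'   `2 * frame_offset + fill_spacing`.
#' @param layers Number of layers (>= 1).
#' @param config A [path_config()].
#' @param pattern `"grid"` (0/90 alternating) or `"solid"`.
#' @return A `tool_path`.
#' @export
plan_grid_prism <- function(width, depth, layers, config = path_config(),
                            pattern = c("grid", "solid")) {
  stopifnot(inherits(config, "path_config"))
  pattern <- match.arg(pattern)
  if (layers < 1L) stop("layers must be >= 1")
  if (width <= 2 * config$frame_offset || depth <= 2 * config$frame_offset)
    stop("part must be larger than twice the frame-to-fill spacing")
  segs <- empty_segments()
  pos <- c(0, 0, 0)
  for (l in seq_len(layers)) {
    z <- l * config$layer_thickness
    # travel to the frame start
    start <- c(0, 0, z)
    segs <- rbind(segs, seg_row(pos, start, config$travel_speed, FALSE, FALSE, l))
    # perimeter frame (continuous; slow start on the first edge)
    corners <- list(c(width, 0, z), c(width, depth, z), c(0, depth, z),
                    c(0, 0, z))
    prev <- start
    for (i in seq_along(corners)) {
      segs <- rbind(segs, stroke_segments(prev, corners[[i]], config, l,
                                          resume = i == 1L))
      prev <- corners[[i]]
    }
    # travel to infill entry, then serpentine fill
    axis <- if (pattern == "grid" && l %% 2L == 0L) "y" else "x"
    fill <- serpentine_fill(width, depth, z, config, l, axis)
    entry <- c(fill$x0[1], fill$y0[1], fill$z0[1])
    segs <- rbind(segs, seg_row(prev, entry, config$travel_speed, FALSE, FALSE, l))
    segs <- rbind(segs, fill)
    pos <- c(fill$x1[nrow(fill)], fill$y1[nrow(fill)], fill$z1[nrow(fill)])
  }
  new_tool_path(segs, config)
}

#' Extrusion-volume bookkeeping for a toolpath
#'
#' Per printed segment: residence time, deposited volume `Q * time`, and the
#' filament diameter predicted by volume conservation at that segment's speed
#' ([filament_diameter()]). Totals are conserved: the summed volume equals Q
#' times the total printing time.
#'
#' @param path A `tool_path`.
#' @param Q Extrusion flow rate, uL/s (> 0).
#' @return The segment table with `length_mm`, `time_s`, `volume_ul` and
#'   `diameter_mm` columns appended (travel rows get zero volume, NA diameter).
#' @export
extrusion_bookkeeping <- function(path, Q) {
  stopifnot(inherits(path, "tool_path"))
  if (!is.finite(Q) || Q <= 0) stop("Q must be finite and > 0")
  s <- path$segments
  s$length_mm <- segment_lengths(path)
  s$time_s <- s$length_mm / s$speed_mm_s
  s$volume_ul <- ifelse(s$extruding, Q * s$time_s, 0)
  s$diameter_mm <- ifelse(s$extruding, filament_diameter(Q, s$speed_mm_s),
                          NA_real_)
  s
}
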