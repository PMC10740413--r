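#' Export a toolpath to G-code
#'
#' Minimal dialect for pneumatic extrusion printers (no E axis): `G0` travel
#' moves, `G1` printing moves with `F` feed in mm/min, `M101`/`M103` toggling
#' extrusion on/off at stroke boundaries, a `G92` origin statement giving the
#' first segment's start point, and comments marking layer boundaries and
#' slow-start segments. The file is fully deterministic (no timestamps) and
#' [import_gcode()] round-trips it to an identical toolpath.
#'
#' @param path A `tool_path`.
#' @param file Output file path.
#' @return The file path, invisibly.
#' @export
export_gcode <- function(path, file) {
  stopifnot(inherits(path, "tool_path"))
  s <- path$segments
  fmt <- function(x) sprintf("%.5f", x)
  lines <- c("; inkflow toolpath", "; units: mm, feed mm/min")
  if (nrow(s) > 0) {
    lines <- c(lines, sprintf("G92 X%s Y%s Z%s",
                              fmt(s$x0[1]), fmt(s$y0[1]), fmt(s$z0[1])))
    extruding <- FALSE
    layer <- NA_integer_
    for (i in seq_len(nrow(s))) {
      if (!identical(layer, s$layer[i])) {
        layer <- s$layer[i]
        lines <- c(lines, sprintf("; layer %d", layer))
      }
      if (s$extruding[i] && !extruding) { lines <- c(lines, "M101"); extruding <- TRUE }
      if (!s$extruding[i] && extruding) { lines <- c(lines, "M103"); extruding <- FALSE }
      lines <- c(lines, sprintf("%s X%s Y%s Z%s F%s%s",
                                if (s$extruding[i]) "G1" else "G0",
                                fmt(s$x1[i]), fmt(s$y1[i]), fmt(s$z1[i]),
                                fmt(s$speed_mm_s[i] * 60),
                                if (s$slow_start[i]) " ; slow-start" else ""))
    }
    if (extruding) lines <- c(lines, "M103")
  }
  lines <- c(lines, "; end")
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Re-import a G-code file written by [export_gcode()]
#'
#' @param file G-code file path.
#' @param config Optional [path_config()] to attach to the result.
#' @return A `tool_path`.
#' @export
import_gcode <- function(file, config = path_config()) {
  lines <- readLines(file, encoding = "UTF-8")
  segs <- empty_segments()
  pos <- c(0, 0, 0)
  extruding <- FALSE
  layer <- 1L
  grab <- function(line, key) {
    m <- regmatches(line, regexpr(paste0(key, "[-0-9.]+"), line))
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub(key, "", m))
  }
  for (line in lines) {
    if (grepl("^; layer ", line)) {
      layer <- as.integer(sub("^; layer ", "", line))
    } else if (grepl("^M101", line)) {
      extruding <- TRUE
    } else if (grepl("^M103", line)) {
      extruding <- FALSE
    } else if (grepl("^G92", line)) {
      pos <- c(grab(line, "X"), grab(line, "Y"), grab(line, "Z"))
    } else if (grepl("^G[01] ", line)) {
      p1 <- c(grab(line, "X"), grab(line, "Y"), grab(line, "Z"))
      speed <- grab(line, "F") / 60
      segs <- rbind(segs, seg_row(pos, p1, speed, extruding,
                                  grepl("slow-start", line), layer))
      pos <- p1
    }
  }
  new_tool_path(segs, config)
}
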