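#' Three-factor Box-Behnken design
#'
#' Constructs the classical 3-factor Box-Behnken response-surface design: the
#' 12 edge midpoints of the factor cube (each run has exactly one factor at
#' its center and the other two at +/-1) plus replicated center points. Row
#' order is deterministic: factor pairs in lexicographic order, signs in
#' (-,-), (-,+), (+,-), (+,+) order, center runs last.
#'
#' @param levels A named list of length 3; each element a numeric vector
#'   `c(low, center, high)` with `low < center < high`.
#' @param center_replicates Number of center-point replicates (>= 1).
#' @return An object of class `bb_design` with elements `factors`, `levels`
#'   (3 x 3 matrix, rows = factors, cols = low/center/high), `coded`
#'   (runs x 3 matrix in {-1, 0, +1}), `uncoded` (runs x 3 data frame in
#'   natural units) and `center_replicates`.
#' @examples
#' d <- bb_design(list(Gel = c(6, 8, 10), SA = c(3, 4, 5), MC = c(2, 3, 4)))
#' nrow(d$coded) # 17
#' @export
bb_design <- function(levels, center_replicates = 5L) {
  if (length(levels) != 3L || is.null(names(levels)))
    stop("levels must be a named list of 3 factors")
  lv <- do.call(rbind, levels)
  colnames(lv) <- c("low", "center", "high")
  if (any(lv[, "low"] >= lv[, "center"]) || any(lv[, "center"] >= lv[, "high"]))
    stop("factor levels must satisfy low < center < high")
  if (center_replicates < 1L) stop("center_replicates must be >= 1")

  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  signs <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  coded <- matrix(0, nrow = 12L + center_replicates, ncol = 3L,
                  dimnames = list(NULL, names(levels)))
  r <- 1L
  for (p in pairs) {
    for (s in seq_len(4L)) {
      coded[r, p] <- signs[s, ]
      r <- r + 1L
    }
  }
  structure(list(
    factors = names(levels),
    levels = lv,
    coded = coded,
    uncoded = as.data.frame(coded_to_uncoded(coded, lv)),
    center_replicates = as.integer(center_replicates)
  ), class = "bb_design")
}

#' Box-Behnken design over the ink composition cube
#'
#' Convenience constructor for the gelatin / sodium alginate / methylcellulose
#' design space: Gel 6/8/10 wt%, SA 3/4/5 wt%, MC 2/3/4 wt%, with 5 center
#' replicates (17 runs).
#'
#' @inheritParams bb_design
#' @return A [bb_design()] object.
#' @export
bb_design_ink <- function(center_replicates = 5L) {
  bb_design(list(Gel = c(6, 8, 10), SA = c(3, 4, 5), MC = c(2, 3, 4)),
            center_replicates = center_replicates)
}

# affine coded <-> uncoded maps; coded units are (x - center) / half-range
coded_to_uncoded <- function(coded, levels) {
  center <- levels[, "center"]
  half <- (levels[, "high"] - levels[, "low"]) / 2
  sweep(sweep(coded, 2, half, "*"), 2, center, "+")
}

uncoded_to_coded <- function(uncoded, levels) {
  center <- levels[, "center"]
  half <- (levels[, "high"] - levels[, "low"]) / 2
  sweep(sweep(as.matrix(uncoded), 2, center, "-"), 2, half, "/")
}

#' Map design points between coded and natural units
#'
#' The coded-unit map is affine and invertible:
#' `coded = (uncoded - center) / ((high - low) / 2)`.
#'
#' @param design A [bb_design()].
#' @param coded,uncoded Matrix or data frame of points (columns = factors).
#' @return A matrix of points in the other unit system.
#' @export
design_uncode <- function(design, coded) {
  stopifnot(inherits(design, "bb_design"))
  coded_to_uncoded(as.matrix(coded), design$levels)
}

#' @rdname design_uncode
#' @export
design_code <- function(design, uncoded) {
  stopifnot(inherits(design, "bb_design"))
  uncoded_to_coded(as.matrix(uncoded), design$levels)
}

#' @export
print.bb_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d factors (%s), %d runs (%d center replicates)\n",
              length(x$factors), paste(x$factors, collapse = ", "),
              nrow(x$coded), x$center_replicates))
  invisible(x)
}
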