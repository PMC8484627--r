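#' Construct a contour
#'
#' A contour is an ordered open polyline of fiducial points on a pixel
#' canvas, the unit on which all contour features (orientation, length,
#' angularity) are computed.  Coordinates follow the image convention:
#' origin at the top-left, x rightward, y downward.
#'
#' @param points numeric matrix with two columns (x, y) or a data frame with
#'   columns `x` and `y`; at least two rows.  Consecutive points must be
#'   distinct so that every segment has positive length.
#' @param id opaque identifier for the contour.
#' @return an object of class `contour`: a list with elements `points`
#'   (n x 2 matrix) and `id`.
#' @examples
#' ct <- contour(cbind(c(0, 10, 10), c(0, 0, 10)))
#' contour_length(ct)
#' @export
contour <- function(points, id = NULL) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a numeric matrix with columns x, y", call. = FALSE)
  if (nrow(points) < 2L)
    stop("invalid contour: fewer than 2 points", call. = FALSE)
  if (any(!is.finite(points)))
    stop("invalid contour: non-finite coordinates", call. = FALSE)
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    stop("invalid contour: consecutive points coincide (zero-length segment)",
         call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, id = id), class = "contour")
}

#' @exportS3Method print contour
print.contour <- function(x, ...) {
  cat(sprintf("<contour%s: %d points, length %.2f px>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$points), contour_length(x)), sep = "")
  invisible(x)
}

as_contour <- function(x) {
  if (inherits(x, "contour")) x else contour(x)
}

#' Construct a line drawing
#'
#' A line drawing is a set of contours on a rectangular pixel canvas
#' (e.g. 800 x 600 for traced drawings, 200 x 150 for generated stimuli).
#'
#' @param contours list of [contour()] objects (at least one).
#' @param canvas_width,canvas_height canvas size in pixels.
#' @param id optional drawing identifier.
#' @param validate_canvas if `TRUE` (default), error when any point lies
#'   outside the canvas rectangle.
#' @return an object of class `line_drawing`.
#' @export
line_drawing <- function(contours, canvas_width = 800, canvas_height = 600,
                         id = NULL, validate_canvas = TRUE) {
  if (inherits(contours, "contour")) contours <- list(contours)
  if (!length(contours)) stop("a line drawing needs at least one contour",
                              call. = FALSE)
  contours <- lapply(contours, as_contour)
  if (validate_canvas) {
    for (ct in contours) {
      p <- ct$points
      if (any(p[, 1] < 0 | p[, 1] > canvas_width |
              p[, 2] < 0 | p[, 2] > canvas_height))
        stop(sprintf("contour %s has points outside the %g x %g canvas",
                     if (is.null(ct$id)) "<unnamed>" else ct$id,
                     canvas_width, canvas_height), call. = FALSE)
    }
  }
  structure(list(contours = contours, canvas_width = canvas_width,
                 canvas_height = canvas_height, id = id),
            class = "line_drawing")
}

#' @exportS3Method print line_drawing
print.line_drawing <- function(x, ...) {
  cat(sprintf("<line_drawing%s: %d contours on %g x %g canvas>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$contours), x$canvas_width, x$canvas_height))
  invisible(x)
}

#' Segment lengths of a contour
#'
#' @param ct a [contour()].
#' @return numeric vector of Euclidean segment lengths in pixels, one per
#'   consecutive point pair; all strictly positive.
#' @export
segment_lengths <- function(ct) {
  ct <- as_contour(ct)
  d <- diff(ct$points)
  sqrt(as.numeric(d[, 1])^2 + as.numeric(d[, 2])^2)
}

#' Segment orientations of a contour
#'
#' Orientation is the counter-clockwise angle from horizontal in visual
#' space.  Because canvas y grows downward, orientation is computed from
#' (dx, -dy) and reduced modulo 180 so it is direction-invariant: reversing
#' the contour leaves every value unchanged.
#'
#' @param ct a [contour()].
#' @return numeric vector of orientations in degrees, in `[0, 180)`.
#' @export
segment_orientations <- function(ct) {
  ct <- as_contour(ct)
  d <- diff(ct$points)
  ang <- atan2(-as.numeric(d[, 2]), as.numeric(d[, 1])) * 180 / pi
  ang %% 180
}

#' Total contour length
#'
#' Sum of the Euclidean lengths of a contour's line segments, in pixels.
#'
#' @param ct a [contour()].
#' @return total length in pixels (strictly positive).
#' @export
contour_length <- function(ct) {
  sum(segment_lengths(ct))
}

#' Per-vertex angularity of a contour
#'
#' Angularity at an interior vertex is the absolute turn angle between the
#' incoming and outgoing segment directions (degrees, in `[0, 180]`) divided
#' by the length of the adjacent segments, giving degrees per pixel.  It is
#' the discrete analogue of curvature magnitude; collinear vertices give 0.
#'
#' @param ct a [contour()].
#' @param denominator how to combine the two adjacent segment lengths into
#'   the divisor: `"mean"` (default), `"min"`, or `"sum"`.
#' @return numeric vector with one value per interior vertex (length
#'   `n_points - 2`); empty for a two-point contour.
#' @export
vertex_angularities <- function(ct, denominator = c("mean", "min", "sum")) {
  denominator <- match.arg(denominator)
  ct <- as_contour(ct)
  d <- diff(ct$points)
  n <- nrow(d)
  if (n < 2L) return(numeric(0))
  len <- sqrt(as.numeric(d[, 1])^2 + as.numeric(d[, 2])^2)
  # directed headings in visual space
  head <- atan2(-as.numeric(d[, 2]), as.numeric(d[, 1])) * 180 / pi
  turn <- abs(diff(head)) %% 360
  turn <- pmin(turn, 360 - turn)           # absolute turn in [0, 180]
  den <- switch(denominator,
                mean = (len[-n] + len[-1]) / 2,
                min  = pmin(len[-n], len[-1]),
                sum  = len[-n] + len[-1])
  turn / den
}

#' Folded mean orientation of a contour
#'
#' Segment orientations in `[0, 180)` are folded onto `[0, 90]`
#' (theta > 90 maps to 180 - theta) so that near-horizontal directions
#' coincide at 0 and near-vertical at 90; the pixel-length-weighted
#' arithmetic mean of the folded values summarises the contour's dominant
#' orientation for classification.
#'
#' @param ct a [contour()].
#' @param weighted if `TRUE` (default) weight each segment by its pixel
#'   length; otherwise take the unweighted mean.
#' @return mean folded orientation in degrees, in `[0, 90]`.
#' @export
folded_mean_orientation <- function(ct, weighted = TRUE) {
  ct <- as_contour(ct)
  th <- segment_orientations(ct)
  thf <- ifelse(th > 90, 180 - th, th)
  if (weighted) {
    w <- segment_lengths(ct)
    sum(thf * w) / sum(w)
  } else {
    mean(thf)
  }
}

#' Folded segment orientations
#'
#' @param ct a [contour()].
#' @return per-segment orientations folded onto `[0, 90]`.
#' @keywords internal
folded_orientations <- function(ct) {
  th <- segment_orientations(ct)
  ifelse(th > 90, 180 - th, th)
}
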