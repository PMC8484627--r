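#' Histogram bin specification
#'
#' Bin centers for the three 8-bin contour-feature histograms.  Orientation
#' centers are evenly spaced over the 180-degree orientation circle; length
#' and angularity centers are evenly spaced in log10 over the range observed
#' in traced line drawings and are used verbatim as constants.
#'
#' @param orientation_centers degrees, 8 values.
#' @param length_centers pixels, 8 values (log-spaced).
#' @param angularity_centers degrees per pixel, 8 values (log-spaced).
#' @return an object of class `bin_spec`.
#' @export
bin_spec <- function(orientation_centers = seq(0, 157.5, by = 22.5),
                     length_centers = c(1.66, 4.47, 12.02, 32.36, 87.10,
                                        232.42, 630.96, 1698.24),
                     angularity_centers = c(1.38, 2.63, 5.13, 9.77, 18.62,
                                            35.48, 67.61, 131.83)) {
  for (v in list(orientation_centers, length_centers, angularity_centers)) {
    if (length(v) != 8L || any(diff(v) <= 0))
      stop("each feature needs 8 strictly increasing bin centers",
           call. = FALSE)
  }
  structure(list(orientation_centers = orientation_centers,
                 length_centers = length_centers,
                 angularity_centers = angularity_centers),
            class = "bin_spec")
}

# Distribute masses over 8 circularly adjacent orientation bins by linear
# (triangular) interpolation; the last center wraps back to the first.
bin_circular <- function(values, masses, centers, mode) {
  step <- centers[2] - centers[1]
  period <- 8 * step
  pos <- (values %% period) / step          # in [0, 8)
  w <- numeric(8)
  if (mode == "nearest") {
    idx <- (round(pos) %% 8) + 1
    for (k in seq_along(idx)) w[idx[k]] <- w[idx[k]] + masses[k]
  } else {
    i <- floor(pos)
    frac <- pos - i
    lo <- (i %% 8) + 1
    hi <- ((i + 1) %% 8) + 1
    for (k in seq_along(lo)) {
      w[lo[k]] <- w[lo[k]] + masses[k] * (1 - frac[k])
      w[hi[k]] <- w[hi[k]] + masses[k] * frac[k]
    }
  }
  w
}

# Distribute masses over log10-spaced bins with triangular interpolation
# between adjacent centers; values at or beyond the extreme centers are
# clamped to the end bins.  Non-positive values fall in bin 1.
bin_log <- function(values, masses, centers, mode) {
  zc <- log10(centers)
  w <- numeric(8)
  for (k in seq_along(values)) {
    v <- values[k]
    if (v <= centers[1]) { w[1] <- w[1] + masses[k]; next }
    if (v >= centers[8]) { w[8] <- w[8] + masses[k]; next }
    z <- log10(v)
    i <- findInterval(z, zc)               # 1..7 here
    frac <- (z - zc[i]) / (zc[i + 1] - zc[i])
    if (mode == "nearest") {
      j <- if (frac < 0.5) i else i + 1
      w[j] <- w[j] + masses[k]
    } else {
      w[i] <- w[i] + masses[k] * (1 - frac)
      w[i + 1] <- w[i + 1] + masses[k] * frac
    }
  }
  w
}

new_feature_histogram <- function(feature_name, bin_centers, weights) {
  structure(list(feature_name = feature_name, bin_centers = bin_centers,
                 weights = weights), class = "feature_histogram")
}

#' @exportS3Method print feature_histogram
print.feature_histogram <- function(x, ...) {
  cat(sprintf("<feature_histogram: %s>\n", x$feature_name))
  print(stats::setNames(round(x$weights, 3), signif(x$bin_centers, 4)))
  invisible(x)
}

check_drawing <- function(drawing) {
  if (!inherits(drawing, "line_drawing"))
    stop("expected a line_drawing object", call. = FALSE)
  if (!length(drawing$contours))
    stop("empty drawing: no contours", call. = FALSE)
  drawing
}

#' Orientation histogram of a line drawing
#'
#' Each line segment contributes its pixel length, split between the two
#' circularly adjacent orientation bin centers by triangular interpolation
#' (157.5 degrees wraps around to 0).  Total mass equals the drawing's total
#' contour length.
#'
#' @param drawing a [line_drawing()].
#' @param spec a [bin_spec()].
#' @param mode `"triangular"` (default) or `"nearest"` center assignment.
#' @return a `feature_histogram` with 8 non-negative pixel weights.
#' @export
orientation_histogram <- function(drawing, spec = bin_spec(),
                                  mode = c("triangular", "nearest")) {
  mode <- match.arg(mode)
  check_drawing(drawing)
  th <- unlist(lapply(drawing$contours, segment_orientations))
  len <- unlist(lapply(drawing$contours, segment_lengths))
  w <- bin_circular(th, len, spec$orientation_centers, mode)
  new_feature_histogram("orientation", spec$orientation_centers, w)
}

#' Length histogram of a line drawing
#'
#' Each contour contributes its total pixel length to length bins according
#' to the base-10 logarithm of that length, interpolated triangularly
#' between adjacent log-spaced centers; contours at or beyond the extreme
#' centers are clamped to the end bins.
#'
#' @inheritParams orientation_histogram
#' @return a `feature_histogram` with 8 non-negative pixel weights.
#' @export
length_histogram <- function(drawing, spec = bin_spec(),
                             mode = c("triangular", "nearest")) {
  mode <- match.arg(mode)
  check_drawing(drawing)
  lens <- vapply(drawing$contours, contour_length, numeric(1))
  w <- bin_log(lens, lens, spec$length_centers, mode)
  new_feature_histogram("length", spec$length_centers, w)
}

#' Angularity histogram of a line drawing
#'
#' Each interior vertex contributes the pixel length of its two adjacent
#' half-segments to angularity bins by log10 triangular interpolation.
#' Half-segments not adjacent to any interior vertex (the outer halves of a
#' contour's first and last segments, and both halves of a two-point
#' contour) carry zero turn and are assigned to bin 1, as are vertices with
#' angularity at or below the first bin center.  Mass is therefore conserved:
#' the weights sum to the drawing's total contour length.
#'
#' @inheritParams orientation_histogram
#' @param denominator passed to [vertex_angularities()].
#' @return a `feature_histogram` with 8 non-negative pixel weights.
#' @export
angularity_histogram <- function(drawing, spec = bin_spec(),
                                 mode = c("triangular", "nearest"),
                                 denominator = "mean") {
  mode <- match.arg(mode)
  check_drawing(drawing)
  w <- numeric(8)
  for (ct in drawing$contours) {
    len <- segment_lengths(ct)
    n <- length(len)
    if (n < 2L) {
      w[1] <- w[1] + sum(len)
      next
    }
    ang <- vertex_angularities(ct, denominator = denominator)
    mass <- (len[-n] + len[-1]) / 2         # half of each adjacent segment
    w <- w + bin_log(ang, mass, spec$angularity_centers, mode)
    w[1] <- w[1] + (len[1] + len[n]) / 2    # endpoint half-segments
  }
  new_feature_histogram("angularity", spec$angularity_centers, w)
}

#' Regression feature vector of a line drawing
#'
#' Concatenates the orientation, length, and angularity histograms
#' (Orientation 1-8, Length 1-7, Angularity 1-8), dropping the sparsely
#' populated Length 8 bin, and optionally applies an element-wise square
#' root to reduce the influence of outliers.
#'
#' @inheritParams orientation_histogram
#' @param apply_sqrt take the element-wise square root (default `TRUE`).
#' @return an object of class `feature_vector`: list with `values` (named
#'   numeric of length 23: O1-O8, L1-L7, A1-A8) and `sqrt_applied`.
#' @export
feature_vector <- function(drawing, spec = bin_spec(), apply_sqrt = TRUE,
                           mode = "triangular") {
  o <- orientation_histogram(drawing, spec, mode)$weights
  l <- length_histogram(drawing, spec, mode)$weights
  a <- angularity_histogram(drawing, spec, mode)$weights
  v <- c(o, l[1:7], a)
  names(v) <- c(paste0("O", 1:8), paste0("L", 1:7), paste0("A", 1:8))
  if (apply_sqrt) v <- sqrt(v)
  structure(list(values = v, sqrt_applied = apply_sqrt),
            class = "feature_vector")
}

#' Feature table for a set of drawings
#'
#' @param drawings list of [line_drawing()] objects.
#' @param ids image identifiers (defaults to each drawing's `id`, then to
#'   `img_<i>`).
#' @inheritParams feature_vector
#' @return data frame: `image_id` plus the 23 named feature columns.
#' @export
feature_table <- function(drawings, ids = NULL, spec = bin_spec(),
                          apply_sqrt = TRUE, mode = "triangular") {
  if (is.null(ids))
    ids <- vapply(seq_along(drawings), function(i) {
      id <- drawings[[i]]$id
      if (is.null(id)) sprintf("img_%04d", i) else as.character(id)
    }, character(1))
  rows <- t(vapply(drawings, function(d)
    feature_vector(d, spec, apply_sqrt, mode)$values, numeric(23)))
  out <- data.frame(image_id = ids, rows, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "sqrt_applied") <- apply_sqrt
  out
}

#' Write / read a feature table as CSV
#'
#' The square-root flag is stored in a `#`-prefixed metadata header line.
#'
#' @param features data frame from [feature_table()].
#' @param path file path.
#' @return `read_feature_table` returns the data frame with the
#'   `sqrt_applied` attribute restored.
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sqrt_applied: %s",
                     isTRUE(attr(features, "sqrt_applied"))), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  out <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  attr(out, "sqrt_applied") <- grepl("TRUE", first, fixed = TRUE)
  out
}
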