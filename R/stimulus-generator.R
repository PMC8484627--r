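#' Factor levels of the stimulus design
#'
#' The 24-cell factorial over contour length (2), angularity (3) and
#' orientation (4) used to label contours and build stimuli.
#'
#' @name bin-labels
NULL

length_levels <- c("short", "long")
angularity_levels <- c("low", "medium", "high")
orientation_levels <- c("horizontal", "vertical", "both", "diagonal")

#' Construct a bin label
#'
#' @param length_class `"short"` or `"long"`.
#' @param angularity_class `"low"`, `"medium"` or `"high"`.
#' @param orientation_class `"horizontal"`, `"vertical"`, `"both"` or
#'   `"diagonal"`.
#' @return object of class `bin_label`.
#' @export
bin_label <- function(length_class, angularity_class, orientation_class) {
  length_class <- match.arg(length_class, length_levels)
  angularity_class <- match.arg(angularity_class, angularity_levels)
  orientation_class <- match.arg(orientation_class, orientation_levels)
  structure(list(length_class = length_class,
                 angularity_class = angularity_class,
                 orientation_class = orientation_class),
            class = "bin_label")
}

#' @exportS3Method format bin_label
format.bin_label <- function(x, ...) {
  paste(x$length_class, x$angularity_class, x$orientation_class, sep = "_")
}

#' @exportS3Method print bin_label
print.bin_label <- function(x, ...) {
  cat("<bin_label:", format(x), ">\n"); invisible(x)
}

#' All 24 bin labels
#'
#' @return list of 24 `bin_label` objects in a fixed canonical order.
#' @export
all_bin_labels <- function() {
  g <- expand.grid(orientation_class = orientation_levels,
                   angularity_class = angularity_levels,
                   length_class = length_levels,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    bin_label(g$length_class[i], g$angularity_class[i],
              g$orientation_class[i]))
}

#' Classification thresholds for contour binning
#'
#' Cut values separating short/long contours, low/medium/high angularity,
#' and the four orientation classes.  Defaults reuse the feature-histogram
#' bin geometry: the length split and the angularity splits sit on histogram
#' bin centers near the middle of the log range, the orientation band is
#' half the histogram bin width on the folded 0-90 degree scale.
#'
#' @param length_split pixels; contours at least this long are `"long"`.
#' @param angularity_splits two increasing values (deg/px) separating
#'   low/medium and medium/high mean angularity.
#' @param orientation_band degrees; folded mean orientation below this is
#'   `"horizontal"`, above `90 - orientation_band` is `"vertical"`.
#' @param extreme_fraction proportion; in the middle orientation range, a
#'   contour is `"both"` when more than this pixel-weighted fraction of its
#'   segments lies within `orientation_band` of 0 or 90 degrees (folded),
#'   else `"diagonal"`.
#' @return object of class `bin_thresholds`.
#' @export
bin_thresholds <- function(length_split = 87.10,
                           angularity_splits = c(5.13, 35.48),
                           orientation_band = 22.5,
                           extreme_fraction = 0.5) {
  stopifnot(length(angularity_splits) == 2L,
            diff(angularity_splits) > 0,
            orientation_band > 0, orientation_band < 45,
            extreme_fraction >= 0, extreme_fraction <= 1)
  structure(list(length_split = length_split,
                 angularity_splits = angularity_splits,
                 orientation_band = orientation_band,
                 extreme_fraction = extreme_fraction),
            class = "bin_thresholds")
}

#' Classify a contour into one of the 24 feature bins
#'
#' Length class compares total contour length against the length split;
#' angularity class compares the mean vertex angularity (0 for two-point
#' contours) against the two angularity splits; orientation class uses the
#' folded mean orientation: below the band is horizontal, above 90 minus
#' the band vertical, and in between the contour is "both" when the
#' pixel-weighted fraction of segments within the band of 0 or 90 degrees
#' exceeds `extreme_fraction`, otherwise "diagonal".
#'
#' @param ct a [contour()].
#' @param thresholds a [bin_thresholds()].
#' @return a `bin_label`.
#' @export
classify_contour <- function(ct, thresholds = bin_thresholds()) {
  ct <- as_contour(ct)
  len <- contour_length(ct)
  length_class <- if (len < thresholds$length_split) "short" else "long"
  ang <- vertex_angularities(ct)
  mean_ang <- if (length(ang)) mean(ang) else 0
  angularity_class <-
    if (mean_ang < thresholds$angularity_splits[1]) "low"
    else if (mean_ang < thresholds$angularity_splits[2]) "medium"
    else "high"
  fm <- folded_mean_orientation(ct)
  band <- thresholds$orientation_band
  orientation_class <- if (fm < band) "horizontal"
  else if (fm > 90 - band) "vertical"
  else {
    thf <- folded_orientations(ct)
    w <- segment_lengths(ct)
    extreme <- thf <= band | thf >= 90 - band
    if (sum(w[extreme]) / sum(w) > thresholds$extreme_fraction) "both"
    else "diagonal"
  }
  bin_label(length_class, angularity_class, orientation_class)
}

#' Pool contours from drawings into the 24 bins
#'
#' Classifies every contour of every drawing; each contour lands in exactly
#' one bin.
#'
#' @param drawings list of [line_drawing()] objects (non-empty).
#' @param thresholds a [bin_thresholds()].
#' @return object of class `contour_pool`: named list of contour lists, one
#'   entry per bin label string, with attribute `empty_bins` naming bins
#'   that received no contour.
#' @export
build_contour_pool <- function(drawings, thresholds = bin_thresholds()) {
  if (!length(drawings)) stop("no drawings supplied", call. = FALSE)
  if (inherits(drawings, "line_drawing")) drawings <- list(drawings)
  labels <- vapply(all_bin_labels(), format, character(1))
  pool <- stats::setNames(vector("list", length(labels)), labels)
  for (d in drawings) {
    for (ct in d$contours) {
      key <- format(classify_contour(ct, thresholds))
      pool[[key]] <- c(pool[[key]], list(ct))
    }
  }
  empty <- labels[vapply(pool, length, integer(1)) == 0L]
  structure(pool, empty_bins = empty, class = c("contour_pool", "list"))
}

#' @exportS3Method print contour_pool
print.contour_pool <- function(x, ...) {
  n <- vapply(x, length, integer(1))
  cat(sprintf("<contour_pool: %d contours over %d/%d non-empty bins>\n",
              sum(n), sum(n > 0), length(n)))
  invisible(x)
}

#' Place a contour on the stimulus canvas
#'
#' Coordinates are divided by `scale` (original 800 x 600 tracings map onto
#' the 200 x 150 stimulus grid at `scale = 4`, so a contour starting at
#' pixel `[400, 300]` starts at `[100, 75]`).  If any point then falls
#' outside the canvas, the whole contour is shifted by the minimal offset
#' that brings its bounding box inside.  If the bounding box exceeds the
#' canvas in either dimension even after shifting, points are truncated
#' from the tail end until it fits, then shifted.
#'
#' @param ct a [contour()].
#' @param canvas_width,canvas_height stimulus canvas size in pixels.
#' @param scale divisor applied to all coordinates.
#' @return the placed `contour` with attribute `adjustment` in
#'   `c("as-is", "shifted", "shortened")`, or `NULL` (skip signal) when
#'   truncation would leave fewer than 2 points.
#' @export
place_contour <- function(ct, canvas_width = 200, canvas_height = 150,
                          scale = 4) {
  ct <- as_contour(ct)
  p <- ct$points / scale
  adjustment <- "as-is"
  bw <- diff(range(p[, 1])); bh <- diff(range(p[, 2]))
  if (bw > canvas_width || bh > canvas_height) {
    adjustment <- "shortened"
    while (nrow(p) > 2L &&
           (diff(range(p[, 1])) > canvas_width ||
            diff(range(p[, 2])) > canvas_height))
      p <- p[-nrow(p), , drop = FALSE]
    if (diff(range(p[, 1])) > canvas_width ||
        diff(range(p[, 2])) > canvas_height)
      return(NULL)                      # cannot fit even two points
  }
  shift_x <- max(0, -min(p[, 1])) - max(0, max(p[, 1]) - canvas_width)
  shift_y <- max(0, -min(p[, 2])) - max(0, max(p[, 2]) - canvas_height)
  if (shift_x != 0 || shift_y != 0) {
    if (adjustment == "as-is") adjustment <- "shifted"
    p[, 1] <- p[, 1] + shift_x
    p[, 2] <- p[, 2] + shift_y
  }
  out <- contour(p, id = ct$id)
  attr(out, "adjustment") <- adjustment
  out
}

#' Generate stimulus images for one bin
#'
#' Contours are randomly sampled from the bin's pool, without replacement
#' within an image (with replacement across images), placed on the canvas,
#' and appended until the summed placed contour length exceeds the length
#' budget.
#'
#' @param pool a `contour_pool` from [build_contour_pool()].
#' @param bin a [bin_label()] (or its string form).
#' @param n_images number of images to build.
#' @param length_budget pixels; each image accumulates placed contours until
#'   its total placed length exceeds this.
#' @param canvas_width,canvas_height,scale see [place_contour()].
#' @return list of `stimulus_image` objects: each has `image_id`, `bin`,
#'   `drawing` (a `line_drawing` on the stimulus canvas), `total_length`,
#'   and `provenance` (source contour ids and adjustment flags).
#' @export
generate_images_for_bin <- function(pool, bin, n_images = 20,
                                    length_budget = 1000,
                                    canvas_width = 200, canvas_height = 150,
                                    scale = 4) {
  key <- if (inherits(bin, "bin_label")) format(bin) else bin
  contours <- pool[[key]]
  if (is.null(contours) || !length(contours))
    stop(sprintf("bin '%s' has no contours in the pool", key), call. = FALSE)
  binlab <- if (inherits(bin, "bin_label")) bin else {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    bin_label(parts[1], parts[2], parts[3])
  }
  images <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    order_idx <- sample.int(length(contours))
    placed <- list(); src <- character(0); adj <- character(0)
    total <- 0; k <- 0
    while (total <= length_budget) {
      k <- k + 1
      if (k > length(order_idx))
        stop(sprintf("bin '%s': pool exhausted before reaching the %g px budget",
                     key, length_budget), call. = FALSE)
      ct <- contours[[order_idx[k]]]
      pc <- place_contour(ct, canvas_width, canvas_height, scale)
      if (is.null(pc)) next             # unplaceable; draw another contour
      placed <- c(placed, list(pc))
      src <- c(src, if (is.null(ct$id)) NA_character_ else as.character(ct$id))
      adj <- c(adj, attr(pc, "adjustment"))
      total <- total + contour_length(pc)
    }
    drawing <- line_drawing(placed, canvas_width, canvas_height)
    images[[i]] <- structure(list(
      image_id = sprintf("%s_%02d", key, i),
      bin = binlab, drawing = drawing, total_length = total,
      provenance = data.frame(source_id = src, adjustment = adj,
                              stringsAsFactors = FALSE)),
      class = "stimulus_image")
  }
  images
}

#' @exportS3Method print stimulus_image
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image %s: %d contours, %.1f px>\n", x$image_id,
              length(x$drawing$contours), x$total_length))
  invisible(x)
}

#' Generate the full stimulus set
#'
#' Builds `n_per_bin` images for each of the 24 bins (480 by default).
#'
#' @inheritParams generate_images_for_bin
#' @param n_per_bin images per bin.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `stimulus_set`: list with `images` (list of
#'   `stimulus_image`) and `manifest` (data frame: `image_id`,
#'   `length_class`, `angularity_class`, `orientation_class`, `n_contours`,
#'   `total_length`, `seed`).
#' @export
generate_stimulus_set <- function(pool, n_per_bin = 20, length_budget = 1000,
                                  canvas_width = 200, canvas_height = 150,
                                  scale = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(all_bin_labels(), format, character(1))
  missing <- labels[vapply(labels, function(k)
    is.null(pool[[k]]) || !length(pool[[k]]), logical(1))]
  if (length(missing))
    stop("empty bins in pool: ", paste(missing, collapse = ", "),
         call. = FALSE)
  images <- unlist(lapply(labels, function(k)
    generate_images_for_bin(pool, k, n_per_bin, length_budget,
                            canvas_width, canvas_height, scale)),
    recursive = FALSE)
  manifest <- do.call(rbind, lapply(images, function(im)
    data.frame(image_id = im$image_id,
               length_class = im$bin$length_class,
               angularity_class = im$bin$angularity_class,
               orientation_class = im$bin$orientation_class,
               n_contours = length(im$drawing$contours),
               total_length = im$total_length,
               seed = if (is.null(seed)) NA_integer_ else seed,
               stringsAsFactors = FALSE)))
  structure(list(images = images, manifest = manifest),
            class = "stimulus_set")
}

#' @exportS3Method print stimulus_set
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d images over %d bins, min length %.1f px>\n",
              nrow(x$manifest),
              length(unique(paste(x$manifest$length_class,
                                  x$manifest$angularity_class,
                                  x$manifest$orientation_class))),
              min(x$manifest$total_length)))
  invisible(x)
}

#' Write a stimulus manifest CSV
#'
#' @param set a `stimulus_set` (or its manifest data frame).
#' @param path output file.
#' @export
write_manifest <- function(set, path) {
  manifest <- if (inherits(set, "stimulus_set")) set$manifest else set
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
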