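#' Write a line drawing as JSON
#'
#' Serializes the drawing dialect: `schema_version`, `canvas`
#' (width/height), and `contours` as a list of `{id, points: [[x, y], ...]}`
#' with coordinates written at 6 decimal digits.  Reading a written file
#' reproduces coordinates exactly at that precision.
#'
#' @param drawing a [line_drawing()].
#' @param path output file.
#' @export
write_drawing <- function(drawing, path) {
  stopifnot(inherits(drawing, "line_drawing"))
  doc <- list(
    schema_version = 1L,
    canvas = list(width = drawing$canvas_width,
                  height = drawing$canvas_height),
    contours = lapply(seq_along(drawing$contours), function(i) {
      ct <- drawing$contours[[i]]
      list(id = if (is.null(ct$id)) sprintf("c%03d", i) else
        as.character(ct$id),
        points = round(unname(ct$points), 6))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a line drawing from JSON
#'
#' @param path input file written by [write_drawing()] (or conforming to
#'   the same dialect).
#' @return a [line_drawing()].
#' @export
read_drawing <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("malformed drawing file '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  for (field in c("canvas", "contours"))
    if (is.null(doc[[field]]))
      stop(sprintf("drawing file '%s': missing $%s", path, field),
           call. = FALSE)
  for (field in c("width", "height"))
    if (is.null(doc$canvas[[field]]))
      stop(sprintf("drawing file '%s': missing $canvas.%s", path, field),
           call. = FALSE)
  cts <- doc$contours
  get_contour <- function(i) {
    ct <- if (is.data.frame(cts)) list(id = cts$id[i],
                                       points = cts$points[[i]])
    else cts[[i]]
    p <- ct$points
    if (is.list(p)) p <- do.call(rbind, lapply(p, unlist))
    p <- as.matrix(p)
    if (is.null(ct$points) || nrow(p) < 2L)
      stop(sprintf("drawing file '%s': $contours[%d] has fewer than 2 points",
                   path, i), call. = FALSE)
    bad <- which(p[, 1] < 0 | p[, 2] < 0 |
                   p[, 1] > doc$canvas$width | p[, 2] > doc$canvas$height)
    if (length(bad))
      stop(sprintf("drawing file '%s': $contours[%d].points[%s] outside canvas",
                   path, i, paste(bad, collapse = ",")), call. = FALSE)
    contour(p, id = ct$id)
  }
  n <- if (is.data.frame(cts)) nrow(cts) else length(cts)
  if (!n) stop(sprintf("drawing file '%s': no contours", path),
               call. = FALSE)
  line_drawing(lapply(seq_len(n), get_contour),
               doc$canvas$width, doc$canvas$height)
}

#' Write a stimulus image (or any drawing) as an SVG file
#'
#' One `polyline` element per contour: black stroke, width 1, no fill;
#' the viewBox matches the drawing canvas.
#'
#' @param x a `stimulus_image` or [line_drawing()].
#' @param path output file.
#' @export
write_svg <- function(x, path) {
  drawing <- if (inherits(x, "stimulus_image")) x$drawing else x
  stopifnot(inherits(drawing, "line_drawing"))
  w <- drawing$canvas_width; h <- drawing$canvas_height
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
    w, h, w, h))
  for (ct in drawing$contours) {
    pts <- paste(sprintf("%.6g,%.6g", ct$points[, 1], ct$points[, 2]),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '  <polyline points="%s" fill="none" stroke="black" stroke-width="1"/>',
      pts))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Import an SVG file as a line drawing
#'
#' Reads `polyline` elements and `path` elements whose data contain only
#' move-to / line-to commands; each becomes one contour.  Curved path
#' commands (C, S, Q, T, A) are rejected.
#'
#' @param path SVG file.
#' @param canvas_width,canvas_height canvas size; defaults are taken from
#'   the root `width`/`height` attributes when present.
#' @return a [line_drawing()].
#' @export
import_svg <- function(path, canvas_width = NULL, canvas_height = NULL) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_ns_strip(doc)
  if (is.null(canvas_width))
    canvas_width <- as.numeric(xml2::xml_attr(root, "width"))
  if (is.null(canvas_height))
    canvas_height <- as.numeric(xml2::xml_attr(root, "height"))
  cts <- list()
  for (node in xml2::xml_find_all(root, ".//polyline")) {
    pts <- xml2::xml_attr(node, "points")
    nums <- as.numeric(strsplit(trimws(pts), "[ ,]+")[[1]])
    cts <- c(cts, list(contour(matrix(nums, ncol = 2, byrow = TRUE))))
  }
  for (node in xml2::xml_find_all(root, ".//path")) {
    d <- xml2::xml_attr(node, "d")
    if (grepl("[CcSsQqTtAa]", d))
      stop("unsupported geometry: SVG path contains curve commands",
           call. = FALSE)
    cts <- c(cts, list(contour(parse_path_lines(d))))
  }
  if (!length(cts))
    stop(sprintf("no polyline/path geometry found in '%s'", path),
         call. = FALSE)
  line_drawing(cts, canvas_width, canvas_height)
}

# parse an SVG path containing only M/m, L/l, H/h, V/v, Z ignored
parse_path_lines <- function(d) {
  tokens <- regmatches(d, gregexpr("[MmLlHhVvZz]|-?[0-9.]+(e-?[0-9]+)?",
                                   d))[[1]]
  x <- 0; y <- 0; pts <- NULL; cmd <- "M"
  i <- 1
  while (i <= length(tokens)) {
    t <- tokens[i]
    if (grepl("^[A-Za-z]$", t)) {
      cmd <- t; i <- i + 1
      if (cmd %in% c("Z", "z")) next
      next
    }
    rel <- cmd %in% c("m", "l", "h", "v")
    if (toupper(cmd) %in% c("M", "L")) {
      nx <- as.numeric(tokens[i]); ny <- as.numeric(tokens[i + 1])
      i <- i + 2
      if (rel) { nx <- x + nx; ny <- y + ny }
    } else if (toupper(cmd) == "H") {
      nx <- as.numeric(tokens[i]); i <- i + 1
      if (rel) nx <- x + nx
      ny <- y
    } else {
      ny <- as.numeric(tokens[i]); i <- i + 1
      if (rel) ny <- y + ny
      nx <- x
    }
    x <- nx; y <- ny
    pts <- rbind(pts, c(x, y))
    if (toupper(cmd) == "M") cmd <- if (rel) "l" else "L"
  }
  pts
}

#' Write every image of a stimulus set as SVG files
#'
#' Files are named `<image_id>.svg` under `dir`; the manifest is written
#' alongside as `manifest.csv`.
#'
#' @param set a `stimulus_set` from [generate_stimulus_set()].
#' @param dir output directory (created if needed).
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (im in set$images)
    write_svg(im, file.path(dir, paste0(im$image_id, ".svg")))
  write_manifest(set, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Synthetic design manifest without images
#'
#' A manifest listing `n_per_bin` image ids per design cell, for
#' simulations that need only cell labels (e.g. bernoulli-direct recovery
#' or type-I-error studies) and not actual stimulus geometry.
#'
#' @param n_per_bin rows per cell (20 gives the standard 480-image set).
#' @return manifest data frame (`image_id` + the three factor columns).
#' @export
design_manifest <- function(n_per_bin = 20) {
  labs <- all_bin_labels()
  do.call(rbind, lapply(labs, function(b)
    data.frame(image_id = sprintf("%s_%02d", format(b), seq_len(n_per_bin)),
               length_class = b$length_class,
               angularity_class = b$angularity_class,
               orientation_class = b$orientation_class,
               stringsAsFactors = FALSE)))
}
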