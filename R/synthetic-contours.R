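#' Recipe for a synthetic contour
#'
#' Describes a directed random walk whose realized features land in a
#' requested feature bin.  The walk alternates between two base headings
#' chosen per orientation class; the absolute turn between them, divided by
#' the segment length, sets the per-vertex angularity, and the walk stops
#' once the target length is reached.  Class defaults keep realized
#' features well inside their bin under the default [bin_thresholds()]:
#' mean angularity targets of about 2, 13 and 60-80 deg/px for the low,
#' medium and high classes, and folded mean orientations at least a few
#' degrees clear of the class boundaries.
#'
#' @param bin a [bin_label()] (or string `"length_angularity_orientation"`).
#' @param target_length pixels; defaults drawn per length class
#'   (short: 40-75, long: 200-550).
#' @param turn_jitter_deg half-width of the uniform jitter on each turn.
#' @param length_jitter relative half-width of the uniform jitter on each
#'   segment length.
#' @return object of class `contour_recipe` with the resolved base headings
#'   (`heading1`, `heading2`), `segment_length`, `turn` and `target_length`.
#' @export
contour_recipe <- function(bin, target_length = NULL, turn_jitter_deg = 3,
                           length_jitter = 0.1) {
  if (is.character(bin)) {
    parts <- strsplit(bin, "_", fixed = TRUE)[[1]]
    bin <- bin_label(parts[1], parts[2], parts[3])
  }
  stopifnot(inherits(bin, "bin_label"))
  oc <- bin$orientation_class; ac <- bin$angularity_class
  if (oc == "both") {
    # alternate pure horizontal / vertical segments; turn fixed at 90 deg,
    # segment length tunes angularity
    heading <- c(0, 90)
    seg_len <- switch(ac, low = NA, medium = 7, high = 1.5)   # low: see below
    turn <- 90
  } else {
    turn <- switch(ac, low = 20, medium = 150, high = 160)
    heading <- switch(oc,
                      horizontal = c(0, turn),
                      vertical   = c(90, 90 + turn),
                      diagonal   = switch(ac,
                                          low = c(35, 55),
                                          medium = c(30, -120),
                                          high = c(55, 215)))
    seg_len <- switch(ac, low = 10, medium = 150 / 13.5, high = 2)
  }
  if (is.null(target_length)) {
    target_length <- if (bin$length_class == "short") stats::runif(1, 48, 80)
    else stats::runif(1, 200, 550)
  }
  if (oc == "both" && ac == "low") {
    # angularity 90/L must stay below the low/medium split while a short
    # contour still needs >= 2 segments below the length split
    seg_len <- if (bin$length_class == "short") target_length / 2 else 45
  }
  if (target_length <= 0) stop("unreachable recipe: non-positive target length",
                               call. = FALSE)
  structure(list(bin = bin, target_length = target_length,
                 heading1 = heading[1], heading2 = heading[2],
                 segment_length = seg_len, turn = turn,
                 turn_jitter_deg = turn_jitter_deg,
                 length_jitter = length_jitter),
            class = "contour_recipe")
}

# walk headings in visual degrees -> canvas steps (y grows downward)
walk_points <- function(headings, lengths) {
  dx <- cos(headings * pi / 180) * lengths
  dy <- -sin(headings * pi / 180) * lengths
  cbind(c(0, cumsum(dx)), c(0, cumsum(dy)))
}

#' Synthesize one contour from a recipe
#'
#' @param recipe a [contour_recipe()].
#' @param canvas_width,canvas_height canvas on which to position the walk
#'   (uniformly at random such that it fits entirely).
#' @param id contour identifier.
#' @return a [contour()] whose [classify_contour()] label equals the
#'   recipe's bin under default thresholds.
#' @export
synth_contour <- function(recipe, canvas_width = 800, canvas_height = 600,
                          id = NULL) {
  stopifnot(inherits(recipe, "contour_recipe"))
  n_seg <- max(2L, round(recipe$target_length / recipe$segment_length))
  base <- rep(c(recipe$heading1, recipe$heading2), length.out = n_seg)
  jit <- stats::runif(n_seg, -recipe$turn_jitter_deg, recipe$turn_jitter_deg)
  lens <- recipe$segment_length *
    stats::runif(n_seg, 1 - recipe$length_jitter, 1 + recipe$length_jitter)
  lens <- lens * recipe$target_length / sum(lens)  # realized length == target
  p <- walk_points(base + jit, lens)
  bw <- diff(range(p[, 1])); bh <- diff(range(p[, 2]))
  if (bw > canvas_width || bh > canvas_height)
    stop("synthesized walk exceeds the canvas; reduce target_length",
         call. = FALSE)
  p[, 1] <- p[, 1] - min(p[, 1]) + stats::runif(1, 0, canvas_width - bw)
  p[, 2] <- p[, 2] - min(p[, 2]) + stats::runif(1, 0, canvas_height - bh)
  contour(p, id = id)
}

#' Synthesize a contour pool covering all 24 bins
#'
#' Generates `n_per_bin` contours per feature bin on an 800 x 600 canvas
#' (the traced-drawing geometry, so that the divide-by-four placement path
#' is exercised), grouped into drawings, and audits each contour's realized
#' classification against its intended bin.
#'
#' @param n_per_bin contours per bin.
#' @param seed optional RNG seed.
#' @param contours_per_drawing how many contours to group per
#'   [line_drawing()].
#' @param canvas_width,canvas_height pool canvas size.
#' @return list with `drawings` (list of `line_drawing`), `intended`
#'   (character vector, one intended bin label per contour in drawing
#'   order) and `mismatch_rate` (fraction of contours whose realized label
#'   differs from the intended one).
#' @export
synth_pool <- function(n_per_bin = 50, seed = NULL,
                       contours_per_drawing = 12,
                       canvas_width = 800, canvas_height = 600) {
  stopifnot(n_per_bin >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(all_bin_labels(), format, character(1))
  contours <- list(); intended <- character(0)
  k <- 0
  for (lab in labels) {
    for (i in seq_len(n_per_bin)) {
      k <- k + 1
      ct <- synth_contour(contour_recipe(lab), canvas_width, canvas_height,
                          id = sprintf("c%05d_%s", k, lab))
      contours <- c(contours, list(ct))
      intended <- c(intended, lab)
    }
  }
  realized <- vapply(contours, function(ct) format(classify_contour(ct)),
                     character(1))
  idx <- split(seq_along(contours),
               ceiling(seq_along(contours) / contours_per_drawing))
  drawings <- lapply(seq_along(idx), function(i)
    line_drawing(contours[idx[[i]]], canvas_width, canvas_height,
                 id = sprintf("pool_%03d", i)))
  list(drawings = drawings, intended = intended,
       mismatch_rate = mean(realized != intended))
}

#' Synthesize an unconstrained random contour
#'
#' A free random walk with lognormal segment lengths and Gaussian signed
#' turns whose scale varies between contours, giving a broad, continuous
#' spread of length, orientation and angularity values for regression
#' studies (unlike [synth_contour()], which targets one bin).
#'
#' @param canvas_width,canvas_height canvas size.
#' @param id contour identifier.
#' @return a [contour()].
#' @export
synth_random_contour <- function(canvas_width = 800, canvas_height = 600,
                                 id = NULL) {
  n_seg <- sample.int(25L, 1L)
  seg_scale <- stats::rlnorm(1, log(6), 0.9)
  turn_scale <- stats::rlnorm(1, log(15), 1)
  lens <- stats::rlnorm(n_seg, log(seg_scale), 0.4)
  h0 <- stats::runif(1, 0, 360)
  turns <- pmax(pmin(stats::rnorm(max(0, n_seg - 1), 0, turn_scale),
                     170), -170)
  headings <- h0 + c(0, cumsum(turns))
  p <- walk_points(headings, lens)
  bw <- diff(range(p[, 1])); bh <- diff(range(p[, 2]))
  if (bw > canvas_width || bh > canvas_height) {
    s <- 0.95 * min(canvas_width / bw, canvas_height / bh)
    p <- p * s
    bw <- bw * s; bh <- bh * s
  }
  p[, 1] <- p[, 1] - min(p[, 1]) + stats::runif(1, 0, canvas_width - bw)
  p[, 2] <- p[, 2] - min(p[, 2]) + stats::runif(1, 0, canvas_height - bh)
  contour(p, id = id)
}

#' Synthesize a random line drawing
#'
#' @param n_contours number of contours (default: 5 plus a Poisson(5) draw).
#' @inheritParams synth_random_contour
#' @return a [line_drawing()].
#' @export
synth_random_drawing <- function(n_contours = NULL, canvas_width = 800,
                                 canvas_height = 600, id = NULL) {
  if (is.null(n_contours)) n_contours <- 5L + stats::rpois(1, 5)
  cts <- lapply(seq_len(n_contours), function(i)
    synth_random_contour(canvas_width, canvas_height,
                         id = sprintf("%s_c%02d",
                                      if (is.null(id)) "rnd" else id, i)))
  line_drawing(cts, canvas_width, canvas_height, id = id)
}
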