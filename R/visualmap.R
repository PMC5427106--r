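#' Visual map style
#'
#' Rendering parameters for timeline bars. Defaults give a 600 px bar for
#' a 5-minute trial.
#'
#' @param px_per_second Horizontal scale (> 0, default 2).
#' @param bar_height_px Bar height in pixels (default 40).
#' @param gap_color Color for unscored gaps (default light gray).
#' @param tick_width_px Width of point-event ticks (default 1).
#' @param label_gutter_px Width of the left label gutter (default 0: no
#'   labels). Labels use a built-in 3x5 bitmap font so rendering is
#'   byte-deterministic.
#' @param row_gap_px Vertical spacing between rows in collated maps.
#' @param bg_color Background color for gutters and row spacing.
#' @return A `map_style` object.
#' @export
map_style <- function(px_per_second = 2, bar_height_px = 40L,
                      gap_color = "#D3D3D3", tick_width_px = 1L,
                      label_gutter_px = 0L, row_gap_px = 4L,
                      bg_color = "#FFFFFF") {
  if (!is_pos_scalar(px_per_second) || !is_count(bar_height_px) ||
      !is_count(tick_width_px))
    abort_etho("style", "px_per_second, bar_height_px, tick_width_px must be positive")
  if (!is_hex_color(gap_color) || !is_hex_color(bg_color))
    abort_etho("style", "gap_color/bg_color must be hex RGB")
  if (!is.numeric(label_gutter_px) || label_gutter_px < 0 ||
      !is.numeric(row_gap_px) || row_gap_px < 0)
    abort_etho("style", "gutter and row gap must be >= 0")
  structure(list(px_per_second = px_per_second,
                 bar_height_px = as.integer(bar_height_px),
                 gap_color = toupper(gap_color),
                 tick_width_px = as.integer(tick_width_px),
                 label_gutter_px = as.integer(label_gutter_px),
                 row_gap_px = as.integer(row_gap_px),
                 bg_color = toupper(bg_color)),
            class = "ethoscore_style")
}

# 3x5 bitmap glyphs (rows top-to-bottom, 3 bits per row) for gutter labels
.glyphs <- local({
  g <- list(
    "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
    "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
    "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
    "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
    "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
    A = c("010","101","111","101","101"), B = c("110","101","110","101","110"),
    C = c("011","100","100","100","011"), D = c("110","101","101","101","110"),
    E = c("111","100","110","100","111"), F = c("111","100","110","100","100"),
    G = c("011","100","101","101","011"), H = c("101","101","111","101","101"),
    I = c("111","010","010","010","111"), J = c("001","001","001","101","010"),
    K = c("101","110","100","110","101"), L = c("100","100","100","100","111"),
    M = c("101","111","111","101","101"), N = c("101","111","111","111","101"),
    O = c("010","101","101","101","010"), P = c("110","101","110","100","100"),
    Q = c("010","101","101","110","011"), R = c("110","101","110","110","101"),
    S = c("011","100","010","001","110"), T = c("111","010","010","010","010"),
    U = c("101","101","101","101","111"), V = c("101","101","101","101","010"),
    W = c("101","101","111","111","101"), X = c("101","101","010","101","101"),
    Y = c("101","101","010","010","010"), Z = c("111","001","010","100","111"),
    "-" = c("000","000","111","000","000"), "_" = c("000","000","000","000","111"),
    "." = c("000","000","000","000","010"), " " = c("000","000","000","000","000"))
  lapply(g, function(rows)
    matrix(as.integer(unlist(strsplit(rows, ""))) == 1L, nrow = 5,
           byrow = TRUE))
})

draw_label <- function(canvas, text, row0, col0, color, scale = 2L) {
  text <- toupper(text)
  chars <- strsplit(text, "")[[1]]
  x <- col0
  for (ch in chars) {
    gl <- .glyphs[[ch]] %||% .glyphs[["."]]
    for (r in 1:5) for (cc in 1:3) if (gl[r, cc]) {
      rows <- row0 + (r - 1L) * scale + seq_len(scale) - 1L
      cols <- x + (cc - 1L) * scale + seq_len(scale) - 1L
      rows <- rows[rows >= 1 & rows <= nrow(canvas)]
      cols <- cols[cols >= 1 & cols <= ncol(canvas)]
      if (length(rows) && length(cols)) canvas[rows, cols] <- color
    }
    x <- x + 4L * scale
    if (x > ncol(canvas)) break
  }
  canvas
}

# bar raster for one trial: bar_height_px x round(duration * pps)
bar_raster <- function(trial, etho, style) {
  pps <- style$px_per_second
  w <- as.integer(round_half_up(trial$duration_s * pps))
  if (w < 1L)
    abort_etho("style", "degenerate style: bar width would be %d px", w)
  h <- style$bar_height_px
  canvas <- matrix(style$gap_color, nrow = h, ncol = w)
  cols <- behavior_colors(etho)
  px <- function(t) as.integer(round_half_up(t * pps))
  b <- trial$bouts
  for (i in seq_len(nrow(b))) {
    c0 <- px(b$start[i]) + 1L; c1 <- px(b$end[i])
    if (c1 >= c0) canvas[, c0:c1] <- toupper(cols[[b$behavior[i]]])
  }
  # point ticks overdraw states; ethogram order decides pixel collisions
  p <- trial$points
  if (nrow(p)) {
    ord <- order(match(p$behavior, names(cols)))
    for (i in ord) {
      c0 <- min(max(px(p$t[i]) + 1L, 1L), w)
      c1 <- min(c0 + style$tick_width_px - 1L, w)
      canvas[, c0:c1] <- toupper(cols[[p$behavior[i]]])
    }
  }
  canvas
}

#' Render a visual map for one trial
#'
#' Draws the trial as a horizontal color-coded bar: total bar length is
#' proportional to the trial duration (`round(duration * px_per_second)`
#' pixels), each bout is a run of its behavior's color with length
#' proportional to its duration (within +/- 1 px rounding), unscored gaps
#' use the gap color, and point occurrences are full-height vertical ticks
#' overlaid on the states. Bout boundaries are placed by round-half-up on
#' cumulative pixel positions, so adjacent bouts neither overlap nor leave
#' seams. The bar region is byte-deterministic: identical inputs give
#' byte-identical PNG files.
#'
#' @param trial A scored trial.
#' @param etho The governing ethogram (colors).
#' @param style A [map_style()].
#' @param file Optional path; if given, the map is written as a PNG.
#' @return A `visual_map` object with fields `raster` (character matrix of
#'   hex colors), `width`, `height`, `bar_region` (columns spanned by the
#'   bar) and `style`.
#' @examples
#' fst <- builtin_template("FST")
#' tr <- keystrokes_to_timeline(key_events(0, "i"), fst, 300)
#' m <- render_map(tr, fst)
#' dim(m$raster)
#' @export
render_map <- function(trial, etho, style = map_style(), file = NULL) {
  validate_trial(trial, etho)
  bar <- bar_raster(trial, etho, style)
  gut <- style$label_gutter_px
  canvas <- if (gut > 0L) {
    left <- matrix(style$bg_color, nrow = nrow(bar), ncol = gut)
    left <- draw_label(left, trial$subject_id, row0 = 2L, col0 = 2L,
                       color = "#000000")
    cbind(left, bar)
  } else bar
  map <- structure(list(raster = canvas, width = ncol(canvas),
                        height = nrow(canvas),
                        bar_region = (gut + 1L):ncol(canvas),
                        style = style),
                   class = "ethoscore_map")
  if (!is.null(file)) png_write_raster(canvas, file)
  map
}

#' Collate several maps into one image
#'
#' Stacks one bar per trial vertically, in input order, left-aligned, with
#' row labels in the gutter — the layout used to compare animals or to put
#' a trainer's and a trainee's scoring of the same animal side by side.
#' Trials may differ in duration; row widths stay proportional.
#'
#' @param trials List of scored trials sharing an ethogram.
#' @param etho The governing ethogram.
#' @param style A [map_style()]; set `label_gutter_px > 0` to show labels.
#' @param labels Row labels; defaults to `subject_id/rater_id`.
#' @param file Optional PNG output path.
#' @return A `visual_map` object for the collated image.
#' @export
collate_maps <- function(trials, etho, style = map_style(), labels = NULL,
                         file = NULL) {
  if (!length(trials))
    abort_etho("input", "collate_maps needs at least one trial")
  labels <- labels %||% vapply(trials, function(tr)
    paste0(tr$subject_id, if (nzchar(tr$rater_id)) paste0("/", tr$rater_id)),
    character(1))
  gut <- style$label_gutter_px
  bars <- lapply(trials, function(tr) {
    validate_trial(tr, etho)
    bar_raster(tr, etho, style)
  })
  wmax <- max(vapply(bars, ncol, integer(1)))
  h1 <- style$bar_height_px
  htot <- length(bars) * (h1 + style$row_gap_px)
  canvas <- matrix(style$bg_color, nrow = htot, ncol = gut + wmax)
  for (i in seq_along(bars)) {
    r0 <- (i - 1L) * (h1 + style$row_gap_px)
    canvas[r0 + seq_len(h1), gut + seq_len(ncol(bars[[i]]))] <- bars[[i]]
    if (gut > 0L)
      canvas <- draw_label(canvas, labels[i], row0 = r0 + 2L, col0 = 2L,
                           color = "#000000")
  }
  map <- structure(list(raster = canvas, width = ncol(canvas),
                        height = nrow(canvas),
                        bar_region = (gut + 1L):ncol(canvas),
                        style = style),
                   class = "ethoscore_map")
  if (!is.null(file)) png_write_raster(canvas, file)
  map
}

#' Read a visual-map PNG back as a raster
#'
#' Reads PNG files written by [render_map()] / [collate_maps()] back into
#' a matrix of hex colors (used for audits and round-trip testing).
#'
#' @param path PNG file path.
#' @return Character matrix of `"#RRGGBB"` values.
#' @export
read_visual_map <- function(path) png_read_raster(path)

#' @export
print.ethoscore_map <- function(x, ...) {
  cat(sprintf("<visual_map> %d x %d px\n", x$width, x$height))
  invisible(x)
}
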