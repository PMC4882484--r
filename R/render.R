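# Rendering of sampled contours to SVG (native writer) and PNG (direct
# rasterization onto a pixel matrix, written with the png package). Both
# writers are deterministic: identical inputs give identical bytes.

#' Render a contour to an image file
#'
#' Draws the contour as a black outline on a white background, centred on a
#' square canvas. The vector writer emits plain SVG 1.1; the raster writer
#' stamps the stroked outline directly onto a grayscale pixel matrix and
#' writes it with [png::writePNG()], so output bytes depend only on the
#' inputs. The mathematical y-up convention of the contour is flipped to the
#' image y-down convention at export.
#'
#' @param contour an `"rf_contour"` from [sample_contour()].
#' @param path output file; extension selects the format unless `format`
#'   is given.
#' @param canvas_px canvas side length in pixels.
#' @param stroke_px stroke width in pixels.
#' @param format `"svg"`, `"png"` or `"auto"` (from the file extension).
#' @param scale_px pixels per contour length unit; by default chosen so the
#'   shape fills the canvas. Fix it to compare rendered sizes across shapes.
#' @return `path`, invisibly.
#' @export
render_shape <- function(contour, path, canvas_px = 512L, stroke_px = 3L,
                         format = c("auto", "svg", "png"),
                         scale_px = NULL) {
  if (!inherits(contour, "rf_contour"))
    stop("`contour` must be an rf_contour", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("svg", "png"))
      stop("cannot infer format from extension '", ext, "'", call. = FALSE)
    format <- ext
  }
  rmax <- max(sqrt(rowSums(contour$vertices^2)))
  if (canvas_px / 2 - stroke_px - 2 <= 0)
    stop("canvas too small for the stroke width", call. = FALSE)
  scale <- scale_px %||% ((canvas_px / 2 - stroke_px - 2) / rmax)
  cx <- canvas_px / 2
  px <- cbind(cx + scale * contour$vertices[, 1L],
              cx - scale * contour$vertices[, 2L])  # y flip at export
  if (format == "svg") {
    .write_svg(px, path, canvas_px, stroke_px)
  } else {
    .write_png(px, path, canvas_px, stroke_px)
  }
  invisible(path)
}

.write_svg <- function(px, path, canvas_px, stroke_px) {
  pts <- paste(sprintf("%.3f,%.3f", px[, 1L], px[, 2L]), collapse = " ")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            canvas_px, canvas_px, canvas_px, canvas_px),
    sprintf('<rect width="%d" height="%d" fill="white"/>', canvas_px,
            canvas_px),
    sprintf('<polygon points="%s" fill="none" stroke="black" stroke-width="%d"/>',
            pts, stroke_px),
    '</svg>'
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

.write_png <- function(px, path, canvas_px, stroke_px) {
  # densify the polyline so consecutive samples are < 0.5 px apart, then
  # stamp a disc of radius stroke_px / 2 at every sample
  seg <- sqrt(rowSums((px[-1L, , drop = FALSE] -
                       px[-nrow(px), , drop = FALSE])^2))
  nsub <- pmax(1L, ceiling(seg / 0.5))
  xs <- ys <- vector("list", length(nsub))
  for (i in seq_along(nsub)) {
    t <- seq(0, 1, length.out = nsub[i] + 1L)[-(nsub[i] + 1L)]
    xs[[i]] <- px[i, 1L] + t * (px[i + 1L, 1L] - px[i, 1L])
    ys[[i]] <- px[i, 2L] + t * (px[i + 1L, 2L] - px[i, 2L])
  }
  x <- unlist(xs); y <- unlist(ys)
  rad <- max(stroke_px / 2, 0.5)
  w <- ceiling(rad)
  off <- expand.grid(dx = -w:w, dy = -w:w)
  off <- off[off$dx^2 + off$dy^2 <= rad^2 + 0.25, , drop = FALSE]
  img <- matrix(1, nrow = canvas_px, ncol = canvas_px)  # white background
  xi <- round(x); yi <- round(y)
  for (k in seq_len(nrow(off))) {
    cxi <- xi + off$dx[k]
    cyi <- yi + off$dy[k]
    ok <- cxi >= 1 & cxi <= canvas_px & cyi >= 1 & cyi <= canvas_px
    img[cbind(cyi[ok], cxi[ok])] <- 0  # row = y (down), col = x
  }
  png::writePNG(img, target = path)
}

#' Render every condition of a stimulus design
#'
#' Writes one image per factorial condition, named
#' `rf_F{frequency}_A{amplitude}_S{spikiness}.{ext}`, plus the `"rounded"`
#' and `"angular"` composite controls when the design includes them.
#'
#' @param design a [stimulus_design()].
#' @param dir output directory (created if missing).
#' @param format `"svg"` or `"png"`.
#' @param canvas_px canvas side length in pixels.
#' @param stroke_px stroke width in pixels.
#' @param n_points contour sampling resolution.
#' @return Character vector of the files written, invisibly.
#' @export
render_design <- function(design = stimulus_design(), dir, format = "svg",
                          canvas_px = 512L, stroke_px = 3L,
                          n_points = 4096L) {
  format <- match.arg(format, c("svg", "png"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- design_grid(design)
  files <- character(0)
  for (i in seq_len(nrow(grid))) {
    spec <- rf_spec(frequency = grid$frequency[i],
                    amplitude = grid$amplitude[i],
                    spikiness = grid$spikiness[i])
    stem <- sprintf("rf_F%d_A%s_S%d.%s", grid$frequency[i],
                    format(grid$amplitude[i]), grid$spikiness[i], format)
    f <- file.path(dir, stem)
    render_shape(sample_contour(spec, n_points), f, canvas_px, stroke_px,
                 format = format)
    files <- c(files, f)
  }
  if (design$include_controls) {
    for (nm in c("rounded", "angular")) {
      f <- file.path(dir, sprintf("control_%s.%s", nm, format))
      render_shape(sample_contour(composite_preset(nm), n_points), f,
                   canvas_px, stroke_px, format = format)
      files <- c(files, f)
    }
  }
  invisible(files)
}
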