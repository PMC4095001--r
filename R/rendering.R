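## Grayscale contact / consensus map rendering.
##
## Each contact is a square mark at (residue of A, residue of B); its
## gray level encodes the conservation rate, linearly from white
## (CR -> 0, absent) to black (CR = 1), optionally gamma-adjusted so
## sparse low-CR contacts stay visible. Partner A is on the x axis by
## default.

#' Map rendering style
#'
#' @param gamma exponent applied to CR before the linear gray ramp
#'   (gray level `1 - cr^gamma`); 1 = linear. Values < 1 darken
#'   weakly-conserved contacts.
#' @param marker_size plotting character expansion (`cex`).
#' @param flip_axes put partner B on the x axis instead of A.
#' @param format output image format, `"png"` or `"svg"`.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return a `map_style` list.
#' @export
map_style <- function(gamma = 1, marker_size = 1, flip_axes = FALSE,
                      format = c("png", "svg"), width = NULL,
                      height = NULL) {
  format <- match.arg(format)
  structure(list(gamma = gamma, marker_size = marker_size,
                 flip_axes = flip_axes, format = format,
                 width = width %||% if (format == "png") 800 else 7,
                 height = height %||% if (format == "png") 800 else 7),
            class = "map_style")
}

open_device <- function(path, style) {
  ok <- tryCatch({
    if (style$format == "png") {
      grDevices::png(path, width = style$width, height = style$height)
    } else {
      grDevices::svg(path, width = style$width, height = style$height)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) mdc_stop(sprintf("cannot open output device for %s", path),
                    "mdc_error_unwritable")
}

#' Render a grayscale consensus contact map
#'
#' One mark per nonzero cell of the consensus matrix; darkness is a
#' strictly increasing function of the conservation rate. Axes carry
#' author residue numbers (ticks) and chain labels.
#'
#' @param matrix a [consensus_matrix()].
#' @param style a [map_style()].
#' @param out_path output image path (extension does not override
#'   `style$format`).
#' @return `out_path`, invisibly.
#' @export
render_consensus_map <- function(matrix, style = map_style(), out_path) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    mdc_stop("consensus matrix is degenerate (empty axis)",
             "mdc_error_degenerate_matrix")
  }
  ri <- attr(matrix, "row_info")
  ci <- attr(matrix, "col_info")
  nz <- which(unclass(matrix) > 0, arr.ind = TRUE)
  xs_info <- if (style$flip_axes) ci else ri
  ys_info <- if (style$flip_axes) ri else ci
  xi <- if (style$flip_axes) nz[, 2L] else nz[, 1L]
  yi <- if (style$flip_axes) nz[, 1L] else nz[, 2L]
  cr <- unclass(matrix)[nz]
  gray_lv <- 1 - cr^style$gamma

  dir <- dirname(out_path)
  if (!dir.exists(dir)) {
    mdc_stop(sprintf("output directory does not exist: %s", dir),
             "mdc_error_unwritable")
  }
  open_device(out_path, style)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, 1.5, 1))
  graphics::plot(NA, xlim = c(0.5, nrow(xs_info) + 0.5),
                 ylim = c(0.5, nrow(ys_info) + 0.5),
                 xlab = sprintf("residue (chain %s)",
                                paste(unique(xs_info$chain), collapse = ",")),
                 ylab = sprintf("residue (chain %s)",
                                paste(unique(ys_info$chain), collapse = ",")),
                 xaxt = "n", yaxt = "n")
  tick <- function(info, side) {
    at <- pretty(seq_len(nrow(info)))
    at <- at[at >= 1 & at <= nrow(info)]
    graphics::axis(side, at = at, labels = info$resno[at])
  }
  tick(xs_info, 1)
  tick(ys_info, 2)
  if (length(cr)) {
    ord <- order(cr)  # darkest drawn last
    graphics::points(xi[ord], yi[ord], pch = 15,
                     cex = style$marker_size,
                     col = grDevices::gray(gray_lv[ord]))
  }
  invisible(out_path)
}

#' Render the contact map of a single structure
#'
#' A single structure is drawn as the N = 1 consensus of itself: every
#' contact is a full-black mark.
#'
#' @param contacts a [frame_contacts()] result.
#' @param registry residue registry covering the contact residues.
#' @inheritParams render_consensus_map
#' @return `out_path`, invisibly.
#' @export
render_contact_map <- function(contacts, registry, style = map_style(),
                               out_path) {
  rec <- conservation_rates(list(contacts), n_frames = 1L)
  m <- consensus_matrix(rec, registry)
  render_consensus_map(m, style, out_path)
}
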