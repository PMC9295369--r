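# ---------------------------------------------------------------------------
# Registration of count-derived rasters to histology (H&E) images.
# Convention for all images here: plain numeric R matrices, row-major,
# origin top-left, y down; row = y, column = x. Offsets are 0-based pixel
# translations of the template's top-left corner within the reference.
# ---------------------------------------------------------------------------

#' Render under-tissue units as a Visium-style binary raster
#'
#' A \code{dim x dim} (default 1000 x 1000) raster covering a square puck
#' (default 6.5 mm side); each unit is drawn as a filled disk whose
#' diameter is the spot diameter (default 55 um) scaled to pixels
#' (\code{round(55 / 6500 * 1000) = 8} px at the defaults). Foreground
#' (disk) pixels are 1.
#'
#' @param units data frame with columns \code{barcode}, \code{x}, \code{y}
#'   (micrometres), already filtered to under-tissue units.
#' @param puck_side_um puck side length, micrometres (default 6500).
#' @param dim raster side, pixels (default 1000).
#' @param spot_diameter_um spot diameter, micrometres (default 55).
#' @return binary matrix (\code{dim x dim}); units outside the puck are
#'   clipped with a warning.
#' @export
render_visium_raster <- function(units, puck_side_um = 6500, dim = 1000L,
                                 spot_diameter_um = 55) {
  img <- matrix(0L, nrow = dim, ncol = dim)
  if (nrow(units) == 0L) return(img)
  scale <- dim / puck_side_um
  cx <- round(units$x * scale); cy <- round(units$y * scale)
  outside <- cx < 1L | cx > dim | cy < 1L | cy > dim
  if (any(outside))
    warning(sum(outside), " unit(s) outside the puck were clipped")
  d_px <- round(spot_diameter_um * scale)
  r <- d_px / 2
  # even diameters center the disk between pixels so the drawn span is
  # exactly d_px pixels; odd diameters center on a pixel
  off <- if (d_px %% 2 == 0) 0.5 else 0
  ir <- ceiling(r + off)
  for (i in which(!outside)) {
    rows <- max(1L, cy[i] - ir):min(dim, cy[i] + ir)
    cols <- max(1L, cx[i] - ir):min(dim, cx[i] + ir)
    dy2 <- (rows - cy[i] - off)^2
    dx2 <- (cols - cx[i] - off)^2
    img[rows, cols][outer(dy2, dx2, `+`) <= r * r] <- 1L
  }
  img
}

#' Render a count-intensity raster and binarize it
#'
#' Counts are scaled linearly to a maximum of 255 (8-bit), binned onto a
#' \code{dim x dim} grid (mean intensity per bin, empty bins 0), and
#' binarized. The default \code{"connectivity"} rule searches the threshold
#' t in \code{band} that maximizes the size of the largest connected
#' foreground component of \{intensity >= t\}; \code{"band"} keeps exactly
#' the pixels whose intensity falls inside the band.
#'
#' @param units data frame with columns \code{x}, \code{y} and
#'   \code{total_counts} (at least one positive).
#' @param dim raster side in pixels (default 1000).
#' @param band intensity window, default \code{c(190, 200)}.
#' @param mode \code{"connectivity"} (default) or \code{"band"}.
#' @param bbox optional \code{c(xmin, ymin, xmax, ymax)}; default the
#'   units' range.
#' @return binary matrix; the grayscale raster is attached as attribute
#'   \code{"intensity"}.
#' @export
render_grid_raster <- function(units, dim = 1000L, band = c(190, 200),
                               mode = c("connectivity", "band"),
                               bbox = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("x", "y", "total_counts") %in% names(units)))
  if (all(units$total_counts <= 0)) stop("all counts are zero")
  if (is.null(bbox))
    bbox <- c(min(units$x), min(units$y), max(units$x), max(units$y))
  scaled <- units$total_counts * 255 / max(units$total_counts)
  px <- pmin(dim, pmax(1L, ceiling((units$x - bbox[1L]) /
                                     max(bbox[3L] - bbox[1L], 1e-12) * dim)))
  py <- pmin(dim, pmax(1L, ceiling((units$y - bbox[2L]) /
                                     max(bbox[4L] - bbox[2L], 1e-12) * dim)))
  key <- (px - 1L) * dim + py
  sums <- tapply(scaled, key, mean)
  img <- matrix(0, nrow = dim, ncol = dim)
  img[as.integer(names(sums))] <- sums
  if (mode == "band") {
    mask <- (img >= band[1L] & img <= band[2L]) * 1L
  } else {
    best_t <- band[1L]; best_size <- -1L
    for (t in seq(band[1L], band[2L])) {
      m <- img >= t
      if (!any(m)) next
      lab <- EBImage::bwlabel(m)
      size <- max(tabulate(lab[lab > 0]))
      if (size > best_size) { best_size <- size; best_t <- t }
    }
    mask <- (img >= best_t) * 1L
  }
  attr(mask, "intensity") <- img
  mask
}

#' Binarize an H&E image by automatic (Otsu) thresholding
#'
#' RGB rasters are converted to luminance grayscale
#' (0.299 R + 0.587 G + 0.114 B); the global threshold maximizing the
#' between-class variance (Otsu) is computed and pixels darker than it —
#' H&E tissue is dark on a light background — become foreground.
#'
#' @param image numeric matrix (grayscale) or 3-d array (RGB); 8-bit
#'   \code{[0, 255]} or unit-scale \code{[0, 1]} values.
#' @return binary matrix (1 = tissue).
#' @export
binarize_hne <- function(image) {
  if (length(base::dim(image)) == 3L) {
    image <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
      0.114 * image[, , 3L]
  }
  stopifnot(is.matrix(image), length(image) > 0L)
  if (max(image) > 1) image <- image / 255
  if (diff(range(image)) < 1e-12)
    stop("no threshold separates classes: constant image")
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  (image < thr) * 1L
}

# ---------------------------------------------------------------------------
# Zero-normalized cross-correlation (Pearson per offset) of a template
# against all valid offsets of a reference, via FFT for the cross term and
# integral images for the window sums.
# ---------------------------------------------------------------------------

#' Correlation map of a template over a reference image
#'
#' @param reference,template numeric matrices; template no larger than the
#'   reference in either dimension.
#' @return matrix of ZNCC scores; entry \code{[i, j]} is the correlation
#'   with the template's top-left at 0-based offset
#'   \code{(y = i - 1, x = j - 1)}. Offsets where the reference window or
#'   the template has zero variance score 0.
#' @export
ncc_map <- function(reference, template) {
  rh <- nrow(reference); rw <- ncol(reference)
  th <- nrow(template); tw <- ncol(template)
  stopifnot(th <= rh, tw <= rw)
  n <- th * tw
  mu_t <- mean(template)
  ss_t <- sum((template - mu_t)^2)
  ph <- rh + th - 1L; pw <- rw + tw - 1L
  pad <- function(m) {
    out <- matrix(0, ph, pw)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  # cross-correlation: conj-FFT of the template against the reference
  cc <- Re(stats::fft(stats::fft(pad(reference)) *
                        Conj(stats::fft(pad(template))), inverse = TRUE)) /
    (ph * pw)
  cross <- cc[seq_len(rh - th + 1L), seq_len(rw - tw + 1L), drop = FALSE]
  # window sums of the reference and its square via integral images
  isum <- function(m) {
    z <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed cumsum
    t(z)
  }
  wsum <- function(ii) {
    A <- matrix(0, rh + 1L, rw + 1L)
    A[-1L, -1L] <- ii
    y2 <- th + seq_len(rh - th + 1L); x2 <- tw + seq_len(rw - tw + 1L)
    y1 <- y2 - th; x1 <- x2 - tw
    A[y2, x2] - A[y1, x2] - A[y2, x1] + A[y1, x1]
  }
  s1 <- wsum(isum(reference))
  s2 <- wsum(isum(reference^2))
  num <- cross - s1 * mu_t
  den2 <- (s2 - s1^2 / n) * ss_t
  den2[den2 < 1e-9] <- NA_real_
  out <- num / sqrt(den2)
  out[is.na(out)] <- 0
  if (ss_t < 1e-12) out[] <- 0
  out
}

#' Register a template to a reference by multiscale template matching
#'
#' The template is resized over a grid of x/y scale pairs — scaled widths
#' run from \code{scale_start_frac} (default one-third) to
#' \code{scale_max_frac} of the reference dimensions in steps of
#' \code{scale_step}, x and y independently, plus the template's native
#' size when it lies inside that range — and the zero-normalized
#' cross-correlation is evaluated at every offset; the global argmax is
#' returned. Ties break deterministically toward the lowest
#' (y_offset, x_offset, x_scale, y_scale).
#'
#' @param reference,template numeric (typically binary) matrices.
#' @param scale_start_frac smallest scaled-template size as a fraction of
#'   the reference (default 1/3).
#' @param scale_step scale-grid step as a fraction of the reference
#'   (default 0.02).
#' @param scale_max_frac largest fraction (default 1).
#' @return a \code{placement}: list with \code{x_offset}, \code{y_offset}
#'   (0-based pixels), \code{x_scale}, \code{y_scale} (template-to-
#'   reference linear factors), \code{score}.
#' @export
match_multiscale <- function(reference, template, scale_start_frac = 1 / 3,
                             scale_step = 0.02, scale_max_frac = 1) {
  rh <- nrow(reference); rw <- ncol(reference)
  th <- nrow(template); tw <- ncol(template)
  fr <- seq(scale_start_frac, scale_max_frac, by = scale_step)
  hs <- unique(pmax(2L, round(fr * rh)))
  ws <- unique(pmax(2L, round(fr * rw)))
  if (th >= round(scale_start_frac * rh) && th <= round(scale_max_frac * rh))
    hs <- sort(unique(c(hs, th)))
  if (tw >= round(scale_start_frac * rw) && tw <= round(scale_max_frac * rw))
    ws <- sort(unique(c(ws, tw)))
  hs <- hs[hs <= rh]; ws <- ws[ws <= rw]
  if (length(hs) == 0L || length(ws) == 0L)
    stop("template larger than reference at the minimum scale")
  best <- NULL
  for (h in hs) for (w in ws) {
    tmpl <- if (h == th && w == tw) template else
      EBImage::resize(template, w = h, h = w)  # EBImage: w = first dim
    sc <- ncc_map(reference, tmpl)
    m <- max(sc)
    cand <- which(sc == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    p <- list(x_offset = unname(cand[1L, 2L] - 1L),
              y_offset = unname(cand[1L, 1L] - 1L),
              x_scale = w / tw, y_scale = h / th, score = m)
    if (is.null(best) || m > best$score + 1e-12) best <- p
  }
  structure(best, class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf(
    "<placement> offset (x=%d, y=%d) px, scale (x=%.3f, y=%.3f), score %.4f\n",
    x$x_offset, x$y_offset, x$x_scale, x$y_scale, x$score))
  invisible(x)
}

#' Write a placement as JSON
#' @param placement a \code{placement}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_placement <- function(placement, path) {
  jsonlite::write_json(placement[c("x_offset", "y_offset", "x_scale",
                                   "y_scale", "score")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map spatial units into reference-image pixels
#'
#' Composes the unit-to-template-pixel map used when rendering the count
#' raster with a placement's scale and offset, yielding per-unit
#' coordinates in the reference (H&E) image. Row-major, origin top-left,
#' y down; offsets 0-based.
#'
#' @param units data frame with columns \code{barcode}, \code{x}, \code{y}
#'   (micrometres).
#' @param placement a \code{placement} from \code{\link{match_multiscale}}.
#' @param puck_side_um,dim the render parameters used for the template
#'   (see \code{\link{render_visium_raster}}).
#' @return data frame \code{barcode}, \code{px_x}, \code{px_y}.
#' @export
map_units_to_pixels <- function(units, placement, puck_side_um = 6500,
                                dim = 1000L) {
  scale <- dim / puck_side_um
  tx <- units$x * scale
  ty <- units$y * scale
  data.frame(barcode = units$barcode,
             px_x = tx * placement$x_scale + placement$x_offset,
             px_y = ty * placement$y_scale + placement$y_offset,
             stringsAsFactors = FALSE)
}
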