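#' Reconstruction pixel grid
#'
#' 8-mm (by default) pixel grid covering the panel footprint projected onto
#' the reconstruction plane, with a pixel edge anchored at z = 0 (the plan
#' isocenter) and at x = 0.  Bins are half-open `[lo, hi)`.
#'
#' @param geometry A [panel_geometry()].
#' @param pixel_mm Pixel pitch in mm (8 by default; 4 is the high-resolution
#'   option).
#' @return List with `x_edges` and `z_edges` (mm).
#' @export
recon_grid <- function(geometry = panel_geometry(), pixel_mm = 8) {
  stopifnot(pixel_mm > 0)
  nx <- ceiling(geometry$panel_half_width_x_mm / pixel_mm)
  nzp <- ceiling(geometry$panel_half_length_z_mm / pixel_mm)
  zc <- geometry$panel_center_z_mm
  # anchor the z edges at multiples of the pixel pitch around the isocenter
  z_lo <- floor((zc - nzp * pixel_mm) / pixel_mm) * pixel_mm
  z_hi <- ceiling((zc + nzp * pixel_mm) / pixel_mm) * pixel_mm
  list(x_edges = seq(-nx * pixel_mm, nx * pixel_mm, by = pixel_mm),
       z_edges = seq(z_lo, z_hi, by = pixel_mm))
}

#' Intersection of one line of response with the reconstruction plane
#'
#' The LOR is the straight segment between the two detector hits; the event
#' maps to the (x, z) point where the segment crosses the plane `y =
#' plane_y`.  Events whose segment does not cross the plane, or with
#' coincident hits, are rejected (reported, not an error).
#'
#' @param event List or one-row data frame with `x1_mm, y1_mm, z1_mm, x2_mm,
#'   y2_mm, z2_mm`.
#' @param plane_y_mm Reconstruction plane position (0 = mid-plane).
#' @return List with `accepted` (logical), `point` (c(x, z) or NULL) and
#'   `reason`.
#' @export
lor_plane_intersection <- function(event, plane_y_mm = 0) {
  e <- as.list(event)
  if (e$x1_mm == e$x2_mm && e$y1_mm == e$y2_mm && e$z1_mm == e$z2_mm) {
    return(list(accepted = FALSE, point = NULL, reason = "degenerate"))
  }
  dy <- e$y2_mm - e$y1_mm
  if (dy == 0) {
    return(list(accepted = FALSE, point = NULL, reason = "no_crossing"))
  }
  t <- (plane_y_mm - e$y1_mm) / dy
  if (t < 0 || t > 1) {
    return(list(accepted = FALSE, point = NULL, reason = "no_crossing"))
  }
  list(accepted = TRUE,
       point = c(x = e$x1_mm + t * (e$x2_mm - e$x1_mm),
                 z = e$z1_mm + t * (e$z2_mm - e$z1_mm)),
       reason = "ok")
}

#' Mid-plane 2D image reconstruction
#'
#' Pure count histogram of the LOR intersection points with the
#' reconstruction plane.  No attenuation, sensitivity or scatter corrections
#' are applied.
#'
#' @param events A `listmode_stream` or an events data frame.
#' @param grid Pixel grid from [recon_grid()].
#' @param plane_y_mm Reconstruction plane position (mm).
#' @return An `image2d`: list with `x_edges`, `z_edges`, `counts` (matrix,
#'   rows = x bins, cols = z bins), `plane_y_mm` and the event accounting
#'   `n_events`, `n_accepted`, `n_rejected_no_crossing`, `n_rejected_fov`,
#'   `n_rejected_degenerate`.
#' @export
reconstruct <- function(events, grid = recon_grid(), plane_y_mm = 0) {
  ev <- if (inherits(events, "listmode_stream")) events$events else events
  ev <- as.data.frame(ev)
  nx <- length(grid$x_edges) - 1L
  nz <- length(grid$z_edges) - 1L
  counts <- matrix(0L, nrow = nx, ncol = nz)
  n <- nrow(ev)
  n_deg <- 0L; n_cross <- 0L; n_fov <- 0L
  if (n > 0) {
    deg <- ev$x1_mm == ev$x2_mm & ev$y1_mm == ev$y2_mm & ev$z1_mm == ev$z2_mm
    dy <- ev$y2_mm - ev$y1_mm
    t <- ifelse(dy == 0, NA_real_, (plane_y_mm - ev$y1_mm) / dy)
    crossing <- !deg & !is.na(t) & t >= 0 & t <= 1
    n_deg <- sum(deg)
    n_cross <- sum(!deg & !crossing)
    x <- ev$x1_mm + t * (ev$x2_mm - ev$x1_mm)
    z <- ev$z1_mm + t * (ev$z2_mm - ev$z1_mm)
    in_fov <- crossing &
      x >= grid$x_edges[1] & x < grid$x_edges[nx + 1L] &
      z >= grid$z_edges[1] & z < grid$z_edges[nz + 1L]
    n_fov <- sum(crossing & !in_fov)
    if (any(in_fov)) {
      ix <- findInterval(x[in_fov], grid$x_edges)
      iz <- findInterval(z[in_fov], grid$z_edges)
      idx <- ix + (iz - 1L) * nx
      tab <- tabulate(idx, nbins = nx * nz)
      counts <- matrix(tab, nrow = nx, ncol = nz)
    }
  }
  structure(list(x_edges = grid$x_edges, z_edges = grid$z_edges,
                 counts = counts, plane_y_mm = plane_y_mm,
                 n_events = n, n_accepted = sum(counts),
                 n_rejected_no_crossing = n_cross,
                 n_rejected_fov = n_fov,
                 n_rejected_degenerate = n_deg),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d pixels, %d counts (of %d events)\n",
              nrow(x$counts), ncol(x$counts), x$n_accepted, x$n_events))
  invisible(x)
}

#' Write / read a 2D image
#'
#' Text format: two header lines with the x and z bin edges, then the counts
#' matrix (one row per z bin).  JSON holds the same fields.  The format is
#' chosen from the file extension (`.json` vs anything else).
#'
#' @param image An `image2d`.
#' @param path File path.
#' @return `read_image2d()` returns an `image2d` (event accounting fields are
#'   not stored and read back as `NA`).
#' @export
write_image2d <- function(image, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(x_edges = image$x_edges, z_edges = image$z_edges,
           plane_y_mm = image$plane_y_mm,
           counts = unname(t(image$counts))),  # row-major in z
      path, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# x_edges:", paste(image$x_edges, collapse = " ")), con)
  writeLines(paste("# z_edges:", paste(image$z_edges, collapse = " ")), con)
  utils::write.table(t(image$counts), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image2d
#' @export
read_image2d <- function(path) {
  mk <- function(x_edges, z_edges, counts_zmajor) {
    structure(list(x_edges = x_edges, z_edges = z_edges,
                   counts = t(counts_zmajor), plane_y_mm = NA_real_,
                   n_events = NA_integer_,
                   n_accepted = sum(counts_zmajor),
                   n_rejected_no_crossing = NA_integer_,
                   n_rejected_fov = NA_integer_,
                   n_rejected_degenerate = NA_integer_),
              class = "image2d")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(mk(j$x_edges, j$z_edges, as.matrix(j$counts)))
  }
  lines <- readLines(path)
  parse_edges <- function(line) {
    as.numeric(strsplit(sub("^# [xz]_edges: *", "", line), " +")[[1]])
  }
  x_edges <- parse_edges(lines[1])
  z_edges <- parse_edges(lines[2])
  counts <- as.matrix(utils::read.table(text = lines[-(1:2)]))
  dimnames(counts) <- NULL
  mk(x_edges, z_edges, counts)
}
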