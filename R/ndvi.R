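#' Construct a two-band reflectance scene
#'
#' Bundles near-infrared and red reflectance grids with a validity mask
#' (false where cloud, shadow or no-data make a pixel unusable) and the
#' ground pixel size. Coordinates are pixel-centre coordinates in metres:
#' x increases with column, y with row, so pixel (row r, col c) has centre
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)`.
#'
#' @param nir,red Numeric matrices of surface reflectance, congruent
#'   shapes, values in \[0, 1.5\] (permissive of correction overshoot).
#' @param valid_mask Logical matrix, `FALSE` for unusable pixels; defaults
#'   to all valid.
#' @param pixel_size Ground pixel edge, m (default 3).
#' @param acquisition_date Optional date tag carried through to results.
#' @return A list of class `raster_scene`.
#' @export
raster_scene <- function(nir, red, valid_mask = NULL, pixel_size = 3,
                         acquisition_date = NULL) {
  if (!is.matrix(nir) || !is.matrix(red) || !all(dim(nir) == dim(red))) {
    abort("`nir` and `red` must be matrices of identical shape.")
  }
  rng <- range(c(nir, red), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1.5) {
    abort("Reflectances must lie in [0, 1.5].")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(nir), ncol(nir))
  }
  if (!is.logical(valid_mask) || !all(dim(valid_mask) == dim(nir))) {
    abort("`valid_mask` must be a logical matrix congruent with the bands.")
  }
  structure(list(nir = nir, red = red, valid_mask = valid_mask,
                 pixel_size = pixel_size,
                 acquisition_date = acquisition_date),
            class = "raster_scene")
}

#' Normalized difference vegetation index
#'
#' Computes `(nir - red) / (nir + red)` per pixel. Pixels that are masked
#' invalid, or where both bands are zero (undefined ratio), are missing.
#' Floating Sargassum is strongly positive; open water is negative.
#'
#' @param scene A [raster_scene()].
#' @return A numeric matrix in \[-1, 1\] with NA for undefined pixels.
#' @export
ndvi <- function(scene) {
  stopifnot(inherits(scene, "raster_scene"))
  denom <- scene$nir + scene$red
  out <- (scene$nir - scene$red) / denom
  out[denom == 0] <- NA_real_
  out[!scene$valid_mask] <- NA_real_
  out
}

#' Classify Sargassum pixels from NDVI
#'
#' A pixel is labelled Sargassum when its NDVI exceeds `threshold` and the
#' pixel is valid. The default cutoff of 0 separates vegetation (positive
#' NDVI) from water (negative).
#'
#' @param ndvi_grid NDVI matrix from [ndvi()].
#' @param threshold Classification cutoff (default 0).
#' @return A logical matrix: `TRUE` Sargassum, `FALSE` other, `NA`
#'   invalid/undefined.
#' @export
classify_sargassum <- function(ndvi_grid, threshold = 0) {
  if (!is.matrix(ndvi_grid)) abort("`ndvi_grid` must be a matrix.")
  ndvi_grid > threshold
}

#' Define an area-of-interest polygon
#'
#' A simple (non-self-intersecting) polygon in scene coordinates (metres,
#' see [raster_scene()] for the frame) over which percent cover is
#' computed.
#'
#' @param x,y Vertex coordinates (not closed; the closing edge is
#'   implicit).
#' @param name Optional label.
#' @return A list of class `aoi_polygon`.
#' @export
aoi_polygon <- function(x, y, name = "aoi") {
  if (length(x) != length(y) || length(x) < 3) {
    abort("An AOI polygon needs at least 3 vertices with matching x and y.")
  }
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) < .Machine$double.eps * 100) {
    abort("AOI polygon has zero area.")
  }
  if (polygon_self_intersects(x, y)) {
    abort("AOI polygon is self-intersecting; supply a simple polygon.")
  }
  structure(list(x = x, y = y, name = name, area = abs(area2) / 2),
            class = "aoi_polygon")
}

# brute-force segment-pair crossing test; AOIs are small vertex lists
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through closure
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
      d2 <- cross(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
      d3 <- cross(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
      d4 <- cross(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Sargassum percent cover within an area of interest
#'
#' Counts classified Sargassum pixels whose centres fall inside the AOI
#' polygon, as a percentage of the valid (unmasked) pixels inside the
#' AOI. Areas are pixel counts times the squared pixel size. A scene is
#' flagged unusable for an AOI when the masked fraction inside it exceeds
#' `max_masked_frac`, mirroring the exclusion of cloud-contaminated
#' imagery.
#'
#' @param mask Logical classification matrix from [classify_sargassum()].
#' @param scene The [raster_scene()] the mask came from.
#' @param aoi An [aoi_polygon()].
#' @param max_masked_frac Masked-fraction limit above which the result is
#'   marked unusable (default 0.2).
#' @return A one-row tibble: `aoi`, `sargassum_area_m2`, `aoi_area_m2`,
#'   `percent_cover`, `n_valid_px`, `n_masked_px`, `usable`.
#' @export
percent_cover <- function(mask, scene, aoi, max_masked_frac = 0.2) {
  stopifnot(inherits(scene, "raster_scene"), inherits(aoi, "aoi_polygon"))
  if (!all(dim(mask) == dim(scene$nir))) {
    abort("`mask` shape does not match the scene.")
  }
  px <- scene$pixel_size
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * px
  cy <- (rep(seq_len(nr), times = nc) - 0.5) * px
  inside <- pracma::inpolygon(cx, cy, aoi$x, aoi$y, boundary = TRUE)
  if (!any(inside)) abort("AOI does not intersect the scene.")
  m <- as.vector(mask)[inside]
  v <- as.vector(scene$valid_mask)[inside]
  n_valid <- sum(v)
  n_masked <- sum(!v)
  n_sarg <- sum(m[v], na.rm = TRUE)
  pct <- if (n_valid > 0) 100 * n_sarg / n_valid else NA_real_
  tibble::tibble(
    aoi = aoi$name,
    sargassum_area_m2 = n_sarg * px^2,
    aoi_area_m2 = length(m) * px^2,
    percent_cover = pct,
    n_valid_px = as.integer(n_valid),
    n_masked_px = as.integer(n_masked),
    usable = n_masked / length(m) <= max_masked_frac
  )
}

#' Read and write two-band scenes as plain-text band files
#'
#' Scenes are exchanged as a pair of CSV band matrices
#' (`<stem>_nir.csv`, `<stem>_red.csv`), an optional 0/1 mask
#' (`<stem>_mask.csv`) and a JSON sidecar (`<stem>.json`) carrying pixel
#' size and acquisition date. `read_scene_tiff()` additionally reads an
#' unreferenced two-band TIFF (band order NIR, red by default) when the
#' \pkg{tiff} package is available.
#'
#' @param stem Path stem for the band files.
#' @return `read_scene()` returns a [raster_scene()].
#' @export
read_scene <- function(stem) {
  nir <- as.matrix(utils::read.csv(paste0(stem, "_nir.csv"), header = FALSE))
  red <- as.matrix(utils::read.csv(paste0(stem, "_red.csv"), header = FALSE))
  dimnames(nir) <- dimnames(red) <- NULL
  mask_path <- paste0(stem, "_mask.csv")
  mask <- if (file.exists(mask_path)) {
    m <- as.matrix(utils::read.csv(mask_path, header = FALSE))
    dimnames(m) <- NULL
    m > 0
  } else NULL
  meta_path <- paste0(stem, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  raster_scene(nir, red, valid_mask = mask,
               pixel_size = meta$pixel_size %||% 3,
               acquisition_date = meta$acquisition_date)
}

#' @rdname read_scene
#' @param scene A [raster_scene()].
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "raster_scene"))
  utils::write.table(scene$nir, paste0(stem, "_nir.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(scene$red, paste0(stem, "_red.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(scene$valid_mask * 1L, paste0(stem, "_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(pixel_size = scene$pixel_size,
         acquisition_date = scene$acquisition_date),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(scene)
}

#' @rdname read_scene
#' @param path TIFF file path.
#' @param band_order Order of the two bands in the file.
#' @param pixel_size,acquisition_date Passed to [raster_scene()].
#' @export
read_scene_tiff <- function(path, band_order = c("nir", "red"),
                            pixel_size = 3, acquisition_date = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Reading TIFF scenes requires the 'tiff' package; use read_scene() for CSV band files.")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 2) {
    abort("Expected a two-band TIFF (rows x cols x 2).")
  }
  bands <- setNames(list(img[, , 1], img[, , 2]), band_order)
  raster_scene(bands$nir, bands$red, pixel_size = pixel_size,
               acquisition_date = acquisition_date)
}
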