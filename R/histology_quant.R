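#' Default picrosirius stain matrix
#'
#' Normalized optical-density vectors (rows) of the red collagen stain, the
#' pale counterstain, and their orthogonal complement, matched to the
#' synthetic renderer's palette. Override when quantifying slides with other
#' staining characteristics.
#'
#' @return 3 x 3 numeric matrix, rows = stains, columns = R, G, B optical
#'   densities.
#' @export
picrosirius_stain_matrix <- function() {
  pal <- picrosirius_palette()
  od <- function(rgb) -log10(pmax(rgb, 1e-3))
  v1 <- od(pal$collagen)
  v2 <- od(pal$tissue)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  v3 <- v3 / sqrt(sum(v3^2))
  m <- rbind(collagen = v1, counterstain = v2, residual = v3)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Colour deconvolution of an RGB tile
#'
#' Converts the image to optical density (`-log10(I)`, unit illumination)
#' and unmixes it into per-stain concentration images using the inverse of
#' the stain matrix (Ruifrok-Johnston colour deconvolution).
#'
#' @param pixels RGB array `[rows, cols, 3]` in [0, 1].
#' @param stain_matrix 3 x 3 matrix of normalized stain OD vectors (rows).
#' @return Array `[rows, cols, 3]` of stain concentrations (OD units).
#' @export
colour_deconvolve <- function(pixels, stain_matrix = picrosirius_stain_matrix()) {
  d <- dim(pixels)
  od <- -log10(pmax(pixels, 1e-3))
  odm <- matrix(od, ncol = 3)
  conc <- odm %*% solve(stain_matrix)
  array(conc, dim = d)
}

otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) < 1e-12) return(rng[1])
  y <- (x - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(y), range = c(0, 1), levels = 256)
  th * diff(rng) + rng[1]
}

#' Collagen fraction of a picrosirius-red tile
#'
#' Colour deconvolution separates the red collagen stain from the
#' counterstain; the collagen concentration channel is thresholded with
#' Otsu's method (with an absolute concentration floor so that unstained
#' tiles yield zero rather than split noise), and the fraction is stained
#' pixels over tissue pixels. Tissue is defined by optical-density
#' background exclusion.
#'
#' @param slide A `cmre_slide` with `stain == "picrosirius"`, or an RGB
#'   array.
#' @param stain_matrix Stain OD matrix, see [picrosirius_stain_matrix()].
#' @param tissue_od_min Minimum OD norm for a pixel to count as tissue.
#' @param stain_floor Absolute floor on the Otsu threshold (OD units).
#' @return A tibble: `collagen_fraction` (%), `n_objects` (stained pixel
#'   count), `tissue_area` (mm^2, `NA` if pixel size unknown).
#' @export
collagen_fraction <- function(slide,
                              stain_matrix = picrosirius_stain_matrix(),
                              tissue_od_min = 0.1,
                              stain_floor = 0.3) {
  if (inherits(slide, "cmre_slide")) {
    if (!identical(slide$stain, "picrosirius")) {
      stop("collagen_fraction expects a picrosirius-stained slide")
    }
    px <- slide$pixels
    ps <- slide$pixel_size
  } else {
    px <- slide
    ps <- NA_real_
  }
  if (length(dim(px)) != 3 || dim(px)[3] != 3) stop("an RGB image is required")
  od <- -log10(pmax(px, 1e-3))
  od_norm <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2)
  tissue <- od_norm > tissue_od_min
  if (!any(tissue)) stop("empty tissue mask: no tissue found on the tile")
  conc <- colour_deconvolve(px, stain_matrix)[, , 1]
  vals <- conc[tissue]
  th <- max(otsu_threshold(vals), stain_floor)
  stained <- sum(vals > th)
  tibble::tibble(
    collagen_fraction = 100 * stained / sum(tissue),
    n_objects = stained,
    tissue_area = if (is.na(ps)) NA_real_ else sum(tissue) * (ps / 1000)^2
  )
}

#' Count nuclei and compute cellularity
#'
#' Otsu global thresholding extracts the bright nuclei, holes are filled,
#' and a distance-transform watershed splits touching nuclei. Objects
#' smaller than `min_area_um2` are discarded. Cellularity is the object
#' count divided by the field area.
#'
#' @param slide A `cmre_slide` with `stain == "nucleus"`, or a grayscale
#'   matrix (then `pixel_size` must be given).
#' @param pixel_size Pixel size in um (taken from the slide if present).
#' @param min_area_um2 Minimum nucleus area, um^2.
#' @param watershed_tolerance Minimum height of an object in the distance
#'   map for it to count as a separate nucleus (px).
#' @return A tibble: `cell_density` (cells/mm^2), `n_objects`,
#'   `tissue_area` (mm^2).
#' @export
count_nuclei <- function(slide, pixel_size = NULL, min_area_um2 = 25,
                         watershed_tolerance = 1) {
  if (inherits(slide, "cmre_slide")) {
    if (!identical(slide$stain, "nucleus")) {
      stop("count_nuclei expects a nucleus-stained slide")
    }
    px <- slide$pixels
    ps <- slide$pixel_size
  } else {
    px <- slide
    ps <- pixel_size
  }
  if (is.null(ps) || !is.finite(ps) || ps <= 0) {
    stop("pixel_size is required to compute cell density")
  }
  if (length(dim(px)) == 3) px <- px[, , 1]
  area_mm2 <- prod(dim(px)) * (ps / 1000)^2
  th <- otsu_threshold(px)
  mask <- px > th
  n_fg <- sum(mask)
  if (n_fg == 0 || th < 0.2) {
    # empty field: Otsu on pure background splits noise; reject by absolute level
    if (max(px) < 0.5) {
      return(tibble::tibble(cell_density = 0, n_objects = 0L,
                            tissue_area = area_mm2))
    }
  }
  img <- EBImage::Image(mask * 1)
  img <- EBImage::fillHull(img)
  dm <- EBImage::distmap(img)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  areas <- tabulate(as.integer(EBImage::imageData(labels)))
  min_px <- min_area_um2 / ps^2
  n_obj <- sum(areas >= min_px)
  tibble::tibble(
    cell_density = n_obj / area_mm2,
    n_objects = as.integer(n_obj),
    tissue_area = area_mm2
  )
}
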