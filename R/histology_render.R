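# Renderer palette: optical densities per channel for the two stains and the
# counterstained tissue. Kept in one place so the quantifier's default stain
# matrix can be matched to it (and overridden by the user).
picrosirius_palette <- function() {
  list(
    background = c(0.97, 0.97, 0.97),
    tissue     = c(0.95, 0.88, 0.62),  # pale yellow counterstain
    collagen   = c(0.72, 0.12, 0.18)   # picrosirius red
  )
}

#' Render a synthetic picrosirius-red stained tile
#'
#' Draws red fibrillar collagen structures over pale counterstained tissue
#' (a disk on a white slide background) so that the stained pixels cover
#' exactly `round(true_fraction/100 * tissue pixels)` of the tissue area.
#' Fibres are random thick line segments; the last fibre is trimmed pixel by
#' pixel so the construction mask hits the target count. The ground-truth
#' collagen and tissue masks are retained for testing.
#'
#' @param true_fraction True collagen fraction, percent of tissue area
#'   (0 to 100).
#' @param tile_px Tile edge length in pixels.
#' @param pixel_size Pixel size in um.
#' @param seed Optional integer seed.
#' @param color_noise_sd SD of Gaussian RGB noise.
#' @return A `cmre_slide`: `pixels` (tile_px x tile_px x 3 in [0, 1]),
#'   `pixel_size`, `stain = "picrosirius"`, `true_collagen_fraction`, and
#'   masks `collagen_mask`, `tissue_mask`.
#' @export
render_picrosirius_slide <- function(true_fraction, tile_px = 512,
                                     pixel_size = 2, seed = NULL,
                                     color_noise_sd = 0.015) {
  if (!is.finite(true_fraction) || true_fraction < 0 || true_fraction > 100) {
    stop("true_fraction must lie in [0, 100]")
  }
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- tile_px
  ctr <- (n + 1) / 2
  rad <- 0.47 * n
  tissue <- outer(seq_len(n), seq_len(n),
                  function(r, c) (r - ctr)^2 + (c - ctr)^2 <= rad^2)
  n_tissue <- sum(tissue)
  target <- round(true_fraction / 100 * n_tissue)
  collagen <- matrix(FALSE, n, n)

  draw_fibre <- function() {
    # a thick line segment, returned as pixel indices within the tissue
    r0 <- runif(1, 1, n)
    c0 <- runif(1, 1, n)
    ang <- runif(1, 0, pi)
    len <- runif(1, 0.04, 0.18) * n
    wid <- sample(1:2, 1)
    t_seq <- seq(0, len, by = 0.5)
    rr <- r0 + t_seq * cos(ang)
    cc <- c0 + t_seq * sin(ang)
    px <- unique(do.call(rbind, lapply(seq(-wid, wid, by = 0.5), function(o) {
      cbind(round(rr - o * sin(ang)), round(cc + o * cos(ang)))
    })))
    px <- px[px[, 1] >= 1 & px[, 1] <= n & px[, 2] >= 1 & px[, 2] <= n, ,
             drop = FALSE]
    px[tissue[px], , drop = FALSE]
  }

  count <- 0L
  guard <- 0L
  while (count < target && guard < 100000L) {
    guard <- guard + 1L
    px <- draw_fibre()
    if (nrow(px) == 0) next
    new <- px[!collagen[px], , drop = FALSE]
    if (nrow(new) == 0) next
    excess <- count + nrow(new) - target
    if (excess > 0) {
      # trim the last fibre from its tail to land exactly on target
      new <- new[seq_len(nrow(new) - excess), , drop = FALSE]
    }
    collagen[new] <- TRUE
    count <- count + nrow(new)
  }
  if (count != target) stop("fibre renderer failed to reach the target area")

  pal <- picrosirius_palette()
  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], n, n)
    plane[tissue] <- pal$tissue[ch]
    plane[collagen] <- pal$collagen[ch]
    img[, , ch] <- plane
  }
  if (color_noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, color_noise_sd), dim = dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  structure(
    list(pixels = img, pixel_size = pixel_size, stain = "picrosirius",
         true_collagen_fraction = 100 * count / n_tissue,
         collagen_mask = collagen, tissue_mask = tissue),
    class = "cmre_slide"
  )
}

#' Render a synthetic nucleus-stained (DAPI-like) field
#'
#' Places `round(cell_density * field_area)` bright elliptical nuclei on a
#' dark background. A fraction of the nuclei is placed in touching pairs to
#' exercise watershed splitting. The ground-truth count is retained.
#'
#' @param cell_density Nuclei per mm^2 (>= 0).
#' @param field_area Field area in mm^2.
#' @param overlap_fraction Fraction of nuclei placed touching a neighbour,
#'   in [0, 0.3].
#' @param pixel_size Pixel size in um.
#' @param seed Optional integer seed.
#' @return A `cmre_slide` with `pixels` (grayscale matrix in [0, 1]),
#'   `pixel_size`, `stain = "nucleus"`, `true_count`, `field_area`.
#' @export
render_nucleus_field <- function(cell_density, field_area = 1,
                                 overlap_fraction = 0.1, pixel_size = 0.5,
                                 seed = NULL) {
  if (cell_density < 0) stop("cell_density must be >= 0")
  if (overlap_fraction < 0 || overlap_fraction > 0.3) {
    stop("overlap_fraction must lie in [0, 0.3]")
  }
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(sqrt(field_area) * 1000 / pixel_size)
  img <- matrix(0.08, n, n)
  n_cells <- round(cell_density * field_area)
  if (n_cells > 0) {
    n_pairs <- round(overlap_fraction * n_cells / 2)
    centres <- matrix(NA_real_, n_cells, 2)
    radii <- runif(n_cells, 3.5, 5) / pixel_size      # semi-major axis, px
    placed <- 0L
    min_sep <- 2.6 * max(radii)
    add_centre <- function(rc) {
      force(rc) # evaluate before touching `placed` (rc may call sample_free)
      placed <<- placed + 1L
      centres[placed, ] <<- rc
    }
    sample_free <- function() {
      for (i in 1:2000) {
        cand <- runif(2, max(radii) + 2, n - max(radii) - 2)
        if (placed == 0L) return(cand)
        dmin <- min(sqrt(rowSums(sweep(centres[seq_len(placed), , drop = FALSE],
                                       2, cand)^2)))
        if (dmin > min_sep) return(cand)
      }
      stop("could not place nuclei without overlap; density too high")
    }
    for (p in seq_len(n_pairs)) {
      a <- sample_free()
      add_centre(a)
      ang <- runif(1, 0, 2 * pi)
      gap <- 0.85 * (radii[placed] + radii[placed + 1])
      add_centre(a + gap * c(cos(ang), sin(ang)))
    }
    while (placed < n_cells) add_centre(sample_free())
    # rasterize ellipses
    for (i in seq_len(n_cells)) {
      a <- radii[i]
      b <- a * runif(1, 0.8, 1)
      th <- runif(1, 0, pi)
      bb <- ceiling(a) + 1
      r0 <- round(centres[i, 1])
      c0 <- round(centres[i, 2])
      rr <- max(1, r0 - bb):min(n, r0 + bb)
      cc <- max(1, c0 - bb):min(n, c0 + bb)
      dr <- outer(rr - centres[i, 1], rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - centres[i, 2])
      x <- dr * cos(th) + dc * sin(th)
      y <- -dr * sin(th) + dc * cos(th)
      inside <- (x / a)^2 + (y / b)^2 <= 1
      sub <- img[rr, cc]
      sub[inside] <- 0.78
      img[rr, cc] <- sub
    }
  }
  img <- img + matrix(rnorm(n * n, 0, 0.03), n, n)
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(
    list(pixels = img, pixel_size = pixel_size, stain = "nucleus",
         true_count = if (cell_density > 0) n_cells else 0L,
         field_area = field_area),
    class = "cmre_slide"
  )
}
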