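#' Specification of a synthetic droplet micrograph
#'
#' Describes the rendering geometry and intensity model for synthetic
#' bright-field images of a single water-in-oil droplet containing dark
#' microbial cell blobs. Intensities are on a [0, 1] scale; the droplet
#' medium is rendered slightly darker than the surrounding oil so the
#' droplet boundary is detectable, and cells darker still.
#'
#' @param width_px,height_px frame size in pixels (>= 32 each).
#' @param um_per_px pixel scale, micrometres per pixel.
#' @param droplet_diameter_um droplet diameter; default 120 um, the nominal
#'   WODL size.
#' @param background_level oil background intensity in [0, 1].
#' @param medium_level droplet-interior (medium) intensity in [0, 1].
#' @param cell_level cell-pixel intensity in [0, 1].
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return an `image_spec` list.
#' @examples
#' image_spec(um_per_px = 1.5, width_px = 112, height_px = 112)
#' @export
image_spec <- function(width_px = 160, height_px = 160, um_per_px = 1,
                       droplet_diameter_um = 120,
                       background_level = 0.95, medium_level = 0.80,
                       cell_level = 0.25, noise_sd = 0.01) {
  check_scalar(width_px, "width_px", min = 32)
  check_scalar(height_px, "height_px", min = 32)
  check_scalar(um_per_px, "um_per_px", min = .Machine$double.eps)
  check_scalar(droplet_diameter_um, "droplet_diameter_um", min = 1)
  check_scalar(background_level, "background_level", min = 0, max = 1)
  check_scalar(medium_level, "medium_level", min = 0, max = 1)
  check_scalar(cell_level, "cell_level", min = 0, max = 1)
  check_scalar(noise_sd, "noise_sd", min = 0)
  if (background_level == cell_level) {
    abort("`background_level` and `cell_level` must differ")
  }
  r_px <- droplet_diameter_um / um_per_px / 2
  if (2 * r_px + 4 > min(width_px, height_px)) {
    abort("droplet does not fit inside the frame (including a 2 px margin)")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 um_per_px = um_per_px,
                 droplet_diameter_um = droplet_diameter_um,
                 background_level = background_level,
                 medium_level = medium_level,
                 cell_level = cell_level,
                 noise_sd = noise_sd),
            class = "image_spec")
}

#' A droplet micrograph with its pixel scale
#'
#' @param pixels numeric matrix of intensities in [0, 1] (rows = y).
#' @param um_per_px pixel scale in micrometres per pixel.
#' @return a `droplet_image` object.
#' @export
droplet_image <- function(pixels, um_per_px) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(!is.finite(pixels))) {
    abort("`pixels` must be a finite numeric matrix")
  }
  if (any(dim(pixels) < 32)) abort("image must be at least 32 px in each dimension")
  check_scalar(um_per_px, "um_per_px", min = .Machine$double.eps)
  structure(list(pixels = pixels, um_per_px = um_per_px),
            class = "droplet_image")
}

#' @export
print.droplet_image <- function(x, ...) {
  cat(sprintf("droplet_image: %d x %d px at %.3g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$um_per_px))
  invisible(x)
}

# pixel-centre circle mask; 0-based coordinate convention
circle_mask <- function(nr, nc, cx, cy, r) {
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Render a synthetic droplet image with known occupancy ground truth
#'
#' Renders one circular droplet centred in the frame with `n_blobs` dark cell
#' blobs whose rendered pixel area inside the droplet matches
#' `target_occupancy_pct` of the droplet area to within 0.5 percentage points
#' (before noise). Blob seed positions are placed without overlap by
#' rejection sampling; a shared blob radius is then tuned by bisection on the
#' rendered union area, so blobs can merge at high occupancy the way a
#' confluent culture does. Targets of exactly 0 or 100 render an empty or a
#' fully occupied interior.
#'
#' @param spec an [image_spec()].
#' @param target_occupancy_pct desired occupancy, percent of droplet area.
#' @param n_blobs number of cell blobs (ignored for targets 0 and 100).
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return list with `image` (a [droplet_image()]), `truth` (one-row tibble:
#'   `a_droplet_px`, `a_ex_px`, `occupancy_pct` from the rendered mask) and
#'   `geometry` (true centre/radius in px).
#' @examples
#' g <- generate_droplet_image(image_spec(), 40, n_blobs = 12, seed = 1)
#' g$truth
#' @export
generate_droplet_image <- function(spec, target_occupancy_pct, n_blobs = 12,
                                   seed = 1) {
  stopifnot(inherits(spec, "image_spec"))
  check_scalar(target_occupancy_pct, "target_occupancy_pct", min = 0, max = 100)
  check_scalar(n_blobs, "n_blobs", min = 0)

  nr <- spec$height_px
  nc <- spec$width_px
  r <- spec$droplet_diameter_um / spec$um_per_px / 2
  cx <- (nc - 1) / 2
  cy <- (nr - 1) / 2
  droplet <- circle_mask(nr, nc, cx, cy, r)
  a_droplet <- sum(droplet)

  cells <- withr::with_seed(seed, {
    render_cell_mask(nr, nc, cx, cy, r, droplet, a_droplet,
                     target_occupancy_pct, n_blobs)
  })
  n_cell <- sum(cells)

  img <- matrix(spec$background_level, nr, nc)
  img[droplet] <- spec$medium_level
  img[cells] <- spec$cell_level
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(substream_seed(seed, 1), {
      img + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    })
    img <- pmin(pmax(img, 0), 1)
  }

  list(image = droplet_image(img, spec$um_per_px),
       truth = tibble(a_droplet_px = a_droplet,
                      a_ex_px = a_droplet - n_cell,
                      occupancy_pct = 100 * n_cell / a_droplet),
       geometry = tibble(center_x = cx, center_y = cy, radius_px = r))
}

render_cell_mask <- function(nr, nc, cx, cy, r, droplet, a_droplet,
                             target_pct, n_blobs) {
  if (target_pct == 0) return(matrix(FALSE, nr, nc))
  if (target_pct == 100) return(droplet)
  if (n_blobs < 1) abort("occupancy > 0 requires at least one blob")

  target_px <- target_pct / 100 * a_droplet
  r0 <- sqrt(target_px / (n_blobs * pi))  # nominal per-blob radius

  # non-overlapping seed placement, capped attempts; spacing relaxed rather
  # than failed when the packing is tight, since dilation merges blobs anyway
  centers <- matrix(NA_real_, n_blobs, 2)
  placed <- 0
  min_d2 <- (1.8 * r0)^2
  attempts <- 0
  while (placed < n_blobs) {
    attempts <- attempts + 1
    if (attempts > 4000) {
      if (min_d2 > 1) {
        min_d2 <- min_d2 / 2
        attempts <- 0
      } else {
        abort("could not place blobs to reach the requested occupancy")
      }
    }
    u <- stats::runif(1)
    th <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(u) * max(r - 1, 1)
    px <- cx + rad * cos(th)
    py <- cy + rad * sin(th)
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - px)^2 +
        (centers[seq_len(placed), 2] - py)^2
      if (min(d2) < min_d2) next
    }
    placed <- placed + 1
    centers[placed, ] <- c(px, py)
  }

  union_area <- function(rb) {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(n_blobs)) {
      m <- m | circle_mask(nr, nc, centers[i, 1], centers[i, 2], rb)
    }
    m & droplet
  }

  # bisection on the shared blob radius; rendered union area is monotone in it
  lo <- 0
  hi <- 2 * r
  tol_px <- 0.0025 * a_droplet  # 0.25 percentage points
  mask <- NULL
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    mask <- union_area(mid)
    err <- sum(mask) - target_px
    if (abs(err) <= tol_px) break
    if (err < 0) lo <- mid else hi <- mid
  }
  if (abs(sum(mask) / a_droplet * 100 - target_pct) > 0.5) {
    abort("requested occupancy unreachable with this blob configuration")
  }
  mask
}

#' Generate a synthetic OD600 calibration series of droplet images
#'
#' One image per OD600 level, rendered at occupancy `occupancy_per_od * od`,
#' so measured occupancy is linear in OD600 by construction. Mirrors sealing
#' droplets with media of known OD600 to build an occupancy calibration.
#'
#' @param spec an [image_spec()]; its `noise_sd` controls pixel noise.
#' @param od_values OD600 levels, each >= 0.
#' @param occupancy_per_od occupancy percentage points per OD600 unit.
#' @param n_blobs blobs per image.
#' @param seed integer seed.
#' @return tibble with columns `od600`, `target_occupancy_pct`, `image`
#'   (list-column of [droplet_image()]), and the rendered-truth columns
#'   `a_droplet_px`, `a_ex_px`, `occupancy_pct`.
#' @examples
#' generate_calibration_series(image_spec(), od_values = c(0, 0.5, 1),
#'                             occupancy_per_od = 50, seed = 1)
#' @export
generate_calibration_series <- function(spec, od_values,
                                        occupancy_per_od = 50,
                                        n_blobs = 12, seed = 1) {
  stopifnot(inherits(spec, "image_spec"))
  check_number(od_values, "od_values", min = 0)
  check_scalar(occupancy_per_od, "occupancy_per_od", min = 0)
  if (occupancy_per_od * max(od_values) > 100) {
    abort("occupancy_per_od * max(od_values) exceeds 100% occupancy")
  }
  purrr::imap_dfr(od_values, function(od, i) {
    g <- generate_droplet_image(spec, occupancy_per_od * od,
                                n_blobs = n_blobs,
                                seed = substream_seed(seed, 100 + i))
    dplyr::bind_cols(tibble(od600 = od,
                            target_occupancy_pct = occupancy_per_od * od,
                            image = list(g$image)),
                     g$truth)
  })
}

#' Read and write droplet images
#'
#' Images are stored as 16-bit grayscale TIFF (or PNG when the path ends in
#' `.png`); intensities are mapped linearly between [0, 1] and the file
#' range. The pixel scale is not stored in the file and must be supplied on
#' read.
#'
#' @param img a [droplet_image()].
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return `write_droplet_image()` returns `path` invisibly;
#'   `read_droplet_image()` returns a [droplet_image()].
#' @export
write_droplet_image <- function(img, path) {
  stopifnot(inherits(img, "droplet_image"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) abort("package png not available")
    png::writePNG(img$pixels, path)
  } else {
    tiff::writeTIFF(img$pixels, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' @rdname write_droplet_image
#' @param um_per_px pixel scale of the stored image.
#' @export
read_droplet_image <- function(path, um_per_px) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) abort("package png not available")
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(px)) == 3) px <- px[, , 1]
  droplet_image(px, um_per_px)
}
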