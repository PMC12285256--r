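#' Detect the droplet boundary in a micrograph
#'
#' Finds the single dominant droplet as the largest connected foreground
#' component against the oil background (estimated from the frame border),
#' then fits a circle through the component centroid and equivalent radius.
#' Components touching the frame edge (partial droplets) and non-circular
#' objects are rejected.
#'
#' @param img a [droplet_image()].
#' @return one-row tibble: `center_x`, `center_y` (0-based px), `radius_px`,
#'   `a_droplet_px` (pixel count of the fitted circle).
#' @examples
#' g <- generate_droplet_image(image_spec(), 30, seed = 2)
#' detect_droplet(g$image)
#' @export
detect_droplet <- function(img) {
  stopifnot(inherits(img, "droplet_image"))
  px <- img$pixels
  nr <- nrow(px)
  nc <- ncol(px)
  sm <- px

  border <- c(sm[1:2, ], sm[(nr - 1):nr, ], sm[, 1:2], sm[, (nc - 1):nc])
  bg <- median(border)
  noise <- mad(border)

  # Foreground = pixels deviating from the oil background by more than the
  # border noise and a small fraction of the image's own dynamic range. Both
  # terms scale with affine intensity rescaling, so detection is invariant
  # to contrast/brightness changes.
  dev <- abs(sm - bg)
  thr <- max(5 * noise, 0.02 * diff(range(sm)))
  if (thr <= 0) abort("no droplet found: image has no contrast")
  mask <- dev > thr
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, "disc")) > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) abort("no droplet found in image")
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  if (areas[biggest] < 500) abort("no droplet found: largest object too small")
  comp <- lab == biggest
  comp <- EBImage::fillHull(comp) > 0

  edge_hit <- any(comp[1, ]) || any(comp[nr, ]) || any(comp[, 1]) ||
    any(comp[, nc])
  if (edge_hit) abort("droplet touches the frame edge; partial droplets are rejected")

  idx <- which(comp, arr.ind = TRUE)
  cy <- mean(idx[, 1]) - 1
  cx <- mean(idx[, 2]) - 1
  area <- nrow(idx)
  radius <- sqrt(area / pi)

  circ <- circle_mask(nr, nc, cx, cy, radius)
  overlap <- sum(circ & comp)
  if (overlap < 0.95 * area || overlap < 0.95 * sum(circ)) {
    abort("dominant object is not circular; no droplet found")
  }
  tibble(center_x = cx, center_y = cy, radius_px = radius,
         a_droplet_px = sum(circ))
}

#' Segment cell pixels inside a detected droplet
#'
#' Binarises the droplet interior with an Otsu threshold computed on the
#' interior pixels only, keeps pixels on the cell side of the threshold
#' (darker by default), and suppresses salt noise with a 1 px morphological
#' opening before counting. Returns the cell-free area `A_ex` in pixels. A
#' near-uniform interior is classified as all-medium or all-cells by its
#' darkness relative to the surrounding oil.
#'
#' @param img a [droplet_image()].
#' @param geometry one-row data frame from [detect_droplet()] (or supplied
#'   manually with columns `center_x`, `center_y`, `radius_px`).
#' @param cells_darker are cells darker than the medium? Default `TRUE`.
#' @param opening_px radius of the morphological opening applied to the cell
#'   mask; 0 disables it.
#' @return `a_ex_px`, the count of non-cell pixels inside the droplet circle.
#' @export
segment_cells <- function(img, geometry, cells_darker = TRUE, opening_px = 1) {
  stopifnot(inherits(img, "droplet_image"))
  px <- img$pixels
  nr <- nrow(px)
  nc <- ncol(px)
  circ <- circle_mask(nr, nc, geometry$center_x, geometry$center_y,
                      geometry$radius_px)
  a_droplet <- sum(circ)
  if (a_droplet == 0) abort("geometry selects no pixels")
  # threshold on pixels strictly inside the rim to avoid boundary mixing
  inner <- circle_mask(nr, nc, geometry$center_x, geometry$center_y,
                       max(geometry$radius_px - 1.5, 1))
  vals <- px[inner]

  border <- c(px[1:2, ], px[(nr - 1):nr, ], px[, 1:2], px[, (nc - 1):nc])
  bg <- median(border)

  thr <- otsu_threshold(vals)
  lo <- vals[vals <= thr]
  hi <- vals[vals > thr]
  contrast <- length(lo) > 0 && length(hi) > 0 &&
    (mean(hi) - mean(lo)) > 5 * max(sd(lo), sd(hi), 0.005, na.rm = TRUE)

  if (!contrast) {
    # uniform interior: empty droplet if its level is oil-like, confluent if
    # much darker than the oil
    uniform_dark <- mean(vals) < 0.5 * bg
    cell_in_circ <- if (xor(uniform_dark, !cells_darker)) a_droplet else 0
    return(a_droplet - cell_in_circ)
  }

  cell <- if (cells_darker) px <= thr else px > thr
  cell <- cell & circ
  if (opening_px > 0) {
    cell <- EBImage::opening(cell,
                             EBImage::makeBrush(2 * opening_px + 1, "disc")) > 0
  }
  a_droplet - sum(cell)
}

# Otsu's method on a 256-bin histogram of the supplied pixel values;
# computed interior-only by the caller
otsu_threshold <- function(vals, n_bins = 256) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(vals, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Droplet occupancy from droplet and cell-free areas
#'
#' The occupancy percentage `A_occup = (A_droplet - A_ex) / A_droplet * 100`:
#' the fraction of the droplet's projected area covered by cells, the image
#' proxy for culture turbidity.
#'
#' @param a_droplet_px droplet area in pixels (> 0).
#' @param a_ex_px cell-free area in pixels, in [0, `a_droplet_px`].
#' @return occupancy percentage in [0, 100]; vectorised.
#' @examples
#' compute_occupancy(10000, 1600) # 84
#' @export
compute_occupancy <- function(a_droplet_px, a_ex_px) {
  check_number(a_droplet_px, "a_droplet_px", min = .Machine$double.xmin)
  check_number(a_ex_px, "a_ex_px", min = 0)
  if (any(a_ex_px > a_droplet_px)) {
    abort("`a_ex_px` cannot exceed `a_droplet_px`")
  }
  (a_droplet_px - a_ex_px) / a_droplet_px * 100
}

#' Measure occupancy of one droplet image
#'
#' Runs droplet detection, interior cell segmentation and the occupancy
#' formula. Deterministic for a fixed input image.
#'
#' @inheritParams segment_cells
#' @param geometry optional pre-supplied geometry (as from
#'   [detect_droplet()]); when `NULL` the droplet is detected automatically.
#' @return one-row tibble: `center_x`, `center_y`, `radius_px`,
#'   `a_droplet_px`, `a_ex_px`, `occupancy_pct`.
#' @export
measure_image <- function(img, geometry = NULL, cells_darker = TRUE,
                          opening_px = 1) {
  if (is.null(geometry)) geometry <- detect_droplet(img)
  if (!"a_droplet_px" %in% names(geometry)) {
    circ_n <- sum(circle_mask(nrow(img$pixels), ncol(img$pixels),
                              geometry$center_x, geometry$center_y,
                              geometry$radius_px))
    geometry$a_droplet_px <- circ_n
  }
  a_ex <- segment_cells(img, geometry, cells_darker = cells_darker,
                        opening_px = opening_px)
  tibble(center_x = geometry$center_x, center_y = geometry$center_y,
         radius_px = geometry$radius_px,
         a_droplet_px = geometry$a_droplet_px, a_ex_px = a_ex,
         occupancy_pct = compute_occupancy(geometry$a_droplet_px, a_ex))
}

#' Measure occupancy over a batch of droplet images
#'
#' @param images list of [droplet_image()] objects (one droplet each).
#' @inheritParams measure_image
#' @return tibble with one row per image (`droplet_id` prepended).
#' @export
measure_droplets <- function(images, cells_darker = TRUE, opening_px = 1) {
  purrr::imap_dfr(images, function(im, i) {
    dplyr::bind_cols(tibble(droplet_id = i),
                     measure_image(im, cells_darker = cells_darker,
                                   opening_px = opening_px))
  })
}

#' Summarise replicate occupancy measurements
#'
#' Mean and standard deviation of occupancy over replicate droplets, the
#' per-time-point summary used for droplet growth curves (SD over five
#' droplets in the reference workflow).
#'
#' @param measurements tibble from [measure_droplets()].
#' @return one-row tibble: `n`, `mean_occupancy_pct`, `sd_occupancy_pct`.
#' @export
occupancy_stats <- function(measurements) {
  dplyr::summarise(measurements,
                   n = dplyr::n(),
                   mean_occupancy_pct = mean(.data$occupancy_pct),
                   sd_occupancy_pct = sd(.data$occupancy_pct))
}
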