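#' Gate the top fraction of droplets by fluorescence
#'
#' The gate threshold is the empirical `1 - q` quantile (linear
#' interpolation between order statistics); droplets strictly above it are
#' selected, so ties at the threshold are excluded and the gate never sorts
#' more than requested. Mirrors sorting the droplets with the top 1% of
#' green fluorescence.
#'
#' @param data droplet table (data frame) with an intensity column.
#' @param q fraction to select, in (0, 1); e.g. 0.01 for the top 1%.
#' @param intensity column (unquoted) holding fluorescence intensities.
#' @return a `sort_gate`: `mode`, `q`, `threshold_used`, `selected_count`,
#'   `n`, `selected` (logical vector aligned with `data` rows),
#'   `degenerate` flag (TRUE when nothing exceeded the threshold).
#' @examples
#' tb <- tibble::tibble(intensity = 1:1000)
#' top_fraction_gate(tb, 0.01)
#' @export
top_fraction_gate <- function(data, q, intensity = intensity) {
  x <- dplyr::pull(data, {{ intensity }})
  if (length(x) == 0) abort("empty droplet table")
  check_number(x, "intensity")
  check_scalar(q, "q", min = .Machine$double.xmin)
  if (q >= 1) abort("`q` must be in (0, 1)")
  thr <- quantile(x, 1 - q, names = FALSE, type = 7)
  sel <- x > thr
  structure(list(mode = "top_fraction", q = q, threshold_used = thr,
                 selected_count = sum(sel), n = length(x), selected = sel,
                 degenerate = !any(sel)),
            class = "sort_gate")
}

#' Gate droplets at a fixed fluorescence threshold
#'
#' @inheritParams top_fraction_gate
#' @param threshold intensity cut; droplets strictly above it are selected.
#' @return a `sort_gate` (see [top_fraction_gate()]); `q` is `NA`.
#' @export
fixed_threshold_gate <- function(data, threshold, intensity = intensity) {
  x <- dplyr::pull(data, {{ intensity }})
  if (length(x) == 0) abort("empty droplet table")
  check_scalar(threshold, "threshold")
  sel <- x > threshold
  structure(list(mode = "fixed_threshold", q = NA_real_,
                 threshold_used = threshold, selected_count = sum(sel),
                 n = length(x), selected = sel, degenerate = !any(sel)),
            class = "sort_gate")
}

#' @export
print.sort_gate <- function(x, ...) {
  cat(sprintf("sort_gate [%s]: threshold %.4g, selected %d / %d (%.3g%%)%s\n",
              x$mode, x$threshold_used, x$selected_count, x$n,
              100 * x$selected_count / x$n,
              if (x$degenerate) "  [degenerate: nothing selected]" else ""))
  invisible(x)
}

#' Fraction of droplets exceeding each fluorescence threshold
#'
#' For a set of ascending intensity cuts, the proportion of droplets
#' strictly above each — the threshold-exceedance summary used to follow
#' activity development over culture days.
#'
#' @inheritParams top_fraction_gate
#' @param thresholds ascending numeric thresholds (e.g.
#'   `c(1000, 2000, 3000, 4000, 5000)`).
#' @return tibble: `threshold`, `fraction` (non-increasing in threshold).
#' @export
fraction_exceeding <- function(data, thresholds, intensity = intensity) {
  x <- dplyr::pull(data, {{ intensity }})
  check_number(thresholds, "thresholds")
  if (is.unsorted(thresholds)) abort("`thresholds` must be sorted ascending")
  tibble(threshold = thresholds,
         fraction = vapply(thresholds, function(t) mean(x > t), numeric(1)))
}

#' Histogram of droplet fluorescence intensities
#'
#' Bin counts over linear or (default) logarithmically spaced bins, the
#' display used on the sorter to locate the empty-droplet peak.
#'
#' @inheritParams top_fraction_gate
#' @param n_bins number of bins.
#' @param log_axis logarithmically spaced bins? Requires strictly positive
#'   intensities.
#' @return tibble: `bin_lo`, `bin_hi`, `bin_mid`, `count`; counts sum to the
#'   number of droplets.
#' @export
intensity_histogram <- function(data, n_bins = 50, log_axis = TRUE,
                                intensity = intensity) {
  x <- dplyr::pull(data, {{ intensity }})
  if (length(x) == 0) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(),
                  bin_mid = numeric(), count = integer()))
  }
  check_number(x, "intensity")
  check_scalar(n_bins, "n_bins", min = 1)
  if (log_axis && any(x <= 0)) {
    abort("log-axis histogram requires strictly positive intensities")
  }
  if (log_axis) {
    edges <- exp(seq(log(min(x)), log(max(x)), length.out = n_bins + 1))
    mids <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  } else {
    edges <- seq(min(x), max(x), length.out = n_bins + 1)
    mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  }
  if (edges[1] == edges[n_bins + 1]) {
    # all values identical: a single bin holds everything
    return(tibble(bin_lo = edges[1], bin_hi = edges[1], bin_mid = edges[1],
                  count = length(x)))
  }
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  tibble(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
         bin_mid = mids, count = counts)
}

#' Strain-content composition of a droplet table before and after a gate
#'
#' Classifies each droplet by which strains it contains (`empty`,
#' `only_<strain>`, or `multiple`) and counts droplets per class before and
#' after applying a [top_fraction_gate()] / [fixed_threshold_gate()].
#'
#' @param data the droplet table the gate was computed from.
#' @param gate a `sort_gate` computed from the same table.
#' @param strain_cols character vector of count column names; defaults to
#'   all integer-count columns other than `droplet_id`.
#' @return tibble: `class`, `n_pre`, `n_post`.
#' @export
gate_composition <- function(data, gate, strain_cols = NULL) {
  stopifnot(inherits(gate, "sort_gate"))
  if (length(gate$selected) != nrow(data)) {
    abort("gate was not computed from this table")
  }
  if (is.null(strain_cols)) {
    strain_cols <- setdiff(names(data), c("droplet_id", "intensity"))
  }
  missing <- setdiff(strain_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("unknown strain column(s): ", paste(missing, collapse = ", ")))
  }
  present <- sapply(strain_cols, function(s) data[[s]] > 0)
  if (is.null(dim(present))) present <- matrix(present, nrow = nrow(data))
  n_strain <- rowSums(present)
  cls <- rep("multiple", nrow(data))
  cls[n_strain == 0] <- "empty"
  for (s in seq_along(strain_cols)) {
    only <- present[, s] & n_strain == 1
    cls[only] <- paste0("only_", strain_cols[s])
  }
  levels <- c("empty", paste0("only_", strain_cols),
              if (length(strain_cols) > 1) "multiple")
  tibble(class = levels,
         n_pre = vapply(levels, function(l) sum(cls == l), integer(1),
                        USE.NAMES = FALSE),
         n_post = vapply(levels, function(l) sum(cls == l & gate$selected),
                         integer(1), USE.NAMES = FALSE))
}

#' Plot a droplet intensity histogram
#'
#' @param hist_tb tibble from [intensity_histogram()].
#' @param gate optional `sort_gate`; its threshold is drawn as a vertical
#'   line.
#' @return a ggplot.
#' @export
plot_intensity_histogram <- function(hist_tb, gate = NULL) {
  p <- ggplot2::ggplot(hist_tb,
                       ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = hist_tb$bin_hi - hist_tb$bin_lo,
                      fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "green fluorescence intensity", y = "droplets")
  if (!is.null(gate)) {
    p <- p + ggplot2::geom_vline(xintercept = gate$threshold_used,
                                 colour = "red", linetype = 2)
  }
  p
}
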