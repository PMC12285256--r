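#' Relative abundance of OTUs in one sample
#'
#' @param data data frame with OTU ids and counts for one sample.
#' @param otu,count columns (unquoted) holding ids and non-negative counts.
#' @return tibble: `otu_id`, `count`, `fraction` (sums to 1).
#' @examples
#' relative_abundance(tibble::tibble(otu_id = c("a", "b"),
#'                                   count = c(10, 30)))
#' @export
relative_abundance <- function(data, otu = otu_id, count = count) {
  ids <- dplyr::pull(data, {{ otu }})
  cnt <- dplyr::pull(data, {{ count }})
  check_number(cnt, "count", min = 0)
  if (anyDuplicated(ids)) abort("duplicate OTU ids")
  total <- sum(cnt)
  if (total <= 0) abort("sample total is zero; cannot normalise")
  tibble(otu_id = ids, count = cnt, fraction = cnt / total)
}

#' Per-OTU enrichment ratios across a droplet sort
#'
#' The enrichment ratio of an OTU is its relative abundance in the
#' post-sorting sample divided by its relative abundance in the
#' post-droplet-cultivation (pre-sort) sample. Ratios above 1 mark taxa
#' concentrated by the activity gate. Amounts are compared as fractions,
#' not raw reads, so differing library depths do not confound the ratio.
#' OTUs absent from the pre-sort sample have an undefined ratio and are
#' flagged rather than pseudocounted by default.
#'
#' @param pre,post data frames with `otu_id` and `count` columns for the
#'   pre-sort and post-sort libraries. The OTU universe is their union;
#'   an OTU missing from one table counts 0 there.
#' @param pseudo_fraction optional small fraction added to both samples'
#'   fractions before the ratio (e.g. `0.5 / depth`); `NULL` (default)
#'   disables it.
#' @return tibble: `otu_id`, `pre_fraction`, `post_fraction`, `ratio`,
#'   `undefined` (TRUE where `pre_fraction` is 0 and no pseudocount used).
#' @examples
#' pre <- tibble::tibble(otu_id = c("a", "b"), count = c(100, 900))
#' post <- tibble::tibble(otu_id = c("a", "b"), count = c(200, 800))
#' enrichment_ratios(pre, post)
#' @export
enrichment_ratios <- function(pre, post, pseudo_fraction = NULL) {
  pre_ra <- relative_abundance(pre)
  post_ra <- relative_abundance(post)
  if (length(intersect(pre_ra$otu_id, post_ra$otu_id)) == 0) {
    abort("pre and post tables share no OTU ids")
  }
  joined <- dplyr::full_join(
    dplyr::select(pre_ra, "otu_id", pre_fraction = "fraction"),
    dplyr::select(post_ra, "otu_id", post_fraction = "fraction"),
    by = "otu_id")
  joined <- tidyr::replace_na(joined,
                              list(pre_fraction = 0, post_fraction = 0))
  if (!is.null(pseudo_fraction)) {
    check_scalar(pseudo_fraction, "pseudo_fraction", min = .Machine$double.xmin)
    joined$pre_fraction <- joined$pre_fraction + pseudo_fraction
    joined$post_fraction <- joined$post_fraction + pseudo_fraction
  }
  dplyr::mutate(joined,
                undefined = .data$pre_fraction == 0,
                ratio = dplyr::if_else(.data$undefined, NA_real_,
                                       .data$post_fraction /
                                         .data$pre_fraction))
}

#' Classify OTUs by enrichment status
#'
#' Exhaustive partition of the OTU universe into enriched (ratio > 1),
#' depleted (ratio < 1), unchanged (ratio exactly 1) and undefined (absent
#' pre-sort). Counts always sum to the number of OTUs.
#'
#' @param results tibble from [enrichment_ratios()].
#' @return tibble: `status`, `n`.
#' @export
classify_enrichment <- function(results) {
  if (nrow(results) == 0) abort("no enrichment results to classify")
  cls <- dplyr::case_when(
    results$undefined ~ "undefined",
    results$ratio > 1 ~ "enriched",
    results$ratio < 1 ~ "depleted",
    TRUE ~ "unchanged")
  levels <- c("enriched", "depleted", "unchanged", "undefined")
  tibble(status = levels,
         n = vapply(levels, function(s) sum(cls == s), integer(1),
                    USE.NAMES = FALSE))
}

#' Plot per-OTU enrichment ratios
#'
#' Log-scale ratio per OTU, coloured by enrichment status; undefined OTUs
#' are dropped with a message.
#'
#' @param results tibble from [enrichment_ratios()].
#' @return a ggplot.
#' @export
plot_enrichment <- function(results) {
  keep <- !results$undefined
  if (any(!keep)) {
    message(sum(!keep), " OTU(s) with undefined ratio omitted from plot")
  }
  tb <- dplyr::mutate(results[keep, ],
                      status = dplyr::if_else(.data$ratio > 1, "enriched",
                                              "depleted"),
                      otu_id = stats::reorder(.data$otu_id, .data$ratio))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$otu_id, y = .data$ratio,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(enriched = "firebrick",
                                          depleted = "steelblue")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment ratio (post / pre)")
}
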