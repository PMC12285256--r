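#' Growth and fluorescence parameters of a simulated strain
#'
#' @param name strain label (used as the count column name in droplet
#'   tables).
#' @param lag_h lag time in hours.
#' @param mu_max_per_h maximum specific growth rate, 1/h.
#' @param y0_od,ymax_od initial and maximal OD600 of the in-droplet culture.
#' @param fluor_rate fluorescence units accumulated per (OD600 x hour) of
#'   biomass exposure — the strain's secreted-protease signal strength.
#' @return a `strain_params` list.
#' @examples
#' strain_params("p_mexicana", lag_h = 8.9, mu_max_per_h = 0.6,
#'               fluor_rate = 60)
#' @export
strain_params <- function(name, lag_h, mu_max_per_h, y0_od = 0.01,
                          ymax_od = 1.5, fluor_rate = 50) {
  stopifnot(is.character(name), nzchar(name))
  check_scalar(lag_h, "lag_h", min = 0)
  check_scalar(mu_max_per_h, "mu_max_per_h", min = 0)
  check_scalar(y0_od, "y0_od", min = .Machine$double.xmin)
  check_scalar(ymax_od, "ymax_od", min = y0_od)
  check_scalar(fluor_rate, "fluor_rate", min = 0)
  structure(list(name = name, lag_h = lag_h, mu_max_per_h = mu_max_per_h,
                 y0_od = y0_od, ymax_od = ymax_od, fluor_rate = fluor_rate),
            class = "strain_params")
}

#' The two model strains used throughout examples and tests
#'
#' A fast protease producer with the short in-droplet lag of
#' Pseudoxanthomonas mexicana (8.9 h) and a slower, weakly proteolytic
#' E. coli-like strain with the longer bulk-type lag (14.3 h).
#'
#' @return named list of two [strain_params()].
#' @export
default_strains <- function() {
  list(
    p_mexicana = strain_params("p_mexicana", lag_h = 8.9,
                               mu_max_per_h = 0.60, y0_od = 0.01,
                               ymax_od = 1.5, fluor_rate = 60),
    e_coli = strain_params("e_coli", lag_h = 14.3, mu_max_per_h = 0.45,
                           y0_od = 0.01, ymax_od = 1.2, fluor_rate = 6)
  )
}

# cumulative OD x time exposure over [0, t] from the Baranyi trajectory;
# trapezoidal integral, fine grid
biomass_exposure <- function(p, culture_time_h, n_grid = 400) {
  tt <- seq(0, culture_time_h, length.out = n_grid)
  od <- exp(baranyi_log_od(tt, p$mu_max_per_h, p$lag_h * p$mu_max_per_h,
                           log(p$y0_od), log(p$ymax_od)))
  sum(diff(tt) * (od[-1] + od[-n_grid]) / 2)
}

#' Simulate a Poisson-loaded droplet screening population
#'
#' Per-strain cell counts are i.i.d. Poisson(`lambda`) per droplet.
#' Fluorescence is a baseline draw (lognormal, emulating the empty-droplet
#' peak at intensity 10–20) plus, for each strain present, a contribution
#' proportional to the strain's accumulated biomass exposure over the
#' culture time under its Baranyi growth trajectory, with per-droplet
#' lognormal jitter.
#'
#' @param n_droplets number of droplets (> 0).
#' @param lambdas named numeric vector, mean cells per droplet per strain;
#'   names must match `strains`.
#' @param strains list of [strain_params()] (e.g. [default_strains()]).
#' @param culture_time_h droplet cultivation time; default 72 h (3 days).
#' @param empty_fluor_meanlog,empty_fluor_sdlog lognormal baseline-intensity
#'   parameters; the defaults put the modal intensity of empty droplets in
#'   the 10–20 band.
#' @param jitter_sdlog lognormal droplet-to-droplet variation of the growth
#'   fluorescence contribution.
#' @param seed integer seed; identical seeds give identical tables.
#' @return tibble (a droplet table): `droplet_id`, one integer count column
#'   per strain, `intensity`.
#' @examples
#' pop <- generate_screen_population(1000, c(p_mexicana = 0.25,
#'                                           e_coli = 0.173), seed = 1)
#' @export
generate_screen_population <- function(n_droplets, lambdas,
                                       strains = default_strains(),
                                       culture_time_h = 72,
                                       empty_fluor_meanlog = log(14),
                                       empty_fluor_sdlog = 0.35,
                                       jitter_sdlog = 0.1,
                                       seed = 1) {
  check_scalar(n_droplets, "n_droplets", min = 1)
  check_number(lambdas, "lambdas", min = 0)
  if (is.null(names(lambdas)) || any(!nzchar(names(lambdas)))) {
    abort("`lambdas` must be a named vector")
  }
  strain_names <- vapply(strains, function(s) s$name, character(1))
  missing <- setdiff(names(lambdas), strain_names)
  if (length(missing) > 0) {
    abort(paste0("no strain parameters for: ", paste(missing, collapse = ", ")))
  }
  n <- as.integer(n_droplets)

  withr::with_seed(seed, {
    counts <- lapply(names(lambdas),
                     function(s) rpois(n, lambdas[[s]]))
    names(counts) <- names(lambdas)
    intensity <- rlnorm(n, empty_fluor_meanlog, empty_fluor_sdlog)
    for (s in names(lambdas)) {
      p <- strains[[match(s, strain_names)]]
      contrib <- p$fluor_rate * biomass_exposure(p, culture_time_h)
      present <- counts[[s]] > 0
      if (any(present)) {
        intensity[present] <- intensity[present] +
          contrib * rlnorm(sum(present), 0, jitter_sdlog)
      }
    }
    dplyr::bind_cols(tibble(droplet_id = seq_len(n)),
                     as_tibble(counts),
                     tibble(intensity = intensity))
  })
}

#' Simulate an OD600 growth time series
#'
#' Baranyi–Roberts trajectory for one strain plus additive Gaussian noise on
#' the OD scale.
#'
#' @param params a [strain_params()].
#' @param times_h sorted sampling times in hours (>= 5 points, all >= 0).
#' @param noise_sd SD of the Gaussian OD noise; absolute OD units for
#'   `noise_type = "additive"`, a fraction of the model value for
#'   `"relative"` (e.g. 0.05 for 5% measurement noise).
#' @param noise_type additive or relative (heteroscedastic) noise.
#' @param seed integer seed.
#' @return tibble: `time_h`, `od600`.
#' @examples
#' generate_growth_series(default_strains()$p_mexicana,
#'                        times_h = seq(0, 48, 4), noise_sd = 0, seed = 1)
#' @export
generate_growth_series <- function(params, times_h, noise_sd = 0,
                                   noise_type = c("additive", "relative"),
                                   seed = 1) {
  noise_type <- match.arg(noise_type)
  stopifnot(inherits(params, "strain_params"))
  check_number(times_h, "times_h", min = 0)
  if (length(times_h) < 5) abort("need at least 5 time points")
  if (is.unsorted(times_h, strictly = TRUE)) abort("times must be strictly increasing")
  check_scalar(noise_sd, "noise_sd", min = 0)
  od <- exp(baranyi_log_od(times_h, params$mu_max_per_h,
                           params$lag_h * params$mu_max_per_h,
                           log(params$y0_od), log(params$ymax_od)))
  if (noise_sd > 0) {
    sdv <- if (noise_type == "additive") noise_sd else noise_sd * od
    od <- withr::with_seed(seed, od + rnorm(length(od), sd = sdv))
    od <- pmax(od, 1e-6)
  }
  tibble(time_h = times_h, od600 = od)
}

#' Simulate paired pre/post-sort OTU count tables
#'
#' The pre-sort (post-droplet-cultivation) sample is multinomial at
#' `depth_pre` over `pre_abundances`; the post-sort sample is multinomial at
#' `depth_post` over abundances proportional to
#' `pre_abundances * enrichment_factors` (renormalised). Configurable
#' per-OTU factors let a scenario mirror a screen where some taxa are
#' enriched (> 1) and others depleted (< 1) by the sort.
#'
#' Because post fractions are renormalised, the expected enrichment ratio of
#' OTU i is `f_i / sum(p * f)`; factors equal the expected ratios exactly
#' only when their pre-abundance-weighted mean is 1. Construct scenario
#' factors that way when a target enriched/depleted split must be recovered.
#'
#' @param pre_abundances probability vector over OTUs (sums to 1).
#' @param enrichment_factors per-OTU positive factors, same length.
#' @param depth_pre,depth_post library sizes (reads) for the two samples.
#' @param otu_ids optional labels; defaults to `otu_001`, ...
#' @param seed integer seed.
#' @return list: `pre` and `post` tibbles (`otu_id`, `count`; column sums
#'   equal the requested depths exactly) and `truth` (per-OTU expected
#'   fractions and factors).
#' @examples
#' generate_otu_tables(c(0.5, 0.5), c(10, 0.1), seed = 1)
#' @export
generate_otu_tables <- function(pre_abundances, enrichment_factors,
                                depth_pre = 1e5, depth_post = 1e5,
                                otu_ids = NULL, seed = 1) {
  check_number(pre_abundances, "pre_abundances", min = 0)
  check_number(enrichment_factors, "enrichment_factors",
               min = .Machine$double.xmin)
  if (length(pre_abundances) != length(enrichment_factors)) {
    abort("`pre_abundances` and `enrichment_factors` lengths differ")
  }
  if (sum(pre_abundances) == 0) abort("all-zero abundance vector")
  if (abs(sum(pre_abundances) - 1) > 1e-9) {
    abort("`pre_abundances` must sum to 1")
  }
  check_scalar(depth_pre, "depth_pre", min = 1)
  check_scalar(depth_post, "depth_post", min = 1)
  k <- length(pre_abundances)
  if (is.null(otu_ids)) otu_ids <- sprintf("otu_%03d", seq_len(k))

  post_p <- pre_abundances * enrichment_factors
  post_p <- post_p / sum(post_p)
  withr::with_seed(seed, {
    pre_counts <- as.integer(rmultinom(1, depth_pre, pre_abundances))
    post_counts <- as.integer(rmultinom(1, depth_post, post_p))
    list(pre = tibble(otu_id = otu_ids, count = pre_counts),
         post = tibble(otu_id = otu_ids, count = post_counts),
         truth = tibble(otu_id = otu_ids,
                        pre_fraction = pre_abundances,
                        expected_post_fraction = post_p,
                        enrichment_factor = enrichment_factors))
  })
}
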