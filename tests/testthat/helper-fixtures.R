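# small, fast rendering geometry shared across image tests:
# 120 um droplet at 1.5 um/px -> radius 40 px in a 112 px frame
small_spec <- function(noise_sd = 0.01) {
  image_spec(width_px = 112, height_px = 112, um_per_px = 1.5,
             noise_sd = noise_sd)
}

pm_params <- function() {
  strain_params("p_mexicana", lag_h = 8.9, mu_max_per_h = 0.6,
                y0_od = 0.01, ymax_od = 1.5, fluor_rate = 60)
}

# 80-OTU scenario with 45 enriched / 35 depleted; factors normalised so
# their pre-abundance-weighted mean is 1 and expected ratios equal them
split_scenario_factors <- function() {
  c(rep(1.5, 45), rep((80 - 45 * 1.5) / 35, 35))
}
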