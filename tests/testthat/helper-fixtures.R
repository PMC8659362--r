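# Shared fixtures, memoised so expensive renders happen once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

field_layout <- function() fixture("layout", build_field_layout("0421"))

# A default-conditions scene render at c = 5 mg/L.
default_render <- function() fixture("render_c5", {
  sc <- synthetic_scene(field_layout(), 5,
                        scene = scene_params(seed = 42))
  render_device_image(sc)
})

# Clean (noise-free, no deposition scatter) render helper.
clean_scene <- function(conc, seed = 1, blank_level = 0.02, ...) {
  synthetic_scene(
    field_layout(), conc,
    kinetics = kinetics_params(blank_level = blank_level),
    scene = scene_params(noise_sd = 0, zone_cv = 0, seed = seed, ...)
  )
}

# Reduced calibration set (6 levels x 3 replicates) quantified and fitted;
# used wherever a working model is needed without the full-size set.
small_calibration <- function() fixture("small_cal", {
  lay <- field_layout()
  cal <- generate_calibration_set(concs = seq(0, 10, 2), replicates = 3,
                                  seed = 11)
  pts <- do.call(rbind, lapply(cal, function(e) {
    data.frame(concentration = e$concentration,
               ari = quantify_device(e$render$image, lay)$ari_mean)
  }))
  fit_calibration(pts)
})

# The generator's effective noiseless ARI-vs-concentration slope over the
# calibrated 0-10 mg/L range (closed form, no rendering).
effective_slope <- function(concs = 0:10) {
  a <- expected_ari(pmb_signal(concs, 3, kinetics_params()), field_layout())
  unname(stats::coef(stats::lm(a ~ concs))[2])
}
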