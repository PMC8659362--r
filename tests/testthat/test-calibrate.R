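test_that("calibration recovers an exact line and reports blank dispersion", {
  pts <- data.frame(concentration = rep(0:10, 2),
                    ari = rep(0.01 * (0:10), 2))
  m <- fit_calibration(pts)
  expect_equal(m$beta1, 0.01, tolerance = 1e-12)
  expect_equal(m$beta0, 0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_true(m$accepted)
  expect_equal(m$valid_range, c(0, 10))
  # c = 0 replicates present -> sigma_blank from them
  expect_equal(m$sigma_blank, 0, tolerance = 1e-12)

  nozero <- data.frame(concentration = c(1, 1, 5, 5, 9, 9),
                       ari = c(0.011, 0.009, 0.051, 0.049, 0.091, 0.089))
  m2 <- fit_calibration(nozero)
  expect_equal(m2$sigma_blank, m2$sigma_resid)

  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 2),
                                          ari = c(0.1, 0.1, 0.2))),
               "3 distinct")
  expect_error(fit_calibration(data.frame(concentration = c(0, 5, 10),
                                          ari = 1:3),
                               form = "log-linear"), "> 0")
})

test_that("a non-increasing response is refused for inversion and limits", {
  pts <- data.frame(concentration = c(0, 0, 5, 5, 10, 10),
                    ari = c(0.10, 0.11, 0.05, 0.06, 0.01, 0.02))
  m <- fit_calibration(pts)
  expect_false(m$accepted)
  expect_error(lod_loq(m), "not accepted")
  expect_error(invert_concentration(m, 0.05), "not accepted")
})

test_that("LOD/LOQ follow the 3.3/10 sigma-over-slope convention", {
  m <- structure(list(beta1 = 0.010, sigma_blank = 0.007, accepted = TRUE),
                 class = "pad_calibration")
  ll <- lod_loq(m)
  expect_equal(ll$lod, 2.31)
  expect_equal(ll$loq, 7.0)
  expect_equal(ll$loq / ll$lod, 10 / 3.3, tolerance = 1e-12)

  m$sigma_blank <- 0
  expect_equal(unlist(lod_loq(m)), c(lod = 0, loq = 0))

  # scale equivariance: doubling both dispersion and slope changes nothing
  m2 <- m
  m2$sigma_blank <- 0.014; m2$beta1 <- 0.020
  m1 <- m
  m1$sigma_blank <- 0.007; m1$beta1 <- 0.010
  expect_equal(lod_loq(m1), lod_loq(m2), tolerance = 1e-12)
})

test_that("inverse prediction is the identity on the fitted line", {
  pts <- data.frame(concentration = rep(0:10, 3),
                    ari = 0.05 + 0.012 * rep(0:10, 3))
  m <- fit_calibration(pts)
  expect_equal(invert_concentration(m, m$beta0)$estimate, 0,
               tolerance = 1e-9)
  expect_equal(invert_concentration(m, m$beta0 + m$beta1 * 5)$estimate, 5,
               tolerance = 1e-9)
  for (cc in c(0.3, 2, 7.7, 10)) {
    est <- invert_concentration(m, m$beta0 + m$beta1 * cc)$estimate
    expect_equal(est, cc, tolerance = 1e-9)
  }
  expect_error(invert_concentration(m, m$beta0 + m$beta1 * 30),
               "not extrapolating")
})

test_that("inverse prediction censors below-LOD estimates without losing them", {
  pts <- data.frame(concentration = rep(0:10, each = 3),
                    ari = 0.05 + 0.012 * rep(0:10, each = 3) +
                      rep(c(-0.004, 0, 0.004), 11))
  m <- fit_calibration(pts)
  ll <- lod_loq(m)
  small <- invert_concentration(m, m$beta0 + m$beta1 * ll$lod * 0.5,
                                ari_sd = 0.01, n = 6)
  expect_true(small$below_lod)
  expect_equal(small$label, "<LOD")
  expect_equal(small$estimate, ll$lod * 0.5, tolerance = 1e-6)
  expect_lt(small$lower, small$estimate)
  expect_gt(small$upper, small$estimate)
})

test_that("round-trip recovery near the quantification limit is accurate", {
  lay <- field_layout()
  m <- small_calibration()
  errs <- vapply(1:20, function(s) {
    sc <- synthetic_scene(lay, 8, scene = scene_params(seed = 3000 + s))
    rd <- quantify_device(render_device_image(sc)$image, lay)
    invert_concentration(m, rd$ari_mean, rd$ari_sd, rd$n_detection)$estimate - 8
  }, 0)
  expect_lte(mean(abs(errs)), 1.5)
})

test_that("bracket classification reproduces the map legend", {
  expect_equal(as.character(classify_level(0.4)), "none")
  expect_equal(as.character(classify_level(5)), "medium")
  # rounding half-up resolves the printed gaps between brackets
  expect_equal(as.character(classify_level(c(3.4, 3.6))), c("low", "medium"))
  expect_equal(as.character(classify_level(c(0.5, 6.4, 6.5))),
               c("low", "medium", "high"))
  # integer boundaries of the printed legend
  ints <- classify_level(0:12)
  expect_equal(max(which(ints == "low")) - 1, 3)   # largest "low" integer
  expect_equal(min(which(ints == "high")) - 1, 7)  # smallest "high" integer
  expect_error(classify_level(-0.1), ">= 0")
})

test_that("bracket classification is monotone in concentration", {
  set.seed(11)
  cs <- sort(runif(200, 0, 15))
  cats <- classify_level(cs)
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("blank equivalence testing matches the Welch formula oracle", {
  r <- blank_equivalence_test(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(r$statistic, 0)
  expect_true(r$indistinguishable)

  r2 <- blank_equivalence_test(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                               c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_false(r2$indistinguishable)

  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1), 0.1, 0.03)
    y <- rnorm(sample(3:9, 1), 0.08, 0.05)
    got <- blank_equivalence_test(x, y)
    # textbook Welch statistic and Welch-Satterthwaite df
    se2 <- var(x) / length(x) + var(y) / length(y)
    t_oracle <- (mean(x) - mean(y)) / sqrt(se2)
    df_oracle <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                            (var(y) / length(y))^2 / (length(y) - 1))
    expect_equal(got$statistic, t_oracle, tolerance = 1e-9)
    expect_equal(got$df, df_oracle, tolerance = 1e-9)
    expect_identical(got$indistinguishable,
                     abs(t_oracle) < qt(0.975, df_oracle))
  }
  expect_error(blank_equivalence_test(1, c(1, 2)), ">= 2")
})

test_that("method comparison agrees after rounding to one significant figure", {
  cm <- compare_methods(c(4.2, 4.2), c(3.8, 5.6))
  expect_equal(cm$table$agree, c(TRUE, FALSE))
  expect_equal(cm$agreement, 0.5)

  set.seed(7)
  pad <- runif(40, 0, 12); ref <- pad + rnorm(40, 0, 1)
  cm2 <- compare_methods(pad, ref)
  expect_equal(cm2$agreement,
               sum(signif(pad, 1) == signif(ref, 1)) / 40)
  expect_error(compare_methods(1:3, 1:4), "equal length")
})

test_that("plateau_time finds the earliest near-plateau sample", {
  t <- seq(0, 5, by = 0.25)
  y <- 1 - exp(-1.5 * t)
  expect_equal(plateau_time(t, y), 2.0)
  expect_equal(plateau_time(1:5, rep(3, 5)), 1)
  expect_error(plateau_time(c(1, 3, 2, 4), 1:4), "increasing")
  expect_error(plateau_time(1:3, 1:3), ">= 4")
  # the generator's default kinetics are stable within the field incubation
  kp <- kinetics_params()
  expect_lte(plateau_time(t, pmb_signal(10, t, kp)), 3)
})

test_that("calibration models persist through JSON", {
  m <- small_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path, provenance = list(seed = 11))
  back <- read_calibration(path)
  expect_equal(back$beta1, m$beta1, tolerance = 1e-12)
  expect_equal(back$sigma_blank, m$sigma_blank, tolerance = 1e-12)
  expect_equal(unlist(lod_loq(back)), unlist(lod_loq(m)), tolerance = 1e-12)
})
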