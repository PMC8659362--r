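#' Fit a concentration--ARI calibration curve
#'
#' Ordinary least-squares fit of ARI on concentration (`form = "linear"`,
#' the default, appropriate over the regulatory-relevant 0--10 mg/L range)
#' or on `log10` concentration (`form = "log-linear"`, for wide-range
#' demonstration sets; requires all concentrations > 0). The blank
#' dispersion `sigma_blank` -- the quantity that sets the detection limit --
#' is estimated from the replicate ARIs at zero concentration when present,
#' otherwise from the fit residuals.
#'
#' @param points data frame with columns `concentration` (mg/L) and `ari`,
#'   one row per replicate device.
#' @param form `"linear"` or `"log-linear"`.
#' @return a `pad_calibration` with `beta0`, `beta1`, `sigma_resid`,
#'   `sigma_blank`, `r_squared`, `valid_range`, `form`, `n`, `accepted`
#'   (FALSE when the fitted slope is non-positive; such a model refuses
#'   inversion).
#' @export
fit_calibration <- function(points, form = c("linear", "log-linear")) {
  form <- match.arg(form)
  if (!all(c("concentration", "ari") %in% names(points))) {
    stop_domain("points must have columns 'concentration' and 'ari'")
  }
  points <- points[is.finite(points$concentration) & is.finite(points$ari), ]
  n_distinct <- length(unique(points$concentration))
  if (n_distinct < 3L) {
    stop_domain("insufficient data: need >= 3 distinct concentrations, got ",
                n_distinct)
  }
  x <- if (form == "log-linear") {
    if (any(points$concentration <= 0)) {
      stop_domain("log-linear form requires all concentrations > 0")
    }
    log10(points$concentration)
  } else {
    points$concentration
  }
  fit <- stats::lm(points$ari ~ x)
  beta0 <- unname(stats::coef(fit)[1])
  beta1 <- unname(stats::coef(fit)[2])
  # noiseless validation sets fit exactly; summary.lm warns about that
  sm <- suppressWarnings(summary(fit))
  sigma_resid <- sm$sigma
  r_squared <- sm$r.squared

  blanks <- points$ari[points$concentration == 0]
  sigma_blank <- if (length(blanks) >= 2L) stats::sd(blanks) else sigma_resid

  structure(
    list(beta0 = beta0, beta1 = beta1,
         sigma_resid = sigma_resid, sigma_blank = sigma_blank,
         r_squared = r_squared,
         valid_range = range(points$concentration),
         form = form, n = nrow(points),
         accepted = is.finite(beta1) && beta1 > 0),
    class = "pad_calibration"
  )
}

#' @export
print.pad_calibration <- function(x, ...) {
  cat(sprintf("PAD calibration (%s), n = %d%s\n", x$form, x$n,
              if (x$accepted) "" else " [NOT ACCEPTED: non-positive slope]"))
  cat(sprintf("  ARI = %.4f + %.5f * %s,  R^2 = %.4f\n", x$beta0, x$beta1,
              if (x$form == "linear") "c" else "log10(c)", x$r_squared))
  cat(sprintf("  sigma_resid = %.5f, sigma_blank = %.5f, valid %g-%g mg/L\n",
              x$sigma_resid, x$sigma_blank,
              x$valid_range[1], x$valid_range[2]))
  if (x$accepted) {
    ll <- lod_loq(x)
    cat(sprintf("  LOD = %.2f mg/L, LOQ = %.2f mg/L (3.3/10 sigma_blank / slope)\n",
                ll$lod, ll$loq))
  }
  invisible(x)
}

#' Limits of detection and quantification
#'
#' ICH-style convention: `LOD = 3.3 * sigma_blank / beta1` and
#' `LOQ = 10 * sigma_blank / beta1`, so `LOQ / LOD = 10 / 3.3` always.
#'
#' @param model an accepted `pad_calibration`.
#' @return list with `lod` and `loq` in mg/L.
#' @examples
#' m <- structure(list(beta1 = 0.010, sigma_blank = 0.007, accepted = TRUE),
#'                class = "pad_calibration")
#' lod_loq(m) # 2.31, 7.0
#' @export
lod_loq <- function(model) {
  if (!isTRUE(model$accepted) || model$beta1 <= 0) {
    stop_domain("calibration not accepted (non-positive slope); cannot compute LOD/LOQ")
  }
  list(lod = 3.3 * model$sigma_blank / model$beta1,
       loq = 10 * model$sigma_blank / model$beta1)
}

#' Inverse prediction: ARI reading to concentration
#'
#' Inverts the calibration, `c_hat = (ari_mean - beta0) / beta1`, with a
#' first-order uncertainty interval propagating the reading's standard
#' error (`ari_sd / sqrt(n)`) and the calibration residual dispersion.
#' Estimates below the LOD keep their numeric value but are labelled
#' `"<LOD"` for human-facing output. Readings above the calibrated response
#' range are refused -- the curve is not extrapolated.
#'
#' @param model an accepted `pad_calibration`.
#' @param ari_mean mean ARI over the detection zones.
#' @param ari_sd standard deviation over the detection zones (optional).
#' @param n number of detection zones averaged (optional).
#' @param level coverage of the interval.
#' @return list with `estimate` (mg/L), `lower`, `upper`, `se`,
#'   `below_lod`, `below_loq`, `label`.
#' @export
invert_concentration <- function(model, ari_mean, ari_sd = NA, n = NA,
                                 level = 0.95) {
  if (!isTRUE(model$accepted)) {
    stop_domain("calibration not accepted; refusing inversion")
  }
  if (model$form != "linear") {
    stop_domain("inversion is implemented for the linear form")
  }
  ari_max <- model$beta0 + model$beta1 * model$valid_range[2]
  if (ari_mean > ari_max + 3 * model$sigma_resid) {
    stop_domain(sprintf(
      "ARI %.4f above the calibrated response at %g mg/L; not extrapolating",
      ari_mean, model$valid_range[2]))
  }
  est <- (ari_mean - model$beta0) / model$beta1
  var_ari <- model$sigma_resid^2
  if (is.finite(ari_sd) && is.finite(n) && n > 0) {
    var_ari <- var_ari + ari_sd^2 / n
  }
  se <- sqrt(var_ari) / model$beta1
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ll <- lod_loq(model)
  below_lod <- est < ll$lod
  list(estimate = est, lower = est - zq * se, upper = est + zq * se, se = se,
       below_lod = below_lod, below_loq = est < ll$loq,
       label = if (below_lod) "<LOD" else sprintf("%.2f mg/L", est))
}

#' Classify a concentration into the four map brackets
#'
#' The public map legend brackets: none (< 1 mg/L), low (1--3), medium
#' (4--6), high (>= 7). The printed brackets are integer-valued, leaving
#' (3, 4) and (6, 7) open; concentrations are therefore rounded half-up to
#' the nearest integer before bracketing, so 3.4 is low and 3.6 is medium.
#'
#' @param c concentration(s) in mg/L (>= 0).
#' @return ordered factor with levels `none < low < medium < high`.
#' @examples
#' classify_level(c(0.4, 2, 5, 9))
#' @export
classify_level <- function(c) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop_domain("concentrations must be finite and >= 0")
  }
  k <- floor(c + 0.5) # round half-up
  lab <- ifelse(k <= 0, "none",
                ifelse(k <= 3, "low",
                       ifelse(k <= 6, "medium", "high")))
  factor(lab, levels = c("none", "low", "medium", "high"), ordered = TRUE)
}

#' Bracket colours used for map pins
#' @return named character vector of hex colours.
#' @export
level_palette <- function() {
  c(none = "#2ecc71", low = "#f1c40f", medium = "#e67e22", high = "#e74c3c")
}

#' Test whether a sample reads as a blank
#'
#' Two-sample two-tailed t-test (Welch by default -- the unequal-variance
#' form is the safer choice when blank and sample dispersions differ)
#' comparing a sample's ARI replicates to blank replicates. The verdict is
#' "indistinguishable from blank" when |t| is below the critical value at
#' the given alpha.
#'
#' @param sample_aris,blank_aris numeric vectors, each of length >= 2.
#' @param alpha significance level.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list with `statistic`, `df`, `t_crit`, `p_value`,
#'   `indistinguishable` (logical verdict).
#' @export
blank_equivalence_test <- function(sample_aris, blank_aris, alpha = 0.05,
                                   var_equal = FALSE) {
  if (length(sample_aris) < 2L || length(blank_aris) < 2L) {
    stop_domain("need >= 2 values in each group")
  }
  if (stats::sd(sample_aris) == 0 && stats::sd(blank_aris) == 0) {
    # degenerate constant groups: identical -> t = 0, else infinite t
    same <- isTRUE(all.equal(mean(sample_aris), mean(blank_aris)))
    df <- length(sample_aris) + length(blank_aris) - 2
    tc <- stats::qt(1 - alpha / 2, df)
    return(list(statistic = if (same) 0 else Inf, df = df, t_crit = tc,
                p_value = if (same) 1 else 0, indistinguishable = same))
  }
  ht <- stats::t.test(sample_aris, blank_aris, var.equal = var_equal,
                      alternative = "two.sided")
  tc <- stats::qt(1 - alpha / 2, unname(ht$parameter))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       t_crit = tc, p_value = ht$p.value,
       indistinguishable = abs(unname(ht$statistic)) < tc)
}

#' Compare paired PAD and reference-method estimates
#'
#' The field device is semi-quantitative: agreement with the laboratory
#' reference (UV/vis) is judged after rounding both estimates to one
#' significant figure.
#'
#' @param pad_estimates,reference_estimates equal-length numeric vectors
#'   of paired concentration estimates, mg/L.
#' @return list with `table` (per-pair values, 1 s.f. roundings, agreement
#'   flag) and `agreement` (fraction of pairs agreeing).
#' @export
compare_methods <- function(pad_estimates, reference_estimates) {
  if (length(pad_estimates) != length(reference_estimates)) {
    stop_domain("paired lists must have equal length")
  }
  tab <- data.frame(
    pad = pad_estimates,
    reference = reference_estimates,
    pad_1sf = signif(pad_estimates, 1),
    reference_1sf = signif(reference_estimates, 1)
  )
  tab$agree <- tab$pad_1sf == tab$reference_1sf
  list(table = tab, agreement = mean(tab$agree))
}

#' Time at which a colour-development curve reaches its plateau
#'
#' The plateau level is estimated as the mean of the last two intensity
#' values; the plateau time is the earliest sampled time at which intensity
#' reaches `(1 - tolerance)` of that level. Used to confirm that the
#' assay's colour is stable within the chosen field incubation time.
#'
#' @param t sampling times, minutes, strictly increasing (>= 4 points).
#' @param intensity colour intensities at `t`.
#' @param tolerance fractional distance from the plateau, default 0.05.
#' @return plateau time in minutes.
#' @export
plateau_time <- function(t, intensity, tolerance = 0.05) {
  if (length(t) < 4L || length(t) != length(intensity)) {
    stop_domain("need >= 4 (t, intensity) pairs of equal length")
  }
  if (any(diff(t) <= 0)) stop_domain("t must be strictly increasing")
  plateau <- mean(utils::tail(intensity, 2))
  hit <- which(intensity >= (1 - tolerance) * plateau)
  if (length(hit) == 0L) return(t[length(t)])
  t[hit[1]]
}

#' Persist / load a calibration model as JSON
#'
#' @param model a `pad_calibration`.
#' @param path file path.
#' @param provenance optional list (input hash, seed, ...) stored verbatim.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   a `pad_calibration`.
#' @export
write_calibration <- function(model, path, provenance = NULL) {
  doc <- unclass(model)
  doc$provenance <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                      provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$provenance <- NULL
  doc$valid_range <- as.numeric(doc$valid_range)
  structure(doc, class = "pad_calibration")
}
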