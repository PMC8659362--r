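#' Colour-development kinetics parameters
#'
#' Parameters of the generator's model for phosphomolybdenum-blue (PMB)
#' colour development on the paper device: a saturating (Michaelis-type)
#' dose response in phosphate concentration crossed with first-order
#' development in time,
#' \deqn{S(c, t) = b + a_{max} \frac{c}{c + K} (1 - e^{-k t}),}
#' where `S` is the fractional reflectance deficit of the zone (0 = white
#' paper, 1 = fully dark). The defaults plateau by 2--3 minutes
#' (`1 - exp(-1.5 * 3) = 0.989`) and are near-linear below ~10 mg/L,
#' matching the observed development time course of the assay.
#'
#' @param a_max maximum colour signal, in (0, 1].
#' @param K_half concentration of half-maximal colour, mg/L.
#' @param k_rate first-order development rate, 1/min.
#' @param blank_level reagent background signal at zero phosphate
#'   (present only in reagent-loaded zones).
#' @return a `pad_kinetics` parameter list.
#' @export
kinetics_params <- function(a_max = 0.55, K_half = 40, k_rate = 1.5,
                            blank_level = 0.02) {
  stopifnot(a_max > 0, a_max <= 1, K_half > 0, k_rate > 0,
            blank_level >= 0, blank_level < a_max)
  structure(list(a_max = a_max, K_half = K_half, k_rate = k_rate,
                 blank_level = blank_level),
            class = "pad_kinetics")
}

#' PMB colour signal at a given concentration and incubation time
#'
#' @param c phosphate concentration, mg/L (>= 0).
#' @param t incubation time, minutes (>= 0). `c` and `t` are recycled.
#' @param kp a [kinetics_params()] object.
#' @return signal in `[0, 1]`: `blank_level + a_max * c/(c + K_half) *
#'   (1 - exp(-k_rate * t))`; monotone non-decreasing in both arguments.
#' @examples
#' pmb_signal(10, 3, kinetics_params())
#' @export
pmb_signal <- function(c, t, kp = kinetics_params()) {
  if (any(c < 0)) stop_domain("concentration must be >= 0")
  if (any(t < 0)) stop_domain("incubation time must be >= 0")
  kp$blank_level + kp$a_max * (c / (c + kp$K_half)) * (1 - exp(-kp$k_rate * t))
}

#' Signal of a slow-reacting interferent (silicate)
#'
#' Silicate forms the analogous heteropoly blue complex but over much longer
#' timescales, so within the 3-minute field incubation it contributes almost
#' nothing. Modelled with the same functional form as [pmb_signal()] with
#' the development rate scaled down by `rate_multiplier`; at the default
#' multiplier, 1000 mg/L silicate after 3 min sits within 0.02 of the blank
#' level, i.e. it is read as a blank.
#'
#' @param c_int interferent concentration, mg/L.
#' @param t incubation time, minutes.
#' @param kp a [kinetics_params()] object.
#' @param rate_multiplier fractional slowdown of the development rate,
#'   in (0, 1).
#' @return signal in `[0, 1]`.
#' @export
interferent_signal <- function(c_int, t, kp = kinetics_params(),
                               rate_multiplier = 0.008) {
  if (rate_multiplier <= 0 || rate_multiplier >= 1) {
    stop_domain("rate_multiplier must lie in (0, 1)")
  }
  kp2 <- kp
  kp2$k_rate <- kp$k_rate * rate_multiplier
  pmb_signal(c_int, t, kp2)
}

#' Imaging and illumination parameters of one synthetic capture
#'
#' Describes how a device is photographed: overall gain and a left-to-right
#' gain gradient (uneven illumination), an additive sensor offset, a water
#' tint added inside every porous zone (the colour cast a pigmented or
#' turbid sample leaves on the wet paper; signed 8-bit counts per channel,
#' negative values darken), per-pixel Gaussian noise, raster scale, an
#' in-plane rotation, and a per-zone reagent-deposition variability
#' (`zone_cv`, the coefficient of variation of the deposited signal between
#' zones -- the dominant source of zone-to-zone scatter on real devices).
#'
#' @param gain multiplicative illumination factor (> 0).
#' @param gain_gradient fractional gain change across the image width.
#' @param offset additive intensity offset, 8-bit counts.
#' @param water_tint length-3 signed per-channel cast inside porous zones.
#' @param noise_sd per-pixel Gaussian noise SD, 8-bit counts.
#' @param pixels_per_mm raster scale.
#' @param rotation in-plane rotation, degrees (|rotation| <= 10).
#' @param zone_cv per-zone deposition coefficient of variation.
#' @param seed integer seed; all randomness in rendering derives from it.
#' @return a `pad_scene_params` list.
#' @export
scene_params <- function(gain = 1, gain_gradient = 0, offset = 0,
                         water_tint = c(0, 0, 0), noise_sd = 6,
                         pixels_per_mm = 5, rotation = 0,
                         zone_cv = 0.12, seed = 1L) {
  stopifnot(gain > 0, noise_sd >= 0, pixels_per_mm > 0,
            abs(rotation) <= 10, zone_cv >= 0, length(water_tint) == 3L)
  structure(list(gain = gain, gain_gradient = gain_gradient, offset = offset,
                 water_tint = as.numeric(water_tint), noise_sd = noise_sd,
                 pixels_per_mm = pixels_per_mm, rotation = rotation,
                 zone_cv = zone_cv, seed = as.integer(seed)),
            class = "pad_scene_params")
}

#' Assemble a ground-truthed synthetic scene
#'
#' Combines a device layout, a true phosphate concentration, incubation
#' time, kinetics and capture parameters into a renderable scene. The
#' per-zone noiseless truth signals are drawn here (deposition variability
#' from the scene seed): detection zones carry `S(c, t)` times a per-zone
#' deposition factor, blank zones -- which hold no reagent -- carry zero.
#'
#' @param layout a `pad_layout`.
#' @param concentration true phosphate concentration, mg/L.
#' @param incubation incubation time, minutes.
#' @param kinetics a [kinetics_params()] object.
#' @param scene a [scene_params()] object.
#' @param interferent optional `list(species=, concentration=,
#'   rate_multiplier=)` adding a slow interferent signal to detection zones.
#' @param a_max_attenuation multiplier on `a_max` emulating reagent decay
#'   after long ambient storage (1 = fresh device).
#' @return a `pad_scene` with a `truth` data frame (one row per zone).
#' @export
synthetic_scene <- function(layout, concentration, incubation = 3,
                            kinetics = kinetics_params(),
                            scene = scene_params(),
                            interferent = NULL,
                            a_max_attenuation = 1) {
  if (concentration < 0) stop_domain("concentration must be >= 0")
  if (incubation < 0) stop_domain("incubation must be >= 0")
  kp <- kinetics
  kp$a_max <- kp$a_max * a_max_attenuation
  s_det <- pmb_signal(concentration, incubation, kp)
  if (!is.null(interferent)) {
    s_det <- s_det +
      (interferent_signal(interferent$concentration, incubation, kp,
                          interferent$rate_multiplier %||% 0.008) -
         kp$blank_level)
  }
  eta <- with_seed(derive_seed(scene$seed, 101L),
                   stats::rnorm(nrow(layout$zones), 0, scene$zone_cv))
  truth <- layout$zones[, c("zone_id", "role")]
  truth$signal <- ifelse(truth$role == "detection",
                         clamp(s_det * (1 + eta), 0, 1), 0)
  structure(
    list(layout = layout, concentration = concentration,
         incubation = incubation, kinetics = kinetics, scene = scene,
         interferent = interferent, a_max_attenuation = a_max_attenuation,
         truth = truth),
    class = "pad_scene"
  )
}

#' Render a synthetic device photograph
#'
#' Paints the device onto an 8-bit RGB canvas: white laminate over a grey
#' background, dark wax box border and zone rings, porous zone interiors
#' with the blue complex (red and green channels attenuated by `1 - S`,
#' blue by `1 - 0.15 S`), the water tint added inside every porous zone,
#' and the printed blue internal-standard square. The whole frame is then
#' multiplied by the gain field, offset, perturbed with Gaussian noise,
#' clipped to `[0, 255]` and quantised. Rendering is bit-identical for a
#' fixed scene seed.
#'
#' @param scene a [synthetic_scene()].
#' @param margin_mm background margin around the laminate.
#' @param paper_white 8-bit value of the dry laminated paper.
#' @param wax_gray 8-bit value of the printed wax.
#' @param bg_gray 8-bit value of the background surface.
#' @param ring_width_mm width of the dark ring drawn on the zone boundary.
#' @return list with `image` (H x W x 3 integer-valued array, 0--255) and
#'   `truth` (zone centres in pixel coordinates, per-zone signals, scale,
#'   rotation, concentration and seed).
#' @export
render_device_image <- function(scene, margin_mm = 6, paper_white = 235,
                                wax_gray = 60, bg_gray = 205,
                                ring_width_mm = 0.8) {
  lay <- scene$layout
  sp <- scene$scene
  s <- sp$pixels_per_mm
  lw <- lay$laminate_size[1]
  lh <- lay$laminate_size[2]
  W <- as.integer(round((lw + 2 * margin_mm) * s))
  H <- as.integer(round((lh + 2 * margin_mm) * s))
  if (W < 8L || H < 8L) stop_domain("image too small to contain the layout")

  # pixel-centre coordinates in the image frame (mm, origin at laminate TL)
  xs <- (seq_len(W) - 0.5) / s - margin_mm
  ys <- (seq_len(H) - 0.5) / s - margin_mm
  X <- matrix(xs, nrow = H, ncol = W, byrow = TRUE)
  Y <- matrix(ys, nrow = H, ncol = W)

  # map image frame -> device frame (device rotated by +rotation about the
  # laminate centre within the image)
  th <- sp$rotation * pi / 180
  cx0 <- lw / 2; cy0 <- lh / 2
  U <- cos(th) * (X - cx0) + sin(th) * (Y - cy0) + cx0
  V <- -sin(th) * (X - cx0) + cos(th) * (Y - cy0) + cy0

  R <- matrix(bg_gray, H, W); G <- matrix(bg_gray, H, W)
  B <- matrix(bg_gray, H, W)

  on_lam <- U >= 0 & U <= lw & V >= 0 & V <= lh
  R[on_lam] <- paper_white; G[on_lam] <- paper_white; B[on_lam] <- paper_white

  # wax box border (band of width 1 mm centred on the rectangle outline)
  wb <- lay$wax_box
  bw <- 0.5
  in_rect <- function(u, v, rect, grow) {
    u >= rect[1] - grow & u <= rect[1] + rect[3] + grow &
      v >= rect[2] - grow & v <= rect[2] + rect[4] + grow
  }
  box_band <- in_rect(U, V, wb, bw) & !in_rect(U, V, wb, -bw)
  R[box_band] <- wax_gray; G[box_band] <- wax_gray; B[box_band] <- wax_gray

  # zones: wax ring + porous interior
  tint <- sp$water_tint
  hw <- ring_width_mm / 2
  for (i in seq_len(nrow(lay$zones))) {
    z <- lay$zones[i, ]
    rad <- z$diameter / 2
    d <- sqrt((U - z$cx)^2 + (V - z$cy)^2)
    ring <- abs(d - rad) <= hw
    R[ring] <- wax_gray; G[ring] <- wax_gray; B[ring] <- wax_gray
    interior <- d < rad - hw
    sg <- scene$truth$signal[scene$truth$zone_id == z$zone_id]
    R[interior] <- paper_white * (1 - sg) + tint[1]
    G[interior] <- paper_white * (1 - sg) + tint[2]
    B[interior] <- paper_white * (1 - 0.15 * sg) + tint[3]
  }

  # internal-standard square
  rs <- lay$ref_square
  sq <- in_rect(U, V, rs$rect, 0)
  R[sq] <- rs$rgb[1]; G[sq] <- rs$rgb[2]; B[sq] <- rs$rgb[3]

  # illumination field in the camera frame, offset, noise
  gfield <- sp$gain * (1 + sp$gain_gradient *
                         (matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE) - 0.5))
  R <- R * gfield + sp$offset
  G <- G * gfield + sp$offset
  B <- B * gfield + sp$offset
  if (sp$noise_sd > 0) {
    noise <- with_seed(derive_seed(sp$seed, 202L),
                       stats::rnorm(3 * H * W, 0, sp$noise_sd))
    R <- R + matrix(noise[seq_len(H * W)], H, W)
    G <- G + matrix(noise[H * W + seq_len(H * W)], H, W)
    B <- B + matrix(noise[2 * H * W + seq_len(H * W)], H, W)
  }
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- round(clamp(R, 0, 255))
  img[, , 2] <- round(clamp(G, 0, 255))
  img[, , 3] <- round(clamp(B, 0, 255))

  # ground-truth zone centres in pixel coordinates (device -> image frame)
  zc <- lay$zones
  px <- cos(th) * (zc$cx - cx0) - sin(th) * (zc$cy - cy0) + cx0
  py <- sin(th) * (zc$cx - cx0) + cos(th) * (zc$cy - cy0) + cy0
  truth <- scene$truth
  truth$cx_px <- (px + margin_mm) * s
  truth$cy_px <- (py + margin_mm) * s

  list(
    image = img,
    truth = list(
      zones = truth,
      concentration = scene$concentration,
      incubation = scene$incubation,
      pixels_per_mm = s,
      rotation = sp$rotation,
      seed = sp$seed
    )
  )
}

#' Write a rendered scene as PNG with a ground-truth sidecar
#'
#' @param render output of [render_device_image()].
#' @param path PNG path; the truth annotation is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(render, path) {
  png::writePNG(render$image / 255, path)
  jsonlite::write_json(render$truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an 8-bit RGB device photograph
#'
#' Supports PNG and TIFF (and anything EBImage can decode, e.g. JPEG).
#' Returns an H x W x 3 array of 8-bit values.
#'
#' @param path image file.
#' @return numeric array, dimensions height x width x 3, values 0--255.
#' @export
read_device_image <- function(path) {
  if (!file.exists(path)) stop_domain("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_domain("reading TIFF requires the 'tiff' package")
    }
    a <- tiff::readTIFF(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- aperm(a, c(2, 1, 3)) # EBImage stores x,y; we use row = y
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' Generate a seeded synthetic calibration set
#'
#' Renders `length(concs) * replicates` device images at known
#' concentrations, each with an independent seed-derived noise stream --
#' the synthetic counterpart of photographing replicate devices dipped in
#' phosphate standards.
#'
#' @param concs concentrations of the standards, mg/L.
#' @param replicates devices per concentration.
#' @param layout a `pad_layout`; default field layout.
#' @param incubation incubation time, minutes.
#' @param kinetics a [kinetics_params()] object.
#' @param template a [scene_params()] object; its seed field is replaced by
#'   the per-image derived seeds.
#' @param seed master seed for the whole set.
#' @return list of entries, each with `concentration`, `scene`, `render`.
#' @export
generate_calibration_set <- function(concs = 0:10, replicates = 6,
                                     layout = build_field_layout("0421"),
                                     incubation = 3,
                                     kinetics = kinetics_params(),
                                     template = scene_params(),
                                     seed = 1L) {
  if (length(concs) == 0L) stop_domain("concs must be non-empty")
  if (replicates < 1L) stop_domain("replicates must be >= 1")
  grid <- expand.grid(rep = seq_len(replicates), conc = concs)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- template
    sp$seed <- derive_seed(seed, i)
    sc <- synthetic_scene(layout, grid$conc[i], incubation = incubation,
                          kinetics = kinetics, scene = sp)
    out[[i]] <- list(concentration = grid$conc[i], scene = sc,
                     render = render_device_image(sc))
  }
  out
}

#' Generate a synthetic citizen-sampling campaign
#'
#' Produces `n` geolocated sampling records with rendered device images and
#' known true concentrations. Sampling points are scattered uniformly in
#' the bounding box, timestamps uniformly over the date range, and true
#' concentrations follow a lognormal baseline modulated by a sinusoidal
#' seasonal term peaking in late July:
#' `log c = log(median) + amplitude * sin(2 pi (doy - 121) / 365) + eps`.
#' Capture conditions (gain, gradient, offset, rotation) vary per record.
#'
#' @param n number of records.
#' @param bbox `c(west, south, east, north)` in decimal degrees.
#' @param date_range length-2 `Date` (or coercible) vector.
#' @param seasonal_amplitude amplitude of the seasonal term on the log
#'   scale (0 = no seasonality).
#' @param median_conc median concentration of the lognormal baseline, mg/L.
#' @param sdlog lognormal dispersion of the baseline.
#' @param layout a `pad_layout` template (each record gets its own code).
#' @param template a [scene_params()] capture template.
#' @param tinted_fraction fraction of records whose water leaves a visible
#'   tint on the porous zones (pigmented/turbid samples).
#' @param seed master seed.
#' @param render_images render a device image per record (set `FALSE` for
#'   record-level work where only the sampling design and ground truth are
#'   needed; `renders` is then empty).
#' @param dir optional directory; when given, images and the records CSV
#'   are written there (`records.csv`, `img_<record_id>.png` + sidecars).
#' @return list with `records` (data frame in the campaign CSV schema plus
#'   `true_concentration`), `renders` (list of rendered images + truth) and
#'   `layouts` (per-record `pad_layout`).
#' @export
generate_campaign <- function(n, bbox = c(-1.2, 53.5, 0.2, 54.2),
                              date_range = as.Date(c("2020-01-01", "2020-12-31")),
                              seasonal_amplitude = 0.5,
                              median_conc = 3, sdlog = 0.6,
                              layout = build_field_layout("0421"),
                              template = scene_params(),
                              tinted_fraction = 0,
                              seed = 1L, render_images = TRUE, dir = NULL) {
  if (n < 1L) stop_domain("n must be >= 1")
  if (!(bbox[1] < bbox[3]) || !(bbox[2] < bbox[4])) {
    stop_domain("invalid bbox: need west < east and south < north")
  }
  date_range <- as.Date(date_range)
  if (any(is.na(date_range)) || date_range[1] > date_range[2]) {
    stop_domain("invalid or empty date range")
  }
  draws <- with_seed(derive_seed(seed, 7L), {
    lon <- stats::runif(n, bbox[1], bbox[3])
    lat <- stats::runif(n, bbox[2], bbox[4])
    day <- as.Date(stats::runif(
      n, as.numeric(date_range[1]), as.numeric(date_range[2])),
      origin = "1970-01-01")
    tod <- stats::runif(n, 8 * 3600, 18 * 3600) # daylight sampling
    doy <- as.integer(format(day, "%j"))
    eps <- stats::rnorm(n, 0, sdlog)
    conc <- exp(log(median_conc) +
                  seasonal_amplitude * sin(2 * pi * (doy - 121) / 365) + eps)
    code <- sprintf("%04d", sample.int(10000L, n, replace = FALSE) - 1L)
    # smartphone capture of a flat device under diffuse daylight: wide
    # overall gain variation (cancelled exactly by the internal standard)
    # but bounded above -- autoexposure keeps the white laminate off the
    # 255 rail -- and only mild illumination gradients and black-level
    # offsets, which Eq-1-style normalization cannot remove
    gain <- stats::runif(n, 0.80, 1.02)
    grad <- stats::runif(n, -0.02, 0.02)
    offs <- stats::runif(n, -2, 2)
    rot <- stats::runif(n, -5, 5)
    tinted <- stats::runif(n) < tinted_fraction
    user_err <- stats::rnorm(n, 0, 1)
    waterbody <- sample(c("Pocklington Canal", "River Aire", "River Hull",
                          "Market Weighton Canal", "Leven Canal"),
                        n, replace = TRUE)
    list(lon = lon, lat = lat, day = day, tod = tod, conc = conc,
         code = code, gain = gain, grad = grad, offs = offs, rot = rot,
         tinted = tinted, user_err = user_err, waterbody = waterbody)
  })

  ts <- as.POSIXct(draws$day, tz = "UTC") + draws$tod
  record_id <- sprintf("R%05d", seq_len(n))
  records <- data.frame(
    record_id = record_id,
    device_code = draws$code,
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%S+00:00"),
    lat = draws$lat,
    lon = draws$lon,
    waterbody = draws$waterbody,
    incubation_s = rep(180L, n),
    image_path = sprintf("img_%s.png", record_id),
    user_level = pmin(10L, pmax(0L, as.integer(round(draws$conc + draws$user_err)))),
    notes = "",
    true_concentration = draws$conc,
    stringsAsFactors = FALSE
  )

  renders <- if (render_images) vector("list", n) else list()
  layouts <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- template
    sp$gain <- draws$gain[i]
    sp$gain_gradient <- draws$grad[i]
    sp$offset <- draws$offs[i]
    sp$rotation <- draws$rot[i]
    if (draws$tinted[i]) sp$water_tint <- c(-25, -10, -35)
    sp$seed <- derive_seed(seed, 1000L + i)
    lay <- layout
    lay$device_code <- draws$code[i]
    layouts[[i]] <- lay
    if (render_images) {
      sc <- synthetic_scene(lay, draws$conc[i], scene = sp)
      renders[[i]] <- render_device_image(sc)
    }
  }
  if (render_images) names(renders) <- record_id
  names(layouts) <- record_id

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (render_images) {
      for (i in seq_len(n)) {
        write_scene_png(renders[[i]], file.path(dir, records$image_path[i]))
      }
    }
    utils::write.csv(records[, setdiff(names(records), "true_concentration")],
                     file.path(dir, "records.csv"), row.names = FALSE)
  }
  list(records = records, renders = renders, layouts = layouts)
}

#' Expected noiseless ARI of the generator's rendering model
#'
#' Closed-form ARI that the quantifier recovers from a noiseless, unit-gain
#' rendering: the zone-vs-blank luma deficit divided by the
#' internal-standard luma. Used as the generator-truth reference in
#' calibration-recovery checks.
#'
#' @param signal noiseless zone signal(s) `S`.
#' @param layout a `pad_layout` (for the reference-square colour).
#' @param paper_white 8-bit paper value used in rendering.
#' @return expected ARI value(s).
#' @export
expected_ari <- function(signal, layout = build_field_layout("0421"),
                         paper_white = 235) {
  rgbv <- layout$ref_square$rgb
  ref_luma <- luma601(rgbv[1], rgbv[2], rgbv[3])
  deficit <- paper_white * ((0.299 + 0.587) * signal + 0.114 * 0.15 * signal)
  deficit / ref_luma
}
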