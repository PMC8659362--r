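#' Grayscale (Rec.601 luma) of an 8-bit RGB image array
#'
#' @param image H x W x 3 array, values 0--255.
#' @return H x W matrix of luma values, 0--255.
#' @export
image_gray <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop_domain("image must be an H x W x 3 array")
  }
  luma601(image[, , 1], image[, , 2], image[, , 3])
}

#' Average intensity (AI) over a pixel mask
#'
#' The zone intensity statistic: the mean over the mask of
#' `255 - grayscale`, where grayscale is the Rec.601 luma of the RGB
#' triplet. More colour development (a darker zone) gives a larger AI.
#'
#' @param image H x W x 3 array, values 0--255.
#' @param mask integer matrix with columns `row`, `col` (as produced by
#'   [zone_mask()]).
#' @return the AI value (unitless counts in `[0, 255]`).
#' @export
mean_intensity <- function(image, mask) {
  255 - mean_luma(image, mask)
}

# Mean raw luma over a mask, with bounds checking.
mean_luma <- function(image, mask) {
  if (is.null(dim(mask)) || nrow(mask) == 0L) stop_domain("empty mask")
  d <- dim(image)
  if (any(mask[, 1] < 1L) || any(mask[, 1] > d[1]) ||
      any(mask[, 2] < 1L) || any(mask[, 2] > d[2])) {
    stop_domain("mask extends outside the image bounds")
  }
  idx <- cbind(mask[, 1], mask[, 2])
  mean(luma601(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx]))
}

#' Average relative intensity (ARI)
#'
#' The internally standardised readout of one detection zone:
#' `ARI = (AI_reaction - AI_blank) / AI_ref`. The blank subtraction removes
#' the colour the water itself leaves on the porous paper; the division by
#' the internal-standard intensity removes the capture's illumination gain,
#' so readings from different cameras and lighting are comparable.
#'
#' @param ai_reaction AI of a detection zone.
#' @param ai_blank AI of the blank zones (their mean).
#' @param ai_ref intensity of the internal-standard square (> 0).
#' @return the ARI value; may be negative on noisy input when a blank reads
#'   darker than a reaction zone.
#' @examples
#' compute_ari(120, 20, 200) # 0.5
#' @export
compute_ari <- function(ai_reaction, ai_blank, ai_ref) {
  if (any(!is.finite(ai_ref)) || any(ai_ref <= 0)) {
    stop_domain("AI_ref must be > 0 (reference square not found or washed out)")
  }
  (ai_reaction - ai_blank) / ai_ref
}

#' Locate the layout's zones in a photograph
#'
#' Detects the dark wax rings printed around the zones (threshold on the
#' grayscale image, connected components, shape/size/colour filters -- the
#' blue internal standard is rejected by its blueness, the wax box outline
#' by its size), then fits a similarity transform (scale, rotation,
#' translation) mapping the layout's zone centres onto the detected ring
#' centroids. Zone identities -- and hence the detection/blank role of each
#' circle -- are inherited from the layout through the fit, never inferred
#' from colour.
#'
#' @param image H x W x 3 array, values 0--255.
#' @param layout a `pad_layout`.
#' @param dark_threshold grayscale value below which a pixel is wax.
#' @param residual_threshold maximum tolerated mean distance (px) between
#'   fitted and detected centres before an alignment error is raised.
#' @return list with `zones` (data frame: `zone_id`, `role`, `cx`, `cy` in
#'   pixel coordinates -- the fitted centres), `detected` (matched raw
#'   centroids), `pixels_per_mm`, `rotation` (degrees), `residual_px`, and
#'   `transform` (the fitted `list(scale, theta, tx, ty)` mapping layout mm
#'   to image px).
#' @export
locate_zones <- function(image, layout, dark_threshold = 130,
                         residual_threshold = 3) {
  gray <- image_gray(image)
  dark <- gray < dark_threshold
  labels <- EBImage::bwlabel(dark)
  nlab <- max(labels)
  if (nlab == 0L) {
    stop_domain("zone detection failed: found 0 dark components ",
                "(expected ", nrow(layout$zones), " wax rings)")
  }

  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  size <- tabulate(lab, nlab)
  # centroids in edge-based pixel coordinates (pixel (i, j) centre at
  # (j - 0.5, i - 0.5)), matching the renderer's truth convention
  cx <- tapply(cols, lab, mean) - 0.5
  cy <- tapply(rows, lab, mean) - 0.5
  w <- tapply(cols, lab, function(v) diff(range(v)) + 1)
  h <- tapply(rows, lab, function(v) diff(range(v)) + 1)
  blueness <- tapply(image[, , 3][idx] - image[, , 1][idx], lab, mean)

  keep <- size >= 20 & blueness < 60 &
    pmin(w, h) / pmax(w, h) > 0.75 &
    pmax(w, h) < 0.5 * min(dim(gray))
  if (sum(keep) == 0L) {
    stop_domain("zone detection failed: found 0 ring-like components ",
                "(expected ", nrow(layout$zones), ")")
  }
  # rings all share the zone diameter: keep the size cluster around the
  # median candidate bounding box
  dim_px <- (w + h)[keep] / 2
  med <- stats::median(dim_px)
  sel <- which(keep)[abs(dim_px - med) / med < 0.3]
  n_expect <- nrow(layout$zones)
  if (length(sel) < n_expect) {
    stop_domain("zone detection failed: found ", length(sel),
                " candidate rings (expected ", n_expect, ")")
  }
  if (length(sel) > n_expect) {
    sel <- sel[order(abs(((w + h)[sel] / 2) - med))][seq_len(n_expect)]
  }
  det <- cbind(cx[sel], cy[sel])

  # expected ring outer extent: zone diameter plus the printed ring width
  ring_extent_mm <- layout$zones$diameter[1] + 0.8
  scale0 <- stats::median((w + h)[sel] / 2) / ring_extent_mm

  P <- as.matrix(layout$zones[, c("cx", "cy")])
  fit <- fit_similarity(P, det, scale0)
  resid <- sqrt(rowSums((fit$fitted - fit$matched)^2))
  residual <- mean(resid)
  if (residual > residual_threshold) {
    stop_domain(sprintf(
      "zone alignment failed: mean centre residual %.2f px exceeds %.2f px",
      residual, residual_threshold))
  }

  zones <- data.frame(zone_id = layout$zones$zone_id,
                      role = layout$zones$role,
                      cx = fit$fitted[, 1], cy = fit$fitted[, 2],
                      stringsAsFactors = FALSE)
  list(zones = zones, detected = fit$matched,
       pixels_per_mm = fit$scale, rotation = fit$theta * 180 / pi,
       residual_px = residual,
       transform = fit[c("scale", "theta", "tx", "ty")])
}

# Similarity (scale + rotation + translation) fit of layout points P (mm)
# onto detected points Q (px), correspondence by nearest neighbour after a
# centroid/scale pre-alignment, refined once.
fit_similarity <- function(P, Q, scale0) {
  match_nn <- function(A, B) {
    # for each row of A pick the nearest unclaimed row of B
    n <- nrow(A)
    taken <- rep(FALSE, nrow(B))
    out <- integer(n)
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, n), rowSums(B^2)) - 2 * A %*% t(B)
    ord <- order(apply(d2, 1, min))
    for (i in ord) {
      j <- which.min(ifelse(taken, Inf, d2[i, ]))
      out[i] <- j
      taken[j] <- TRUE
    }
    out
  }
  solve_kabsch <- function(P, Qm) {
    cp <- colMeans(P); cq <- colMeans(Qm)
    Pc <- sweep(P, 2, cp); Qc <- sweep(Qm, 2, cq)
    H <- t(Pc) %*% Qc
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rm <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    s <- sum(diag(diag(c(1, d)) %*% diag(sv$d))) / sum(Pc^2)
    tv <- cq - s * as.vector(Rm %*% cp)
    list(R = Rm, scale = s, t = tv,
         theta = atan2(Rm[2, 1], Rm[1, 1]))
  }
  apply_tf <- function(tf, P) {
    sweep(t(tf$scale * tf$R %*% t(P)), 2, tf$t, `+`)
  }

  # pre-align: scaled layout, centroids matched
  P0 <- sweep(P * scale0, 2, colMeans(P * scale0))
  Q0 <- sweep(Q, 2, colMeans(Q))
  j <- match_nn(P0, Q0)
  for (it in 1:2) {
    tf <- solve_kabsch(P, Q[j, , drop = FALSE])
    fitted <- apply_tf(tf, P)
    j <- match_nn(sweep(fitted, 2, colMeans(fitted)),
                  sweep(Q, 2, colMeans(Q)))
  }
  tf <- solve_kabsch(P, Q[j, , drop = FALSE])
  fitted <- apply_tf(tf, P)
  list(fitted = fitted, matched = Q[j, , drop = FALSE],
       scale = tf$scale, theta = tf$theta,
       tx = tf$t[1], ty = tf$t[2], R = tf$R)
}

# Pixels inside the (possibly rotated) reference square, inset by `inset_mm`
# to keep clear of the printed edge.
ref_square_mask <- function(layout, transform, dims, inset_mm = 1) {
  rs <- layout$ref_square$rect
  cxs <- rs[1] + rs[3] / 2
  cys <- rs[2] + rs[4] / 2
  hx <- rs[3] / 2 - inset_mm
  hy <- rs[4] / 2 - inset_mm
  s <- transform$scale; th <- transform$theta
  ctr <- c(s * (cos(th) * cxs - sin(th) * cys) + transform$tx,
           s * (sin(th) * cxs + cos(th) * cys) + transform$ty)
  rad <- s * sqrt(hx^2 + hy^2)
  cols <- seq(max(1L, floor(ctr[1] - rad)), min(dims[2], ceiling(ctr[1] + rad)))
  rows <- seq(max(1L, floor(ctr[2] - rad)), min(dims[1], ceiling(ctr[2] + rad)))
  grid <- expand.grid(row = rows, col = cols)
  # back to device frame
  dx <- (grid$col - 0.5 - ctr[1]) / s
  dy <- (grid$row - 0.5 - ctr[2]) / s
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  keep <- abs(u) <= hx & abs(v) <= hy
  m <- as.matrix(grid[keep, c("row", "col")])
  storage.mode(m) <- "integer"
  if (nrow(m) == 0L) stop_domain("reference square mask is empty")
  m
}

# Paper-background mask: pixels inside the wax box but clear of all zones,
# used to estimate the colour of the dry paper around the zones.
paper_mask <- function(layout, transform, dims, clearance_mm = 1.5) {
  wb <- layout$wax_box
  s <- transform$scale; th <- transform$theta
  xs <- seq(wb[1] + clearance_mm, wb[1] + wb[3] - clearance_mm, by = 1)
  ys <- seq(wb[2] + clearance_mm, wb[2] + wb[4] - clearance_mm, by = 1)
  grid <- expand.grid(u = xs, v = ys)
  z <- layout$zones
  clear <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(z))) {
    d2 <- (grid$u - z$cx[i])^2 + (grid$v - z$cy[i])^2
    clear <- clear & d2 > (z$diameter[i] / 2 + clearance_mm)^2
  }
  grid <- grid[clear, ]
  col <- s * (cos(th) * grid$u - sin(th) * grid$v) + transform$tx + 0.5
  row <- s * (sin(th) * grid$u + cos(th) * grid$v) + transform$ty + 0.5
  m <- cbind(row = as.integer(round(row)), col = as.integer(round(col)))
  m <- m[m[, 1] >= 1 & m[, 1] <= dims[1] & m[, 2] >= 1 & m[, 2] <= dims[2], ,
         drop = FALSE]
  m
}

#' Quantify a device photograph
#'
#' Full readout of one photographed device: locates the zones
#' ([locate_zones()]), samples each zone's interior at `sampling_fraction`
#' of its radius, computes per-zone AI values, the blank AI (mean of the
#' two negative-control zones), the internal-standard intensity, and the
#' per-zone and summary ARI statistics over the six detection zones.
#'
#' The internal-standard intensity `AI_ref` is measured as the direct
#' Rec.601 luminance of the blue square (not inverted against the 255 white
#' point): with both the blank-subtracted numerator and the reference
#' denominator scaling linearly with capture gain, the ARI ratio is exactly
#' invariant under a change of illumination or camera gain, which is the
#' point of carrying an internal standard on the device.
#'
#' Zones with more than `saturation_fraction` of sampled pixels at the 0 or
#' 255 grayscale rails are flagged as saturated (reading retained). A
#' `high_dispersion` flag is raised when `ARI_sd / |ARI_mean|` exceeds
#' `dispersion_threshold`.
#'
#' @param image H x W x 3 array (0--255) or a path readable by
#'   [read_device_image()].
#' @param layout a `pad_layout`.
#' @param sampling_fraction fraction of the zone radius sampled, (0, 1].
#' @param channel `"gray"` (Rec.601 luma, default) or `"red"` for
#'   single-channel intensity.
#' @param capture_source provenance tag: `"scanner"`, `"smartphone"` or
#'   `"synthetic"`.
#' @param dispersion_threshold relative-dispersion flag threshold.
#' @param saturation_fraction saturated-pixel fraction above which a zone
#'   is flagged.
#' @param ... passed to [locate_zones()].
#' @return a `pad_reading`: per-zone table (`zone_id`, `role`, centres,
#'   `AI`, `n_pixels`, `saturated`), `AI_blank`, `AI_ref`, `ari` (one row
#'   per detection zone), `ari_mean`, `ari_sd`, `tint_index` (blank-vs-paper
#'   darkness contrast, for pigmented-water QC), `flags`, and the location
#'   fit diagnostics.
#' @export
quantify_device <- function(image, layout, sampling_fraction = 0.7,
                            channel = c("gray", "red"),
                            capture_source = "synthetic",
                            dispersion_threshold = 0.5,
                            saturation_fraction = 0.01, ...) {
  channel <- match.arg(channel)
  if (is.character(image)) image <- read_device_image(image)
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    stop_domain("sampling_fraction must lie in (0, 1]")
  }
  loc <- locate_zones(image, layout, ...)
  dims <- dim(image)

  gray <- if (channel == "gray") image_gray(image) else image[, , 1]
  rad_px <- layout$zones$diameter / 2 * loc$pixels_per_mm * sampling_fraction

  zt <- loc$zones
  zt$AI <- NA_real_
  zt$n_pixels <- NA_integer_
  zt$saturated <- FALSE
  for (i in seq_len(nrow(zt))) {
    m <- disc_mask(zt$cx[i], zt$cy[i], rad_px[i])
    vals <- gray[cbind(m[, 1], m[, 2])]
    zt$AI[i] <- mean(255 - vals)
    zt$n_pixels[i] <- nrow(m)
    zt$saturated[i] <- mean(vals <= 0 | vals >= 255) > saturation_fraction
  }

  ref_m <- ref_square_mask(layout, loc$transform, dims)
  ai_ref <- mean(gray[cbind(ref_m[, 1], ref_m[, 2])])
  ai_blank <- mean(zt$AI[zt$role == "blank"])

  det <- zt[zt$role == "detection", ]
  ari <- data.frame(zone_id = det$zone_id,
                    ari = compute_ari(det$AI, ai_blank, ai_ref))
  ari_mean <- mean(ari$ari)
  ari_sd <- stats::sd(ari$ari)

  pm <- paper_mask(layout, loc$transform, dims)
  tint_index <- if (nrow(pm) > 0) {
    paper_luma <- mean(gray[cbind(pm[, 1], pm[, 2])])
    blank_luma <- 255 - ai_blank
    (paper_luma - blank_luma) / ai_ref
  } else NA_real_

  flags <- character(0)
  if (any(zt$saturated)) flags <- c(flags, "saturated")
  if (is.finite(ari_sd) && abs(ari_mean) > 0 &&
      ari_sd / abs(ari_mean) > dispersion_threshold) {
    flags <- c(flags, "high_dispersion")
  }

  structure(
    list(device_code = layout$device_code,
         zones = zt, AI_blank = ai_blank, AI_ref = ai_ref,
         ari = ari, ari_mean = ari_mean, ari_sd = ari_sd,
         n_detection = nrow(ari), tint_index = tint_index,
         flags = flags, capture_source = capture_source,
         pixels_per_mm = loc$pixels_per_mm, rotation = loc$rotation,
         residual_px = loc$residual_px),
    class = "pad_reading"
  )
}

#' @export
print.pad_reading <- function(x, ...) {
  cat(sprintf("PAD reading, device %s (%s capture)\n",
              x$device_code, x$capture_source))
  cat(sprintf("  ARI = %.4f +/- %.4f (n = %d detection zones)\n",
              x$ari_mean, x$ari_sd, x$n_detection))
  cat(sprintf("  AI_blank = %.2f, AI_ref = %.2f, scale %.2f px/mm, rotation %.2f deg\n",
              x$AI_blank, x$AI_ref, x$pixels_per_mm, x$rotation))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a device reading to JSON
#'
#' @param reading a `pad_reading`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reading <- function(reading, path) {
  jsonlite::write_json(unclass(reading), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
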