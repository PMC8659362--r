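#' Construct the field PAD layout
#'
#' Builds the machine-readable geometry of the field paper analytical device
#' (PAD): eight 10 mm circular zones on a 4 x 2 grid inside a rectangular wax
#' box, six loaded with the phosphomolybdenum-blue reagents (detection) and
#' two left unloaded as negative controls (blank), plus a printed blue
#' internal-standard square next to the device code. All coordinates are in
#' millimetres in the device frame: origin at the top-left corner of the
#' laminate, x rightward, y downward.
#'
#' Zones are numbered in reading order (top row left to right, then bottom
#' row); zones 1--6 are detection zones and zones 7--8 -- the two rightmost
#' of the bottom row -- are blanks.
#'
#' @param device_code four-digit identification code printed on the device.
#' @param pitch centre-to-centre zone spacing in mm.
#' @param zone_diameter zone diameter in mm (10 mm in the field design).
#' @param laminate_size width and height of the laminate pouch in mm.
#' @param wax_box `c(x, y, width, height)` of the wax containment box in mm.
#' @param ref_square_rect `c(x, y, width, height)` of the internal-standard
#'   square in mm, placed right of the wax box.
#' @param ref_square_rgb nominal printed colour of the internal standard
#'   (8-bit RGB; a saturated blue).
#' @return an object of class `pad_layout`.
#' @examples
#' lay <- build_field_layout("0421")
#' table(lay$zones$role)
#' @export
build_field_layout <- function(device_code,
                               pitch = 14,
                               zone_diameter = 10,
                               laminate_size = c(80, 50),
                               wax_box = c(4, 8, 62, 34),
                               ref_square_rect = c(69, 8, 8, 8),
                               ref_square_rgb = c(45, 70, 200)) {
  if (!is_four_digit_code(device_code)) {
    stop_domain("device_code must be exactly four digits, got: ",
                deparse(device_code))
  }
  r <- zone_diameter / 2
  # centre the 4 x 2 grid inside the wax box
  x0 <- wax_box[1] + (wax_box[3] - 3 * pitch) / 2
  y0 <- wax_box[2] + (wax_box[4] - pitch) / 2
  cx <- x0 + pitch * rep(0:3, 2)
  cy <- y0 + pitch * rep(c(0, 1), each = 4)
  zones <- data.frame(
    zone_id = 1:8,
    cx = cx,
    cy = cy,
    diameter = zone_diameter,
    role = c(rep("detection", 6), rep("blank", 2)),
    stringsAsFactors = FALSE
  )
  # blanks are the two rightmost zones of the bottom row; reading order puts
  # them last, so reorder ids to keep 1..6 = detection, 7..8 = blank
  ord <- order(zones$cy, zones$cx)
  zones <- zones[ord, ]
  zones$role <- c(rep("detection", 4), rep("detection", 2), rep("blank", 2))
  zones$zone_id <- 1:8
  rownames(zones) <- NULL

  layout <- structure(
    list(
      layout_version = "1.0",
      device_code = device_code,
      zones = zones,
      wax_box = wax_box,
      ref_square = list(rect = ref_square_rect, rgb = ref_square_rgb),
      laminate_size = laminate_size
    ),
    class = "pad_layout"
  )
  viol <- validate_layout(layout)
  if (length(viol) > 0L) {
    stop_domain("constructed layout violates invariants: ",
                paste(viol, collapse = "; "))
  }
  layout
}

#' Validate a PAD layout against its geometric invariants
#'
#' Checks the layout contract: exactly eight zones, six detection and two
#' blank; all zones inside the wax box and pairwise non-overlapping; the
#' reference square disjoint from every zone; a four-digit device code.
#' Validation never raises -- it reports.
#'
#' @param layout a `pad_layout`.
#' @return character vector of human-readable violations; empty when the
#'   layout is valid.
#' @export
validate_layout <- function(layout) {
  v <- character(0)
  z <- layout$zones
  if (!is.data.frame(z)) return("zones: missing or not tabular")
  if (nrow(z) != 8L) {
    v <- c(v, sprintf("zones: expected 8 zones, found %d", nrow(z)))
  }
  n_det <- sum(z$role == "detection")
  n_blk <- sum(z$role == "blank")
  if (n_det != 6L || n_blk != 2L) {
    v <- c(v, sprintf(
      "zones: expected 6 detection + 2 blank, found %d + %d", n_det, n_blk))
  }
  if (any(!z$role %in% c("detection", "blank"))) {
    v <- c(v, "zones: role must be 'detection' or 'blank'")
  }
  if (any(z$diameter <= 0)) v <- c(v, "zones: non-positive diameter")

  # pairwise overlap
  if (nrow(z) >= 2L) {
    for (i in seq_len(nrow(z) - 1L)) {
      for (j in seq(i + 1L, nrow(z))) {
        d <- sqrt((z$cx[i] - z$cx[j])^2 + (z$cy[i] - z$cy[j])^2)
        if (d < (z$diameter[i] + z$diameter[j]) / 2) {
          v <- c(v, sprintf("zones: zones %d and %d overlap (centre distance %.2f mm)",
                            z$zone_id[i], z$zone_id[j], d))
        }
      }
    }
  }

  # containment in the wax box
  wb <- layout$wax_box
  r <- z$diameter / 2
  out <- z$cx - r < wb[1] | z$cx + r > wb[1] + wb[3] |
    z$cy - r < wb[2] | z$cy + r > wb[2] + wb[4]
  if (any(out)) {
    v <- c(v, sprintf("wax_box: zone(s) %s not fully inside the wax box",
                      paste(z$zone_id[out], collapse = ", ")))
  }

  # reference square disjoint from all zones
  rs <- layout$ref_square$rect
  dx <- pmax(rs[1] - z$cx, 0, z$cx - (rs[1] + rs[3]))
  dy <- pmax(rs[2] - z$cy, 0, z$cy - (rs[2] + rs[4]))
  hit <- sqrt(dx^2 + dy^2) < r
  if (any(hit)) {
    v <- c(v, sprintf("ref_square: intersects zone(s) %s",
                      paste(z$zone_id[hit], collapse = ", ")))
  }

  if (!is_four_digit_code(layout$device_code)) {
    v <- c(v, sprintf("device_code: '%s' does not match the four-digit pattern",
                      as.character(layout$device_code)))
  }
  v
}

#' Pixel mask of a zone's sampled region
#'
#' Converts one zone of a layout to the set of pixel centres lying within
#' `sampling_fraction` of the zone radius, in an unrotated raster of the
#' device at `pixels_per_mm`. The default fraction (0.7) excludes pixels
#' near the wax ring, where printed wax bleeds into the porous paper.
#'
#' Pixel `(row i, col j)` has its centre at millimetre position
#' `((j - 0.5) / pixels_per_mm, (i - 0.5) / pixels_per_mm)`.
#'
#' @param layout a `pad_layout`.
#' @param zone_id zone to sample.
#' @param pixels_per_mm raster scale (> 0).
#' @param sampling_fraction fraction of the zone radius sampled, in (0, 1].
#' @return integer matrix with columns `row`, `col` of pixel coordinates.
#' @export
zone_mask <- function(layout, zone_id, pixels_per_mm,
                      sampling_fraction = 0.7) {
  if (!is.numeric(sampling_fraction) || length(sampling_fraction) != 1L ||
      sampling_fraction <= 0 || sampling_fraction > 1) {
    stop_domain("sampling_fraction must lie in (0, 1]")
  }
  if (!is.numeric(pixels_per_mm) || pixels_per_mm <= 0) {
    stop_domain("pixels_per_mm must be > 0")
  }
  z <- layout$zones[layout$zones$zone_id == zone_id, ]
  if (nrow(z) != 1L) stop_domain("unknown zone_id: ", zone_id)
  disc_mask(cx = z$cx * pixels_per_mm, cy = z$cy * pixels_per_mm,
            radius = z$diameter / 2 * pixels_per_mm * sampling_fraction)
}

# Pixel centres within `radius` px of (cx, cy) px; pixel (i, j) centre at
# (j - 0.5, i - 0.5).
disc_mask <- function(cx, cy, radius) {
  cols <- seq(floor(cx - radius), ceiling(cx + radius) + 1L)
  rows <- seq(floor(cy - radius), ceiling(cy + radius) + 1L)
  grid <- expand.grid(row = rows, col = cols)
  dx <- grid$col - 0.5 - cx
  dy <- grid$row - 0.5 - cy
  keep <- dx * dx + dy * dy <= radius * radius
  m <- as.matrix(grid[keep, c("row", "col")])
  storage.mode(m) <- "integer"
  if (nrow(m) == 0L) stop_domain("empty mask: radius too small for the raster")
  m
}

#' Write / read a PAD layout as YAML
#'
#' The on-disk document carries a `layout_version` key and mirrors the
#' `pad_layout` fields, so layouts can be exchanged between the generator
#' and the quantifier (or hand-edited for a redesigned device).
#'
#' @param layout a `pad_layout`.
#' @param path file to write / read.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   `pad_layout`.
#' @export
write_layout <- function(layout, path) {
  doc <- list(
    layout_version = layout$layout_version,
    device_code = layout$device_code,
    laminate_size = as.numeric(layout$laminate_size),
    wax_box = as.numeric(layout$wax_box),
    ref_square = list(rect = as.numeric(layout$ref_square$rect),
                      rgb = as.numeric(layout$ref_square$rgb)),
    zones = lapply(seq_len(nrow(layout$zones)), function(i) {
      z <- layout$zones[i, ]
      list(zone_id = z$zone_id, cx = z$cx, cy = z$cy,
           diameter = z$diameter, role = z$role)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- yaml::read_yaml(path)
  zones <- do.call(rbind, lapply(doc$zones, function(z) {
    data.frame(zone_id = as.integer(z$zone_id), cx = z$cx, cy = z$cy,
               diameter = z$diameter, role = z$role,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(
      layout_version = doc$layout_version %||% "1.0",
      device_code = doc$device_code,
      zones = zones,
      wax_box = as.numeric(doc$wax_box),
      ref_square = list(rect = as.numeric(doc$ref_square$rect),
                        rgb = as.numeric(doc$ref_square$rgb)),
      laminate_size = as.numeric(doc$laminate_size)
    ),
    class = "pad_layout"
  )
}

#' @export
print.pad_layout <- function(x, ...) {
  cat(sprintf("PAD layout (version %s), device code %s\n",
              x$layout_version, x$device_code))
  cat(sprintf("  laminate %g x %g mm, wax box [%g, %g, %g, %g] mm\n",
              x$laminate_size[1], x$laminate_size[2],
              x$wax_box[1], x$wax_box[2], x$wax_box[3], x$wax_box[4]))
  cat(sprintf("  %d zones (%d detection, %d blank), diameter %g mm\n",
              nrow(x$zones), sum(x$zones$role == "detection"),
              sum(x$zones$role == "blank"), x$zones$diameter[1]))
  invisible(x)
}
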