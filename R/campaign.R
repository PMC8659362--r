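CAMPAIGN_COLUMNS <- c("record_id", "device_code", "timestamp", "lat", "lon",
                      "waterbody", "incubation_s", "image_path",
                      "user_level", "notes")

#' Parse citizen sampling records
#'
#' Reads a campaign records file (CSV with the documented header, or
#' JSON-lines with the same fields) and validates every row: coordinate
#' bounds, four-digit device code (when present), parseable timestamp,
#' non-negative incubation. Malformed rows are returned with their reason,
#' never silently dropped; unknown columns produce a warning and are
#' carried through.
#'
#' @param path records file (`.csv`, or `.jsonl`/`.ndjson` JSON-lines).
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return list with `records` (accepted rows, with `qc_flags` initialised)
#'   and `rejected` (data frame of row numbers, offending rows as text, and
#'   reasons).
#' @export
parse_records <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_domain("records file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("jsonl", "ndjson",
                                                        "json")) "jsonl" else "csv"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(device_code = "character"))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      r <- jsonlite::fromJSON(l)
      r[vapply(r, function(v) is.null(v) || length(v) == 0L, TRUE)] <- NA
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    do.call(rbind, lapply(rows, function(r) {
      missing <- setdiff(CAMPAIGN_COLUMNS, names(r))
      for (m in missing) r[[m]] <- NA
      r[, union(CAMPAIGN_COLUMNS, names(r))]
    }))
  }
  extra <- setdiff(names(df), CAMPAIGN_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown record column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(CAMPAIGN_COLUMNS, names(df))
  for (m in missing_cols) df[[m]] <- NA

  reasons <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    why <- character(0)
    lat <- suppressWarnings(as.numeric(r$lat))
    lon <- suppressWarnings(as.numeric(r$lon))
    if (!is.finite(lat) || lat < -90 || lat > 90) {
      why <- c(why, sprintf("lat %s outside [-90, 90]", as.character(r$lat)))
    }
    if (!is.finite(lon) || lon < -180 || lon > 180) {
      why <- c(why, sprintf("lon %s outside [-180, 180]", as.character(r$lon)))
    }
    if (!is.na(r$device_code) && !grepl("^[0-9]{4}$", r$device_code)) {
      why <- c(why, sprintf("device_code '%s' does not match the four-digit pattern",
                            r$device_code))
    }
    inc <- suppressWarnings(as.numeric(r$incubation_s))
    if (is.finite(inc) && inc < 0) why <- c(why, "incubation_s negative")
    if (!is.na(r$timestamp) && is.na(parse_timestamp(r$timestamp))) {
      why <- c(why, sprintf("unparseable timestamp '%s'", r$timestamp))
    }
    why
  })

  bad <- lengths(reasons) > 0L
  accepted <- df[!bad, , drop = FALSE]
  if (nrow(accepted)) {
    accepted$lat <- as.numeric(accepted$lat)
    accepted$lon <- as.numeric(accepted$lon)
    accepted$incubation_s <- as.numeric(accepted$incubation_s)
    accepted$qc_flags <- vector("list", nrow(accepted))
  }
  rejected <- data.frame(
    row = which(bad),
    record_id = as.character(df$record_id[bad]),
    reason = vapply(reasons[bad], paste, "", collapse = "; "),
    stringsAsFactors = FALSE
  )
  rownames(accepted) <- NULL
  list(records = accepted, rejected = rejected)
}

# ISO 8601 (with or without offset); offset-less timestamps are assumed UTC.
parse_timestamp <- function(x) {
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%d")
  for (f in fmts) {
    p <- as.POSIXct(x, format = f, tz = "UTC")
    if (!is.na(p)) return(p)
  }
  as.POSIXct(NA)
}

has_tz_offset <- function(x) grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)

#' Quality-control flags for one record
#'
#' Annotating, never blocking: `incubation_short` when the recorded
#' incubation is below the protocol's 3 minutes, `blank_anomaly` when the
#' blank zones read darker than the surrounding dry paper by more than
#' `tint_threshold` (in units of the internal-standard intensity --
#' pigmented or turbid water), `saturated` when the reading reports
#' saturated zones, `missing_image` when no reading is available, and
#' `assumed_utc` for offset-less timestamps.
#'
#' @param record one accepted record (a one-row data frame or list).
#' @param reading the record's `pad_reading`, or `NULL` when the image is
#'   missing or unquantifiable.
#' @param min_incubation_s protocol incubation floor, seconds.
#' @param tint_threshold blank-vs-paper contrast above which the water is
#'   flagged as pigmented.
#' @return character vector of flags (possibly empty).
#' @export
qc_record <- function(record, reading = NULL, min_incubation_s = 180,
                      tint_threshold = 0.10) {
  flags <- character(0)
  inc <- suppressWarnings(as.numeric(record$incubation_s))
  if (is.finite(inc) && inc < min_incubation_s) {
    flags <- c(flags, "incubation_short")
  }
  if (!is.na(record$timestamp) && !has_tz_offset(record$timestamp)) {
    flags <- c(flags, "assumed_utc")
  }
  if (is.null(reading)) {
    flags <- c(flags, "missing_image")
  } else {
    if (is.finite(reading$tint_index) &&
        reading$tint_index > tint_threshold) {
      flags <- c(flags, "blank_anomaly")
    }
    if ("saturated" %in% reading$flags) flags <- c(flags, "saturated")
  }
  flags
}

#' Build map features from records and device readings
#'
#' Joins records to their quantified device readings, inverts the
#' calibration to a concentration for each, classifies into the map
#' bracket, and attaches QC flags. Records without a quantifiable reading
#' (missing image, failed location, reading outside the calibrated range)
#' are returned in `skipped` with reasons -- accepted features plus skipped
#' records always partition the input.
#'
#' @param records accepted records from [parse_records()] (or the
#'   generator).
#' @param readings named list of `pad_reading` objects, keyed by
#'   `record_id`; entries may be `NULL`.
#' @param model an accepted `pad_calibration`.
#' @param ... passed to [qc_record()].
#' @return list with `features` (data frame: position, `concentration`,
#'   `below_lod`, `category`, carried-through properties, `qc_flags`) and
#'   `skipped` (record ids + reasons).
#' @export
build_map <- function(records, readings, model, ...) {
  if (!isTRUE(model$accepted)) stop_domain("calibration not accepted")
  feats <- list()
  skipped <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    rid <- as.character(rec$record_id)
    reading <- readings[[rid]]
    flags <- qc_record(rec, reading, ...)
    if (is.null(reading)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(record_id = rid, reason = "missing or unquantifiable image")
      next
    }
    inv <- tryCatch(
      invert_concentration(model, reading$ari_mean, reading$ari_sd,
                           reading$n_detection),
      error = function(e) e)
    if (inherits(inv, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(record_id = rid, reason = conditionMessage(inv))
      next
    }
    conc <- max(inv$estimate, 0) # negative estimates read as zero phosphate
    feats[[length(feats) + 1L]] <- data.frame(
      record_id = rid,
      lon = rec$lon, lat = rec$lat,
      timestamp = as.character(rec$timestamp),
      concentration = conc,
      below_lod = inv$below_lod,
      category = as.character(classify_level(conc)),
      waterbody = as.character(rec$waterbody),
      user_level = rec$user_level,
      notes = as.character(rec$notes),
      qc_flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(record_id = character(0), lon = numeric(0), lat = numeric(0),
               timestamp = character(0), concentration = numeric(0),
               below_lod = logical(0), category = character(0),
               waterbody = character(0), user_level = numeric(0),
               notes = character(0), qc_flags = character(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(record_id = character(0), reason = character(0))
  list(features = features, skipped = skipped)
}

#' Export map features as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection of Point features, coordinates
#' ordered (lon, lat). The bracket is encoded both as the `level` property
#' and as the conventional `marker-color`.
#'
#' @param features feature data frame from [build_map()].
#' @param path output file.
#' @param palette named colour vector, see [level_palette()].
#' @return `path`, invisibly.
#' @export
export_geojson <- function(features, path, palette = level_palette()) {
  fl <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(f$lon, f$lat)),
      properties = list(
        record_id = f$record_id,
        level = f$category,
        `marker-color` = unname(palette[[f$category]]),
        concentration_mg_per_L = f$concentration,
        below_lod = f$below_lod,
        date = substr(f$timestamp, 1, 10),
        waterbody = f$waterbody,
        user_level = f$user_level,
        notes = f$notes,
        qc_flags = f$qc_flags
      )
    )
  })
  doc <- list(type = "FeatureCollection", features = fl)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection back into a feature data frame
#'
#' @param path GeoJSON file.
#' @return data frame with the same columns as [build_map()] features.
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection")) {
    stop_domain("not a GeoJSON FeatureCollection")
  }
  rows <- lapply(doc$features, function(f) {
    p <- f$properties
    data.frame(
      record_id = p$record_id,
      lon = f$geometry$coordinates[[1]],
      lat = f$geometry$coordinates[[2]],
      timestamp = p$date,
      concentration = p$concentration_mg_per_L,
      below_lod = p$below_lod,
      category = p$level,
      waterbody = p$waterbody,
      user_level = p$user_level,
      notes = p$notes %||% "",
      qc_flags = p$qc_flags %||% "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Seasonal summary of map features
#'
#' Aggregates features by month-of-year (or quarter) across years: sample
#' count, mean concentration, and per-bracket counts. Periods with no data
#' appear with `n = 0`, so a full seasonal cycle is always reported.
#'
#' @param features feature data frame from [build_map()].
#' @param grouping `"month"` or `"quarter"`.
#' @return data frame with one row per period.
#' @export
seasonal_summary <- function(features, grouping = c("month", "quarter")) {
  grouping <- match.arg(grouping)
  ts <- as.POSIXct(vapply(features$timestamp, function(x)
    as.numeric(parse_timestamp(x)), 0), origin = "1970-01-01", tz = "UTC")
  month <- as.integer(format(ts, "%m"))
  period <- if (grouping == "month") month else (month - 1L) %/% 3L + 1L
  periods <- if (grouping == "month") 1:12 else 1:4
  labels <- if (grouping == "month") month.abb else paste0("Q", 1:4)

  cats <- c("none", "low", "medium", "high")
  out <- do.call(rbind, lapply(periods, function(p) {
    sel <- which(period == p)
    row <- data.frame(period = labels[p], n = length(sel),
                      mean_concentration = if (length(sel))
                        mean(features$concentration[sel]) else NA_real_,
                      stringsAsFactors = FALSE)
    for (ct in cats) {
      row[[paste0("n_", ct)]] <- sum(features$category[sel] == ct)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Agreement between volunteers' slider readings and computed brackets
#'
#' Volunteers record their own interpretation of the colour on a 0--10
#' slider; interpreting the slider position as a concentration guess, this
#' reports how often the volunteer's bracket matches the image-derived one.
#' The slider is never used for calibration -- it is a engagement/sanity
#' metric only.
#'
#' @param features feature data frame from [build_map()].
#' @return fraction of features whose `user_level` bracket matches
#'   `category` (NA when no usable slider readings).
#' @export
user_level_agreement <- function(features) {
  ok <- is.finite(features$user_level)
  if (!any(ok)) return(NA_real_)
  user_cat <- as.character(classify_level(features$user_level[ok]))
  mean(user_cat == features$category[ok])
}
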