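make_records_csv <- function(n = 6, seed = 2, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  camp <- generate_campaign(n, seed = seed, render_images = FALSE, dir = dir)
  list(path = file.path(dir, "records.csv"), camp = camp)
}

test_that("generator-produced record files parse losslessly", {
  x <- make_records_csv()
  parsed <- parse_records(x$path)
  expect_equal(nrow(parsed$records), 6L)
  expect_equal(nrow(parsed$rejected), 0L)
  expect_equal(parsed$records$record_id, x$camp$records$record_id)
  expect_equal(parsed$records$lat, x$camp$records$lat, tolerance = 1e-9)
  expect_equal(parsed$records$device_code, x$camp$records$device_code)

  # re-serialisation reproduces the accepted rows
  out <- withr::local_tempfile(fileext = ".csv")
  cols <- setdiff(names(parsed$records), "qc_flags")
  utils::write.csv(parsed$records[, cols], out, row.names = FALSE)
  again <- parse_records(out)
  expect_equal(again$records[, cols], parsed$records[, cols],
               tolerance = 1e-9)
})

test_that("malformed rows are rejected with reasons, never dropped silently", {
  x <- make_records_csv()
  df <- utils::read.csv(x$path, colClasses = c(device_code = "character"))
  df$lat[2] <- 95
  df$device_code[4] <- "12a4"
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  parsed <- parse_records(bad)
  expect_equal(nrow(parsed$records) + nrow(parsed$rejected), nrow(df))
  expect_equal(nrow(parsed$rejected), 2L)
  expect_true(any(grepl("lat 95", parsed$rejected$reason)))
  expect_true(any(grepl("12a4", parsed$rejected$reason)))
})

test_that("json-lines records parse like the CSV dialect", {
  x <- make_records_csv()
  df <- utils::read.csv(x$path, colClasses = c(device_code = "character"))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(df)), function(i) {
    as.character(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE))
  }, ""), jl)
  parsed <- parse_records(jl)
  expect_equal(nrow(parsed$records), nrow(df))
  expect_equal(parsed$records$device_code, df$device_code)
})

test_that("unknown columns warn but do not reject", {
  x <- make_records_csv()
  df <- utils::read.csv(x$path, colClasses = c(device_code = "character"))
  df$extra_column <- 1
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_warning(parsed <- parse_records(p), "extra_column")
  expect_equal(nrow(parsed$records), nrow(df))
})

test_that("QC flags annotate short incubation, missing images and tinted water", {
  rec <- list(record_id = "R1", incubation_s = 120,
              timestamp = "2020-05-01T10:00:00+00:00")
  expect_true("incubation_short" %in% qc_record(rec, reading = NULL))
  expect_true("missing_image" %in% qc_record(rec, reading = NULL))

  lay <- field_layout()
  clean <- quantify_device(default_render()$image, lay)
  ok <- list(record_id = "R2", incubation_s = 180,
             timestamp = "2020-05-01T10:00:00+00:00")
  expect_identical(qc_record(ok, clean), character(0))

  # offset-less timestamps are assumed UTC and flagged
  naive <- list(record_id = "R3", incubation_s = 180,
                timestamp = "2020-05-01T10:00:00")
  expect_true("assumed_utc" %in% qc_record(naive, clean))

  tinted_scene <- synthetic_scene(
    lay, 2, scene = scene_params(seed = 15, water_tint = c(-25, -10, -35)))
  tinted <- quantify_device(render_device_image(tinted_scene)$image, lay)
  expect_true("blank_anomaly" %in% qc_record(ok, tinted))
})

test_that("map features carry the right brackets end-to-end", {
  lay <- field_layout()
  m <- small_calibration()
  concs <- c(0.5, 2, 5, 9)
  records <- data.frame(
    record_id = sprintf("T%d", 1:4), device_code = "0421",
    timestamp = "2020-06-01T09:00:00+00:00",
    lat = 53.9, lon = -0.8, waterbody = "Pocklington Canal",
    incubation_s = 180, image_path = "", user_level = 2, notes = "",
    stringsAsFactors = FALSE
  )
  readings <- lapply(seq_along(concs), function(i) {
    sc <- synthetic_scene(lay, concs[i],
                          scene = scene_params(seed = 40 + i, zone_cv = 0.03,
                                               noise_sd = 3))
    quantify_device(render_device_image(sc)$image, lay)
  })
  names(readings) <- records$record_id
  mp <- build_map(records, readings, m)
  expect_equal(mp$features$category, c("none", "low", "medium", "high"))
  # stored concentration and category stay consistent
  expect_equal(mp$features$category,
               as.character(classify_level(mp$features$concentration)))
})

test_that("build_map partitions records into features and skipped", {
  m <- small_calibration()
  records <- data.frame(
    record_id = c("A", "B"), device_code = "0421",
    timestamp = "2020-06-01T09:00:00+00:00", lat = 53.9, lon = -0.8,
    waterbody = "x", incubation_s = 180, image_path = "", user_level = 1,
    notes = "", stringsAsFactors = FALSE
  )
  readings <- list(A = quantify_device(default_render()$image, field_layout()),
                   B = NULL)
  mp <- build_map(records, readings, m)
  expect_equal(nrow(mp$features), 1L)
  expect_equal(nrow(mp$skipped), 1L)
  expect_equal(nrow(mp$features) + nrow(mp$skipped), nrow(records))
  expect_match(mp$skipped$reason, "missing")

  empty <- build_map(records[0, ], list(), m)
  expect_equal(nrow(empty$features), 0L)
  expect_equal(nrow(empty$skipped), 0L)
})

test_that("GeoJSON export is an RFC 7946 FeatureCollection that round-trips", {
  feats <- data.frame(
    record_id = c("A", "B", "C"),
    lon = c(-0.8, -0.5, 0.1), lat = c(53.9, 54.0, 53.6),
    timestamp = "2020-06-01T09:00:00+00:00",
    concentration = c(0.2, 4.7, 8.1), below_lod = c(TRUE, FALSE, FALSE),
    category = c("none", "medium", "high"),
    waterbody = "w", user_level = 1, notes = "", qc_flags = "",
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  export_geojson(feats, path)

  # generic reader: plain jsonlite parse
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(doc$type, "FeatureCollection")
  expect_length(doc$features, 3L)
  f1 <- doc$features[[1]]
  expect_equal(f1$geometry$type, "Point")
  # (lon, lat) ordering
  expect_equal(f1$geometry$coordinates[[1]], -0.8)
  expect_equal(f1$geometry$coordinates[[2]], 53.9)
  expect_equal(f1$properties$level, "none")
  expect_equal(f1$properties$`marker-color`, unname(level_palette()["none"]))

  back <- read_geojson(path)
  expect_equal(back$record_id, feats$record_id)
  expect_equal(back$concentration, feats$concentration, tolerance = 1e-12)
  expect_equal(back$category, feats$category)
})

test_that("seasonal summaries conserve counts and expose the injected season", {
  camp <- generate_campaign(150, seasonal_amplitude = 0.5, seed = 64,
                            render_images = FALSE)
  feats <- data.frame(
    record_id = camp$records$record_id,
    lon = camp$records$lon, lat = camp$records$lat,
    timestamp = camp$records$timestamp,
    concentration = camp$records$true_concentration,
    below_lod = FALSE,
    category = as.character(classify_level(camp$records$true_concentration)),
    waterbody = camp$records$waterbody,
    user_level = camp$records$user_level, notes = "", qc_flags = "",
    stringsAsFactors = FALSE
  )
  s <- seasonal_summary(feats, "month")
  expect_equal(nrow(s), 12L)
  expect_equal(sum(s$n), nrow(feats))
  expect_equal(sum(s$n_none + s$n_low + s$n_medium + s$n_high), nrow(feats))
  summer <- mean(s$mean_concentration[s$period %in% c("Jun", "Jul", "Aug")])
  winter <- mean(s$mean_concentration[s$period %in% c("Dec", "Jan", "Feb")])
  expect_gt(summer, winter)

  q <- seasonal_summary(feats, "quarter")
  expect_equal(nrow(q), 4L)
  expect_equal(sum(q$n), nrow(feats))

  agree <- user_level_agreement(feats)
  expect_true(agree >= 0 && agree <= 1)
})
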