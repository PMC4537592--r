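test_that("the default array matches the published station layout", {
  arr <- default_array()
  expect_length(arr, 5)
  bs <- function(st) sort(vapply(st$antennas, `[[`, 0, "boresight"))
  expect_equal(bs(arr$IDH), c(55, 235))
  expect_equal(bs(arr$PetitManan), c(150, 330))
  expect_equal(c(arr$IDH$lat, arr$IDH$lon),
               c(44 + 36 / 60, -(67 + 16 / 60)))
  expect_equal(c(arr$PetitManan$lat, arr$PetitManan$lon),
               c(44 + 24 / 60, -(67 + 54 / 60)))
  # island scan cycle 21.6/43.2 s, coastal 14/28 s, range 15 km everywhere
  expect_equal(c(arr$KentIs1$scan_on, arr$KentIs1$scan_period),
               c(21.6, 43.2))
  expect_equal(c(arr$IDH$scan_on, arr$IDH$scan_period), c(14, 28))
  expect_true(all(vapply(arr, `[[`, 0, "detection_range_km") == 15))
})

test_that("wind fields honour their configuration and seed", {
  cfg0 <- sim_config(wind_shared_sd = 0, wind_level_sd = 0,
                     wind_node_sd = 0, altitude_evening_sd_m = 0,
                     n_evenings = 2)
  set.seed(1); w <- simulate_wind_field(cfg0)
  # zero noise: the field is its level means everywhere
  for (l in c("10m", "925mb"))
    expect_equal(unique(w$wind_speed_ms[w$level_id == l]),
                 cfg0$level_wind_speed[[l]], tolerance = 1e-9)
  expect_equal(unique(w$geopotential_height_m[w$level_id == "925mb"]),
               cfg0$level_altitude_m[["925mb"]])
  # determinism under the seed
  cfg <- sim_config(n_evenings = 3)
  set.seed(7); w1 <- simulate_wind_field(cfg)
  set.seed(7); w2 <- simulate_wind_field(cfg)
  expect_identical(w1, w2)
  # configured mean tailwind is recovered over many segments
  set.seed(42)
  cfg6 <- sim_config(level_wind_speed = setNames(
    rep(6, nrow(default_levels())), default_levels()$level_id),
    level_wind_dir_to = setNames(rep(249, nrow(default_levels())),
                                 default_levels()$level_id))
  d <- simulate_stage_winds(n = 100, generating_level = "925mb",
                            config = cfg6)
  m <- mean(d$annotations$tailwind_ms[d$annotations$level_id == "925mb"])
  expect_equal(m, 6, tolerance = 0.5)
})

test_that("departure choosiness separates the age classes", {
  set.seed(61)
  cfg <- sim_config()
  winds <- simulate_wind_field(cfg)
  dep <- simulate_departures(cfg, winds)
  expect_gt(mean(dep$departure_tailwind[dep$age == "adult"]),
            mean(dep$departure_tailwind[dep$age == "juvenile"]))
  expect_true(all(dep$departure_tailwind[dep$age == "adult"] >
                    cfg$adult_tailwind_threshold))
  # all evenings supportive and immediate readiness: everyone leaves day 1
  cfg1 <- sim_config(adult_tailwind_threshold = -Inf,
                     departure_mean_evening = 1,
                     departure_sd_evenings = 0, n_evenings = 5)
  set.seed(62)
  w1 <- simulate_wind_field(cfg1)
  dep1 <- simulate_departures(cfg1, w1)
  expect_true(all(dep1$departure_evening == 1))
  # unattainable adult threshold: adults grounded, juveniles leave
  cfg2 <- sim_config(adult_tailwind_threshold = 1e6, n_evenings = 5,
                     departure_mean_evening = 1,
                     departure_sd_evenings = 0)
  set.seed(63)
  w2 <- simulate_wind_field(cfg2)
  expect_warning(dep2 <- simulate_departures(cfg2, w2), "did not depart")
  expect_true(all(is.na(dep2$departure_evening[dep2$age == "adult"])))
  expect_true(all(!is.na(dep2$departure_evening[dep2$age == "juvenile"])))
})

test_that("flights obey the wind triangle in controlled conditions", {
  lv <- default_levels()$level_id
  base <- sim_config(wind_shared_sd = 0, wind_level_sd = 0,
                     wind_node_sd = 0, duration_noise_sd_min = 0,
                     climb_rate_ms = 0, p_coast_detected = 0,
                     departure_mean_evening = 1, departure_sd_evenings = 0,
                     n_evenings = 2, n_adults = 1, n_juveniles = 0,
                     adult_tailwind_threshold = -Inf,
                     pattern_probs_idh = c(first_antenna_only = 0,
                                           both = 1,
                                           second_antenna_only = 0))
  run1 <- function(cfg) {
    set.seed(64)
    w <- simulate_wind_field(cfg)
    dep <- simulate_departures(cfg, w)
    simulate_flight(dep[1, ], w, cfg)
  }
  # still air: groundspeed is the airspeed exactly
  cfg <- base
  cfg$level_wind_speed[] <- 0
  fl <- run1(cfg)
  expect_equal(fl$ocean$groundspeed_ms, 12, tolerance = 1e-9)
  # pure 5 m/s tailwind on the island-to-coast track: 17 m/s
  arr <- default_array()
  trk <- initial_bearing(arr$KentIs1$lat, arr$KentIs1$lon,
                         arr$IDH$lat, arr$IDH$lon)
  cfg <- base
  cfg$level_wind_speed[] <- 5
  cfg$level_wind_dir_to[] <- trk
  fl <- run1(cfg)
  expect_equal(fl$ocean$groundspeed_ms, 17, tolerance = 1e-9)
  # pure 6 m/s crosswind: sqrt(144 - 36)
  cfg <- base
  cfg$level_wind_speed[] <- 6
  cfg$level_wind_dir_to[] <- (trk + 90) %% 360
  fl <- run1(cfg)
  expect_equal(fl$ocean$groundspeed_ms, sqrt(144 - 36), tolerance = 1e-9)
  # unholdable crosswind aborts the flight
  cfg <- base
  cfg$level_wind_speed[] <- 13
  cfg$level_wind_dir_to[] <- (trk + 90) %% 360
  expect_warning(fl <- run1(cfg), "cannot hold")
  expect_null(fl)
  # the ocean climb diverts airspeed: slower than the no-climb flight
  cfg <- base
  cfg$level_wind_speed[] <- 0
  cfg$climb_rate_ms <- 1.5
  fl <- run1(cfg)
  expect_lt(fl$ocean$groundspeed_ms, 12)
})

test_that("rendered detections honour range, scan cycle and pulse rate", {
  set.seed(65)
  cfg <- sim_config(p_coast_detected = 0, n_adults = 3, n_juveniles = 2,
                    departure_mean_evening = 2, departure_sd_evenings = 1)
  ds <- suppressWarnings(generate_dataset(cfg, seed = 65))
  # no bird reached the far coastal station: silence there
  expect_false("PetitManan" %in% ds$detections$station)
  # event time recovered within one scan period of the true event
  for (tag in unique(ds$truth$tag_id)) {
    d <- ds$detections[ds$detections$tag_id == tag &
                         ds$detections$station == "IDH", ]
    if (!nrow(d)) next
    t_est <- event_time_from_peak(detection_series(d))
    t_true <- ds$truth$dest_time[ds$truth$tag_id == tag &
                                   ds$truth$stage == "ocean"]
    expect_lt(abs(t_est - t_true), 28)
  }
  # without injected noise the pulse-rate filter is a no-op
  d <- ds$detections[ds$detections$tag_id == ds$detections$tag_id[1] &
                       ds$detections$station == ds$detections$station[1], ]
  f <- filter_false_positives(detection_series(d), cfg$pulse_rate_s)
  expect_equal(nrow(f), nrow(d))
})

test_that("datasets are reproducible and complete at the default config", {
  ds1 <- suppressWarnings(generate_dataset(sim_config(), seed = 1))
  ds2 <- suppressWarnings(generate_dataset(sim_config(), seed = 1))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_detections(ds1$detections, f1)
  write_detections(ds2$detections, f2)
  expect_identical(readLines(f1), readLines(f2))
  ds_alt <- suppressWarnings(generate_dataset(sim_config(), seed = 2))
  expect_false(identical(ds1$detections, ds_alt$detections))
  # at least 20 flights simulated end to end; a healthy two-stage subset
  expect_gte(length(unique(ds1$truth$tag_id)), 20)
  expect_gte(sum(table(ds1$truth$tag_id) == 2), 12)
  # reconstructed durations sit within one coastal scan period of truth
  seg <- reconstruct_segments(ds1$detections, ds1$birds)
  m <- merge(seg, ds1$truth, by = c("tag_id", "stage"))
  expect_lt(median(abs(m$duration_min.x - m$duration_min.y)), 28 / 60)
})

test_that("spurious injections are removed by the pulse-rate filter", {
  cfg <- sim_config(spurious_rate_per_hour = 6, n_adults = 3,
                    n_juveniles = 2, departure_mean_evening = 2,
                    departure_sd_evenings = 1)
  ds <- suppressWarnings(generate_dataset(cfg, seed = 66))
  d <- ds$detections[ds$detections$station == "IDH", ]
  for (tag in unique(d$tag_id)) {
    s <- detection_series(d[d$tag_id == tag, ])
    f <- filter_false_positives(s, cfg$pulse_rate_s)
    expect_lte(nrow(f), nrow(s))
    # despite injected noise the filtered peak recovers the true event
    t_true <- ds$truth$dest_time[ds$truth$tag_id == tag &
                                   ds$truth$stage == "ocean"]
    expect_lt(abs(event_time_from_peak(f) - t_true), 28)
  }
})

test_that("full round trip recovers the generating world", {
  # simulate -> render -> reconstruct -> annotate -> probe -> pathfit at
  # three seeds (one end-to-end run costs seconds; the 90%-of-seeds level
  # recovery statement is checked at scale in scratch studies: 48/50
  # ocean, 50/50 coast at the default config)
  for (s in 1:3) {
    ds <- suppressWarnings(generate_dataset(sim_config(), seed = s))
    res <- suppressWarnings(run_pipeline(ds$detections, ds$winds,
                                         ds$birds))
    # (i) the flown levels are re-identified
    expect_equal(res$scans$ocean$selected_level, "1000mb")
    expect_equal(res$scans$coast$selected_level, "925mb")
    # (ii, iii) sign structure of the full duration model
    pf <- fit_path(full_flight_dag("flight_duration",
                                   interactions = FALSE), res$table)
    cf <- pf$coefficients
    expect_gt(cf$estimate[cf$node == "tailwind" & cf$term == "age"], 0)
    expect_lt(cf$estimate[cf$node == "flight_duration" &
                            cf$term == "tailwind"], 0)
    # (iv) climb penalty on: direct stage effect on log groundspeed
    ed <- res$groundspeed_model$final$dag$edges
    expect_true(any(ed$from == "stage" & ed$to == "log_groundspeed"))
    # (iv) climb penalty off: the direct effect disappears
    ds0 <- suppressWarnings(generate_dataset(sim_config(climb_rate_ms = 0),
                                             seed = s))
    res0 <- suppressWarnings(run_pipeline(ds0$detections, ds0$winds,
                                          ds0$birds))
    ed0 <- res0$groundspeed_model$final$dag$edges
    expect_false(any(ed0$from == "stage" & ed0$to == "log_groundspeed"))
  }
})
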