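test_that("tailwind/crosswind components follow the wind-triangle formulas", {
  w <- wind_components(10, 275, 275)
  expect_equal(c(w$tailwind, w$crosswind), c(10, 0))
  w <- wind_components(10, 95, 275)
  expect_equal(c(w$tailwind, w$crosswind), c(-10, 0))
  # 60 degrees off the track: cos = 0.5, sin = 0.866
  w <- wind_components(8, 335, 275)
  expect_equal(w$tailwind, 4)
  expect_equal(w$crosswind, 8 * sin(pi / 3), tolerance = 1e-9)
  expect_error(wind_components(-1, 0, 0), ">= 0")
})

test_that("wind-component identities hold over random inputs", {
  set.seed(31)
  for (i in 1:500) {
    vw <- runif(1, 0, 25); wd <- runif(1, 0, 360); td <- runif(1, 0, 360)
    w <- wind_components(vw, wd, td)
    expect_equal(w$tailwind^2 + w$crosswind^2, vw^2, tolerance = 1e-9)
    # 360-degree invariance in either argument
    w2 <- wind_components(vw, wd + 360, td)
    w3 <- wind_components(vw, wd, td + 360)
    expect_equal(w$tailwind, w2$tailwind, tolerance = 1e-9)
    expect_equal(w$crosswind, w3$crosswind, tolerance = 1e-9)
    # crosswind is odd and tailwind even in the angle difference
    wneg <- wind_components(vw, td - (wd - td), td)
    expect_equal(wneg$tailwind, w$tailwind, tolerance = 1e-9)
    expect_equal(wneg$crosswind, -w$crosswind, tolerance = 1e-9)
  }
})

test_that("IDW interpolation reproduces nodes, symmetry and hand weights", {
  samp <- function(lat, lon, time, u, v) {
    w <- uv_to_wind(u, v)
    data.frame(lat = lat, lon = lon, time = time,
               wind_speed_ms = w$wind_speed, wind_dir_to_deg = w$wind_dir_to)
  }
  s <- rbind(samp(44, -67, 0, 2, 1), samp(44.3, -67, 0, 5, -2))
  hit <- idw_interpolate(s, 44.3, -67, 0)
  expect_equal(c(hit$u, hit$v), c(5, -2), tolerance = 1e-9)
  # equidistant in time between u = 2 and u = 4: the mean
  s <- rbind(samp(44, -67, 0, 2, 0), samp(44, -67, 7200, 4, 0))
  mid <- idw_interpolate(s, 44, -67, 3600)
  expect_equal(c(mid$u, mid$v), c(3, 0), tolerance = 1e-9)
  # scaled distances 1, 2, 4 with power 1: (8 + 2 + 0.5)/(1 + .5 + .25)
  s <- rbind(samp(44, -67, 3 * 3600, 8, 0),
             samp(44, -67, 6 * 3600, 4, 0),
             samp(44, -67, 12 * 3600, 2, 0))
  q <- idw_interpolate(s, 44, -67, 0, power = 1)
  expect_equal(q$u, 6, tolerance = 1e-9)
  expect_error(idw_interpolate(s[0, ], 44, -67, 0), "no wind samples")
  # constant fields come back exactly; outputs stay in the sample range
  set.seed(32)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    s <- samp(runif(n, 44, 45), runif(n, -68, -66), runif(n, 0, 1e4),
              runif(n, -5, 5), runif(n, -5, 5))
    q <- idw_interpolate(s, 44.5, -67, 5000)
    uv <- wind_to_uv(s$wind_speed_ms, s$wind_dir_to_deg)
    expect_gte(q$u, min(uv$u) - 1e-9); expect_lte(q$u, max(uv$u) + 1e-9)
    expect_gte(q$v, min(uv$v) - 1e-9); expect_lte(q$v, max(uv$v) + 1e-9)
    const <- samp(runif(4, 44, 45), runif(4, -68, -66), runif(4, 0, 1e4),
                  rep(2.5, 4), rep(-1.5, 4))
    qc <- idw_interpolate(const, 44.2, -66.5, 123)
    expect_equal(c(qc$u, qc$v), c(2.5, -1.5), tolerance = 1e-9)
  }
})

test_that("segment midpoints are central in space and time", {
  seg <- list(origin_lat = 0, origin_lon = 0, dest_lat = 0, dest_lon = 2,
              origin_time = 0, dest_time = 3600)
  m <- segment_midpoint(seg)
  expect_equal(c(m$lat, m$lon, m$time), c(0, 1, 1800), tolerance = 1e-9)
  bad <- seg; bad$dest_time <- 0
  expect_error(segment_midpoint(bad), "follow")
  # the island-to-crossing leg, against the independent midpoint oracle
  ne <- destination_point(IDH_LOC["lat"], IDH_LOC["lon"], 55, 7.5)
  seg <- list(origin_lat = KENT["lat"], origin_lon = KENT["lon"],
              dest_lat = ne$lat, dest_lon = ne$lon,
              origin_time = 0, dest_time = 3480)
  m <- segment_midpoint(seg)
  expect_equal(c(m$lat, m$lon), c(44.611, -66.970), tolerance = 0.01,
               ignore_attr = TRUE)
  o <- oracle_midpoint(KENT["lat"], KENT["lon"], ne$lat, ne$lon)
  expect_equal(unname(c(m$lat, m$lon)), unname(o), tolerance = 1e-9)
})

test_that("level mean altitudes and labels behave", {
  a <- level_mean_altitude(c(800, 800, 800))
  expect_equal(c(a$mean_m, a$sd_m), c(800, 0))
  a <- level_mean_altitude(c(120, 208))
  expect_equal(a$mean_m, 164)
  expect_equal(a$sd_m, sd(c(120, 208)), tolerance = 1e-12)
  expect_error(level_mean_altitude(numeric(0)), "no geopotential")
})

test_that("per-level annotation projects midpoint winds on the track", {
  lv <- default_levels()
  mk_winds <- function(dir_to, speed = 6) {
    do.call(rbind, lapply(lv$level_id, function(l)
      data.frame(level_id = l,
                 lat = rep(c(44, 45), each = 2), lon = c(-68, -66),
                 time = 0, wind_speed_ms = speed,
                 wind_dir_to_deg = dir_to,
                 geopotential_height_m =
                   if (grepl("mb$", l))
                     lv$nominal_altitude_m[lv$level_id == l]
                   else NA_real_)))
  }
  seg <- list(tag_id = "t1", stage = "ocean",
              origin_lat = 44.5, origin_lon = -67.5,
              dest_lat = 44.5, dest_lon = -67.0,
              origin_time = 0, dest_time = 3600, track_deg = 275)
  ann <- annotate_segment(seg, mk_winds(275))
  expect_equal(nrow(ann), nrow(lv))   # one annotation per level
  expect_equal(ann$tailwind_ms, rep(6, nrow(lv)), tolerance = 1e-9)
  # headwind everywhere: all tailwinds negative
  ann <- annotate_segment(seg, mk_winds(95))
  expect_true(all(ann$tailwind_ms < 0))
  # missing level: warn and skip
  w <- mk_winds(275)
  w <- w[w$level_id != "925mb", ]
  expect_warning(ann <- annotate_segment(seg, w, levels = lv$level_id),
                 "925mb")
  expect_equal(nrow(ann), nrow(lv) - 1)
  # one supportive level stands out
  w <- mk_winds(95)
  w$wind_dir_to_deg[w$level_id == "925mb"] <- 275
  ann <- annotate_segment(seg, w)
  expect_equal(ann$level_id[which.max(ann$tailwind_ms)], "925mb")
})
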