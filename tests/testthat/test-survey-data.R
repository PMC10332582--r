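test_that("record parsing validates stations, timestamps and deployment windows", {
  st <- make_stations(n = 2, activation = as.Date("2021-01-10"), days = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(station_id = rep(st$station_id[1], 3),
                       species = "tiger_cat",
                       timestamp = c("2021-01-10T10:00", "2021-01-12T08:30",
                                     "2021-02-01T23:59")),
            path, row.names = FALSE)
  rec <- read_records(path, st)
  expect_s3_class(rec, "record_table")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_dropped"), 0L)

  write.csv(data.frame(station_id = "nowhere", species = "x",
                       timestamp = "2021-01-11T10:00"), path, row.names = FALSE)
  expect_error(read_records(path, st), "nowhere")

  write.csv(data.frame(station_id = st$station_id[1], species = "x",
                       timestamp = "2021-02-30T10:00"), path, row.names = FALSE)
  expect_error(read_records(path, st), "row")

  # record before activation is dropped with a warning, not an error
  df <- data.frame(station_id = st$station_id[1], species = "x",
                   timestamp = c("2021-01-05T10:00", "2021-01-15T10:00"))
  expect_warning(rec <- as_record_table(df, st), "dropped")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "n_dropped"), 1L)

  # empty table is allowed
  empty <- as_record_table(data.frame(station_id = character(),
                                      species = character(),
                                      timestamp = character()), st)
  expect_equal(nrow(empty), 0)
})

test_that("guild pooling relabels mapped species and feeds the day filter", {
  st <- make_stations(n = 2)
  rec <- make_records(st, rep(st$station_id[1], 3),
                      c("puma", "dog", "tayra"),
                      c("2021-01-02T03:00", "2021-01-02T14:00",
                        "2021-01-02T20:00"))
  map <- c(puma = "killer", dog = "killer", ocelot = "killer",
           andean_bear = "killer")
  pooled <- pool_guild(rec, map)
  expect_equal(nrow(pooled), 3)
  expect_equal(sort(unique(pooled$species)), c("killer", "tayra"))
  # pooling first, then the 24-h filter: puma + dog same station/day
  # collapse to a single independent killer detection
  ind <- filter_independent(pooled)
  expect_equal(sum(ind$species == "killer"), 1)
  expect_equal(sum(ind$species == "tayra"), 1)
})

test_that("independence filter keeps the earliest record per station/species/day", {
  st <- make_stations(n = 2)
  rec <- make_records(st,
    rep(st$station_id[1], 5),
    c("tiger_cat", "tiger_cat", "tiger_cat", "tiger_cat", "tayra"),
    c("2021-01-02T10:00", "2021-01-02T23:00",   # same day -> 1
      "2021-01-03T01:00", "2021-01-04T01:00",   # consecutive days -> 2
      "2021-01-02T11:00"))                      # other species same day -> kept
  ind <- filter_independent(rec)
  expect_equal(nrow(ind), 4)
  tc_day2 <- ind[ind$species == "tiger_cat" &
                   as.Date(ind$timestamp, tz = "UTC") == "2021-01-02", ]
  expect_equal(format(tc_day2$timestamp, "%H:%M"), "10:00")
  # idempotence
  expect_equal(filter_independent(ind), ind)
})

test_that("weekly histories follow deployment-aligned block arithmetic", {
  st <- make_stations(n = 1, days = 130)
  rec <- make_records(st, st$station_id[1], "tiger_cat", "2021-01-08T10:00")
  h <- build_history(filter_independent(rec), st, "tiger_cat")
  expect_equal(ncol(h$y), 19)                  # ceil(130/7)
  expect_equal(h$effort[1, 19], 4L)            # 130 - 18*7
  expect_equal(unname(h$y[1, 2]), 1L)          # day 8 -> occasion 2
  expect_equal(sum(h$y == 1, na.rm = TRUE), 1)

  # a full inactive block becomes missing with zero effort
  gap <- data.frame(station_id = st$station_id[1],
                    date = as.Date("2021-01-15") + 0:6)   # occasion 3
  h2 <- build_history(filter_independent(rec), st, "tiger_cat",
                      inactive_days = gap)
  expect_equal(h2$effort[1, 3], 0L)
  expect_true(is.na(h2$y[1, 3]))

  # unknown species yields an all zero/missing history with a warning
  expect_warning(h3 <- build_history(filter_independent(rec), st, "ghost"),
                 "ghost")
  expect_true(all(h3$y == 0 | is.na(h3$y)))
})

test_that("single detections land in occasion floor((d-1)/7)+1 for every day", {
  st <- make_stations(n = 1, days = 60)
  for (d in 1:60) {
    ts <- format(as.Date("2021-01-01") + d - 1, "%Y-%m-%dT12:00")
    rec <- make_records(st, st$station_id[1], "sp", ts)
    h <- build_history(rec, st, "sp")
    expect_equal(unname(which(h$y[1, ] == 1)), (d - 1) %/% 7 + 1)
  }
})

test_that("missing cells coincide exactly with zero-effort cells", {
  srv <- make_three_reserve_survey()
  h <- build_history(filter_independent(srv$records), srv$stations,
                     "tiger_cat")
  expect_identical(is.na(h$y), h$effort == 0L)
  # occasion-level count never exceeds the raw record count
  expect_lte(sum(h$y == 1, na.rm = TRUE),
             sum(srv$records$species == "tiger_cat"))
})

test_that("survey summary totals equal block sums and the empty case is zero", {
  srv <- make_three_reserve_survey()
  rec <- filter_independent(srv$records)
  hs <- lapply(names(srv$counts), function(sp)
    build_history(rec, srv$stations, sp))
  names(hs) <- names(srv$counts)
  sm <- summarize_survey(hs, srv$stations, srv$records)
  bl <- sm$blocks
  tot <- bl[bl$block == "total", ]
  expect_equal(tot$trap_nights,
               sum(bl$trap_nights[bl$block != "total"]))
  expect_equal(tot$n_active_stations, 58)
  for (sp in names(srv$counts)) {
    rows <- sm$species[sm$species$species == sp, ]
    expect_equal(rows$detections_occasion[rows$block == "total"],
                 sum(rows$detections_occasion[rows$block != "total"]))
    expect_true(all(rows$naive_occupancy >= 0 & rows$naive_occupancy <= 1))
  }
  empty <- summarize_survey(list(), srv$stations)
  expect_equal(nrow(empty$species), 0)
})

test_that("history CSV round-trips through write_history/read_history", {
  st <- make_stations(n = 3, days = c(20, 15, 9))
  rec <- make_records(st, st$station_id[c(1, 2)], "sp",
                      c("2021-01-03T10:00", "2021-01-12T10:00"))
  h <- build_history(filter_independent(rec), st, "sp")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_history(h, p1, p2)
  h2 <- read_history(p1, p2, species_label = "sp")
  expect_equal(unname(h2$y), unname(h$y))
  expect_equal(unname(h2$effort), unname(h$effort))
})
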