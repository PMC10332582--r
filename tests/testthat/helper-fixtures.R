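# Fixtures built in code: a three-reserve survey whose printed summary
# numbers (per-block trap-nights, MCP areas, occasion-level detection
# counts) are known by construction, plus small station/record builders.

make_stations <- function(n = 3, block = "B1", x = NULL, y = NULL,
                          activation = as.Date("2021-01-01"), days = 70,
                          coord_system = "planar", pir = "fast",
                          ids = NULL) {
  ids <- ids %||% sprintf("%s_st%02d", block, seq_len(n))
  days <- rep_len(days, n)
  activation <- rep(activation, length.out = n)
  as_station_table(data.frame(
    station_id = ids,
    x = x %||% (seq_len(n) * 1000), y = y %||% rep(0, n),
    coord_system = coord_system,
    activation_date = activation,
    retrieval_date = activation + days - 1,
    pir_delay_class = pir, block_id = block))
}

make_records <- function(stations, station_id, species, timestamp) {
  as_record_table(data.frame(station_id = station_id, species = species,
                             timestamp = timestamp), stations)
}

# Three-block survey: block MCPs are exact rectangles (26.57, 26.49 and
# 21.02 km^2), per-block effort sums to 4518, 2829 and 3342 trap-nights,
# and detections are placed one per (station, occasion) cell so that the
# occasion-level counts are 70/46/13 (tiger cat), 63/41/14 (tayra) and
# 46/16/11 (killer guild) across the blocks.
make_three_reserve_survey <- function() {
  block_def <- list(
    list(id = "MPNR", n = 19, effort = 4518, area = 26.57,
         origin = c(0, 0), act = as.Date("2020-08-01")),
    list(id = "CSJIMD", n = 19, effort = 2829, area = 26.49,
         origin = c(20000, 0), act = as.Date("2021-12-01")),
    list(id = "CSCD", n = 20, effort = 3342, area = 21.02,
         origin = c(40000, 0), act = as.Date("2021-02-01")))
  st_list <- lapply(block_def, function(b) {
    w <- b$area * 1e6 / 5000          # rectangle w x 5000 m, exact area
    xs <- numeric(b$n); ys <- numeric(b$n)
    xs[1:4] <- c(0, w, w, 0); ys[1:4] <- c(0, 0, 5000, 5000)
    if (b$n > 4) {  # interior points, inside the hull
      k <- b$n - 4
      xs[5:b$n] <- w * (seq_len(k) / (k + 1))
      ys[5:b$n] <- 2500
    }
    base <- b$effort %/% b$n
    days <- rep(base, b$n)
    extra <- b$effort - base * b$n
    if (extra > 0) days[seq_len(extra)] <- base + 1
    make_stations(n = b$n, block = b$id, x = b$origin[1] + xs,
                  y = b$origin[2] + ys, activation = b$act, days = days)
  })
  stations <- do.call(rbind, st_list)
  class(stations) <- c("station_table", "data.frame")

  counts <- list(tiger_cat = c(MPNR = 70, CSJIMD = 46, CSCD = 13),
                 tayra = c(MPNR = 63, CSJIMD = 41, CSCD = 14),
                 killer = c(MPNR = 46, CSJIMD = 16, CSCD = 11))
  rec_rows <- list()
  for (sp in names(counts)) {
    for (b in names(counts[[sp]])) {
      sel <- which(stations$block_id == b)
      cnt <- counts[[sp]][[b]]
      k <- seq_len(cnt) - 1
      si <- sel[(k %% length(sel)) + 1]
      occ <- (k %/% length(sel)) + 1
      day <- stations$activation_date[si] + (occ - 1) * 7
      rec_rows[[paste(sp, b)]] <- data.frame(
        station_id = stations$station_id[si], species = sp,
        timestamp = paste0(format(day, "%Y-%m-%d"), "T12:00"))
    }
  }
  records <- as_record_table(do.call(rbind, rec_rows), stations)
  list(stations = stations, records = records, counts = counts)
}

# intercept-only design for a history without covariates
null_design <- function(history) {
  tab <- data.frame(station_id = history$stations)
  build_design(tab, effort = history$effort)
}

# brute-force grid-search oracle for the intercept-only occupancy MLE:
# profile the joint likelihood over (psi, p) on a step-1e-3 grid using the
# sufficient statistics (detections and observed occasions per site)
grid_oracle <- function(y, step = 1e-3) {
  det <- rowSums(y == 1, na.rm = TRUE) > 0
  d_i <- rowSums(y == 1, na.rm = TRUE)
  m_i <- rowSums(!is.na(y))
  D <- sum(det); Sd <- sum(d_i[det]); Sm <- sum(m_i[det])
  psi <- seq(step, 1 - step, by = step)
  p <- seq(step, 1 - step, by = step)
  ll <- outer(psi, p, function(ps, pp)
    D * log(ps) + Sd * log(pp) + (Sm - Sd) * log(1 - pp))
  m0 <- table(m_i[!det])
  for (m in names(m0)) {
    mm <- as.numeric(m)
    ll <- ll + as.numeric(m0[[m]]) *
      log(outer(psi, (1 - p)^mm) + (1 - psi))
  }
  best <- arrayInd(which.max(ll), dim(ll))
  c(psi = psi[best[1]], p = p[best[2]])
}

# enumerate all {0,1}^J single-species histories
enum_histories <- function(J) {
  as.matrix(expand.grid(rep(list(0:1), J)))
}

# minimal detection_history wrapper around a y matrix
as_history <- function(y, species = "sp") {
  eff <- matrix(7L, nrow(y), ncol(y))
  eff[is.na(y)] <- 0L
  structure(list(species = species,
                 stations = paste0("st", seq_len(nrow(y))),
                 y = y, effort = eff, occasion_days = 7),
            class = "detection_history")
}
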