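#' Read a camera-trap station table
#'
#' Parses the station metadata CSV: one row per camera station with planar or
#' geographic coordinates, deployment window, PIR trigger-delay class and
#' protected-area block.
#'
#' @param path CSV with columns `station_id, x, y, coord_system, activation_date,
#'   retrieval_date, pir_delay_class, block_id`. `coord_system` must be
#'   `"planar"` (meters) or `"lonlat"` (degrees) and identical on all rows.
#' @return A `data.frame` of class `station_table`.
#' @export
read_stations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_station_table(df)
}

#' Validate a station table
#'
#' @param df data.frame with the columns documented in [read_stations()].
#' @return the validated `station_table`.
#' @export
as_station_table <- function(df) {
  need <- c("station_id", "x", "y", "coord_system", "activation_date",
            "retrieval_date", "pir_delay_class", "block_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("station table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$station_id))
    stop("duplicated station_id: ",
         paste(unique(df$station_id[duplicated(df$station_id)]), collapse = ", "))
  if (length(unique(df$coord_system)) != 1L ||
      !df$coord_system[1] %in% c("planar", "lonlat"))
    stop("coord_system must be a single value, 'planar' or 'lonlat'")
  df$activation_date <- as.Date(df$activation_date)
  df$retrieval_date <- as.Date(df$retrieval_date)
  if (anyNA(df$activation_date) || anyNA(df$retrieval_date))
    stop("unparseable activation/retrieval dates")
  bad <- df$activation_date > df$retrieval_date
  if (any(bad))
    stop("activation after retrieval for station(s): ",
         paste(df$station_id[bad], collapse = ", "))
  class(df) <- c("station_table", "data.frame")
  df
}

# strict ISO-8601 minute/second-resolution parser; returns POSIXct or NA
parse_iso_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"),
                    optional = TRUE)
  # as.POSIXct accepts impossible dates like 2021-02-30 on some platforms;
  # round-trip the date part to catch them
  ok <- !is.na(out) & format(out, "%Y-%m-%d") == substr(x, 1, 10)
  out[!ok] <- as.POSIXct(NA)
  out
}

#' Read camera-trap records
#'
#' Parses a photographic-record CSV and validates it against the station
#' table. Records time-stamped outside their station's deployment window
#' (clock-reset artifacts, test triggers) are dropped with a warning; the
#' number dropped is kept in `attr(x, "n_dropped")`.
#'
#' @param path CSV with header columns `station_id, species, timestamp`
#'   (ISO-8601, minute resolution or finer).
#' @param stations a `station_table`.
#' @return `data.frame` of class `record_table` with columns
#'   `station_id, species, timestamp` (POSIXct, UTC).
#' @export
read_records <- function(path, stations) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "species", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("record table missing columns: ", paste(miss, collapse = ", "))
  as_record_table(df, stations)
}

#' @rdname read_records
#' @param df data.frame with columns `station_id, species, timestamp`.
#' @export
as_record_table <- function(df, stations) {
  stopifnot(inherits(stations, "station_table"))
  if (nrow(df) == 0L) {
    out <- data.frame(station_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"))
    class(out) <- c("record_table", "data.frame")
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  unknown <- setdiff(unique(df$station_id), stations$station_id)
  if (length(unknown))
    stop("unknown station_id in records: ", paste(unknown, collapse = ", "))
  ts <- parse_iso_timestamp(as.character(df$timestamp))
  if (anyNA(ts))
    stop("unparseable timestamp at row(s): ",
         paste(which(is.na(ts)), collapse = ", "))
  df$timestamp <- ts
  idx <- match(df$station_id, stations$station_id)
  day <- as.Date(df$timestamp, tz = "UTC")
  inside <- day >= stations$activation_date[idx] &
    day <= stations$retrieval_date[idx]
  n_dropped <- sum(!inside)
  if (n_dropped > 0)
    warning(n_dropped, " record(s) outside the station deployment window dropped")
  out <- df[inside, c("station_id", "species", "timestamp"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("record_table", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Pool species labels into a guild
#'
#' Relabels records according to a partial map, e.g. pumas, ocelots, dogs and
#' Andean bears into a single "killer" class, or all small mammals into
#' "prey". Pooling is applied before independence filtering so that a guild
#' detection day is any member's record.
#'
#' @param records a `record_table`.
#' @param label_map named character vector or list, `old label -> pooled label`;
#'   unmapped labels pass through unchanged.
#' @return a `record_table` with the same number of rows.
#' @export
pool_guild <- function(records, label_map) {
  stopifnot(inherits(records, "record_table"))
  label_map <- unlist(label_map)
  hit <- records$species %in% names(label_map)
  records$species[hit] <- unname(label_map[records$species[hit]])
  records
}

#' Filter records to one independent detection per day
#'
#' Photographic records of the same species at the same station are pooled
#' over the calendar day: only the earliest record of each
#' (station, species, day) is kept. Day pooling is fixed-bin (not a rolling
#' window), so the operation is order-independent and idempotent.
#'
#' @param records a `record_table`.
#' @return the filtered `record_table`.
#' @export
filter_independent <- function(records) {
  stopifnot(inherits(records, "record_table"))
  if (nrow(records) == 0L) return(records)
  day <- as.Date(records$timestamp, tz = "UTC")
  key <- paste(records$station_id, records$species, day, sep = "\r")
  ord <- order(key, records$timestamp)
  r <- records[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- attr(records, "n_dropped")
  class(out) <- class(records)
  out
}

#' Build a detection history for one species
#'
#' Collapses independence-filtered records into a sites x occasions
#' detection/non-detection matrix. Occasions are consecutive
#' `occasion_days`-long blocks starting at each station's own activation
#' date (the blocks are deployment-aligned, not calendar-aligned, because
#' different reserves run in disjoint calendar windows). A cell is 1 if the
#' species had at least one independent detection in the block, 0 if the
#' camera was active with no detection, and `NA` when effort is zero. The
#' final partial block keeps its remaining days as reduced effort.
#'
#' @param records independence-filtered `record_table`.
#' @param stations a `station_table`.
#' @param species_label species (or pooled guild) to tabulate.
#' @param occasion_days block length in days (default 7, weekly occasions).
#' @param inactive_days optional data.frame `(station_id, date)` of days a
#'   camera is known to have been inoperative (theft/damage gaps); those days
#'   are removed from effort and their blocks can become missing.
#' @return object of class `detection_history`: list with `species`,
#'   `stations` (station id order), `y` (matrix, 0/1/NA), `effort` (matrix of
#'   active days per occasion) and `occasion_days`.
#' @export
build_history <- function(records, stations, species_label, occasion_days = 7,
                          inactive_days = NULL) {
  stopifnot(inherits(stations, "station_table"))
  sp <- records[records$species == species_label, , drop = FALSE]
  if (nrow(sp) == 0L)
    warning("no records of '", species_label, "': history is all zero/missing")
  ndays <- as.integer(stations$retrieval_date - stations$activation_date) + 1L
  J <- max(ceiling(ndays / occasion_days))
  n <- nrow(stations)
  eff <- matrix(0L, n, J, dimnames = list(stations$station_id,
                                          paste0("occ_", seq_len(J))))
  for (i in seq_len(n)) {
    full <- ndays[i] %/% occasion_days
    if (full > 0) eff[i, seq_len(full)] <- occasion_days
    rem <- ndays[i] - full * occasion_days
    if (rem > 0) eff[i, full + 1L] <- rem
  }
  if (!is.null(inactive_days) && nrow(inactive_days) > 0) {
    idx <- match(inactive_days$station_id, stations$station_id)
    if (anyNA(idx)) stop("inactive_days names unknown station(s)")
    d <- as.integer(as.Date(inactive_days$date) -
                      stations$activation_date[idx]) + 1L
    valid <- d >= 1L & d <= ndays[idx]
    occ <- (d[valid] - 1L) %/% occasion_days + 1L
    for (k in seq_along(occ))
      eff[idx[valid][k], occ[k]] <- max(0L, eff[idx[valid][k], occ[k]] - 1L)
  }
  y <- matrix(NA_integer_, n, J, dimnames = dimnames(eff))
  y[eff > 0] <- 0L
  if (nrow(sp) > 0) {
    si <- match(sp$station_id, stations$station_id)
    if (anyNA(si)) stop("record references unknown station")
    d <- as.integer(as.Date(sp$timestamp, tz = "UTC") -
                      stations$activation_date[si]) + 1L
    occ <- (d - 1L) %/% occasion_days + 1L
    ok <- occ >= 1L & occ <= J
    for (k in which(ok)) if (eff[si[k], occ[k]] > 0) y[si[k], occ[k]] <- 1L
  }
  structure(list(species = species_label, stations = stations$station_id,
                 y = y, effort = eff, occasion_days = occasion_days),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat("Detection history:", x$species, "\n")
  cat(sprintf("  %d sites x %d occasions (%d-day), %d detections, %d missing cells\n",
              nrow(x$y), ncol(x$y), x$occasion_days,
              sum(x$y == 1, na.rm = TRUE), sum(is.na(x$y))))
  invisible(x)
}

#' Minimum convex polygon area of a station set
#'
#' Area of the convex hull enclosing station coordinates, the standard
#' sampled-area summary of a camera-trap grid. Planar coordinates use the
#' shoelace formula; lon/lat coordinates use a spherical polygon area.
#'
#' @param x,y coordinate vectors.
#' @param coord_system `"planar"` (meters) or `"lonlat"` (degrees).
#' @return area in square kilometers.
#' @export
mcp_area_km2 <- function(x, y, coord_system = "planar") {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (coord_system == "lonlat") {
    return(geosphere::areaPolygon(cbind(x[h], y[h])) / 1e6)
  }
  xs <- x[h]; ys <- y[h]
  n <- length(h)
  a <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  a / 1e6
}

#' Summarize survey effort and detections
#'
#' Per-block and total trap-nights, active stations, minimum-convex-polygon
#' area, and per-species independent detections at occasion resolution (and
#' daily resolution when the filtered records are supplied), with naive
#' occupancy (fraction of sites with at least one detection).
#'
#' @param histories named list of `detection_history` objects (one per
#'   species/guild) sharing the station set.
#' @param stations a `station_table`.
#' @param records optional independence-filtered `record_table` used for the
#'   daily-resolution counts.
#' @return object of class `survey_summary`: list with `blocks` (data.frame,
#'   one row per block plus a `total` row) and `species` (data.frame of
#'   per-species counts by block and total, with naive occupancy).
#' @export
summarize_survey <- function(histories, stations, records = NULL) {
  stopifnot(inherits(stations, "station_table"))
  blocks <- sort(unique(as.character(stations$block_id)))
  if (length(histories) > 0) {
    for (h in histories)
      if (!identical(as.character(h$stations),
                     as.character(stations$station_id)))
        stop("histories must share the station table's station order")
  }
  eff0 <- if (length(histories)) histories[[1]]$effort else
    matrix(0L, nrow(stations), 0)
  bi <- as.character(stations$block_id)
  block_rows <- lapply(c(blocks, "total"), function(b) {
    sel <- if (b == "total") rep(TRUE, nrow(stations)) else bi == b
    data.frame(
      block = b,
      n_active_stations = sum(sel),
      trap_nights = sum(eff0[sel, , drop = FALSE]),
      mcp_km2 = if (b == "total")
        sum(vapply(blocks, function(bb)
          mcp_area_km2(stations$x[bi == bb], stations$y[bi == bb],
                       stations$coord_system[1]), numeric(1)))
      else mcp_area_km2(stations$x[sel], stations$y[sel],
                        stations$coord_system[1]))
  })
  block_df <- do.call(rbind, block_rows)

  day_counts <- NULL
  if (!is.null(records) && nrow(records) > 0) {
    records <- filter_independent(records)
    rb <- bi[match(records$station_id, stations$station_id)]
    day_counts <- table(records$species, rb)
  }
  sp_rows <- lapply(names(histories), function(spn) {
    h <- histories[[spn]]
    occ_by_block <- vapply(c(blocks, "total"), function(b) {
      sel <- if (b == "total") rep(TRUE, nrow(stations)) else bi == b
      sum(h$y[sel, , drop = FALSE] == 1, na.rm = TRUE)
    }, numeric(1))
    daily <- vapply(c(blocks, "total"), function(b) {
      if (is.null(day_counts) || !spn %in% rownames(day_counts)) return(NA_real_)
      if (b == "total") sum(day_counts[spn, ])
      else if (b %in% colnames(day_counts)) day_counts[spn, b] else 0
    }, numeric(1))
    det_site <- rowSums(h$y == 1, na.rm = TRUE) > 0
    data.frame(species = spn, block = c(blocks, "total"),
               detections_occasion = occ_by_block,
               detections_daily = daily,
               n_sites_with_detection = vapply(c(blocks, "total"), function(b) {
                 sel <- if (b == "total") rep(TRUE, nrow(stations)) else bi == b
                 sum(det_site[sel])
               }, numeric(1)),
               naive_occupancy = vapply(c(blocks, "total"), function(b) {
                 sel <- if (b == "total") rep(TRUE, nrow(stations)) else bi == b
                 mean(det_site[sel])
               }, numeric(1)))
  })
  species_df <- if (length(sp_rows)) do.call(rbind, sp_rows) else
    data.frame(species = character(), block = character(),
               detections_occasion = numeric(), detections_daily = numeric(),
               n_sites_with_detection = numeric(), naive_occupancy = numeric())
  rownames(block_df) <- rownames(species_df) <- NULL
  structure(list(blocks = block_df, species = species_df),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Survey summary\n")
  print(x$blocks, row.names = FALSE)
  if (nrow(x$species)) print(x$species, row.names = FALSE)
  invisible(x)
}

#' Write / read a detection history as CSV
#'
#' The history CSV has a `station_id` first column then `occ_1..occ_J` with
#' values 0/1/NA; the paired effort CSV has the same shape. `"NA"` is the
#' only missing token.
#'
#' @param history a `detection_history`.
#' @param path,effort_path output CSV paths.
#' @export
write_history <- function(history, path, effort_path) {
  df <- data.frame(station_id = history$stations, history$y,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "NA")
  de <- data.frame(station_id = history$stations, history$effort,
                   check.names = FALSE)
  write.csv(de, effort_path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_history
#' @param species_label label to attach to the re-read history.
#' @param occasion_days occasion length of the stored history.
#' @export
read_history <- function(path, effort_path, species_label = "species",
                         occasion_days = 7) {
  df <- read.csv(path, check.names = FALSE)
  de <- read.csv(effort_path, check.names = FALSE)
  stopifnot(identical(df$station_id, de$station_id))
  y <- as.matrix(df[, -1, drop = FALSE])
  eff <- as.matrix(de[, -1, drop = FALSE])
  storage.mode(y) <- "integer"; storage.mode(eff) <- "integer"
  rownames(y) <- rownames(eff) <- df$station_id
  if (!all(is.na(y) == (eff == 0)))
    stop("history/effort mismatch: missing cells must coincide with zero effort")
  structure(list(species = species_label, stations = df$station_id,
                 y = y, effort = eff, occasion_days = occasion_days),
            class = "detection_history")
}
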