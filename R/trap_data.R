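#' Site registry of candidate trap locations
#'
#' A registry holds the integer site labels and planar coordinates (in
#' kilometres) of every candidate trapping location. All spatial structure in
#' the growth model (exponential correlation, kriging) is a function of the
#' pairwise Euclidean distances between these coordinates, so the coordinates
#' must be planar; longitude/latitude input goes through
#' [project_coordinates()] first.
#'
#' @param site_id integer vector of unique site labels.
#' @param x_km,y_km numeric planar coordinates in kilometres.
#' @return A `site_registry`: a `data.frame` with columns `site_id`, `x_km`,
#'   `y_km`.
#' @examples
#' site_registry(1:3, x_km = c(0, 1, 2), y_km = c(0, 0, 1))
#' @export
site_registry <- function(site_id, x_km, y_km) {
  site_id <- as.integer(site_id)
  x_km <- as.numeric(x_km)
  y_km <- as.numeric(y_km)
  if (length(site_id) < 2L) {
    stop("a site registry needs at least 2 sites", call. = FALSE)
  }
  if (anyDuplicated(site_id)) {
    stop("duplicate site_id in registry: ",
         paste(unique(site_id[duplicated(site_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(x_km) != length(site_id) || length(y_km) != length(site_id)) {
    stop("site_id, x_km and y_km must have equal length", call. = FALSE)
  }
  if (!all(is.finite(x_km)) || !all(is.finite(y_km))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  out <- data.frame(site_id = site_id, x_km = x_km, y_km = y_km)
  if (anyDuplicated(out[, c("x_km", "y_km")])) {
    warning("two sites share identical coordinates; distances of zero between ",
            "distinct sites make the spatial correlation matrix singular")
  }
  class(out) <- c("site_registry", "data.frame")
  out
}

#' Pairwise Euclidean distances between registry sites
#' @param registry a [site_registry()].
#' @return symmetric matrix of distances in km, dimnames = site ids.
#' @keywords internal
site_distances <- function(registry) {
  d <- as.matrix(stats::dist(cbind(registry$x_km, registry$y_km)))
  dimnames(d) <- list(registry$site_id, registry$site_id)
  d
}

#' Assemble a weekly trap-count dataset
#'
#' The central data container: weekly pest counts (in hundreds of pests)
#' indexed by (year, site, week), together with the site registry. Counts may
#' be `NA` (flagged missing) until [impute_missing()] is applied; entirely
#' absent site-years are simply not represented (they are excluded, not
#' imputed). Weeks are 1-based indices within a trapping season, not calendar
#' dates.
#'
#' @param records data.frame with columns `year`, `site_id`, `week`, `count`;
#'   `count` in hundreds of pests, `NA` for flagged-missing cells.
#' @param registry a [site_registry()]; every `site_id` in `records` must be
#'   present here.
#' @return A `trap_dataset` object (list with `records`, `registry`,
#'   `weeks_per_year`, `imputed`).
#' @export
trap_dataset <- function(records, registry) {
  stopifnot(is.data.frame(records))
  needed <- c("year", "site_id", "week", "count")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[needed]
  records$year <- as.integer(records$year)
  records$site_id <- as.integer(records$site_id)
  records$week <- as.integer(records$week)
  records$count <- as.numeric(records$count)
  if (any(records$week < 1L)) stop("week indices must be >= 1", call. = FALSE)
  neg <- !is.na(records$count) & records$count < 0
  if (any(neg)) {
    stop("negative count at (year, site, week) = (",
         paste(records[which(neg)[1L], 1:3], collapse = ", "), ")",
         call. = FALSE)
  }
  key <- paste(records$year, records$site_id, records$week, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (year, site_id, week) record: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  unknown <- setdiff(records$site_id, registry$site_id)
  if (length(unknown)) {
    stop("site_id in records but not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  records <- records[order(records$year, records$site_id, records$week), ]
  rownames(records) <- NULL
  weeks_per_year <- tapply(records$week, records$year, max)
  weeks_per_year <- stats::setNames(as.integer(weeks_per_year),
                                    names(weeks_per_year))
  # observed site-years must cover weeks 1..max contiguously
  sy <- unique(records[, c("year", "site_id")])
  for (i in seq_len(nrow(sy))) {
    w <- records$week[records$year == sy$year[i] &
                        records$site_id == sy$site_id[i]]
    expect <- seq_len(weeks_per_year[as.character(sy$year[i])])
    if (!identical(sort(w), expect)) {
      stop("site ", sy$site_id[i], " in year ", sy$year[i],
           " does not cover weeks 1..", max(expect),
           " contiguously", call. = FALSE)
    }
  }
  structure(
    list(records = records, registry = registry,
         weeks_per_year = weeks_per_year,
         imputed = records[0, c("year", "site_id", "week", "count")]),
    class = "trap_dataset"
  )
}

#' @export
print.trap_dataset <- function(x, ...) {
  n_sy <- nrow(unique(x$records[, c("year", "site_id")]))
  cat("<trap_dataset> ", nrow(x$records), " weekly records, ",
      nrow(x$registry), " sites, ", length(x$weeks_per_year), " years (",
      paste(names(x$weeks_per_year), collapse = ", "), "), ",
      n_sy, " site-year combinations, ",
      sum(is.na(x$records$count)), " missing cell(s)\n", sep = "")
  invisible(x)
}

#' Number of observed site-year combinations
#' @param ds a [trap_dataset()].
#' @return integer count of (site, year) pairs with at least one record.
#' @export
n_site_years <- function(ds) {
  nrow(unique(ds$records[, c("year", "site_id")]))
}

#' Read trap counts and site coordinates from delimited text
#'
#' Counts file: header `year,site_id,week,count`, missing marker `NA`.
#' Sites file: header `site_id,x_km,y_km`, or `site_id,lon,lat` with
#' `lonlat = TRUE` (coordinates are then projected to planar km via
#' [project_coordinates()]).
#'
#' @param path counts CSV.
#' @param coord_path sites CSV.
#' @param lonlat logical; sites file holds degrees rather than km.
#' @param counts_in_hundreds logical; if `FALSE` the file holds raw individual
#'   counts and is divided by 100 on read (the internal unit is hundreds of
#'   pests throughout).
#' @return a [trap_dataset()].
#' @export
read_trap_csv <- function(path, coord_path, lonlat = FALSE,
                          counts_in_hundreds = TRUE) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  if (!file.exists(coord_path)) {
    stop("sites file not found: ", coord_path, call. = FALSE)
  }
  counts <- utils::read.csv(path, na.strings = "NA")
  sites <- utils::read.csv(coord_path)
  if (lonlat) {
    if (!all(c("site_id", "lon", "lat") %in% names(sites))) {
      stop("with lonlat = TRUE the sites file needs columns site_id,lon,lat",
           call. = FALSE)
    }
    xy <- project_coordinates(sites[, c("lon", "lat")])
    registry <- site_registry(sites$site_id, xy$x_km, xy$y_km)
  } else {
    if (!all(c("site_id", "x_km", "y_km") %in% names(sites))) {
      stop("sites file needs columns site_id,x_km,y_km", call. = FALSE)
    }
    registry <- site_registry(sites$site_id, sites$x_km, sites$y_km)
  }
  if (!counts_in_hundreds) counts$count <- counts$count / 100
  trap_dataset(counts, registry)
}

#' Write a trap dataset to the CSV dialects read by [read_trap_csv()]
#'
#' Fixed column order, `.` decimal separator, missing marker `NA`; a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param ds a [trap_dataset()].
#' @param path,coord_path output file paths.
#' @return invisibly, `ds`.
#' @export
write_trap_csv <- function(ds, path, coord_path) {
  utils::write.csv(ds$records[, c("year", "site_id", "week", "count")],
                   path, row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.csv(as.data.frame(ds$registry)[, c("site_id", "x_km", "y_km")],
                   coord_path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Impute flagged-missing weekly counts
#'
#' Each missing weekly count is replaced by the arithmetic mean of all other
#' sites' counts for the same year and week (the study convention for an
#' isolated missing trap-week). `on = "cumulative"` instead averages the donor
#' sites' cumulative counts at that week and back-differences against the
#' site's own cumulative count through the previous week (clipped at zero).
#'
#' @param ds a [trap_dataset()].
#' @param on `"weekly"` (default) or `"cumulative"`; which scale the donor
#'   average is taken on.
#' @return a new `trap_dataset` with no missing cells; `$imputed` is an audit
#'   log of every imputed cell (year, site_id, week, count imputed).
#' @export
impute_missing <- function(ds, on = c("weekly", "cumulative")) {
  on <- match.arg(on)
  rec <- ds$records
  miss <- which(is.na(rec$count))
  if (!length(miss)) return(ds)
  log_rows <- vector("list", length(miss))
  for (j in seq_along(miss)) {
    i <- miss[j]
    yr <- rec$year[i]; wk <- rec$week[i]; sid <- rec$site_id[i]
    donors <- rec$site_id != sid & rec$year == yr & rec$week == wk &
      !is.na(rec$count)
    if (!any(donors)) {
      stop("cannot impute (", yr, ", site ", sid, ", week ", wk,
           "): all other sites are missing for that year/week",
           call. = FALSE)
    }
    if (on == "weekly") {
      val <- mean(rec$count[donors])
    } else {
      donor_ids <- unique(rec$site_id[donors])
      donor_cum <- vapply(donor_ids, function(d) {
        sum(rec$count[rec$year == yr & rec$site_id == d & rec$week <= wk])
      }, numeric(1))
      own_prev <- sum(rec$count[rec$year == yr & rec$site_id == sid &
                                  rec$week < wk], na.rm = TRUE)
      val <- max(mean(donor_cum) - own_prev, 0)
    }
    rec$count[i] <- val
    log_rows[[j]] <- data.frame(year = yr, site_id = sid, week = wk,
                                count = val)
  }
  out <- ds
  out$records <- rec
  out$imputed <- rbind(ds$imputed, do.call(rbind, log_rows))
  out
}

#' Cumulative pest counts per site-year
#'
#' The model's response is the cumulative count Y: the running within-season
#' sum of weekly counts, non-decreasing in week by construction.
#'
#' @param ds a [trap_dataset()] with no missing cells (run [impute_missing()]
#'   first).
#' @return data.frame with columns `year`, `site_id`, `week`, `cumulative`
#'   (hundreds of pests), ordered by year, site, week.
#' @export
cumulative_counts <- function(ds) {
  rec <- ds$records
  if (anyNA(rec$count)) {
    stop("dataset has flagged-missing cells; call impute_missing() first",
         call. = FALSE)
  }
  sy <- paste(rec$year, rec$site_id, sep = "/")
  cum <- stats::ave(rec$count, sy, FUN = cumsum)
  data.frame(year = rec$year, site_id = rec$site_id, week = rec$week,
             cumulative = cum)
}

#' Project longitude/latitude to planar kilometres
#'
#' Equirectangular projection about the centroid: with latitudes and
#' longitudes in radians and Earth radius R = 6371 km,
#' `x = R cos(lat0) (lon - lon0)`, `y = R (lat - lat0)`. Adequate for the
#' small extents (a degree or two) of a regional trap network; the centroid
#' maps to (0, 0).
#'
#' @param lonlat data.frame or 2-column matrix of longitude, latitude in
#'   decimal degrees.
#' @return data.frame with columns `x_km`, `y_km`.
#' @export
project_coordinates <- function(lonlat) {
  lonlat <- as.data.frame(lonlat)
  lon <- as.numeric(lonlat[[1L]])
  lat <- as.numeric(lonlat[[2L]])
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]",
                                      call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]",
                                        call. = FALSE)
  R <- 6371
  lat0 <- mean(lat) * pi / 180
  lon0 <- mean(lon) * pi / 180
  data.frame(x_km = R * cos(lat0) * (lon * pi / 180 - lon0),
             y_km = R * (lat * pi / 180 - lat0))
}
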