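test_that("read_trap_csv round-trips a minimal well-formed file", {
  paths <- write_tiny_csvs()
  ds <- read_trap_csv(paths$counts, paths$sites)
  expect_s3_class(ds, "trap_dataset")
  expect_equal(nrow(ds$records), 6L)
  expect_equal(ds$weeks_per_year, c("2021" = 3L))
  expect_equal(n_site_years(ds), 2L)

  out <- tempfile("trapnet"); dir.create(out)
  cp <- file.path(out, "c.csv"); sp <- file.path(out, "s.csv")
  write_trap_csv(ds, cp, sp)
  ds2 <- read_trap_csv(cp, sp)
  expect_equal(ds2$records, ds$records)
  expect_equal(as.data.frame(ds2$registry), as.data.frame(ds$registry))
})

test_that("validation rejects malformed input", {
  paths <- write_tiny_csvs()
  counts <- read.csv(paths$counts)
  # duplicate (year, site, week)
  dup <- rbind(counts, counts[4L, ])
  f <- tempfile(fileext = ".csv")
  write.csv(dup, f, row.names = FALSE)
  expect_error(read_trap_csv(f, paths$sites), "duplicate.*2021/2/1")
  # site missing from registry
  bad <- counts; bad$site_id[1L] <- 99L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_trap_csv(f, paths$sites), "not in registry: 99")
  # negative count
  bad <- counts; bad$count[2L] <- -1
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_trap_csv(f, paths$sites), "negative count")
  # raw-unit conversion flag
  ds_raw <- read_trap_csv(paths$counts, paths$sites,
                          counts_in_hundreds = FALSE)
  expect_equal(ds_raw$records$count,
               read_trap_csv(paths$counts, paths$sites)$records$count / 100)
})

test_that("study-schedule generator yields 83 site-year combinations", {
  sim <- generate_dataset(sim_scenario(seed = 5))
  expect_equal(n_site_years(sim$dataset), 83L)
  expect_equal(sum(is.na(sim$dataset$records$count)), 1L)
})

test_that("impute_missing averages donors for the same year and week", {
  reg <- site_registry(1:3, x_km = c(0, 1, 2), y_km = c(0, 0, 0))
  rec <- expand.grid(year = 2022L, site_id = 1:3, week = 1:3)
  rec$count <- 1
  rec$count[rec$site_id == 1L & rec$week == 2L] <- NA
  rec$count[rec$site_id == 2L & rec$week == 2L] <- 2.0
  rec$count[rec$site_id == 3L & rec$week == 2L] <- 4.0
  ds <- trap_dataset(rec, reg)
  imp <- impute_missing(ds)
  got <- imp$records$count[imp$records$site_id == 1L & imp$records$week == 2L]
  expect_equal(got, 3.0)  # mean of 2 and 4
  expect_equal(nrow(imp$imputed), 1L)
  # constant donors give the constant; idempotence; only flagged cells change
  expect_identical(impute_missing(imp), imp)
  same <- imp$records$count[!(imp$records$site_id == 1L &
                                imp$records$week == 2L)]
  expect_equal(same, ds$records$count[!(ds$records$site_id == 1L &
                                          ds$records$week == 2L)])
  # all donors missing -> error
  rec$count[rec$week == 2L] <- NA
  expect_error(impute_missing(trap_dataset(rec, reg)), "all other sites")
})

test_that("schedule fixture imputes exactly the flagged trap-week", {
  sim <- generate_dataset(sim_scenario(seed = 2))
  imp <- impute_missing(sim$dataset)
  expect_equal(nrow(imp$imputed), 1L)
  expect_equal(imp$imputed$year, 2023L)
  expect_equal(imp$imputed$site_id, 13L)
  expect_equal(imp$imputed$week, 2L)
  donors <- sim$dataset$records
  donors <- donors$count[donors$year == 2023L & donors$week == 2L &
                           donors$site_id != 13L]
  expect_equal(imp$imputed$count, mean(donors))
})

test_that("cumulative_counts is the running sum and is non-decreasing", {
  reg <- site_registry(1:2, x_km = c(0, 1), y_km = c(0, 0))
  rec <- data.frame(year = 2021L, site_id = rep(1:2, each = 3L),
                    week = rep(1:3, 2L),
                    count = c(1, 2, 3, 0.5, 0.0, 2.5))
  cum <- cumulative_counts(trap_dataset(rec, reg))
  expect_equal(cum$cumulative[cum$site_id == 1L], c(1, 3, 6))
  expect_equal(cum$cumulative[cum$site_id == 2L], c(0.5, 0.5, 3.0))
  # zero case
  rec$count <- 0
  expect_equal(cumulative_counts(trap_dataset(rec, reg))$cumulative,
               rep(0, 6))
  # missing cells must be imputed first
  rec$count[2L] <- NA
  expect_error(cumulative_counts(trap_dataset(rec, reg)), "impute_missing")
})

test_that("cumulative series are non-decreasing for every generated site-year", {
  sim <- generate_dataset(sim_scenario(seed = 31))
  cum <- cumulative_counts(impute_missing(sim$dataset))
  for (key in split(cum$cumulative, paste(cum$year, cum$site_id))) {
    expect_true(all(diff(key) >= 0))
  }
  # differencing the cumulative series recovers the weekly counts
  imp <- impute_missing(sim$dataset)
  weekly_back <- unlist(lapply(
    split(cum$cumulative, paste(cum$year, cum$site_id)),
    function(v) diff(c(0, v))), use.names = FALSE)
  weekly_orig <- unlist(lapply(
    split(imp$records$count, paste(imp$records$year, imp$records$site_id)),
    identity), use.names = FALSE)
  expect_equal(sort(weekly_back), sort(weekly_orig))
})

test_that("project_coordinates maps degrees to centred planar km", {
  # identical points -> zero distance
  xy <- project_coordinates(data.frame(lon = c(10, 10), lat = c(40, 40)))
  expect_equal(dist(xy)[1L], 0)
  # 0.1 degree of latitude is about 11.12 km
  xy <- project_coordinates(data.frame(lon = c(0, 0), lat = c(40, 40.1)))
  expect_equal(dist(xy)[1L], 6371 * 0.1 * pi / 180, tolerance = 1e-6)
  # centroid maps to the origin
  xy <- project_coordinates(data.frame(lon = c(-78, -77.5, -77),
                                       lat = c(35.9, 36.2, 36.0)))
  expect_equal(colMeans(as.matrix(xy)), c(x_km = 0, y_km = 0),
               tolerance = 1e-12)
  expect_error(project_coordinates(data.frame(lon = 10, lat = 91)),
               "latitude")
  expect_error(project_coordinates(data.frame(lon = 190, lat = 10)),
               "longitude")
})
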