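#' Simulation scenario for a multi-year weekly trapping study
#'
#' Defaults emulate the structure of a four-season regional pheromone-trap
#' study: 21 sites in a 30 x 30 km region, seasons of 6, 7, 10 and 11 weekly
#' collections, one site absent for the whole first season, and one isolated
#' missing trap-week (site 13, week 2 of the final season). Truth values for
#' the growth-parameter fields are documented package choices, sized so that
#' cumulative trajectories run from tens of counts early to thousands late
#' on the raw scale (the internal unit is hundreds of pests).
#'
#' @param L number of sites.
#' @param region_km side length of the square study region (km).
#' @param years integer vector of season labels.
#' @param weeks_per_year weekly collections per season, same length as
#'   `years`.
#' @param absent_site_years data.frame (`year`, `site_id`) of site-seasons
#'   with no trap at all (excluded, not imputed).
#' @param missing_cells data.frame (`year`, `site_id`, `week`) of isolated
#'   flagged-missing collections.
#' @param mu_beta,mu_gamma process means of the asymptote (hundreds of
#'   pests) and midpoint (weeks) fields.
#' @param k growth scale (weeks).
#' @param sigma2 observation variance on the cumulative scale.
#' @param sigma2_beta,sigma2_gamma process variances of the two fields.
#' @param rho_beta,rho_gamma spatial ranges (km).
#' @param seed integer RNG seed.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(L = 21L, region_km = 30,
                         years = 2020:2023,
                         weeks_per_year = c(6L, 7L, 10L, 11L),
                         absent_site_years = data.frame(year = 2020L,
                                                        site_id = 3L),
                         missing_cells = data.frame(year = 2023L,
                                                    site_id = 13L,
                                                    week = 2L),
                         mu_beta = 15, mu_gamma = 6, k = 1.5,
                         sigma2 = 0.25, sigma2_beta = 16,
                         sigma2_gamma = 1, rho_beta = 10, rho_gamma = 10,
                         seed = 1L) {
  stopifnot(length(weeks_per_year) == length(years),
            all(weeks_per_year >= 3L), L >= 2L,
            k > 0, sigma2 >= 0, sigma2_beta > 0, sigma2_gamma > 0,
            rho_beta > 0, rho_gamma > 0)
  structure(
    list(L = as.integer(L), region_km = region_km,
         years = as.integer(years),
         weeks_per_year = stats::setNames(as.integer(weeks_per_year),
                                          years),
         absent_site_years = absent_site_years,
         missing_cells = missing_cells,
         mu_beta = mu_beta, mu_gamma = mu_gamma, k = k, sigma2 = sigma2,
         sigma2_beta = sigma2_beta, sigma2_gamma = sigma2_gamma,
         rho_beta = rho_beta, rho_gamma = rho_gamma,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Sample site coordinates for a scenario
#'
#' Uniform placement in the square region with a minimum pairwise
#' separation of 1% of the region diagonal, enforced by rejection.
#'
#' @param scenario a [sim_scenario()].
#' @return a [site_registry()] with sites 1..L.
#' @export
sample_sites <- function(scenario) {
  set.seed(scenario$seed)
  L <- scenario$L
  side <- scenario$region_km
  min_sep <- 0.01 * side * sqrt(2)
  xy <- matrix(NA_real_, L, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < L) {
    tries <- tries + 1L
    if (tries > 10000L) {
      stop("could not place ", L, " sites with minimum separation ",
           signif(min_sep, 3), " km in 10,000 tries", call. = FALSE)
    }
    cand <- stats::runif(2L, 0, side)
    if (placed == 0L ||
        min(sqrt(colSums((t(xy[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= min_sep) {
      placed <- placed + 1L
      xy[placed, ] <- cand
    }
  }
  site_registry(seq_len(L), xy[, 1L], xy[, 2L])
}

# Draw one multivariate-normal field with exponential correlation.
draw_gp_field <- function(mu, sigma2, rho, D) {
  C <- exp_corr_jitter(D, rho)
  U <- chol(sigma2 * C)
  as.vector(mu + t(U) %*% stats::rnorm(nrow(D)))
}

#' Sample the true growth-parameter fields
#'
#' Draws the asymptote field `beta(s)` and midpoint field `gamma(s)` from
#' Gaussian processes with exponential correlation at the scenario's true
#' ranges, adds the process means, and fixes `k` at the scenario value.
#' Because the asymptote must be positive for a growth curve to make
#' biological sense, any draw with a non-positive `beta(s)` is redrawn (up
#' to 100 attempts).
#'
#' @param scenario a [sim_scenario()].
#' @param registry a [site_registry()] of the scenario's sites.
#' @return list (the "truth record"): `beta`, `gamma` (site-wise fields),
#'   `k`, `sigma2`, plus the scenario hyper-values.
#' @export
sample_growth_field <- function(scenario, registry) {
  set.seed(scenario$seed + 1L)
  D <- site_distances(registry)
  beta <- NULL
  for (attempt in seq_len(100L)) {
    cand <- draw_gp_field(scenario$mu_beta, scenario$sigma2_beta,
                          scenario$rho_beta, D)
    if (all(cand > 0)) {
      beta <- cand
      break
    }
  }
  if (is.null(beta)) {
    stop("could not draw an all-positive asymptote field in 100 attempts; ",
         "increase mu_beta relative to sigma2_beta", call. = FALSE)
  }
  gamma <- draw_gp_field(scenario$mu_gamma, scenario$sigma2_gamma,
                         scenario$rho_gamma, D)
  list(beta = beta, gamma = gamma, k = scenario$k, sigma2 = scenario$sigma2,
       mu_beta = scenario$mu_beta, mu_gamma = scenario$mu_gamma,
       sigma2_beta = scenario$sigma2_beta,
       sigma2_gamma = scenario$sigma2_gamma,
       rho_beta = scenario$rho_beta, rho_gamma = scenario$rho_gamma)
}

#' Generate a synthetic trap dataset from the growth model
#'
#' For every site-year-week the noiseless cumulative mean is the logistic
#' curve at the site's true parameters; Normal noise with variance `sigma2`
#' is added on the cumulative scale, and the noisy path is made
#' non-decreasing by a running maximum (isotonic projection) so the emitted
#' data satisfy the definitional monotonicity of cumulative counts. Weekly
#' counts are the successive differences of that path. The scenario's
#' absent site-years are then dropped and its missing cells flagged `NA`.
#'
#' @param scenario a [sim_scenario()].
#' @param allow_nonmonotone also return the raw Normal draws without the
#'   running maximum (for likelihood-exactness experiments) as a
#'   `raw_cumulative` data.frame; the emitted `dataset` always satisfies the
#'   monotone/non-negative invariants.
#' @return list: `dataset` (a [trap_dataset()], with the missing cell still
#'   flagged), `truth` (the field record from [sample_growth_field()], never
#'   read by fitting code), `registry`, and `raw_cumulative` when requested.
#' @export
generate_dataset <- function(scenario = sim_scenario(),
                             allow_nonmonotone = FALSE) {
  registry <- sample_sites(scenario)
  truth <- sample_growth_field(scenario, registry)
  set.seed(scenario$seed + 2L)
  rows <- vector("list", length(scenario$years) * scenario$L)
  ri <- 0L
  for (yi in seq_along(scenario$years)) {
    yr <- scenario$years[yi]
    n_weeks <- scenario$weeks_per_year[yi]
    for (s in seq_len(scenario$L)) {
      absent <- nrow(scenario$absent_site_years) > 0 &&
        any(scenario$absent_site_years$year == yr &
              scenario$absent_site_years$site_id == s)
      if (absent) next
      weeks <- seq_len(n_weeks)
      mu <- logistic_mean(weeks, truth$beta[s], truth$gamma[s], truth$k)
      ycum_raw <- mu + stats::rnorm(n_weeks, 0, sqrt(scenario$sigma2))
      ycum <- cummax(pmax(ycum_raw, 0))
      weekly <- pmax(diff(c(0, ycum)), 0)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(year = yr, site_id = s, week = weeks,
                               count = weekly, raw = ycum_raw)
    }
  }
  records <- do.call(rbind, rows[seq_len(ri)])
  raw_cumulative <- data.frame(year = records$year,
                               site_id = records$site_id,
                               week = records$week,
                               cumulative = records$raw)
  records$raw <- NULL
  if (nrow(scenario$missing_cells) > 0) {
    for (i in seq_len(nrow(scenario$missing_cells))) {
      mc <- scenario$missing_cells[i, ]
      hit <- records$year == mc$year & records$site_id == mc$site_id &
        records$week == mc$week
      records$count[hit] <- NA_real_
    }
  }
  ds <- trap_dataset(records, registry)
  out <- list(dataset = ds, truth = truth, registry = registry)
  if (allow_nonmonotone) out$raw_cumulative <- raw_cumulative
  out
}

#' Write a generated dataset plus its truth record to disk
#'
#' Emits the counts/sites CSV dialects of [write_trap_csv()] and a
#' `truth.json` with the generating parameters (for recovery tests; fitting
#' code never reads it).
#'
#' @param sim result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             sites = file.path(dir, "sites.csv"),
             truth = file.path(dir, "truth.json"))
  write_trap_csv(sim$dataset, paths[["counts"]], paths[["sites"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
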