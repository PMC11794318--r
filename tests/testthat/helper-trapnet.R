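# Shared fixtures, all built in code at test time.

# A small fast scenario: fewer sites/weeks than the full study schedule.
tiny_scenario <- function(L = 6L, seed = 11L, ...) {
  sim_scenario(L = L, region_km = 20,
               years = 2020:2022, weeks_per_year = c(6L, 7L, 8L),
               absent_site_years = data.frame(year = integer(),
                                              site_id = integer()),
               missing_cells = data.frame(year = integer(),
                                          site_id = integer(),
                                          week = integer()),
               seed = seed, ...)
}

# Hand-built posterior object for exercising kriging/prediction closed
# forms without running MCMC.
manual_posterior <- function(registry, beta, gamma, k, mu_beta = 0,
                             mu_gamma = 0, rho_beta = 1, rho_gamma = 1) {
  beta <- rbind(beta)
  gamma <- rbind(gamma)
  nd <- nrow(beta)
  rep1 <- function(v) if (length(v) == nd) v else rep(v, nd)
  structure(
    list(draws = list(beta = beta, gamma = gamma, k = rep1(k),
                      sigma2 = rep(1e-6, nd),
                      mu_beta = rep1(mu_beta), mu_gamma = rep1(mu_gamma),
                      sigma2_beta = rep(1, nd), sigma2_gamma = rep(1, nd),
                      rho_beta = rep1(rho_beta), rho_gamma = rep1(rho_gamma)),
         registry = registry,
         site_ids = registry$site_id,
         years = 2020L,
         diagnostics = data.frame(param = "k", rhat = 1),
         priors = NULL, mcmc = NULL),
    class = "growth_posterior")
}

# Minimal well-formed counts/sites CSV pair on disk; returns the paths.
write_tiny_csvs <- function(dir = tempfile("trapnet")) {
  dir.create(dir, showWarnings = FALSE)
  counts <- data.frame(
    year = rep(2021L, 6L), site_id = rep(1:2, each = 3L),
    week = rep(1:3, 2L), count = c(1, 2, 3, 0, 0, 0))
  sites <- data.frame(site_id = 1:2, x_km = c(0, 5), y_km = c(0, 0))
  cp <- file.path(dir, "counts.csv"); sp <- file.path(dir, "sites.csv")
  write.csv(counts, cp, row.names = FALSE, quote = FALSE)
  write.csv(sites, sp, row.names = FALSE, quote = FALSE)
  list(counts = cp, sites = sp)
}
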