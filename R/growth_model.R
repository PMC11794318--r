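#' Logistic growth mean curve
#'
#' The three-parameter logistic curve used as the mean of the cumulative pest
#' count: `beta / (1 + exp(-(week - gamma) / k))`. `beta` is the supremum
#' (season-total asymptote, hundreds of pests), `gamma` the midpoint week at
#' which the curve attains `beta / 2`, and `k > 0` the growth scale in weeks
#' (larger `k`, slower growth).
#'
#' @param week numeric week index (may be a vector).
#' @param beta asymptote.
#' @param gamma midpoint week.
#' @param k growth scale, strictly positive.
#' @return numeric vector of curve values.
#' @examples
#' logistic_mean(6, beta = 10, gamma = 5, k = 1)  # 10 / (1 + exp(-1))
#' @export
logistic_mean <- function(week, beta, gamma, k) {
  if (any(k <= 0)) stop("k must be > 0", call. = FALSE)
  beta * stats::plogis((week - gamma) / k)
}

#' Exponential spatial correlation matrix
#'
#' `Sigma_ij = exp(-d_ij / rho)` with `d_ij` the Euclidean distance in km
#' between sites i and j and `rho > 0` the spatial range parameter (a Matern
#' special case). Symmetric, unit diagonal, entries in (0, 1], positive
#' semi-definite.
#'
#' @param registry a [site_registry()] (or any data.frame with `x_km`,
#'   `y_km`).
#' @param rho spatial range in km, strictly positive.
#' @return correlation matrix with site ids as dimnames.
#' @export
exp_correlation <- function(registry, rho) {
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("rho must be a single positive number", call. = FALSE)
  }
  d <- as.matrix(stats::dist(cbind(registry$x_km, registry$y_km)))
  C <- exp(-d / rho)
  if (!is.null(registry$site_id)) {
    dimnames(C) <- list(registry$site_id, registry$site_id)
  }
  C
}

#' MCMC configuration for [fit_growth_model()]
#'
#' @param n_chains number of independent chains.
#' @param n_warmup warm-up (adaptation) iterations per chain, discarded.
#' @param n_iter post-warmup iterations per chain.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer RNG seed (chain c uses `seed + c - 1`).
#' @param profile optional shortcut: `"full"` (4 chains, 1000 + 1000) for
#'   final analyses, `"fast"` (1 chain, 300 + 300, thin 6) for the many model
#'   fits inside the optimization loop, `"turbo"` (1 chain, 150 + 150,
#'   thin 6) for continuous-integration scale tests. Explicit arguments
#'   override the profile.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = NULL, n_warmup = NULL, n_iter = NULL,
                        thin = NULL, seed = 1L, profile = NULL) {
  base <- list(n_chains = 4L, n_warmup = 1000L, n_iter = 1000L, thin = 1L)
  if (!is.null(profile)) {
    base <- switch(match.arg(profile, c("full", "fast", "turbo")),
      full = base,
      fast = list(n_chains = 1L, n_warmup = 300L, n_iter = 300L, thin = 6L),
      turbo = list(n_chains = 1L, n_warmup = 150L, n_iter = 150L, thin = 6L)
    )
  }
  if (!is.null(n_chains)) base$n_chains <- as.integer(n_chains)
  if (!is.null(n_warmup)) base$n_warmup <- as.integer(n_warmup)
  if (!is.null(n_iter)) base$n_iter <- as.integer(n_iter)
  if (!is.null(thin)) base$thin <- as.integer(thin)
  base$seed <- as.integer(seed)
  structure(base, class = "mcmc_config")
}

default_growth_priors <- function(y, x, site, D) {
  per_site_max <- tapply(y, site, max)
  dpos <- D[D > 0]
  list(
    mu_b_m = mean(per_site_max),
    mu_b_v = (10 * max(mean(per_site_max), 1))^2,
    mu_g_m = stats::median(x),
    mu_g_v = (2 * max(x))^2,
    k_shape = 2, k_rate = 0.5,
    sig2_a = 2, sig2_b = 0.1 * max(stats::var(y), 1e-6),
    s2b_a = 2, s2b_b = max(stats::var(as.numeric(per_site_max)), 1),
    s2g_a = 2, s2g_b = 1,
    rho_lo = if (length(dpos)) min(dpos) / 10 else 0.1,
    rho_hi = if (length(dpos)) 10 * max(dpos) else 100
  )
}

growth_inits <- function(y, x, site, priors, chain) {
  ns <- length(unique(site))
  beta0 <- as.numeric(tapply(y, site, max))
  beta0 <- pmax(beta0, 0.1)
  gamma0 <- vapply(seq_len(ns), function(s) {
    ys <- y[site == s]; xs <- x[site == s]
    half <- max(ys) / 2
    hit <- xs[ys >= half]
    if (length(hit)) min(hit) else priors$mu_g_m
  }, numeric(1))
  jit <- function(v, f) v * exp(stats::rnorm(length(v), 0, f))
  # chain 1 starts at the data-informed values, later chains are dispersed
  f <- if (chain == 1L) 0 else 0.15
  list(beta = jit(beta0, f), gamma = gamma0 + stats::rnorm(ns, 0, f),
       k = jit(max(diff(range(x)) / 8, 0.5), f),
       sigma2 = jit(0.1 * max(stats::var(y), 1e-6), f),
       mu_beta = mean(beta0), mu_gamma = mean(gamma0),
       sigma2_beta = max(stats::var(beta0), 0.5),
       sigma2_gamma = max(stats::var(gamma0), 0.25),
       rho_beta = jit(sqrt(priors$rho_lo * priors$rho_hi), f),
       rho_gamma = jit(sqrt(priors$rho_lo * priors$rho_hi), f))
}

#' Fit the Bayesian spatially-varying logistic growth model
#'
#' The cumulative count for site s at week x is modelled as
#' `Y ~ Normal(mu(x; s), sigma^2)` with
#' `mu(x; s) = beta(s) / (1 + exp(-(x - gamma(s)) / k))`; the asymptote field
#' `beta(s)` and midpoint field `gamma(s)` are Gaussian processes with
#' exponential spatial correlation (range parameters `rho_beta`, `rho_gamma`)
#' around unknown process means, and the growth scale `k` is shared across
#' sites. All included site-years are pooled with no year effect. Fitting is
#' by a blocked Gibbs / adaptive-Metropolis sampler (see the methods
#' vignette for the prior specification and update scheme).
#'
#' @param ds a [trap_dataset()]; must contain no flagged-missing cells.
#' @param train_sites site ids to fit on (default: all registry sites with
#'   data); at least 2.
#' @param years years to pool (default: all years in `ds`).
#' @param mcmc an [mcmc_config()].
#' @return a `growth_posterior` object: `$draws` (matrices/vectors of
#'   retained posterior draws for every parameter), `$registry` (training
#'   sites), `$diagnostics` (split-Rhat per parameter), plus the data and
#'   priors used.
#' @export
fit_growth_model <- function(ds, train_sites = NULL, years = NULL,
                             mcmc = mcmc_config()) {
  stopifnot(inherits(ds, "trap_dataset"))
  cum <- cumulative_counts(ds)
  if (is.null(years)) years <- sort(unique(cum$year))
  cum <- cum[cum$year %in% years, ]
  if (is.null(train_sites)) train_sites <- sort(unique(cum$site_id))
  train_sites <- sort(as.integer(train_sites))
  if (length(train_sites) < 2L) {
    stop("need at least 2 training sites (spatial correlation is undefined ",
         "for a single site)", call. = FALSE)
  }
  cum <- cum[cum$site_id %in% train_sites, ]
  if (!nrow(cum)) stop("no data for the requested sites/years", call. = FALSE)
  sy_weeks <- tapply(cum$week, paste(cum$year, cum$site_id), length)
  if (any(sy_weeks < 3L)) {
    stop("every included site-year needs at least 3 weeks of data",
         call. = FALSE)
  }
  registry <- ds$registry[match(train_sites, ds$registry$site_id), ]
  class(registry) <- class(ds$registry)
  D <- site_distances(registry)

  site <- match(cum$site_id, train_sites)
  dat <- list(y = cum$cumulative, site = site, x = cum$week, D = D,
              idx = split(seq_along(site), site))
  priors <- default_growth_priors(dat$y, dat$x, site, D)

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    seed_ch <- mcmc$seed + ch - 1L
    set.seed(seed_ch)
    init <- growth_inits(dat$y, dat$x, site, priors, ch)
    chains[[ch]] <- run_growth_chain(dat, priors, init, mcmc$n_warmup,
                                     mcmc$n_iter, mcmc$thin, seed_ch)
  }

  draws <- list(
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    gamma = do.call(rbind, lapply(chains, `[[`, "gamma"))
  )
  for (nm in c("k", "sigma2", "mu_beta", "mu_gamma", "sigma2_beta",
               "sigma2_gamma", "rho_beta", "rho_gamma")) {
    draws[[nm]] <- unlist(lapply(chains, `[[`, nm), use.names = FALSE)
  }
  colnames(draws$beta) <- colnames(draws$gamma) <- train_sites

  diag_df <- growth_diagnostics(chains, train_sites)
  bad <- diag_df$rhat > 1.05
  if (any(bad, na.rm = TRUE)) {
    warning("possible non-convergence (split-Rhat > 1.05) for: ",
            paste(diag_df$param[which(bad)], collapse = ", "),
            call. = FALSE)
  }

  structure(
    list(draws = draws, registry = registry, site_ids = train_sites,
         years = years, diagnostics = diag_df, priors = priors,
         mcmc = mcmc),
    class = "growth_posterior"
  )
}

growth_diagnostics <- function(chains, train_sites) {
  scalar <- c("k", "sigma2", "mu_beta", "mu_gamma", "sigma2_beta",
              "sigma2_gamma", "rho_beta", "rho_gamma")
  rows <- lapply(scalar, function(nm) {
    m <- do.call(cbind, lapply(chains, `[[`, nm))
    data.frame(param = nm, rhat = split_rhat(m))
  })
  beta_r <- vapply(seq_along(train_sites), function(j) {
    split_rhat(do.call(cbind, lapply(chains, function(c) c$beta[, j])))
  }, numeric(1))
  gamma_r <- vapply(seq_along(train_sites), function(j) {
    split_rhat(do.call(cbind, lapply(chains, function(c) c$gamma[, j])))
  }, numeric(1))
  rbind(do.call(rbind, rows),
        data.frame(param = paste0("beta[", train_sites, "]"), rhat = beta_r),
        data.frame(param = paste0("gamma[", train_sites, "]"),
                   rhat = gamma_r))
}

#' @export
print.growth_posterior <- function(x, ...) {
  cat("<growth_posterior> ", length(x$draws$k), " draws, ",
      length(x$site_ids), " training sites, years ",
      paste(x$years, collapse = ", "), "\n", sep = "")
  cat("  posterior means: k = ", signif(mean(x$draws$k), 4),
      ", sigma2 = ", signif(mean(x$draws$sigma2), 4),
      ", rho_beta = ", signif(mean(x$draws$rho_beta), 4),
      ", rho_gamma = ", signif(mean(x$draws$rho_gamma), 4), "\n", sep = "")
  worst <- max(x$diagnostics$rhat, na.rm = TRUE)
  cat("  worst split-Rhat: ", signif(worst, 4), "\n", sep = "")
  invisible(x)
}

as_target_coords <- function(targets) {
  t_df <- as.data.frame(targets)
  if (!all(c("x_km", "y_km") %in% names(t_df))) {
    stop("targets need x_km and y_km columns", call. = FALSE)
  }
  if (is.null(t_df$site_id)) t_df$site_id <- seq_len(nrow(t_df))
  t_df
}

#' Krige the growth-parameter fields to unobserved sites
#'
#' Simple-kriging of the posterior `beta` and `gamma` fields: for each
#' retained draw d, `beta_d(s*) = mu_beta_d + r' C_d^{-1} (beta_d -
#' mu_beta_d)` with `r_i = exp(-||s* - s_i|| / rho_beta_d)` and `C_d` the
#' exponential correlation among training sites at that draw's range; same
#' form for `gamma`. At a training site itself the kriging weights reduce to
#' the indicator of that site, so the draw's parameter is reproduced exactly
#' (up to the 1e-8 numerical jitter).
#'
#' @param post a `growth_posterior` from [fit_growth_model()].
#' @param targets data.frame (or [site_registry()]) with `x_km`, `y_km` and
#'   optionally `site_id` for the prediction locations.
#' @return list with matrices `beta_star` and `gamma_star`
#'   (draws x targets) and the target `site_id`s.
#' @export
krige_params <- function(post, targets) {
  stopifnot(inherits(post, "growth_posterior"))
  t_df <- as_target_coords(targets)
  tr <- post$registry
  Dct <- sqrt(outer(t_df$x_km, tr$x_km, "-")^2 +
                outer(t_df$y_km, tr$y_km, "-")^2)  # targets x train
  if (any(apply(Dct, 1L, min) < 1e-9)) {
    message("some targets coincide with training sites; kriging there is ",
            "exact interpolation of the sampled parameter")
  }
  D <- site_distances(tr)
  nd <- length(post$draws$k); nt <- nrow(t_df)
  beta_star <- matrix(NA_real_, nd, nt)
  gamma_star <- matrix(NA_real_, nd, nt)
  dr <- post$draws
  for (d in seq_len(nd)) {
    Cb <- exp_corr_jitter(D, dr$rho_beta[d])
    rb <- exp(-Dct / dr$rho_beta[d])
    beta_star[d, ] <- dr$mu_beta[d] +
      rb %*% solve(Cb, dr$beta[d, ] - dr$mu_beta[d])
    Cg <- exp_corr_jitter(D, dr$rho_gamma[d])
    rg <- exp(-Dct / dr$rho_gamma[d])
    gamma_star[d, ] <- dr$mu_gamma[d] +
      rg %*% solve(Cg, dr$gamma[d, ] - dr$mu_gamma[d])
  }
  list(beta_star = beta_star, gamma_star = gamma_star,
       site_id = t_df$site_id)
}

#' Predict cumulative counts at (possibly unobserved) sites
#'
#' Kriges the parameter fields to the targets ([krige_params()]) and pushes
#' each posterior draw through the logistic mean curve; the point prediction
#' is the posterior mean over draws and the interval the central 95%
#' quantiles.
#'
#' @inheritParams krige_params
#' @param weeks integer vector of week indices to predict at.
#' @return data.frame with `site_id`, `week`, `pred`, `lwr`, `upr`
#'   (hundreds of pests).
#' @export
predict_cumulative <- function(post, targets, weeks) {
  if (!length(weeks)) stop("empty week range", call. = FALSE)
  kp <- krige_params(post, targets)
  nd <- nrow(kp$beta_star); nt <- ncol(kp$beta_star); nw <- length(weeks)
  k <- post$draws$k
  out <- vector("list", nt)
  for (j in seq_len(nt)) {
    # draws x weeks matrix of curve values at target j
    mu <- kp$beta_star[, j] *
      stats::plogis((matrix(weeks, nd, nw, byrow = TRUE) -
                       kp$gamma_star[, j]) / k)
    qs <- apply(mu, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    out[[j]] <- data.frame(site_id = kp$site_id[j], week = weeks,
                           pred = colMeans(mu), lwr = qs[1L, ],
                           upr = qs[2L, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
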