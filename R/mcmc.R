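# Blocked Gibbs / adaptive-Metropolis sampler for the spatial logistic
# growth model.  Conditionally conjugate blocks (the beta field, the
# observation variance, the process means and variances) are updated by exact
# Gibbs draws; the gamma field, the shared growth scale k and the two spatial
# range parameters use adaptive random-walk Metropolis.  Everything is plain
# dense linear algebra on ns x ns matrices (ns = number of training sites,
# at most a few dozen), so no compiled code is needed.

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape, rate = rate)

# Cholesky-based inverse + log-determinant of a correlation matrix with
# jitter already applied; errors if not positive definite.
chol_inv_logdet <- function(C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    stop("correlation matrix not positive definite even after jitter",
         call. = FALSE)
  }
  list(inv = chol2inv(U), logdet = 2 * sum(log(diag(U))))
}

exp_corr_jitter <- function(D, rho, jitter = 1e-8) {
  C <- exp(-D / rho)
  diag(C) <- diag(C) + jitter
  C
}

# One MCMC chain.  `dat` is a list with y, site (integer 1..ns), x, D,
# idx (list of row indices per site).  Returns thinned post-warmup draws.
run_growth_chain <- function(dat, priors, init, n_warmup, n_iter, thin,
                             seed) {
  set.seed(seed)
  y <- dat$y; site <- dat$site; x <- dat$x; D <- dat$D; idx <- dat$idx
  ns <- nrow(D); n <- length(y)
  p <- priors

  beta <- init$beta; gamma <- init$gamma; k <- init$k; sigma2 <- init$sigma2
  mu_b <- init$mu_beta; mu_g <- init$mu_gamma
  s2b <- init$sigma2_beta; s2g <- init$sigma2_gamma
  rho_b <- init$rho_beta; rho_g <- init$rho_gamma

  cb <- chol_inv_logdet(exp_corr_jitter(D, rho_b))
  cg <- chol_inv_logdet(exp_corr_jitter(D, rho_g))

  g <- stats::plogis((x - gamma[site]) / k)

  # adaptive RW scales
  sc_g <- rep(0.5, ns); sc_k <- 0.2; sc_rb <- 0.5; sc_rg <- 0.5
  acc_prob <- function(la) if (is.finite(la)) min(1, exp(la)) else 0
  adapt <- function(sc, la, t) {
    sc * exp((acc_prob(la) - 0.44) / max(t, 1)^0.6)
  }

  n_keep <- floor(n_iter / thin)
  out <- list(beta = matrix(NA_real_, n_keep, ns),
              gamma = matrix(NA_real_, n_keep, ns),
              k = numeric(n_keep), sigma2 = numeric(n_keep),
              mu_beta = numeric(n_keep), mu_gamma = numeric(n_keep),
              sigma2_beta = numeric(n_keep), sigma2_gamma = numeric(n_keep),
              rho_beta = numeric(n_keep), rho_gamma = numeric(n_keep))
  keep_i <- 0L

  for (it in seq_len(n_warmup + n_iter)) {
    ## beta | . : conjugate MVN
    A <- as.vector(rowsum(g * g, site))          # sum g^2 per site
    Gy <- as.vector(rowsum(y * g, site))         # sum y g per site
    Qp <- cb$inv / s2b
    Q <- Qp + diag(A / sigma2, ns)
    rhs <- Qp %*% rep(mu_b, ns) + Gy / sigma2
    U <- chol(Q)
    m <- backsolve(U, forwardsolve(t(U), rhs))
    beta <- as.vector(m + backsolve(U, stats::rnorm(ns)))

    ## sigma2 | . : conjugate inverse-gamma
    resid <- y - beta[site] * g
    sigma2 <- rinvgamma1(p$sig2_a + n / 2, p$sig2_b + 0.5 * sum(resid^2))

    ## gamma_s | . : per-site random-walk MH with conditional GP prior
    Qg <- cg$inv / s2g
    for (s in seq_len(ns)) {
      rows <- idx[[s]]
      cprec <- Qg[s, s]
      cmean <- mu_g - sum(Qg[s, -s] * (gamma[-s] - mu_g)) / cprec
      prop <- gamma[s] + stats::rnorm(1L) * sc_g[s]
      gp <- stats::plogis((x[rows] - prop) / k)
      ll_new <- -0.5 * sum((y[rows] - beta[s] * gp)^2) / sigma2
      ll_old <- -0.5 * sum((y[rows] - beta[s] * g[rows])^2) / sigma2
      lpr <- -0.5 * cprec * ((prop - cmean)^2 - (gamma[s] - cmean)^2)
      la <- ll_new - ll_old + lpr
      if (is.finite(la) && log(stats::runif(1L)) < la) {
        gamma[s] <- prop
        g[rows] <- gp
      }
      if (it <= n_warmup) sc_g[s] <- adapt(sc_g[s], la, it)
    }

    ## mu_gamma | . : conjugate normal
    prec <- sum(Qg) + 1 / p$mu_g_v
    mean_mu <- (sum(Qg %*% gamma) + p$mu_g_m / p$mu_g_v) / prec
    mu_g <- stats::rnorm(1L, mean_mu, sqrt(1 / prec))

    ## sigma2_gamma | . : conjugate inverse-gamma
    dg <- gamma - mu_g
    qg <- sum(dg * (cg$inv %*% dg))
    s2g <- rinvgamma1(p$s2g_a + ns / 2, p$s2g_b + qg / 2)

    ## rho_gamma | . : MH on log scale, uniform prior on [rho_lo, rho_hi]
    prop <- rho_g * exp(stats::rnorm(1L) * sc_rg)
    la <- -Inf
    if (prop >= p$rho_lo && prop <= p$rho_hi) {
      cg_new <- chol_inv_logdet(exp_corr_jitter(D, prop))
      q_new <- sum(dg * (cg_new$inv %*% dg))
      la <- -0.5 * (cg_new$logdet - cg$logdet) - (q_new - qg) / (2 * s2g) +
        (log(prop) - log(rho_g))
      if (log(stats::runif(1L)) < la) {
        rho_g <- prop; cg <- cg_new
      }
    }
    if (it <= n_warmup) sc_rg <- adapt(sc_rg, la, it)

    ## mu_beta | . : conjugate normal
    Qb <- cb$inv / s2b
    prec <- sum(Qb) + 1 / p$mu_b_v
    mean_mu <- (sum(Qb %*% beta) + p$mu_b_m / p$mu_b_v) / prec
    mu_b <- stats::rnorm(1L, mean_mu, sqrt(1 / prec))

    ## sigma2_beta | . : conjugate inverse-gamma
    db <- beta - mu_b
    qb <- sum(db * (cb$inv %*% db))
    s2b <- rinvgamma1(p$s2b_a + ns / 2, p$s2b_b + qb / 2)

    ## rho_beta | . : MH on log scale
    prop <- rho_b * exp(stats::rnorm(1L) * sc_rb)
    la <- -Inf
    if (prop >= p$rho_lo && prop <= p$rho_hi) {
      cb_new <- chol_inv_logdet(exp_corr_jitter(D, prop))
      q_new <- sum(db * (cb_new$inv %*% db))
      la <- -0.5 * (cb_new$logdet - cb$logdet) - (q_new - qb) / (2 * s2b) +
        (log(prop) - log(rho_b))
      if (log(stats::runif(1L)) < la) {
        rho_b <- prop; cb <- cb_new
      }
    }
    if (it <= n_warmup) sc_rb <- adapt(sc_rb, la, it)

    ## k | . : MH on log scale, Gamma prior
    prop <- k * exp(stats::rnorm(1L) * sc_k)
    gp <- stats::plogis((x - gamma[site]) / prop)
    ll_new <- -0.5 * sum((y - beta[site] * gp)^2) / sigma2
    ll_old <- -0.5 * sum((y - beta[site] * g)^2) / sigma2
    la <- ll_new - ll_old +
      (p$k_shape - 1) * (log(prop) - log(k)) - p$k_rate * (prop - k) +
      (log(prop) - log(k))
    if (is.finite(la) && log(stats::runif(1L)) < la) {
      k <- prop; g <- gp
    }
    if (it <= n_warmup) sc_k <- adapt(sc_k, la, it)

    if (it > n_warmup && (it - n_warmup) %% thin == 0L) {
      keep_i <- keep_i + 1L
      out$beta[keep_i, ] <- beta
      out$gamma[keep_i, ] <- gamma
      out$k[keep_i] <- k
      out$sigma2[keep_i] <- sigma2
      out$mu_beta[keep_i] <- mu_b
      out$mu_gamma[keep_i] <- mu_g
      out$sigma2_beta[keep_i] <- s2b
      out$sigma2_gamma[keep_i] <- s2g
      out$rho_beta[keep_i] <- rho_b
      out$rho_gamma[keep_i] <- rho_g
    }
  }
  out
}

# split-Rhat of Gelman et al. for a draws matrix (iterations x chains)
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
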