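# Bayesian optimization over binary site-inclusion vectors with a fixed row
# sum K: random initial designs, a Bayesian linear surrogate for the loss,
# an order-statistic acquisition rule, and a brute-force oracle.

design_key <- function(x) paste(which(x == 1L), collapse = ",")

random_k_subset <- function(L, K) {
  x <- integer(L)
  x[sample.int(L, K)] <- 1L
  x
}

#' Random initial designs for the optimization loop
#'
#' Draws `N0` distinct uniform-random K-subsets of the L candidate sites,
#' encoded as binary inclusion vectors with row sum exactly K. Duplicates
#' are rejection-resampled, so the result is deterministic under a fixed
#' seed.
#'
#' @param L number of candidate sites.
#' @param K subset size, `1 <= K < L`.
#' @param N0 number of initial designs, at most `choose(L, K)`.
#' @param seed integer RNG seed.
#' @return integer matrix `N0 x L` of 0/1 inclusion indicators.
#' @export
init_designs <- function(L, K, N0, seed = 1L) {
  if (K < 1L || K >= L) stop("need 1 <= K < L", call. = FALSE)
  if (N0 < 1L) stop("N0 must be >= 1", call. = FALSE)
  if (N0 > choose(L, K)) {
    stop("N0 = ", N0, " exceeds the number of distinct K-subsets choose(",
         L, ", ", K, ") = ", choose(L, K), call. = FALSE)
  }
  set.seed(seed)
  X <- matrix(0L, N0, L)
  seen <- character(0)
  i <- 1L
  while (i <= N0) {
    x <- random_k_subset(L, K)
    key <- design_key(x)
    if (!key %in% seen) {
      X[i, ] <- x
      seen <- c(seen, key)
      i <- i + 1L
    }
  }
  X
}

#' Fit the linear Bayesian surrogate for the subset loss
#'
#' Models the evaluated losses as `f(x) = sum_j x_j b_j + noise`: each
#' coefficient `b_j` is the marginal contribution of site j to the loss
#' (negative = including the site lowers it). No intercept is used — the
#' fixed row sum K makes one unidentifiable — and the coefficients get a
#' vague proper Normal prior so the posterior stays proper even with fewer
#' designs than sites or rank-deficient design matrices.
#'
#' @param X binary design matrix (rows = evaluated designs).
#' @param losses numeric vector of evaluated objective values, one per row.
#' @param prior_sd prior standard deviation per coefficient; default
#'   `10 * max(sd(losses), 1e-6)` ("non-informative" made proper).
#' @return list of class `surrogate_fit`: `coef_mean`, `coef_cov`,
#'   `n_designs`, `sigma2`.
#' @export
fit_surrogate <- function(X, losses, prior_sd = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 evaluated designs", call. = FALSE)
  if (length(losses) != nrow(X)) {
    stop("one loss per design row required", call. = FALSE)
  }
  L <- ncol(X)
  if (is.null(prior_sd)) prior_sd <- 10 * max(stats::sd(losses), 1e-6)
  tau2 <- prior_sd^2
  if (qr(X)$rank < min(dim(X))) {
    message("surrogate design matrix is rank deficient; the proper prior ",
            "regularizes the posterior")
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, losses)
  # two-pass plug-in for the noise variance: start from the marginal loss
  # variance, refit once with the ridge residuals
  sigma2 <- max(stats::var(losses), 1e-12)
  for (pass in 1:2) {
    Q <- XtX / sigma2 + diag(1 / tau2, L)
    V <- chol2inv(chol(Q))
    m <- V %*% Xty / sigma2
    resid <- losses - X %*% m
    df <- max(nrow(X) - qr(X)$rank, 1L)
    sigma2 <- max(sum(resid^2) / df, 1e-12)
  }
  structure(list(coef_mean = as.vector(m), coef_cov = (V + t(V)) / 2,
                 n_designs = nrow(X), sigma2 = sigma2),
            class = "surrogate_fit")
}

#' Acquisition: minimize the surrogate over row-sum-K binary vectors
#'
#' For a linear surrogate the constrained minimizer is available in closed
#' form: select the K sites with the smallest posterior-mean coefficients
#' (the K-th order statistic rule). Ties at the K-th order statistic are
#' broken by ascending site index so exactly K sites are always selected.
#'
#' @param fit a `surrogate_fit`, or a bare numeric coefficient vector.
#' @param K subset size.
#' @return binary vector of length L with `sum = K`.
#' @export
acquire <- function(fit, K) {
  b <- if (inherits(fit, "surrogate_fit")) fit$coef_mean else as.numeric(fit)
  L <- length(b)
  if (K >= L) stop("need K < L", call. = FALSE)
  sel <- order(b, seq_len(L))[seq_len(K)]
  x <- integer(L)
  x[sel] <- 1L
  x
}

thompson_acquire <- function(fit, K) {
  # one posterior draw of b, then the same order-statistic rule
  U <- chol(fit$coef_cov + diag(1e-12, ncol(fit$coef_cov)))
  b <- fit$coef_mean + as.vector(t(U) %*% stats::rnorm(length(fit$coef_mean)))
  acquire(b, K)
}

#' Bayesian-Optimization loop for subset selection
#'
#' Evaluates `N0` random initial designs, then repeats B times: fit the
#' linear surrogate to all evaluated designs, propose the surrogate
#' minimizer ([acquire()]), evaluate the true objective there, and append.
#' The returned optimum is the best design among all `N0 + B` evaluations.
#' If the proposed design was already evaluated, up to 10 Thompson draws
#' from the coefficient posterior are tried, then a uniform-random unseen
#' subset — the loop always adds a new design.
#'
#' @param objective function taking a binary inclusion vector (length L,
#'   sum K) and returning a finite loss.
#' @param L,K problem dimensions.
#' @param N0 initial design count.
#' @param B number of optimization rounds (B = 0 is pure random search over
#'   the initial designs).
#' @param seed integer RNG seed; the run is reproducible given the seed and
#'   a deterministic objective.
#' @param acquisition `"mean"` (posterior-mean rule, default) or
#'   `"thompson"` (a posterior draw every round).
#' @return list of class `bo_state`: `X`, `losses`, `best_x`, `best_loss`,
#'   `best_members`, `trace` (best-so-far), `surrogate` (final fit), `seed`.
#' @export
bo_loop <- function(objective, L, K, N0 = 20L, B = 30L, seed = 1L,
                    acquisition = c("mean", "thompson")) {
  acquisition <- match.arg(acquisition)
  if (B < 0L) stop("B must be >= 0", call. = FALSE)
  X <- init_designs(L, K, N0, seed = seed)
  eval_obj <- function(x) {
    val <- objective(x)
    if (!is.finite(val)) {
      stop("objective returned a non-finite loss for design {",
           design_key(x), "}", call. = FALSE)
    }
    val
  }
  losses <- apply(X, 1L, eval_obj)
  seen <- apply(X, 1L, design_key)
  set.seed(seed + 1L)  # RNG stream for acquisition fallbacks
  fit <- NULL
  for (b in seq_len(B)) {
    if (length(seen) >= choose(L, K)) break  # design space exhausted
    if (nrow(X) >= 2L) {
      fit <- fit_surrogate(X, losses)
      x_new <- if (acquisition == "mean") acquire(fit, K) else
        thompson_acquire(fit, K)
      tries <- 0L
      while (design_key(x_new) %in% seen && tries < 10L) {
        x_new <- thompson_acquire(fit, K)
        tries <- tries + 1L
      }
    } else {
      x_new <- random_k_subset(L, K)
    }
    while (design_key(x_new) %in% seen) x_new <- random_k_subset(L, K)
    X <- rbind(X, x_new)
    losses <- c(losses, eval_obj(x_new))
    seen <- c(seen, design_key(x_new))
  }
  if (nrow(X) >= 2L) fit <- fit_surrogate(X, losses)
  best <- which.min(losses)
  rownames(X) <- NULL
  structure(list(X = X, losses = losses, best_x = X[best, ],
                 best_loss = losses[best],
                 best_members = which(X[best, ] == 1L),
                 trace = cummin(losses), surrogate = fit, seed = seed,
                 N0 = N0, B = B),
            class = "bo_state")
}

#' @export
print.bo_state <- function(x, ...) {
  cat("<bo_state> ", length(x$losses), " evaluated designs (N0 = ", x$N0,
      ", B = ", x$B, ")\n  best loss ", signif(x$best_loss, 5),
      " at sites {", paste(x$best_members, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' Brute-force enumeration oracle
#'
#' Evaluates the objective at every one of the `choose(L, K)` subsets and
#' returns the exact argmin plus the full ranked table. Only feasible for
#' small instances; the cap guards against combinatorial blow-up (50 choose
#' 20 already exceeds 10^13).
#'
#' @inheritParams bo_loop
#' @param cap refuse to enumerate more than this many subsets.
#' @return list: `best_x`, `best_loss`, `best_members`, `table` (data.frame
#'   of member sets and losses, ascending).
#' @export
brute_force <- function(objective, L, K, cap = 5000L) {
  n_comb <- choose(L, K)
  if (n_comb > cap) {
    stop("choose(", L, ", ", K, ") = ", format(n_comb, big.mark = ","),
         " exceeds the enumeration cap (", cap,
         "); use bo_loop() instead", call. = FALSE)
  }
  combs <- utils::combn(L, K)
  losses <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    x <- integer(L)
    x[combs[, i]] <- 1L
    losses[i] <- objective(x)
  }
  ord <- order(losses)
  best <- ord[1L]
  best_x <- integer(L)
  best_x[combs[, best]] <- 1L
  tab <- data.frame(
    members = vapply(ord, function(i) paste(combs[, i], collapse = ","),
                     character(1)),
    loss = losses[ord]
  )
  list(best_x = best_x, best_loss = losses[best],
       best_members = combs[, best], table = tab)
}
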