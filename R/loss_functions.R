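#' A fixed-size subset of candidate sites
#'
#' Represents a choice of K of the L candidate trap locations, both as the
#' member id list and as the binary inclusion vector `x` with `sum(x) = K`
#' used by the optimization layer.
#'
#' @param members distinct site ids to include.
#' @param site_ids the full ordered candidate list (length L).
#' @return list of class `site_subset` with `members`, `x` (binary, named by
#'   `site_ids`), `K`, `L`.
#' @export
site_subset <- function(members, site_ids) {
  members <- as.integer(members)
  site_ids <- as.integer(site_ids)
  if (anyDuplicated(members)) stop("subset members must be distinct",
                                   call. = FALSE)
  if (!all(members %in% site_ids)) {
    stop("subset members outside the candidate site list: ",
         paste(setdiff(members, site_ids), collapse = ", "), call. = FALSE)
  }
  K <- length(members); L <- length(site_ids)
  if (K < 1L || K >= L) stop("need 1 <= K < L", call. = FALSE)
  x <- as.integer(site_ids %in% members)
  names(x) <- site_ids
  structure(list(members = members, x = x, K = K, L = L),
            class = "site_subset")
}

#' Mean log error between observed and predicted cumulative counts
#'
#' The loss `(1/n) * sum(log(|Y - Yhat| + 1))` over a set of evaluation
#' cells, natural logarithm, counts in hundreds of pests. Taking logs of the
#' absolute errors puts early-season cells (tens of moths) and late-season
#' cells (thousands) on a comparable scale so each cell contributes roughly
#' equally.
#'
#' @param obs,pred numeric vectors of observed and predicted cumulative
#'   counts on the same cells, same order.
#' @param cells optional data.frame labelling the cells (e.g. year, site_id,
#'   week); carried into the report for audit.
#' @return list of class `loss_report`: `value`, `terms` (per-cell
#'   log-errors), `n`, `cells`.
#' @export
mean_log_error <- function(obs, pred, cells = NULL) {
  if (!length(obs)) stop("empty cell set", call. = FALSE)
  if (length(obs) != length(pred)) {
    stop("obs and pred must have equal length", call. = FALSE)
  }
  bad <- which(!is.finite(pred))
  if (length(bad)) {
    lab <- if (!is.null(cells)) {
      paste(unlist(cells[bad[1L], ]), collapse = "/")
    } else as.character(bad[1L])
    stop("non-finite prediction at cell ", lab, call. = FALSE)
  }
  if (any(!is.finite(obs))) stop("non-finite observed value", call. = FALSE)
  terms <- log(abs(obs - pred) + 1)
  structure(list(value = mean(terms), terms = terms, n = length(terms),
                 cells = cells),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("<loss_report> mean log error = ", signif(x$value, 5), " over ",
      x$n, " cells\n", sep = "")
  invisible(x)
}

#' Convert a mean log error to an average count error
#'
#' A mean log error of m corresponds to a typical absolute error of
#' `exp(m) - 1` hundreds of pests, i.e. `(exp(m) - 1) * 100` individual
#' moths.
#'
#' @param mle mean log error value.
#' @param hundreds if `TRUE` (default) return the error in individual pests
#'   assuming the internal hundreds scale.
#' @return numeric error magnitude.
#' @examples
#' mle_to_count_error(1.2)  # about 230 moths
#' @export
mle_to_count_error <- function(mle, hundreds = TRUE) {
  (exp(mle) - 1) * if (hundreds) 100 else 1
}

#' Hold-out loss of a site subset
#'
#' Fits the growth model on the subset's sites over `fit_years`, predicts by
#' kriging at every candidate site *not* in the subset, and returns the
#' [mean_log_error()] over all observed cells at those held-out sites in
#' `eval_years`. With `eval_years = fit_years =` the pre-test years this is
#' the optimization objective; with `eval_years =` the test year it is the
#' final evaluation loss.
#'
#' @param ds a [trap_dataset()] with no missing cells.
#' @param subset a [site_subset()].
#' @param eval_years years whose held-out cells are scored.
#' @param fit_years years pooled into the model fit.
#' @param mcmc an [mcmc_config()].
#' @param clip_negative clip negative kriged predictions at 0 before scoring
#'   (reporting-layer convention; default `TRUE`).
#' @return a `loss_report`; attributes `subset` and `posterior_summary`.
#' @export
holdout_loss <- function(ds, subset, eval_years, fit_years,
                         mcmc = mcmc_config(profile = "fast"),
                         clip_negative = TRUE) {
  stopifnot(inherits(subset, "site_subset"))
  all_sites <- ds$registry$site_id
  held_out <- setdiff(all_sites, subset$members)
  if (!length(held_out)) {
    stop("subset contains every site: no held-out cells to score",
         call. = FALSE)
  }
  post <- fit_growth_model(ds, train_sites = subset$members,
                           years = fit_years, mcmc = mcmc)
  cum <- cumulative_counts(ds)
  cells <- cum[cum$year %in% eval_years & cum$site_id %in% held_out, ]
  if (!nrow(cells)) stop("no evaluation cells at held-out sites",
                         call. = FALSE)
  targets <- ds$registry[match(held_out, ds$registry$site_id), ]
  pred <- predict_cumulative(post, targets, weeks = sort(unique(cells$week)))
  key_p <- paste(pred$site_id, pred$week)
  pv <- pred$pred[match(paste(cells$site_id, cells$week), key_p)]
  if (clip_negative) pv <- pmax(pv, 0)
  rep <- mean_log_error(cells$cumulative, pv,
                        cells = cells[, c("year", "site_id", "week")])
  attr(rep, "subset") <- subset
  rep
}

#' Cost-penalized loss
#'
#' Extends a prediction loss with an operating-cost term:
#' `value + lambda * C(S)` where by default `C(S)` is the sum of per-site
#' costs over the subset; `lambda >= 0` trades off fit (small lambda)
#' against cost (large lambda). A user-supplied `cost_fn(members)` replaces
#' the additive form (e.g. a collection-tour length).
#'
#' @param base a `loss_report` (or a bare numeric loss value).
#' @param subset a [site_subset()].
#' @param costs named numeric vector of per-site costs (names = site ids).
#' @param lambda non-negative tuning weight.
#' @param cost_fn optional function of the member id vector returning a
#'   single total cost; overrides `costs`.
#' @return penalized loss (single numeric).
#' @export
cost_penalized_loss <- function(base, subset, costs = NULL, lambda = 0,
                                cost_fn = NULL) {
  value <- if (inherits(base, "loss_report")) base$value else as.numeric(base)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  total_cost <- if (!is.null(cost_fn)) {
    cost_fn(subset$members)
  } else {
    if (is.null(costs)) stop("provide costs or cost_fn", call. = FALSE)
    idx <- match(as.character(subset$members), names(costs))
    if (anyNA(idx)) {
      stop("missing cost for site(s): ",
           paste(subset$members[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    sum(costs[idx])
  }
  value + lambda * total_cost
}

#' Write a loss report's per-cell audit table
#'
#' @param report a `loss_report` from [mean_log_error()] or
#'   [holdout_loss()].
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
write_loss_report <- function(report, path) {
  df <- if (!is.null(report$cells)) report$cells else
    data.frame(cell = seq_len(report$n))
  df$term <- report$terms
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
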