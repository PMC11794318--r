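# Monte-Carlo experiment harness: sweep over subset sizes K, repeat the
# optimization with fresh seeds, compare against a random baseline on the
# test year, and summarise which sites keep being selected.

# Deterministic per-rep sub-seed derived from a master seed; kept below
# 2^31 so it stays a valid R integer.
derive_seed <- function(master, K, rep, role = 0L) {
  as.integer((as.double(master) * 1000003 + K * 10007 + rep * 101 +
                role * 7 + 1) %% 2147483629)
}

#' Configuration for the K-sweep experiment
#'
#' @param K_values subset sizes to sweep over.
#' @param n_mc Monte-Carlo repetitions per K (the study used 50; scale down
#'   for quick runs).
#' @param N0,B initial-design count and optimization rounds per repetition.
#' @param seed master seed; all per-repetition seeds derive from it.
#' @param test_year held-back season for final evaluation (default: last
#'   year in the data).
#' @param fit_window `"all_years"`: the final model is fitted on the chosen
#'   subset's data from every season including the test year;
#'   `"test_only"`: fitted on the test season alone.
#' @param mcmc an [mcmc_config()] used for every model fit.
#' @param random_budget_match if `TRUE` the random baseline draws `N0 + B`
#'   subsets per repetition and keeps the best on the *training* objective
#'   (equal evaluation budget); default `FALSE` — one random subset per
#'   repetition, mirroring the plain baseline.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(K_values, n_mc = 50L, N0 = 20L, B = 30L,
                              seed = 1L, test_year = NULL,
                              fit_window = c("all_years", "test_only"),
                              mcmc = mcmc_config(profile = "fast"),
                              random_budget_match = FALSE) {
  stopifnot(length(K_values) >= 1L, n_mc >= 1L)
  structure(list(K_values = as.integer(K_values), n_mc = as.integer(n_mc),
                 N0 = as.integer(N0), B = as.integer(B),
                 seed = as.integer(seed), test_year = test_year,
                 fit_window = match.arg(fit_window), mcmc = mcmc,
                 random_budget_match = random_budget_match),
            class = "experiment_config")
}

#' Run the K-sweep Monte-Carlo experiment
#'
#' For every subset size K and repetition: (a) run the Bayesian-Optimization
#' loop on the pre-test-year objective (fit on the candidate subset, score
#' held-out sites within the training years), (b) evaluate the winning
#' subset on the test year, (c) evaluate a uniform-random K-subset the same
#' way as a baseline. Aggregates mean test-year losses per (K, method),
#' per-site inclusion proportions of the winning subsets, and the
#' tied-inclusion tile table.
#'
#' @param ds a [trap_dataset()] with no missing cells.
#' @param cfg an [experiment_config()].
#' @return list of class `experiment_summary`: `mean_mle` (data.frame K,
#'   method, mean_mle, sd, n), `inclusion_prop` (K x site matrix),
#'   `avg_inclusion`, `tiles` (K x site logical matrix), `best_sets`,
#'   `config`.
#' @export
run_sweep <- function(ds, cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  all_years <- sort(as.integer(names(ds$weeks_per_year)))
  test_year <- if (is.null(cfg$test_year)) max(all_years) else
    as.integer(cfg$test_year)
  if (!test_year %in% all_years) {
    stop("test_year ", test_year, " not present in the dataset",
         call. = FALSE)
  }
  train_years <- setdiff(all_years, test_year)
  eval_fit_years <- if (cfg$fit_window == "all_years") all_years else
    test_year
  site_ids <- ds$registry$site_id
  L <- length(site_ids)
  if (any(cfg$K_values < 1L | cfg$K_values >= L)) {
    stop("every K must satisfy 1 <= K < L = ", L, call. = FALSE)
  }

  objective_for <- function(mc_seed) {
    force(mc_seed)
    function(x) {
      sub <- site_subset(site_ids[x == 1L], site_ids)
      m <- cfg$mcmc
      m$seed <- mc_seed
      holdout_loss(ds, sub, eval_years = train_years,
                   fit_years = train_years, mcmc = m)$value
    }
  }
  final_loss <- function(members, mc_seed) {
    sub <- site_subset(members, site_ids)
    m <- cfg$mcmc
    m$seed <- mc_seed
    holdout_loss(ds, sub, eval_years = test_year,
                 fit_years = eval_fit_years, mcmc = m)$value
  }
  with_retry <- function(expr_fn, seed) {
    tryCatch(expr_fn(seed), error = function(e) {
      warning("repetition failed (", conditionMessage(e),
              "); retrying once with jittered seed", call. = FALSE)
      tryCatch(expr_fn(seed + 999983L), error = function(e2) {
        warning("retry failed too; recording NA", call. = FALSE)
        NA_real_
      })
    })
  }

  res_rows <- list()
  best_sets <- list()
  for (K in cfg$K_values) {
    best_sets[[as.character(K)]] <- vector("list", cfg$n_mc)
    for (rep in seq_len(cfg$n_mc)) {
      seed_bo <- derive_seed(cfg$seed, K, rep, 0L)
      seed_fit <- derive_seed(cfg$seed, K, rep, 1L)
      seed_rand <- derive_seed(cfg$seed, K, rep, 2L)

      state <- bo_loop(objective_for(seed_fit), L = L, K = K,
                       N0 = cfg$N0, B = cfg$B, seed = seed_bo)
      members_bo <- site_ids[state$best_x == 1L]
      best_sets[[as.character(K)]][[rep]] <- members_bo
      loss_bo <- with_retry(function(s) final_loss(members_bo, s), seed_fit)

      set.seed(seed_rand)
      if (cfg$random_budget_match) {
        cand <- init_designs(L, K, min(cfg$N0 + cfg$B, choose(L, K)),
                             seed = seed_rand)
        obj <- objective_for(seed_fit)
        tr_losses <- apply(cand, 1L, obj)
        members_rand <- site_ids[cand[which.min(tr_losses), ] == 1L]
      } else {
        members_rand <- sample(site_ids, K)
      }
      loss_rand <- with_retry(function(s) final_loss(members_rand, s),
                              seed_fit)

      res_rows[[length(res_rows) + 1L]] <- data.frame(
        K = K, rep = rep, method = c("bo", "random"),
        loss = c(loss_bo, loss_rand))
    }
  }
  per_rep <- do.call(rbind, res_rows)
  agg <- stats::aggregate(loss ~ K + method, per_rep, mean, na.rm = TRUE)
  names(agg)[names(agg) == "loss"] <- "mean_mle"
  agg$sd <- stats::aggregate(loss ~ K + method, per_rep, stats::sd,
                             na.rm = TRUE)$loss
  agg$n <- stats::aggregate(loss ~ K + method, per_rep,
                            function(v) sum(!is.na(v)))$loss

  ip <- inclusion_proportions(best_sets, site_ids)
  tiles <- tile_table(ip$inclusion_prop, cfg$K_values)

  structure(list(mean_mle = agg, per_rep = per_rep,
                 inclusion_prop = ip$inclusion_prop,
                 avg_inclusion = ip$avg_inclusion, tiles = tiles,
                 best_sets = best_sets, config = cfg,
                 test_year = test_year),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary> test year ", x$test_year, ", ",
      x$config$n_mc, " MC repetition(s) per K\n", sep = "")
  print(x$mean_mle, row.names = FALSE)
  invisible(x)
}

#' Per-site inclusion proportions of the winning subsets
#'
#' For each K and site: the fraction of Monte-Carlo repetitions whose best
#' subset contains the site. The average over K gives a continuous,
#' K-agnostic measure of a site's importance.
#'
#' @param best_sets list (named by K) of lists of member-id vectors, one
#'   per repetition.
#' @param site_ids full candidate site list.
#' @return list: `inclusion_prop` (K x site matrix) and `avg_inclusion`
#'   (named vector, unweighted mean over K).
#' @export
inclusion_proportions <- function(best_sets, site_ids) {
  Ks <- names(best_sets)
  ip <- matrix(0, length(Ks), length(site_ids),
               dimnames = list(Ks, site_ids))
  for (ki in seq_along(Ks)) {
    reps <- best_sets[[ki]]
    if (!length(reps)) stop("no repetitions for K = ", Ks[ki],
                            call. = FALSE)
    for (members in reps) {
      ip[ki, match(members, site_ids)] <- ip[ki, match(members, site_ids)] +
        1 / length(reps)
    }
  }
  list(inclusion_prop = ip, avg_inclusion = colMeans(ip))
}

#' Binary inclusion/exclusion tile table
#'
#' For each K, marks every site whose inclusion proportion is at least the
#' K-th largest proportion for that K. Exact ties at the threshold are all
#' marked, so a row can carry more than K marks.
#'
#' @param inclusion_prop K x site matrix from [inclusion_proportions()].
#' @param K_values the subset sizes (row order of `inclusion_prop`).
#' @return logical matrix, same shape as `inclusion_prop`.
#' @export
tile_table <- function(inclusion_prop, K_values) {
  stopifnot(nrow(inclusion_prop) == length(K_values))
  tiles <- inclusion_prop > 1  # all FALSE
  for (i in seq_along(K_values)) {
    thr <- sort(inclusion_prop[i, ], decreasing = TRUE)[K_values[i]]
    tiles[i, ] <- inclusion_prop[i, ] >= thr
  }
  tiles
}

#' Write an experiment summary to a run directory
#'
#' Emits `summary.csv` (K, method, mean_mle, sd, n), `inclusion.csv`,
#' `tiles.csv` and `run_log.txt` (seed, configuration, package version).
#'
#' @param summary an `experiment_summary`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_experiment <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$mean_mle, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  ip <- as.data.frame(as.table(summary$inclusion_prop))
  names(ip) <- c("K", "site_id", "proportion")
  utils::write.csv(ip, file.path(dir, "inclusion.csv"), row.names = FALSE,
                   quote = FALSE)
  tl <- as.data.frame(as.table(summary$tiles))
  names(tl) <- c("K", "site_id", "selected")
  utils::write.csv(tl, file.path(dir, "tiles.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- summary$config
  writeLines(c(
    paste0("trapnet ", as.character(utils::packageVersion("trapnet"))),
    paste0("master seed: ", cfg$seed),
    paste0("K values: ", paste(cfg$K_values, collapse = ", ")),
    paste0("n_mc: ", cfg$n_mc, "  N0: ", cfg$N0, "  B: ", cfg$B),
    paste0("test year: ", summary$test_year),
    paste0("fit window: ", cfg$fit_window),
    paste0("mcmc: ", cfg$mcmc$n_chains, " chain(s), ",
           cfg$mcmc$n_warmup, " + ", cfg$mcmc$n_iter, " iterations, thin ",
           cfg$mcmc$thin)
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}
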