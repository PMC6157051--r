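# Benchmarking harness: strategy x budget x caller-subset sweeps with
# replicates, per-caller subset-vs-full F1 differences, and strategy ranking
# by median |dF1|. Every stochastic step draws its seed from the master seed
# and its factor coordinates via derive_seed(), so any row of a report can be
# reproduced in isolation.

SUBSET_MODES <- c("complete", "best_per_team", "random_k_of_best",
                  "random_k_of_all")

#' Restrict a profile to a benchmarking subset of callers
#'
#' Subset modes mirror a standard benchmarking design:
#' `complete` keeps every call set; `best_per_team` keeps, for each team,
#' the submission with the highest full-set F1; `random_k_of_best` samples
#' k of those team-best call sets; `random_k_of_all` samples k call sets
#' from the full pool.
#'
#' @param profile a `call_profile`.
#' @param mode one of `"complete"`, `"best_per_team"`, `"random_k_of_best"`,
#'   `"random_k_of_all"`.
#' @param k number of callers for the random modes.
#' @param seed integer seed for the random modes.
#' @param teams named character vector mapping caller -> team; required by
#'   the best-per-team modes (no mapping is ever guessed).
#' @param full_f1 named numeric vector of full-set F1 per caller; required
#'   by the best-per-team modes.
#' @return A `call_profile` restricted to the surviving callers.
#' @export
subset_callers <- function(profile, mode, k = NULL, seed = NULL,
                           teams = NULL, full_f1 = NULL) {
  mode <- match.arg(mode, SUBSET_MODES)
  if (mode == "complete") return(profile)
  pick_best <- function() {
    if (is.null(teams) || is.null(full_f1))
      stop("best-per-team modes require `teams` and `full_f1`", call. = FALSE)
    if (!all(profile$callers %in% names(teams)))
      stop("`teams` must map every caller to a team", call. = FALSE)
    if (!all(profile$callers %in% names(full_f1)))
      stop("`full_f1` must score every caller", call. = FALSE)
    best <- vapply(split(profile$callers, teams[profile$callers]),
                   function(cs) cs[which.max(full_f1[cs])], "")
    # preserve profile caller order
    profile$callers[profile$callers %in% best]
  }
  pool <- switch(mode,
    best_per_team = ,
    random_k_of_best = pick_best(),
    random_k_of_all = profile$callers
  )
  keep <- if (mode == "best_per_team") {
    pool
  } else {
    k <- assert_count(k, "k")
    if (k > length(pool))
      stop(sprintf("k = %d exceeds the %d available call sets",
                   k, length(pool)), call. = FALSE)
    if (is.null(seed)) stop("random subset modes require `seed`", call. = FALSE)
    withr::with_seed(as.integer(seed), sort(sample_keys(pool, k)))
  }
  restrict_callers(profile, keep)
}

#' Run one verification experiment
#'
#' Selects a candidate set with one strategy at one budget, estimates
#' per-caller metrics from it, and reports each caller's subset F1 against
#' its full-prediction-set F1.
#'
#' @param profile a `call_profile`.
#' @param truth a `truth_table` covering all profile variants.
#' @param strategy one of [strategy_names()].
#' @param budget positive integer number of candidates.
#' @param mode precision mode, `"default"` or `"weighted"`.
#' @param seed integer seed for the selection.
#' @param baseline full-set baseline passed to [full_set_metrics()]. The
#'   default `"union"` makes the subset estimate converge to the reference
#'   exactly as the budget approaches the union size (a subset of the call
#'   union can never witness mutations missed by every caller).
#' @param full optional precomputed [full_set_metrics()] table, to avoid
#'   recomputation across replicates.
#' @return data.frame with one row per caller: `strategy`, `mode`, `budget`,
#'   `seed`, `caller`, `subset_f1`, `full_f1`, `delta_f1`, `na_flag`.
#' @export
run_experiment <- function(profile, truth, strategy, budget,
                           mode = "default", seed,
                           baseline = "union", full = NULL) {
  full <- full %||% full_set_metrics(profile, truth, baseline = baseline)
  sel <- select_candidates(profile, budget, strategy, seed)
  est <- evaluate_callers(profile, sel, truth, mode = mode)
  idx <- match(est$caller, full$caller)
  delta <- ifelse(is.na(est$F1) | is.na(full$F1[idx]), NA_real_,
                  est$F1 - full$F1[idx])
  data.frame(strategy = strategy, mode = mode, budget = as.integer(budget),
             seed = as.integer(seed), caller = est$caller,
             subset_f1 = est$F1, full_f1 = full$F1[idx], delta_f1 = delta,
             na_flag = is.na(est$F1), stringsAsFactors = FALSE)
}

#' Enumerate a sweep's experiment configurations
#'
#' Expands datasets x caller-subset draws x budgets into the configuration
#' grid a sweep runs: one draw for `complete` and `best_per_team`, and
#' `n_subset_replicates` draws for each random subset mode.
#'
#' @param datasets character vector of dataset identifiers.
#' @param budgets integer vector of verification budgets.
#' @param subset_modes subset modes to include.
#' @param n_subset_replicates replicate draws per random subset mode.
#' @return data.frame with columns `dataset`, `subset_mode`,
#'   `subset_replicate`, `budget`.
#' @examples
#' nrow(enumerate_design(c("T1", "T2", "T3"), c(100, 250, 500, 1000, 2500)))
#' @export
enumerate_design <- function(datasets, budgets,
                             subset_modes = SUBSET_MODES,
                             n_subset_replicates = 10L) {
  subset_modes <- match.arg(subset_modes, SUBSET_MODES, several.ok = TRUE)
  reps <- ifelse(subset_modes %in% c("complete", "best_per_team"),
                 1L, as.integer(n_subset_replicates))
  subsets <- data.frame(
    subset_mode = rep(subset_modes, reps),
    subset_replicate = unlist(lapply(reps, seq_len)),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(i = seq_len(nrow(subsets)), dataset = datasets,
                      budget = as.integer(budgets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(dataset = grid$dataset,
                    subset_mode = subsets$subset_mode[grid$i],
                    subset_replicate = subsets$subset_replicate[grid$i],
                    budget = grid$budget, stringsAsFactors = FALSE)
  out[order(out$dataset, out$subset_mode, out$subset_replicate, out$budget), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Run a full benchmarking sweep
#'
#' Runs every configured combination of dataset, caller subset, strategy,
#' budget, precision mode and strategy replicate, and summarizes per
#' strategy x mode. Seeds derive from `master_seed` and the factor
#' coordinates.
#'
#' @param config list with elements `budgets`, `strategies` (character,
#'   default all six), `modes` (default `"default"`), `subset_modes`
#'   (default `"complete"`), `subset_k`, `n_subset_replicates` (default 10),
#'   `n_strategy_replicates` (default 10), `master_seed` (default 1),
#'   `baseline` (default `"union"`).
#' @param datasets named list of datasets, each a list with `profile`,
#'   `truth` and optionally `teams` (named caller -> team vector).
#' @return An object of class `sweep_report`: list with `rows` (one row per
#'   configuration x caller) and `summary` (per strategy x mode ranking, see
#'   [rank_strategies()]).
#' @export
run_sweep <- function(config, datasets) {
  stopifnot(is.list(datasets), length(datasets) > 0)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("`datasets` must be a named list", call. = FALSE)
  budgets <- as.integer(config$budgets %||% stop("config$budgets required"))
  strategies <- config$strategies %||% strategy_names()
  modes <- config$modes %||% "default"
  subset_modes <- config$subset_modes %||% "complete"
  n_sub <- as.integer(config$n_subset_replicates %||% 10L)
  n_rep <- as.integer(config$n_strategy_replicates %||% 10L)
  master <- as.integer(config$master_seed %||% 1L)
  baseline <- config$baseline %||% "union"

  design <- enumerate_design(names(datasets), budgets, subset_modes, n_sub)
  subset_specs <- unique(design[c("dataset", "subset_mode", "subset_replicate")])
  rows <- list()
  for (s in seq_len(nrow(subset_specs))) {
    ds_id <- subset_specs$dataset[s]
    smode <- subset_specs$subset_mode[s]
    srep <- subset_specs$subset_replicate[s]
    ds <- datasets[[ds_id]]
    full_all <- NULL
    full_f1 <- NULL
    if (smode %in% c("best_per_team", "random_k_of_best")) {
      full_all <- full_set_metrics(ds$profile, ds$truth, baseline = baseline)
      full_f1 <- setNames(full_all$F1, full_all$caller)
    }
    sub_seed <- derive_seed(master, "subset", ds_id, smode, srep)
    prof <- subset_callers(ds$profile, smode, k = config$subset_k,
                           seed = sub_seed, teams = ds$teams,
                           full_f1 = full_f1)
    full <- full_set_metrics(prof, ds$truth, baseline = baseline)
    for (strategy in strategies) for (budget in budgets)
      for (mode in modes) for (rep in seq_len(n_rep)) {
        seed <- derive_seed(master, ds_id, smode, srep, strategy, budget,
                            mode, rep)
        r <- run_experiment(prof, ds$truth, strategy, budget, mode = mode,
                            seed = seed, baseline = baseline, full = full)
        r <- cbind(data.frame(dataset = ds_id, subset_mode = smode,
                              subset_replicate = srep,
                              strategy_replicate = rep,
                              stringsAsFactors = FALSE), r)
        rows[[length(rows) + 1L]] <- r
      }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  structure(list(rows = rows, summary = rank_strategies(rows)),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("sweep_report: %d rows over %d strategy x mode combinations\n",
              nrow(x$rows), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Summarize and rank strategies from sweep rows
#'
#' Per strategy x precision mode: median signed dF1, median and mean |dF1|,
#' IQR of |dF1| (spread across replicates), and the rate of undefined (N/A)
#' estimates. Undefined scores are excluded from location/spread statistics
#' — they are missing data — but surfaced as `na_rate` so the failure mode
#' stays visible. Strategies are ranked by ascending median |dF1|; ties
#' break by smaller IQR, then name. A strategy with no defined score at all
#' is ranked last and flagged.
#'
#' @param report a `sweep_report` or its `rows` data.frame.
#' @return data.frame ordered by rank with columns `strategy`, `mode`,
#'   `n`, `median_delta_f1`, `median_abs_delta_f1`, `mean_abs_delta_f1`,
#'   `iqr_abs_delta_f1`, `na_rate`, `all_missing`, `rank`.
#' @export
rank_strategies <- function(report) {
  rows <- if (inherits(report, "sweep_report")) report$rows else report
  groups <- split(rows, list(rows$strategy, rows$mode), drop = TRUE)
  summ <- do.call(rbind, lapply(groups, function(g) {
    d <- g$delta_f1[!is.na(g$delta_f1)]
    data.frame(
      strategy = g$strategy[1L], mode = g$mode[1L], n = nrow(g),
      median_delta_f1 = if (length(d)) median(d) else NA_real_,
      median_abs_delta_f1 = if (length(d)) median(abs(d)) else NA_real_,
      mean_abs_delta_f1 = if (length(d)) mean(abs(d)) else NA_real_,
      iqr_abs_delta_f1 = if (length(d))
        unname(diff(quantile(abs(d), c(0.25, 0.75)))) else NA_real_,
      na_rate = mean(is.na(g$delta_f1)),
      all_missing = length(d) == 0L,
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(summ$all_missing, summ$median_abs_delta_f1,
               summ$iqr_abs_delta_f1, summ$strategy, summ$mode)
  summ <- summ[ord, , drop = FALSE]
  summ$rank <- seq_len(nrow(summ))
  rownames(summ) <- NULL
  summ
}
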