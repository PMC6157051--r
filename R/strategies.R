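# The six verification-candidate selection strategies. All sample without
# replacement and share the same budget contract: the selection always holds
# min(n_targets, number of distinct selectable variants) variants — the
# budget runs short only when the calls run out. Quota integerization goes
# through apportion(); shortfalls (a unit with fewer available calls than its
# quota) are redistributed iteratively: after each pass the unspent budget is
# re-apportioned over units that still have unconsumed calls, until the
# budget is spent or no calls remain.

#' Names of the available selection strategies
#' @return Character vector of the six strategy names.
#' @export
strategy_names <- function() {
  c("random_rows", "directed_sampling", "equal_per_caller",
    "equal_per_overlap", "increasing_with_overlap", "decreasing_with_overlap")
}

#' Select verification candidates with a named strategy
#'
#' Dispatches to one of the six selection strategies:
#' \describe{
#'   \item{random_rows}{uniform sampling from the whole call union,
#'     ignoring recurrence and caller identity.}
#'   \item{directed_sampling}{traverses the call overlap-by-caller matrix
#'     from the highest overlap row down, spreading the budget over the
#'     not-yet-examined cells so every caller and overlap level is
#'     represented.}
#'   \item{equal_per_caller}{divides the budget equally among callers; a
#'     call chosen for one caller becomes an invalid choice for all others.}
#'   \item{equal_per_overlap}{divides the budget equally across overlap
#'     levels 1..N.}
#'   \item{increasing_with_overlap}{allocates across levels in proportion to
#'     the overlap level k.}
#'   \item{decreasing_with_overlap}{allocates across levels in proportion to
#'     1/k.}
#' }
#'
#' @param profile a `call_profile`.
#' @param n_targets positive integer verification budget.
#' @param strategy one of [strategy_names()].
#' @param seed integer seed; identical inputs give identical selections.
#' @return A `selection` of `min(n_targets, n_variants)` distinct variants.
#' @examples
#' prof <- build_call_profile(data.frame(
#'   caller = rep(c("A", "B"), each = 4),
#'   chrom = "chr1", pos = c(1:4, 3:6)
#' ))
#' select_candidates(prof, 4, "equal_per_caller", seed = 7)
#' @export
select_candidates <- function(profile, n_targets, strategy, seed) {
  strategy <- match.arg(strategy, strategy_names())
  fn <- switch(strategy,
    random_rows = select_random_rows,
    directed_sampling = select_directed_sampling,
    equal_per_caller = select_equal_per_caller,
    equal_per_overlap = select_equal_per_overlap,
    increasing_with_overlap = select_increasing_with_overlap,
    decreasing_with_overlap = select_decreasing_with_overlap
  )
  fn(profile, n_targets, seed)
}

check_select_args <- function(profile, n_targets, seed) {
  if (!inherits(profile, "call_profile"))
    stop("`profile` must be a call_profile", call. = FALSE)
  assert_count(n_targets, "n_targets")
  assert_count(seed, "seed", min = 0L)
}

#' Random-rows selection
#'
#' Samples calls uniformly at random without replacement from the entire
#' call union until the budget is reached or no calls remain. The recorded
#' attribution is a uniformly chosen member caller per variant (diagnostic
#' only — the draw itself ignores caller identity).
#'
#' @inheritParams select_candidates
#' @return A `selection`.
#' @export
select_random_rows <- function(profile, n_targets, seed) {
  check_select_args(profile, n_targets, seed)
  withr::with_seed(as.integer(seed), {
    pool <- profile$variants$key
    keys <- sample_keys(pool, min(n_targets, length(pool)))
    attribution <- vapply(profile$membership[keys], function(m)
      m[sample.int(length(m), 1L)], "")
  })
  selection_from_keys(profile, keys, attribution, "random_rows",
                      as.integer(seed))
}

#' Equal-per-caller selection
#'
#' Divides the budget equally among callers (largest-remainder split) and
#' samples each caller's still-available calls without replacement up to its
#' quota. A call selected for one caller becomes an invalid choice for all
#' others, so callers are processed in seeded random order to avoid a
#' systematic advantage. Quota a caller cannot spend is redistributed
#' equally over the callers that still have unconsumed calls, iterating
#' until the budget is spent or calls run out.
#'
#' @inheritParams select_candidates
#' @return A `selection` with caller-valued attributions.
#' @export
select_equal_per_caller <- function(profile, n_targets, seed) {
  check_select_args(profile, n_targets, seed)
  withr::with_seed(as.integer(seed), {
    proc_order <- sample_keys(profile$callers, length(profile$callers))
    selected <- character(0)
    attribution <- character(0)
    repeat {
      remaining <- n_targets - length(selected)
      if (remaining == 0L) break
      pools <- lapply(profile$calls_by_caller, setdiff, selected)
      active <- profile$callers[lengths(pools)[profile$callers] > 0L]
      if (length(active) == 0L) break
      plan <- apportion(setNames(rep(1, length(active)), active), remaining)
      n_before <- length(selected)
      for (cl in proc_order[proc_order %in% active]) {
        pool <- setdiff(profile$calls_by_caller[[cl]], selected)
        k <- min(plan$quotas[[cl]], length(pool))
        if (k > 0L) {
          take <- sample_keys(pool, k)
          selected <- c(selected, take)
          attribution <- c(attribution, rep(cl, k))
        }
      }
      if (length(selected) == n_before) break
    }
  })
  selection_from_keys(profile, selected, attribution, "equal_per_caller",
                      as.integer(seed))
}

# Shared engine for the three per-overlap-level strategies. weight_fn maps a
# vector of overlap levels to allocation weights. Levels partition the call
# union, so no cross-unit invalidation arises; redistribution re-apportions
# unspent budget over levels that still hold unselected calls, using the
# strategy's own weights.
select_by_overlap_level <- function(profile, n_targets, seed, weight_fn,
                                    strategy) {
  check_select_args(profile, n_targets, seed)
  N <- length(profile$callers)
  keys_by_level <- split(names(profile$level),
                         factor(profile$level, levels = seq_len(N)))
  withr::with_seed(as.integer(seed), {
    selected <- character(0)
    attribution <- character(0)
    repeat {
      remaining <- n_targets - length(selected)
      if (remaining == 0L) break
      pools <- lapply(keys_by_level, setdiff, selected)
      active <- which(lengths(pools) > 0L)
      if (length(active) == 0L) break
      w <- setNames(weight_fn(active), as.character(active))
      plan <- apportion(w, remaining)
      for (k in active) {
        pool <- pools[[k]]
        take_n <- min(plan$quotas[[as.character(k)]], length(pool))
        if (take_n > 0L) {
          take <- sample_keys(pool, take_n)
          selected <- c(selected, take)
          attribution <- c(attribution, rep(sprintf("overlap=%d", k), take_n))
        }
      }
    }
  })
  selection_from_keys(profile, selected, attribution, strategy,
                      as.integer(seed))
}

#' Equal-per-overlap selection
#'
#' Divides the budget equally across the overlap levels 1..N (level k = the
#' calls made by exactly k callers) and samples within each level without
#' replacement. A level that cannot spend its share passes the shortfall
#' equally to the levels that still have calls.
#'
#' @inheritParams select_candidates
#' @return A `selection` with `"overlap=k"` attributions.
#' @export
select_equal_per_overlap <- function(profile, n_targets, seed) {
  select_by_overlap_level(profile, n_targets, seed,
                          function(k) rep(1, length(k)), "equal_per_overlap")
}

#' Increasing-with-overlap selection
#'
#' Like [select_equal_per_overlap()], but the level-k share is proportional
#' to k, favouring recurrent (widely agreed-on) calls.
#'
#' @inheritParams select_candidates
#' @return A `selection` with `"overlap=k"` attributions.
#' @export
select_increasing_with_overlap <- function(profile, n_targets, seed) {
  select_by_overlap_level(profile, n_targets, seed,
                          function(k) k, "increasing_with_overlap")
}

#' Decreasing-with-overlap selection
#'
#' Like [select_equal_per_overlap()], but the level-k share is proportional
#' to 1/k, favouring unique calls.
#'
#' @inheritParams select_candidates
#' @return A `selection` with `"overlap=k"` attributions.
#' @export
select_decreasing_with_overlap <- function(profile, n_targets, seed) {
  select_by_overlap_level(profile, n_targets, seed,
                          function(k) 1 / k, "decreasing_with_overlap")
}

#' Directed-sampling selection
#'
#' Builds the call overlap-by-caller matrix (see [build_overlap_matrix()])
#' and traverses it row by row from the full-overlap row N down to the
#' unique-call row 1, visiting the cells within a row in ascending order of
#' cell size (ties shuffled by seed). At each cell the cell budget is the
#' remaining budget divided by the number of not-yet-examined cells that
#' still hold selectable calls (floored); the cell's still-available calls
#' are sampled without replacement up to that budget, and each selected call
#' becomes invalid for all future cells. If budget remains after a full
#' traversal the process repeats; a guard pass granting one selection per
#' non-empty cell ensures termination if a traversal ever stalls.
#'
#' @inheritParams select_candidates
#' @return A `selection` with `"overlap=k|caller=j"` cell attributions.
#' @export
select_directed_sampling <- function(profile, n_targets, seed) {
  check_select_args(profile, n_targets, seed)
  om <- build_overlap_matrix(profile)
  N <- length(profile$callers)
  withr::with_seed(as.integer(seed), {
    # traversal order: rows N..1; within a row ascending cell size, equal
    # sizes in seeded random order (shuffle, then stable sort by size)
    cells <- list()
    for (k in rev(seq_len(N))) {
      row <- om$cells[[k]]
      perm <- sample.int(length(row))
      ord <- perm[order(lengths(row)[perm])]
      for (j in ord) {
        cells[[length(cells) + 1L]] <- list(
          level = k, caller = profile$callers[j], keys = row[[j]])
      }
    }
    pool_of <- function(i, selected) setdiff(cells[[i]]$keys, selected)
    selected <- character(0)
    attribution <- character(0)
    take_from <- function(i, k) {
      pool <- pool_of(i, selected)
      k <- min(k, length(pool))
      if (k > 0L) {
        take <- sample_keys(pool, k)
        selected <<- c(selected, take)
        attribution <<- c(attribution, rep(
          sprintf("overlap=%d|caller=%s", cells[[i]]$level,
                  cells[[i]]$caller), k))
      }
      k
    }
    repeat {
      remaining <- n_targets - length(selected)
      if (remaining == 0L) break
      live <- vapply(seq_along(cells), function(i)
        length(pool_of(i, selected)) > 0L, NA)
      if (!any(live)) break
      n_before <- length(selected)
      for (i in seq_along(cells)) {
        remaining <- n_targets - length(selected)
        if (remaining == 0L) break
        if (length(pool_of(i, selected)) == 0L) next
        unexamined <- sum(vapply(i:length(cells), function(j)
          length(pool_of(j, selected)) > 0L, NA))
        take_from(i, remaining %/% unexamined)
      }
      if (length(selected) == n_before) {
        # stalled traversal: grant one selection per non-empty cell in order
        for (i in seq_along(cells)) {
          if (n_targets - length(selected) == 0L) break
          take_from(i, 1L)
        }
        if (length(selected) == n_before) break
      }
    }
  })
  selection_from_keys(profile, selected, attribution, "directed_sampling",
                      as.integer(seed))
}
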