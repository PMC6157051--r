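# Synthetic multi-caller ensembles with known ground truth. The generator
# abstracts the axes of difficulty of real tumour sequencing (contamination,
# sub-clonality, mutation rate) into the properties the selection and
# evaluation arithmetic is actually sensitive to: per-caller sensitivity,
# per-caller false-positive count, and a shared recurrent-error pool that
# gives false positives overlap levels >= 2. Coordinates of true mutations
# and false positives are kept disjoint by construction so truth labels are
# never ambiguous.

#' Configuration for a simulated caller ensemble
#'
#' @param genome_length number of candidate positions (single synthetic
#'   chromosome).
#' @param n_true number of true mutations.
#' @param sensitivity per-caller probability of detecting each true
#'   mutation, independently across mutations and callers.
#' @param n_fp per-caller count of false-positive calls.
#' @param shared_fp_fraction fraction of each caller's false positives drawn
#'   from a common recurrent-error pool (rounded per caller); the rest are
#'   private and globally distinct, hence overlap level 1.
#' @param fp_pool_size size of the shared recurrent-error pool.
#' @param chrom chromosome label for all simulated variants.
#' @param caller_names optional caller identifiers (default `caller_1`, ...).
#' @param seed integer seed; the whole generation path is a pure function of
#'   it.
#'
#' @details Defaults describe a realistic three-caller somatic-SNV ensemble
#' of roughly 10^4 calls: sensitivities 0.9/0.8/0.7 with false positives
#' around 15% of each caller's output, a quarter of them recurrent.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1e6, n_true = 3500,
                              sensitivity = c(0.9, 0.8, 0.7),
                              n_fp = c(550, 490, 430),
                              shared_fp_fraction = 0.25,
                              fp_pool_size = 400,
                              chrom = "chr1", caller_names = NULL,
                              seed = 1L) {
  if (length(sensitivity) != length(n_fp))
    stop("sensitivity and n_fp must have one entry per caller", call. = FALSE)
  if (any(sensitivity < 0 | sensitivity > 1))
    stop("sensitivities must lie in [0, 1]", call. = FALSE)
  if (any(n_fp < 0)) stop("n_fp must be non-negative", call. = FALSE)
  if (shared_fp_fraction < 0 || shared_fp_fraction > 1)
    stop("shared_fp_fraction must lie in [0, 1]", call. = FALSE)
  if (n_true + fp_pool_size + sum(n_fp) > genome_length)
    stop("genome too short for collision-free construction: need ",
         "n_true + fp_pool_size + sum(n_fp) <= genome_length", call. = FALSE)
  callers <- caller_names %||% paste0("caller_", seq_along(sensitivity))
  structure(list(
    genome_length = as.double(genome_length),
    n_true = as.integer(n_true),
    sensitivity = as.double(sensitivity),
    n_fp = as.integer(n_fp),
    shared_fp_fraction = as.double(shared_fp_fraction),
    fp_pool_size = as.integer(fp_pool_size),
    chrom = as.character(chrom),
    callers = as.character(callers),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate the ground-truth mutation set
#'
#' Samples `n_true` distinct positions uniformly without replacement from
#' the genome, all labelled true.
#'
#' @param config a `simulation_config`.
#' @param seed seed override (default `config$seed`).
#' @return A `truth_table` of the true mutations.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  if (config$n_true > config$genome_length)
    stop("n_true exceeds genome_length", call. = FALSE)
  pos <- withr::with_seed(derive_seed(seed, "truth"),
                          sample.int(config$genome_length, config$n_true))
  truth_table(rep(config$chrom, config$n_true), sort(pos),
              rep(TRUE, config$n_true))
}

#' Simulate the caller ensemble over a known truth set
#'
#' Caller k detects each true mutation independently with probability
#' `sensitivity[k]` and adds `n_fp[k]` false calls: a rounded
#' `shared_fp_fraction` of them drawn from the common recurrent-error pool
#' (so the same wrong position can recur across callers), the remainder at
#' private positions unique to that caller. False-positive positions never
#' collide with true mutations.
#'
#' @param config a `simulation_config`.
#' @param truth the `truth_table` from [simulate_truth()].
#' @param seed seed override (default `config$seed`).
#' @return A `call_profile` over `config$callers`.
#' @export
simulate_callers <- function(config, truth, seed = config$seed) {
  n_shared <- as.integer(round(config$shared_fp_fraction * config$n_fp))
  if (any(n_shared > config$fp_pool_size))
    stop("recurrent-error pool exhausted: a caller draws more shared false ",
         "positives than fp_pool_size", call. = FALSE)
  n_priv <- config$n_fp - n_shared
  need <- config$fp_pool_size + sum(n_priv)
  true_pos <- truth$table$pos
  records <- withr::with_seed(derive_seed(seed, "callers"), {
    # draw need + n_true positions without replacement; after removing true
    # positions, the first `need` remaining are uniform over the complement
    draws <- sample.int(config$genome_length,
                        min(config$genome_length, need + length(true_pos)))
    fp_pos <- setdiff(draws, true_pos)[seq_len(need)]
    pool <- fp_pos[seq_len(config$fp_pool_size)]
    priv_all <- fp_pos[setdiff(seq_len(need), seq_len(config$fp_pool_size))]
    priv_offsets <- cumsum(c(0L, n_priv))
    out <- lapply(seq_along(config$callers), function(k) {
      tp <- true_pos[runif(length(true_pos)) < config$sensitivity[k]]
      shared <- if (n_shared[k] > 0L)
        pool[sample.int(length(pool), n_shared[k])] else integer(0)
      priv <- if (n_priv[k] > 0L)
        priv_all[(priv_offsets[k] + 1L):priv_offsets[k + 1L]] else integer(0)
      pos <- c(tp, shared, priv)
      data.frame(caller = rep(config$callers[k], length(pos)),
                 chrom = rep(config$chrom, length(pos)),
                 pos = pos, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  build_call_profile(records, callers = config$callers)
}

#' Simulate a complete ensemble with fully labelled truth
#'
#' Convenience wrapper: simulates truth and callers from one seed and
#' returns a truth table covering every profile variant (false positives
#' labelled false) as well as every true mutation, including those missed
#' by all callers.
#'
#' @param config a `simulation_config`.
#' @param seed seed override (default `config$seed`).
#' @return List with `profile` (a `call_profile`), `truth` (a complete
#'   `truth_table`) and `config`.
#' @export
simulate_ensemble <- function(config, seed = config$seed) {
  tt <- simulate_truth(config, seed)
  profile <- simulate_callers(config, tt, seed)
  list(profile = profile, truth = complete_truth(tt, profile),
       config = config)
}

#' Simulate a size-skewed ensemble
#'
#' One dominant caller holding the vast majority of all calls, plus several
#' minor callers with tiny call sets — the regime in which uniform
#' random-rows selection can leave a minor caller with no selected calls and
#' hence undefined (N/A) scores. Defaults give a dominant call set about
#' 1000 times the minor ones (~10^4 vs ~10 calls).
#'
#' @param seed integer seed.
#' @param n_true number of true mutations.
#' @param dominant_sensitivity,dominant_fp sensitivity and false-positive
#'   count of the dominant caller.
#' @param n_minor number of minor callers.
#' @param minor_sensitivity,minor_fp sensitivity and false-positive count of
#'   each minor caller.
#' @param genome_length candidate positions.
#' @return As [simulate_ensemble()].
#' @export
skewed_ensemble <- function(seed = 1L, n_true = 100L,
                            dominant_sensitivity = 1.0, dominant_fp = 9900L,
                            n_minor = 3L, minor_sensitivity = 0.05,
                            minor_fp = 5L, genome_length = 1e6) {
  config <- simulation_config(
    genome_length = genome_length,
    n_true = n_true,
    sensitivity = c(dominant_sensitivity, rep(minor_sensitivity, n_minor)),
    n_fp = c(dominant_fp, rep(minor_fp, n_minor)),
    shared_fp_fraction = 0,
    fp_pool_size = 0L,
    caller_names = c("dominant", paste0("minor_", seq_len(n_minor))),
    seed = as.integer(seed)
  )
  simulate_ensemble(config)
}
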