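# Brute-force oracles and small-profile enumeration shared across tests.
# The oracles are deliberately naive (plain loops, direct definitions) and
# independent of the package's vectorized implementations.

# Profile from a list caller -> integer positions (chromosome "c").
make_profile <- function(calls, callers = names(calls)) {
  records <- do.call(rbind, lapply(names(calls), function(cl)
    if (length(calls[[cl]]))
      data.frame(caller = cl, chrom = "c", pos = calls[[cl]],
                 stringsAsFactors = FALSE)))
  build_call_profile(records, callers = callers)
}

# Random profile: each variant gets a uniformly random non-empty caller
# subset.
random_profile <- function(n_callers, n_variants, seed) {
  callers <- LETTERS[seq_len(n_callers)]
  withr::with_seed(seed, {
    masks <- sample.int(2^n_callers - 1L, n_variants, replace = TRUE)
  })
  profile_from_masks(masks, n_callers)
}

profile_from_masks <- function(masks, n_callers) {
  callers <- LETTERS[seq_len(n_callers)]
  rec <- do.call(rbind, lapply(seq_along(masks), function(v) {
    members <- callers[bitwAnd(masks[v], 2^(seq_len(n_callers) - 1L)) > 0L]
    data.frame(caller = members, chrom = "c", pos = v,
               stringsAsFactors = FALSE)
  }))
  build_call_profile(rec, callers = callers)
}

# All profiles with n_callers callers and n_variants variants, as multisets
# of non-empty caller subsets, deduplicated up to caller relabeling (strategy
# behaviour is equivariant under caller permutation). Returns a list of mask
# tuples.
enumerate_mask_tuples <- function(n_callers, n_variants) {
  s <- 2L^n_callers - 1L
  cmb <- utils::combn(s + n_variants - 1L, n_variants)
  if (is.null(dim(cmb))) cmb <- matrix(cmb, nrow = n_variants)
  tuples <- cmb - (seq_len(n_variants) - 1L)
  perms <- perms_of(n_callers)
  mask_maps <- lapply(perms, function(pr)
    vapply(seq_len(s), function(mask) {
      bits <- which(bitwAnd(mask, 2L^(seq_len(n_callers) - 1L)) > 0L)
      sum(2L^(pr[bits] - 1L))
    }, 0))
  keys <- apply(tuples, 2, function(tp)
    min(vapply(mask_maps, function(mp)
      paste(sort(mp[tp]), collapse = ","), "")))
  lapply(which(!duplicated(keys)), function(i) tuples[, i])
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  if (n == 2L) return(list(1:2, 2:1))
  out <- list()
  for (a in 1:3) for (b in setdiff(1:3, a))
    out[[length(out) + 1L]] <- c(a, b, setdiff(1:3, c(a, b)))
  out
}

# Direct-definition confusion classifier: one selected variant at a time.
oracle_confusion <- function(profile, sel_keys, labels, caller) {
  tp <- fp <- fn <- 0L
  calls <- profile$calls_by_caller[[caller]]
  for (k in sel_keys) {
    made <- k %in% calls
    tr <- labels[[k]]
    if (made && tr) tp <- tp + 1L
    else if (made && !tr) fp <- fp + 1L
    else if (!made && tr) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, FN = fn)
}

# Group-by-group weighted-precision oracle.
oracle_weighted_precision <- function(profile, sel_keys, labels, caller) {
  calls <- profile$calls_by_caller[[caller]]
  sel <- sel_keys[sel_keys %in% calls]
  if (length(sel) == 0L) return(NA_real_)
  num <- den <- 0
  for (g in sort(unique(profile$level[sel]))) {
    in_g <- sel[profile$level[sel] == g]
    p_g <- sum(labels[in_g]) / length(in_g)
    w_g <- sum(profile$level[calls] == g)
    num <- num + w_g * p_g
    den <- den + w_g
  }
  num / den
}

# Validity check for a largest-remainder apportionment: quotas sum to the
# total, each is floor(share) or floor(share)+1, and every unit granted the
# +1 has a fractional remainder >= every unit denied it.
expect_largest_remainder <- function(quotas, weights, total) {
  shares <- total * weights / sum(weights)
  base <- floor(shares + 1e-9)
  frac <- shares - base
  expect_equal(sum(quotas), total)
  expect_true(all(quotas == base | quotas == base + 1))
  got <- quotas == base + 1
  if (any(got) && any(!got))
    expect_gte(min(frac[got]), max(frac[!got]) - 1e-9)
}

# Truth table over a profile's variants from a logical vector in variant
# order.
truth_for <- function(profile, labels) {
  truth_table(profile$variants$chrom, profile$variants$pos, labels)
}
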