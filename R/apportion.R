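#' Largest-remainder apportionment of an integer budget
#'
#' Splits an integer total over weighted units so that every quota is within
#' one of its exact proportional share and the quotas sum exactly to the
#' total. Fractional shares are integerized by the largest-remainder rule;
#' ties in the remainders are broken by a random shuffle so no unit is
#' systematically favoured. All quota-based selection strategies route their
#' budget division through this function.
#'
#' @param weights named non-negative numeric vector; at least one weight must
#'   be positive.
#' @param total non-negative integer to distribute.
#' @param seed optional integer seed; `NULL` (the default) draws the
#'   tie-break shuffle from the current RNG state, which is what the strategy
#'   functions do inside their own seeded context.
#' @return An object of class `allocation_plan`: list with `quotas` (named
#'   integer vector summing to `total`) and `remainder_order` (the units that
#'   received a +1 from the integer remainder, in order).
#' @examples
#' apportion(c(a = 1, b = 2, c = 3), 12, seed = 1)$quotas
#' @export
apportion <- function(weights, total, seed = NULL) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("`weights` must be a named vector", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(weights == 0)) stop("all-zero weights", call. = FALSE)
  total <- assert_count(total, "total", min = 0L)
  run <- function() {
    shares <- total * weights / sum(weights)
    base <- floor(shares + 1e-9)
    frac <- shares - base
    rem <- total - as.integer(round(sum(base)))
    tie <- sample.int(length(weights))
    ord <- order(-frac, tie)
    quotas <- as.integer(base)
    extra <- if (rem > 0L) ord[seq_len(rem)] else integer(0)
    quotas[extra] <- quotas[extra] + 1L
    structure(list(quotas = setNames(quotas, names(weights)),
                   remainder_order = names(weights)[extra]),
              class = "allocation_plan")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
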