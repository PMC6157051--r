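# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical variant key: "<chromosome>:<position>". Chromosomes are opaque
# strings; positions are 1-based integers.
vkey <- function(chrom, pos) {
  if (length(chrom) == 0L) return(character(0))  # paste0 would recycle to ":"
  paste0(chrom, ":", pos)
}

# sample() interprets a length-1 numeric vector as 1:n; always index instead.
sample_keys <- function(x, k) x[sample.int(length(x), k)]

#' Derive a reproducible child seed from a master seed
#'
#' Combines a master seed with an arbitrary sequence of integer or character
#' coordinates (replicate index, strategy name, budget, ...) into a new seed
#' in `[0, 2^31 - 2]` via a multiplicative hash. Every stochastic step of a
#' sweep draws its own seed this way, so any single experiment can be re-run
#' in isolation from the master seed and its factor coordinates alone.
#'
#' @param master integer master seed.
#' @param ... integer or character coordinates identifying the consumer.
#' @return A single integer seed.
#' @examples
#' derive_seed(42, "random_rows", 100, 3)
#' @export
derive_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.double(as.integer(master) %% 2147483647L)
  for (p in parts) {
    xs <- if (is.character(p)) utf8ToInt(paste(p, collapse = "/")) else as.double(p)
    for (x in xs) h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
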