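# RNG hygiene: every seeded entry point runs in a local RNG state so that
# callers' streams are never disturbed and identical seeds reproduce outputs
# bit for bit.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a master seed and a string key
#'
#' Per-image and per-stage random streams are derived from one master seed by
#' a fixed integer hash of `(master, key)`, so any single image or stage of a
#' run can be reproduced in isolation. The result is a non-negative integer
#' below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param key character key naming the stream (e.g. an image id).
#' @return integer child seed.
#' @examples
#' derive_seed(42, "img-007")
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master), length(key) == 1)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(as.character(key)))
    h <- (h * 69069 + b) %% m # 69069 * m < 2^53: exact in doubles
  as.integer(h)
}

# largest-remainder apportionment of n into parts proportional to fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# clip numeric array into [0, 1]
.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
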