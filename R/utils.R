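#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation. Streams for different (label, ids)
# combinations must not collide, and every derived seed must stay a valid
# 32-bit integer for set.seed().
#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with an arbitrary sequence of integer or character
#' identifiers (subject, channel, replicate, stage label, ...) so that
#' independent simulation streams can be regenerated in isolation.
#'
#' @param master integer master seed.
#' @param ... integers or strings identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
child_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (k in list(...)) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    for (ki in as.numeric(k)) {
      # 69069 * (2^31) < 2^53 so the product is exact in double precision
      s <- (s * 69069 + (ki %% m) + 1) %% m
    }
  }
  as.integer(s)
}

# Evaluate expr under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

# Central-difference numeric derivatives with per-parameter steps; f may be
# scalar- or vector-valued for the jacobian.
num_gradient <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h[i])
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

num_jacobian <- function(f, x, h) {
  cols <- lapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h[i])
    (f(x + e) - f(x - e)) / (2 * h[i])
  })
  do.call(cbind, cols)
}

num_hessian <- function(f, x, h) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}
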