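#' Logit transform for connectivity values
#'
#' Linearizes values bounded in (0, 1), such as coherence, before they enter
#' a linear regression. Values touching the bounds (possible for degenerate
#' estimates on synthetic inputs) are clipped to `[eps, 1 - eps]` with a
#' warning rather than mapped to +/-Inf.
#'
#' @param c Numeric vector in `[0, 1]`.
#' @param eps Clipping margin, default `1e-6`.
#' @return `log(c / (1 - c))`.
#' @examples
#' logit(0.5)           # 0
#' logit(0.7310586)     # ~1
#' @export
logit <- function(c, eps = 1e-6) {
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1)) {
    stop("logit() requires finite values in [0, 1]")
  }
  if (any(c < eps) || any(c > 1 - eps)) {
    warning("values at the (0,1) boundary clipped to [", eps, ", ", 1 - eps,
            "] before logit")
    c <- pmin(pmax(c, eps), 1 - eps)
  }
  log(c / (1 - c))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + k * 40503) %% 2147483647L)
}

# Polynomial rolling hash of a serialized R object (mod 2^31 - 1); used to
# stamp pipeline reports for determinism checks, not cryptography.
object_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Centered moving average used for display smoothing only (edges keep the
# shorter one-sided window).
moving_average <- function(x, width = 3) {
  stopifnot(width >= 1, width %% 2 == 1)
  half <- (width - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
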