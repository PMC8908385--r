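## Internal helpers: deterministic hashing, seeded scoping, Dirichlet draws.

#' 32-bit FNV-1a hash of a character string
#'
#' Used to key per-cell random decisions (seed, individual, locus) so that
#' recoding is reproducible and independent of processing order. Returns a
#' double in [0, 2^31) suitable for `set.seed()`.
#' @noRd
.fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), bitwAnd(b, 255L))
    # h * 16777619 mod 2^32, split to stay within double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483647
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Symmetric-capable Dirichlet draw via gamma variates
#' @noRd
.rdirichlet <- function(alpha) {
  stopifnot(all(is.finite(alpha)), all(alpha > 0))
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) { # extreme underflow for tiny alphas: fall back to argmax
    g <- as.numeric(seq_along(alpha) == which.max(alpha))
  }
  g / sum(g)
}

#' Balding-Nichols style child frequency vector
#'
#' Child ~ Dirichlet(parent * (1 - f) / f); f = 0 copies the parent exactly.
#' @noRd
.bnChild <- function(parent, f) {
  if (f < 0 || f >= 1) stop("differentiation parameter must lie in [0, 1)")
  if (f == 0) return(parent)
  alpha <- parent * (1 - f) / f
  # alleles absent from the parent stay absent
  out <- numeric(length(parent))
  pos <- alpha > 0
  if (!any(pos)) stop("degenerate parent frequency vector")
  out[pos] <- .rdirichlet(alpha[pos])
  out
}

#' @noRd
.assertProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}
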