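# internal geometry and misc helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

# angle i-j-k in radians
bead_angle <- function(pi_, pj, pk) {
  u <- pi_ - pj
  v <- pk - pj
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, ct)))
}

# signed dihedral i-j-k-l in radians, atan2 convention
bead_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# full-precision number formatting: %.17g round-trips IEEE doubles exactly
fmt_num <- function(x) sprintf("%.17g", x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# deterministic small-integer seed stream derived from a master seed;
# kept below 2^31 - 1 so it is always a valid R integer seed
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.double(idx[k]) * 2246822519 + 104729) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
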