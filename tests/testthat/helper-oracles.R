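# Independent oracles and shared fixtures for the test suite.

# Brute-force AUC: exhaustive pair counting, ties count one half.
auc_brute <- function(controls, cases, orientation = "lower") {
  s <- if (orientation == "lower") -1 else 1
  x <- s * controls; y <- s * cases
  mean(outer(y, x, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (doubling rule as in the exact null distribution).
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Coarse, fast scan settings used where sub-millimetre detail is irrelevant.
coarse_scan <- function(seed = 1L, noise_sd = 0, hu_offset = 0, ...) {
  generate_scan(seed = seed, noise_sd = noise_sd, hu_offset = hu_offset,
                spacing = c(4, 4, 5), ...)
}

# Memoized default-condition noise-free scan shared across tests.
.fixture_env <- new.env(parent = emptyenv())
default_clean_scan <- function() {
  if (is.null(.fixture_env$clean))
    .fixture_env$clean <- generate_scan(noise_sd = 0, seed = 1L)
  .fixture_env$clean
}

# A small hand-built axial slice: body disk, cutis rim, muscle wall ring
# with configurable gap, fat inside and outside the wall. Returns HU matrix.
toy_fat_slice <- function(n = 61, wall_gap = FALSE) {
  hu <- matrix(-1000, n, n)
  cx <- (n + 1) / 2
  d <- sqrt(outer(seq_len(n) - cx, seq_len(n) - cx, function(a, b) a^2 + b^2))
  hu[d <= 28] <- 20          # cutis
  hu[d <= 26] <- -100        # subcutaneous fat
  hu[d <= 18] <- 50          # muscle wall
  hu[d <= 14] <- -100        # visceral fat
  hu[d <= 5] <- 240          # contrast-filled bowel
  if (wall_gap) hu[round(cx), d[round(cx), ] > 14 & d[round(cx), ] <= 18 &
                     seq_len(n) > cx] <- -100
  hu
}
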