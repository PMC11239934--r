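# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
# RNG kinds are pinned so results are reproducible across sessions.
.withSeed <- function(seed, expr) {
  withr::with_seed(seed, expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Round-half-up integer boundaries; base round() is round-half-even.
.roundHalfUp <- function(x) floor(x + 0.5)

# Grid-partition boundaries: 0, round(i*n/k), ..., n.  Strictly increasing
# whenever n >= k.
.gridBreaks <- function(n, k) {
  if (k < 1L) stop("grid dimension must be >= 1")
  if (n < k) stop("grid (", k, ") larger than image extent (", n, ")")
  .roundHalfUp((0:k) * n / k)
}

# Radial coordinate in um, increasing toward the pial surface.
.radialUm <- function(row, annotation, pixelSizeUm) {
  if (annotation@radialUp) (annotation@pialRow - row) * pixelSizeUm
  else (row - annotation@pialRow) * pixelSizeUm
}

# Stage labelling for composed pipelines: rethrow with the stage name.
.stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      warning("[", name, "] ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

# Pixels of a filled disk of radius r around (row0, col0), clipped to the
# image; returns a 2-column index matrix.
.diskPixels <- function(row0, col0, r, dims) {
  rr <- max(1L, floor(row0 - r)):min(dims[1], ceiling(row0 + r))
  cc <- max(1L, floor(col0 - r)):min(dims[2], ceiling(col0 + r))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - row0)^2 + (g$col - col0)^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}
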