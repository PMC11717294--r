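# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`; restores the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(deg) deg * pi / 180

# 2D rotation of point rows (n x 2) by angle theta (radians, y-down image
# convention: positive theta rotates +x toward +y, i.e. clockwise on screen).
rotate_xy <- function(xy, theta, center = c(0, 0)) {
  ct <- cos(theta); st <- sin(theta)
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  cbind(center[1] + ct * dx - st * dy, center[2] + st * dx + ct * dy)
}

# Tiny polynomial rolling hash of a character vector -> 8 hex digits; used
# for config hashes in manifests (stable across sessions, no external
# digest package; not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
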