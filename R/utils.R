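# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic per-subunit seed derived from a base seed (kept < 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483587)
}

# Normal draws truncated below at `floor` (resampling; floor must leave
# non-negligible mass).
rnorm_floor <- function(n, mean, sd, floor = 0) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(max(mean, floor), n))
  x <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x <= floor
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x[x <= floor] <- floor + sd * 1e-3
  x
}

# Ellipse geometry -----------------------------------------------------------
# Ellipses are (x, y, a, b, theta): centre in micrometres, semi-major a,
# semi-minor b, orientation theta = angle of the major axis (radians).

ellipse_boundary <- function(e, n = 48L, scale = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- e[["a"]] * scale * cos(t)
  v <- e[["b"]] * scale * sin(t)
  ct <- cos(e[["theta"]]); st <- sin(e[["theta"]])
  cbind(x = e[["x"]] + u * ct - v * st,
        y = e[["y"]] + u * st + v * ct)
}

# Squared elliptical radius of points (x, y) w.r.t. ellipse e (<= 1 inside).
ellipse_radius2 <- function(e, x, y) {
  dx <- x - e[["x"]]; dy <- y - e[["y"]]
  ct <- cos(e[["theta"]]); st <- sin(e[["theta"]])
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / e[["a"]])^2 + (v / e[["b"]])^2
}

points_in_ellipse <- function(e, x, y) ellipse_radius2(e, x, y) <= 1

# Conservative overlap test between two ellipses: bounding-circle reject,
# then mutual boundary-point and centre containment at a small safety pad.
ellipses_overlap <- function(e1, e2, pad = 1.03, n = 48L) {
  d2 <- (e1[["x"]] - e2[["x"]])^2 + (e1[["y"]] - e2[["y"]])^2
  lim <- (e1[["a"]] + e2[["a"]]) * pad
  if (d2 > lim^2) return(FALSE)
  if (points_in_ellipse(e2, e1[["x"]], e1[["y"]])) return(TRUE)
  if (points_in_ellipse(e1, e2[["x"]], e2[["y"]])) return(TRUE)
  b1 <- ellipse_boundary(e1, n, scale = pad)
  if (any(points_in_ellipse(e2, b1[, 1], b1[, 2]))) return(TRUE)
  b2 <- ellipse_boundary(e2, n, scale = pad)
  any(points_in_ellipse(e1, b2[, 1], b2[, 2]))
}

# TRUE if ellipse `inner` lies entirely within `outer` (boundary sampling).
ellipse_contained <- function(inner, outer, n = 32L) {
  b <- ellipse_boundary(inner, n)
  all(points_in_ellipse(outer, b[, 1], b[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
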