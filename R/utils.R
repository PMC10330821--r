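## Internal numerical and geometric helpers.

## Derive a 32-bit substream seed from a master seed and an index, so that
## per-granule / per-trace streams are stable under partial regeneration.
deriveSeed <- function(master, index = 0L) {
  s <- (as.double(master) * 1000003 + 7919 * as.double(index)) %% 2147483629
  as.integer(s) + 1L
}

## Evaluate `expr` with a local RNG seeded at `seed`, restoring the caller's
## RNG state afterwards (no hidden entropy leaks between generators).
withSeed <- function(seed, expr) {
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

## Truncated-normal sampler by inverse-CDF (deterministic given the RNG
## stream; exact for the moments tested against at large n).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Shoelace area of a closed polygon given as an n x 2 vertex matrix.
polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## Even-odd point-in-polygon test, vectorized over points (n x 2 matrix).
pointInPolygon <- function(pts, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  nv <- length(px)
  jx <- c(px[-1], px[1]); jy <- c(py[-1], py[1])
  inside <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  for (k in seq_len(nv)) {
    crosses <- ((py[k] > y) != (jy[k] > y)) &
      (x < (jx[k] - px[k]) * (y - py[k]) / (jy[k] - py[k]) + px[k])
    inside <- xor(inside, crosses)
  }
  inside
}

## Minimum distance from each point (n x 2) to a closed polyline (m x 2).
pointPolylineDistance <- function(pts, poly) {
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  n <- nrow(pts)
  out <- rep(Inf, n)
  for (k in seq_along(ax)) {
    t <- ((pts[, 1] - ax[k]) * dx[k] + (pts[, 2] - ay[k]) * dy[k]) / len2[k]
    t <- pmin(1, pmax(0, t))
    qx <- ax[k] + t * dx[k]; qy <- ay[k] + t * dy[k]
    d <- sqrt((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2)
    out <- pmin(out, d)
  }
  out
}

## Regular polygon approximating a circle (counter-clockwise, nSides vertices).
circlePolygon <- function(cx, cy, r, nSides = 64L) {
  th <- seq(0, 2 * pi, length.out = nSides + 1L)[-(nSides + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

## Physical constants (SI)
.GAS_R <- 8.314462618      # J mol-1 K-1
.FARADAY <- 96485.33212    # C mol-1
.AVOGADRO <- 6.02214076e23 # mol-1
.ECHARGE <- 1.602176634e-19 # C
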