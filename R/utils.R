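# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; all stochastic generators in the package route through this so
# they are pure functions of their arguments.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Cumulative trapezoidal integral of y(t) sampled at strictly increasing t.
cumtrapz <- function(t, y) {
  stopifnot(length(t) == length(y), all(diff(t) > 0))
  c(0, cumsum(diff(t) * (y[-length(y)] + y[-1]) / 2))
}

# Coordinates (mm) of pixel centers for an n_rows x n_cols grid.
# Convention: origin at the image corner, center of pixel (i, j) at
# x = (j - 0.5) * pixel_size, y = (i - 0.5) * pixel_size.
pixel_centers <- function(n_rows, n_cols, pixel_size) {
  x <- (seq_len(n_cols) - 0.5) * pixel_size
  y <- (seq_len(n_rows) - 0.5) * pixel_size
  list(
    x = matrix(x, n_rows, n_cols, byrow = TRUE),
    y = matrix(y, n_rows, n_cols)
  )
}

# Even-odd rule point-in-polygon test. `px`, `py` are vectors; `poly` is a
# two-column matrix of vertices (closed implicitly).
point_in_polygon <- function(px, py, poly) {
  nx <- poly[, 1]
  ny <- poly[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ny[i] > py) != (ny[j] > py)) &
      (px < (nx[j] - nx[i]) * (py - ny[i]) / (ny[j] - ny[i]) + nx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum Euclidean distance from each point to a polygon boundary
# (segments, not just vertices).
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      dx <- px - ax; dy <- py - ay
    } else {
      tt <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
      dx <- px - (ax + tt * vx)
      dy <- py - (ay + tt * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# Bilinear translation of a 2D image by (dx, dy) pixels (positive dx moves
# content toward larger column indices). Out-of-support samples are filled
# with `fill`.
shift_image <- function(img, dx, dy, fill = 0) {
  if (dx == 0 && dy == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  # Sample source coordinates for each target pixel.
  src_r <- matrix(seq_len(nr), nr, nc) - dy
  src_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  get_px <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- matrix(fill, nr, nc)
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  (1 - fr) * (1 - fc) * get_px(r0, c0) +
    (1 - fr) * fc * get_px(r0, c0 + 1) +
    fr * (1 - fc) * get_px(r0 + 1, c0) +
    fr * fc * get_px(r0 + 1, c0 + 1)
}
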