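# Internal numeric helpers shared across modules.

# Centered 1-D gaussian smoothing with reflect padding. sigma in samples;
# sigma = 0 returns x unchanged.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(n, (half + 1):2)], x, x[pmax(1L, (n - 1):(n - half))])
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + n)]
}

# Seeded evaluation that does not disturb the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Even-odd (ray casting) polygon rasterization: pixels whose CENTERS fall
# inside the polygon are set. `poly` is an n x 2 matrix of (x, y) vertices in
# pixel coordinates; `dim` is c(nrow, ncol) of the target matrix. x maps to
# columns, y to rows; pixel (r, c) has center (c - 0.5, r - 0.5).
polygon_mask <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  n <- nrow(poly)
  inside <- logical(nr * nc)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > cy) != (yj > cy)) &
      (cx < (xj - xi) * (cy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = nr, ncol = nc)
}

# Disk mask centered at (x0, y0) px with radius r px (pixel-center rule).
disk_mask <- function(dim, x0, y0, r) {
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  matrix((cx - x0)^2 + (cy - y0)^2 <= r^2, nrow = nr, ncol = nc)
}

# Annulus mask between radii r_in and r_out.
annulus_mask <- function(dim, x0, y0, r_in, r_out) {
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  d2 <- (cx - x0)^2 + (cy - y0)^2
  matrix(d2 >= r_in^2 & d2 <= r_out^2, nrow = nr, ncol = nc)
}

# Thick line segment mask: pixels within `width/2` of the segment p1-p2.
segment_mask <- function(dim, x1, y1, x2, y2, width) {
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((cx - x1) * dx + (cy - y1) * dy) / len2))
  d2 <- (cx - (x1 + t * dx))^2 + (cy - (y1 + t * dy))^2
  matrix(d2 <= (width / 2)^2, nrow = nr, ncol = nc)
}

# Orientation (degrees, in [0, 180)) and aspect ratio of a pixel blob from
# its second central moments. coords: matrix with columns x, y.
blob_shape <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2) + 1 / 12 # pixel extent correction
  cyy <- mean((y - my)^2) + 1 / 12
  cxy <- mean((x - mx) * (y - my))
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  list(orientation_deg = (theta + 180) %% 180, aspect = sqrt(l1 / l2))
}

# Smallest absolute difference between two orientations mod 180 degrees.
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Quantize intensities to a 16-bit grid in [0, 1] so that TIFF serialization
# round-trips exactly.
quantize16 <- function(x) {
  round(pmin(pmax(x, 0), 1) * 65535) / 65535
}
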