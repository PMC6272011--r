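# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so stochastic package
#' functions are deterministic per-call without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# wrap angles (degrees) into (-180, 180]
wrap_angle <- function(x) {
  y <- x - 360 * ceiling((x - 180) / 360)
  y[y <= -180] <- y[y <= -180] + 360  # guard fp edge
  y
}

# shortest periodic difference a-b in degrees, in [-180, 180)
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d >= 180] <- d[d >= 180] - 360
  d
}

## quaternion utilities (w, x, y, z), scalar-first

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) {
  n <- vnorm(q)
  if (n < 1e-12) stop("cannot normalize a zero quaternion")
  q / n
}

quat_from_axis_angle <- function(axis, angle_deg) {
  n <- vnorm(axis)
  if (n < 1e-12) return(quat_identity())
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

quat_multiply <- function(a, b) {
  c(a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L])
}

quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3L, byrow = TRUE)
}

# rotation angle (deg) encoded by a unit quaternion
quat_angle <- function(q) {
  w <- min(1, max(-1, abs(q[1L] / vnorm(q))))
  2 * acos(w) * 180 / pi
}

# uniform random unit quaternion (Shoemake subgroup algorithm)
quat_random <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1L]) * sin(2 * pi * u[2L]),
    sqrt(1 - u[1L]) * cos(2 * pi * u[2L]),
    sqrt(u[1L]) * sin(2 * pi * u[3L]),
    sqrt(u[1L]) * cos(2 * pi * u[3L]))
}

# rotate points (n x 3) about an axis through `origin` with direction `axis`
rotate_about_axis <- function(pts, origin, axis, angle_deg) {
  R <- quat_to_matrix(quat_from_axis_angle(axis, angle_deg))
  shifted <- sweep(pts, 2L, origin)
  sweep(shifted %*% t(R), 2L, origin, `+`)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
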