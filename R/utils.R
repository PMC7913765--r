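# internal helpers shared across modules

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; all synthetic generators route through this so they are pure
# functions of (parameters, seed).
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# rotation by `angle` degrees about unit `axis` (Rodrigues)
rotationAboutAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# apply x' = R (x - centre) + centre + shift to an n x 3 matrix
applyRigid <- function(xyz, R, centre = c(0, 0, 0), shift = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, centre) %*% t(R), 2, centre + shift, `+`)
}

# circular mean of angles in degrees, result in (-180, 180]
circularMeanDeg <- function(deg) {
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (m <= -180) m <- m + 360
  m
}

# deterministic full-precision number formatting for report files
fmtNum <- function(x) formatC(x, digits = 15, format = "g")

.assertScalarPositive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(what, " must be a single positive number")
  invisible(x)
}
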