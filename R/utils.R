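# Internal helpers shared across modules.

# classed condition so callers can distinguish validation/geometry failures
so_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sterolorder_error")))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# map angles in degrees onto [0, 360)
wrap360 <- function(phi) {
  phi <- phi %% 360
  phi[phi == 360] <- 0
  phi
}

# minimum-image displacement along one periodic axis
min_image_1d <- function(d, L) d - L * round(d / L)

# minimum-image displacement of a 3-column matrix; z wrapped only if Lz given
min_image_disp <- function(d, box) {
  d[, 1] <- min_image_1d(d[, 1], box[[1]])
  d[, 2] <- min_image_1d(d[, 2], box[[2]])
  if (length(box) >= 3 && is.finite(box[[3]]) && box[[3]] > 0) {
    d[, 3] <- min_image_1d(d[, 3], box[[3]])
  }
  d
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p))) {
    so_stop(sprintf("'%s' must be a finite numeric 3-vector", what),
            "sterolorder_input_error")
  }
  p
}

# unit vector with degeneracy check
unit3 <- function(v, eps = 1e-12, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < eps) {
    so_stop(sprintf("degenerate geometry: %s has (near-)zero length", what),
            "sterolorder_degenerate_geometry")
  }
  v / n
}

# run an expression with a temporarily seeded RNG, restoring prior state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# von Mises sampler (Best & Fisher rejection scheme); mu in degrees
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- wrap360(mu + rad2deg(theta))
      i <- i + 1L
    }
  }
  out
}

circular_mean_deg <- function(x) {
  wrap360(rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x))))))
}
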