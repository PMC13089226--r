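# Independent oracles used across the suite.

# Rodrigues rotation of point v about unit axis u by angle phi (radians)
rotate_about <- function(v, u, phi) {
  u <- u / sqrt(sum(u * u))
  v * cos(phi) + pracma_cross(u, v) * sin(phi) + u * sum(u * v) * (1 - cos(phi))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Corner-rotation oracle for the rib-plane projection. The rectangle
# A(0,0,0)-B(0,RPW,0)-C-D(0,0,-RPH) hangs from the costovertebral
# articulation A; axes: x anteroposterior, y mediolateral, z dorsoventral.
# Step 1 rotates about the mediolateral edge AB (pump-handle), step 2 about
# the current edge AD (bucket-handle, distal end swinging posteriorly),
# step 3 tilts the drop vector about the mediolateral axis. Heights are the
# vertical drop from A to the distal corner C; widths the mediolateral
# extent of the projected corners.
oracle_rib_projection <- function(RPH, RPW, theta1, theta2, theta3) {
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180; t3 <- theta3 * pi / 180
  B <- c(0, RPW, 0); D <- c(0, 0, -RPH)
  ey <- c(0, 1, 0)
  B1 <- rotate_about(B, ey, -t1)
  D1 <- rotate_about(D, ey, -t1)
  C1 <- B1 + D1
  P1 <- list(h = -D1[3], w = max(B1[2], C1[2], D1[2], 0) - min(B1[2], C1[2], D1[2], 0))
  u2 <- D1 # axis A -> D after step 1
  B2 <- rotate_about(B1, u2, t2)
  C2 <- B2 + D1
  P2 <- list(h = -C2[3], w = max(B2[2], C2[2], D1[2], 0) - min(B2[2], C2[2], D1[2], 0))
  # step 3 tilts the vertical drop vector about the mediolateral axis
  drop3 <- rotate_about(c(0, 0, C2[3]), ey, t3)
  list(RPH_P1 = P1$h, RPW_P1 = P1$w, RPH_P2 = P2$h, RPW_P2 = P2$w,
       RPH_P3 = -drop3[3], RPW_P3 = P2$w)
}

# fan-triangulation polygon area (independent of the shoelace route)
triangulation_area <- function(cc) {
  x <- cc$x; y <- cc$y
  n <- length(x)
  a <- 0
  for (i in 2:(n - 1)) {
    a <- a + ((x[i] - x[1]) * (y[i + 1] - y[1]) -
                (x[i + 1] - x[1]) * (y[i] - y[1])) / 2
  }
  abs(a)
}

# analytic area of a paired half-superellipse cross-section
analytic_section_area <- function(width, dh, vh, nd, nv) {
  half <- function(b, n) 2 * (width / 2) * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
  half(dh, nd) + half(vh, nv)
}

# closed-form leave-one-out |%PE| by explicit normal-equation refits
brute_force_loo <- function(x, y) {
  n <- length(x)
  pe <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i]; yt <- y[-i]
    sxx <- sum((xt - mean(xt))^2)
    slope <- sum((xt - mean(xt)) * (yt - mean(yt))) / sxx
    intercept <- mean(yt) - slope * mean(xt)
    pred <- 10^(intercept + slope * x[i])
    obs <- 10^y[i]
    pe[i] <- abs((obs - pred) / pred) * 100
  }
  list(per_sample = pe, mean = mean(pe), sd = stats::sd(pe))
}

# a regular n-gon contour approximating a circle, ventral point at y = 0
circle_contour <- function(r, n = 512L, x0 = 0, y0 = r) {
  th <- seq(-pi / 2, 3 * pi / 2, length.out = n + 1L)[-(n + 1L)]
  plesiomass::contour(x0 + r * cos(th), y0 + r * sin(th))
}
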