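# Independent oracles and small fixture builders used across test files.

# Build an sc_profile directly from (depth %, drug) points.
make_profile <- function(x, y, participant = "P01", product = "X",
                         L = 10, total_depth_percent = max(x)) {
  structure(
    list(participant_id = participant, product_id = product, site = product,
         points = data.frame(strip_index = seq_along(x),
                             relative_depth_percent = x, drug_amount = y,
                             beyond_sc = x > 100),
         L_um = L, total_depth_um = total_depth_percent / 100 * L,
         total_depth_percent = total_depth_percent,
         dropped_first_n = 0, position = "midpoint"),
    class = "sc_profile")
}

# Trapezoid oracle: exact integral of the linear interpolant, evaluated
# on a fine grid that contains every knot (trapezoid is exact there).
trapz_oracle <- function(x, y) {
  grid <- sort(unique(c(x, seq(min(x), max(x), length.out = 5001))))
  f <- stats::approxfun(x, y)
  yy <- f(grid)
  sum(diff(grid) * (head(yy, -1) + tail(yy, -1)) / 2)
}

# OLS oracle via lm (the implementation uses closed-form sums).
ols_oracle <- function(x, y) {
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, slope_se = s$coefficients[2, 2])
}

# Explicit finite-difference solution of dC/dt = (D/L^2) d2C/dX^2 on
# X in [0,1], C(0,t) = 1, C(1,t) = 0, C(X,0) = 0; returns C(X, t_end)
# per unit surface concentration.
fd_diffusion_oracle <- function(X_eval, t_end, diffusivity_ratio,
                                nx = 201) {
  dx <- 1 / (nx - 1)
  dt <- 0.4 * dx^2 / diffusivity_ratio
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  r <- diffusivity_ratio * dt / dx^2
  C <- numeric(nx)
  C[1] <- 1
  for (i in seq_len(nt)) {
    C[2:(nx - 1)] <- C[2:(nx - 1)] +
      r * (C[3:nx] - 2 * C[2:(nx - 1)] + C[1:(nx - 2)])
    C[1] <- 1; C[nx] <- 0
  }
  stats::approx(seq(0, 1, length.out = nx), C, xout = X_eval)$y
}

# Default product strengths (% w/w) used in synthetic studies.
mtz_scales <- c(Reference = 0.75, T1 = 0.75, T2 = 0.56, T3 = 0.95)
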