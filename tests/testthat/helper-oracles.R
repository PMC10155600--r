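# Independent oracles kept deliberately naive: exhaustive grids, closed-form
# normal equations, and 1-D scans. They never call the package's fitters.

# Exhaustive (nu, R2fast) grid search for the DQF-MA model with the amplitude
# profiled linearly at each grid node: for fixed basis g, the profiled SSR is
# sum(y^2) - (y.g)^2 / (g.g).
oracle_dqf_grid <- function(tau, y, nu_range = c(20, 400), r_range = c(10, 400),
                            nu_step = 1, r_step = 1) {
  nus <- seq(nu_range[1], nu_range[2], by = nu_step)
  rs <- seq(r_range[1], r_range[2], by = r_step)
  S <- sin(2 * pi * outer(tau, nus))          # n_tau x n_nu
  yty <- sum(y * y)
  best <- list(ssr = Inf)
  for (r in rs) {
    G <- S * exp(-r * tau)
    num <- colSums(y * G) ^ 2
    den <- colSums(G * G)
    ssr <- yty - ifelse(den > 0, num / den, 0)
    i <- which.min(ssr)
    if (ssr[i] < best$ssr) {
      best <- list(ssr = ssr[i], nu_eff = nus[i], R2fast = r,
                   C0 = colSums(y * G)[i] / den[i])
    }
  }
  best
}

# 1-D R2slow scan for the constrained TQF model, amplitude profiled.
oracle_tqf_scan <- function(tau, y, nu_eff, R2fast, r_range = c(1, 200),
                            r_step = 0.1) {
  rs <- seq(r_range[1], r_range[2], by = r_step)
  ct <- cos(2 * pi * nu_eff * tau) * exp(-R2fast * tau)
  best <- list(ssr = Inf)
  for (r in rs) {
    g <- exp(-r * tau) - ct
    den <- sum(g * g)
    if (den == 0) next
    c1 <- sum(y * g) / den
    ssr <- sum((c1 * g - y) ^ 2)
    if (ssr < best$ssr) best <- list(ssr = ssr, C1 = c1, R2slow = r)
  }
  best
}

# Conditional grid argmin of R2fast at a fixed coupling (amplitude profiled);
# used to measure the tilt of the (nu, R2fast) valley on the grid itself.
oracle_dqf_conditional_r <- function(tau, y, nu, r_range = c(10, 400),
                                     r_step = 1) {
  rs <- seq(r_range[1], r_range[2], by = r_step)
  s <- sin(2 * pi * nu * tau)
  ssr <- vapply(rs, function(r) {
    g <- s * exp(-r * tau)
    den <- sum(g * g)
    sum(y * y) - if (den > 0) sum(y * g) ^ 2 / den else 0
  }, numeric(1))
  rs[which.min(ssr)]
}

# Closed-form (weighted) simple linear regression via the normal equations.
oracle_linreg <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb) ^ 2)
  list(slope = slope, intercept = yb - slope * xb)
}
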