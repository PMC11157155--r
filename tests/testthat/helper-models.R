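# small fixture models built in code

one_box_model <- function(mass = 100, flux = 10, alpha_in = 1, alpha_out = 1) {
  box_model(
    compartments = data.frame(
      name = c("diet", "body", "waste"),
      mass = c(NA, mass, NA),
      role = c("source", "internal", "sink"),
      delta0 = c(0, 0, NA)
    ),
    fluxes = data.frame(
      from = c("diet", "body"), to = c("body", "waste"),
      rate = c(flux, flux), alpha = c(alpha_in, alpha_out)
    )
  )
}

# fast box fed by the diet and leaking to waste, exchanging with a slow box
two_box_model <- function(m_fast = 50, m_slow = 2000, throughflow = 10,
                          exchange = 5, alpha_fs = 1, alpha_sf = 1) {
  box_model(
    compartments = data.frame(
      name = c("diet", "fast", "slow", "waste"),
      mass = c(NA, m_fast, m_slow, NA),
      role = c("source", "internal", "internal", "sink"),
      delta0 = c(0, 0, 0, NA)
    ),
    fluxes = data.frame(
      from = c("diet", "fast", "fast", "slow"),
      to = c("fast", "waste", "slow", "fast"),
      rate = c(throughflow, throughflow, exchange, exchange),
      alpha = c(1, 1, alpha_fs, alpha_sf)
    )
  )
}

# no-return chain: source -> a -> b -> sink (triangular rate matrix)
chain_model <- function(m_a = 120, m_b = 700, flux = 8) {
  box_model(
    compartments = data.frame(
      name = c("diet", "a", "b", "waste"),
      mass = c(NA, m_a, m_b, NA),
      role = c("source", "internal", "internal", "sink"),
      delta0 = c(0, 0, 0, NA)
    ),
    fluxes = data.frame(
      from = c("diet", "a", "b"), to = c("a", "b", "waste"),
      rate = flux, alpha = 1
    )
  )
}

# brute-force steady state: integrate the per-flux bookkeeping directly
# (independent of the package's linear-solve path)
oracle_steady <- function(model, diet_delta, t_factor = 50) {
  comps <- model$compartments
  fin <- comps$name[comps$role %in% c("internal", "accumulator")]
  M <- stats::setNames(comps$mass[match(fin, comps$name)], fin)
  flx <- model$fluxes
  rhs <- function(t, y, p) {
    dy <- stats::setNames(numeric(length(fin)), fin)
    for (i in seq_len(nrow(flx))) {
      from <- flx$from[i]; to <- flx$to[i]
      d_src <- if (from %in% fin) y[[from]] else diet_delta
      carried <- (d_src + 1000 * log(flx$alpha[i])) * flx$rate[i]
      if (to %in% fin) dy[to] <- dy[to] + carried / M[[to]]
      if (from %in% fin) dy[from] <- dy[from] - carried / M[[from]]
    }
    list(dy)
  }
  t_end <- t_factor * max(relaxation_times(model)$time_days)
  y0 <- stats::setNames(rep(diet_delta, length(fin)), fin)
  out <- deSolve::ode(y0, c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  stats::setNames(as.numeric(out[nrow(out), -1]), fin)
}

steady_vec <- function(model, diet_delta, ...) {
  ss <- steady_state(model, diet_delta, ...)
  stats::setNames(ss$delta, ss$compartment)
}
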