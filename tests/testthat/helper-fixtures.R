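# Shared fixtures, computed once per test run.

fx <- new.env()
fx$frames <- default_frame_schedule()
fx$aif <- simulate_aif()
fx$gt <- default_ground_truth()
fx$mid <- (fx$frames$frame_start + fx$frames$frame_end) / 2

# Noiseless reference TACs reused across files.
fx$tac_1tc <- simulate_tac(kinetic_truth("r1", 0.5, 0.1), fx$aif, fx$frames)
fx$tac_2tc <- simulate_tac(kinetic_truth("r2", 0.5, 0.1, 0.05, 0.05),
                           fx$aif, fx$frames)
fx$tac_putamen <- simulate_tac(fx$gt$putamen, fx$aif, fx$frames)
fx$tac_cerebellum <- simulate_tac(fx$gt$cerebellum, fx$aif, fx$frames)

# Independent oracle for frame-averaged compartment-model TACs: integrates
# the 2TC state equations dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2,
# dC2/dt = k3 C1 - k4 C2 with a stiff ODE solver (no convolution involved),
# then frame-averages the dense solution.
oracle_tac <- function(K1, k2, k3, k4, input, frames, dt = 0.01) {
  cp_fun <- approxfun(input$time, input$conc, rule = 2)
  tg <- seq(0, max(frames$frame_end), by = dt)
  sol <- deSolve::lsoda(
    y = c(C1 = 0, C2 = 0), times = tg,
    func = function(t, y, p) {
      list(c(K1 * cp_fun(t) - (k2 + k3) * y[1] + k4 * y[2],
             k3 * y[1] - k4 * y[2]))
    }, parms = NULL, rtol = 1e-9, atol = 1e-9)
  ct <- sol[, "C1"] + sol[, "C2"]
  vapply(seq_len(nrow(frames)), function(i) {
    a <- frames$frame_start[i]; b <- frames$frame_end[i]
    xs <- c(a, tg[tg > a & tg < b], b)
    ys <- approx(tg, ct, xout = xs)$y
    sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2) / (b - a)
  }, numeric(1))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
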