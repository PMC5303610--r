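# Independent finite-difference oracle for the wave model: the linear 1-D
# wave equation on a single uniform tube, solved on the Riemann invariants
# W+ = p + Zc q (advects at +c) and W- = p - Zc q (advects at -c) with
# Lax-Wendroff transport. The inlet launches W+ = 2 Zc Q(t) and absorbs the
# returning W- (non-reflecting flow source); the outlet reflects with the
# terminal coefficient gamma. Returns inlet pressure (Pa) on the solver's
# time grid. Built before the delay-line implementation and kept as its
# reference solution.
fd_wave_pressure <- function(qfun, L, c, Zc, gamma, duration,
                             nx = 600, cfl = 0.95) {
  dx <- L / nx
  dt <- cfl * dx / c
  nt <- ceiling(duration / dt)
  wp <- numeric(nx + 1)
  wm <- numeric(nx + 1)
  p0 <- numeric(nt + 1)
  nu <- cfl
  i <- 2:nx
  for (k in seq_len(nt)) {
    wp_new <- wp
    wm_new <- wm
    wp_new[i] <- wp[i] - nu / 2 * (wp[i + 1] - wp[i - 1]) +
      nu^2 / 2 * (wp[i + 1] - 2 * wp[i] + wp[i - 1])
    wp_new[nx + 1] <- wp[nx + 1] - nu * (wp[nx + 1] - wp[nx])
    wm_new[i] <- wm[i] + nu / 2 * (wm[i + 1] - wm[i - 1]) +
      nu^2 / 2 * (wm[i + 1] - 2 * wm[i] + wm[i - 1])
    wm_new[1] <- wm[1] + nu * (wm[2] - wm[1])
    wp_new[1] <- 2 * Zc * qfun(k * dt)          # absorbing source inlet
    wm_new[nx + 1] <- gamma * wp_new[nx + 1]    # resistive termination
    wp <- wp_new
    wm <- wm_new
    p0[k + 1] <- (wp[1] + wm[1]) / 2
  }
  list(t = (0:nt) * dt, p = p0)
}
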