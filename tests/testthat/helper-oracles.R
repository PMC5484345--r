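# independent oracles and small generators shared across test files

# brute-force convolution of ca (linearly interpolated to a fine grid) with
# an arbitrary kernel, by Riemann sum; deliberately naive and slow
riemann_convolve <- function(t, ca, kernel_fn, h = 1e-3 / 60) {
  tf <- seq(t[1], t[length(t)], by = h)
  caf <- approx(t, ca, xout = tf)$y
  vapply(t, function(ti) {
    u <- tf[tf <= ti + 1e-15]
    if (length(u) < 2) return(0)
    cu <- caf[seq_along(u)]
    w <- cu * kernel_fn(ti - u)
    (sum(w) - (w[1] + w[length(w)]) / 2) * h  # trapezoid end weights
  }, numeric(1))
}

# draw a random physically valid CTU parameter set
random_ctu_params <- function() {
  ctu_params(fp = runif(1, 0.05, 1.5),
             vp = runif(1, 0.01, 0.6),
             ps = runif(1, 0, 0.5))
}

# one jittered noisy replicate from a sim_config, for tests that need raw
# curves rather than the Monte Carlo summary
one_replicate <- function(cfg, t0_s = NULL) {
  nl <- sim_noiseless(cfg)
  sigma <- if (is.infinite(cfg$cnr)) 0 else sigma_from_cnr(nl$C, cfg$cnr)
  if (is.null(t0_s)) t0_s <- runif(1, 0, cfg$dt_s)
  ca <- downsample_jitter(nl$ca, cfg$dt_s, t0_s = t0_s)
  C <- downsample_jitter(nl$C, cfg$dt_s, t0_s = t0_s)
  list(ca = add_noise(ca, sigma * cfg$aif_noise_mult),
       C = add_noise(C, sigma),
       ca_clean = ca, C_clean = C, sigma = sigma)
}
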