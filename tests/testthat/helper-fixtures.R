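# Shared fixtures built in code.

fp <- params_f_plasmid()

# One-sided numerical quadrature oracle for the occupancy law:
# integrate 4 pi r^2 P(r, s) C(r) over r in [0, Inf).
quadrature_nc <- function(s_bp, params) {
  s_m <- s_bp / params$kuhn_bp
  vapply(s_m, function(sm) {
    if (sm == 0) return(params$kappa)
    stats::integrate(function(r) {
      4 * pi * r^2 *
        loop_contact_probability(r, sm, params$kuhn_nm) *
        cluster_concentration(r, params$kappa, params$sigma_nm)
    }, 0, Inf, rel.tol = 1e-11)$value
  }, numeric(1))
}

# Small centred synthetic dataset at bp resolution (fast default for tests).
make_test_truth <- function(seed = 1, depth = 100, background = 10, ...) {
  synthetic_truth(depth = depth, background = background, fragment_bp = 0,
                  seed = seed, ...)
}

# Decay profile + fit from a generated dataset, plateau-anchored.
recover_fit <- function(ds, window_bp = c(1, 10000)) {
  site <- ds$truth$sites[[1L]]
  bg <- estimate_background(ds$ip, site)
  prof <- make_decay_profile(ds$ip, site, background = bg, side = "right",
                             anchor_convention = "last_repeat_bp")
  fit_nc(prof, sigma_nm = ds$truth$params$sigma_nm, window_bp = window_bp)
}
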