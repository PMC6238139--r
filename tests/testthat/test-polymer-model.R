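test_that("looping contact probability is a normalized 3-D Gaussian", {
  # direct substitution at the origin
  expect_equal(loop_contact_probability(0, 1, 1), (3 / (2 * pi))^1.5,
               tolerance = 1e-12)
  # integrates to 1 over 3-space for several (s, a)
  for (case in list(c(1, 1), c(50, 3.4), c(1500, 7.5))) {
    s <- case[1]; a <- case[2]
    I <- integrate(function(r) 4 * pi * r^2 * loop_contact_probability(r, s, a),
                   0, Inf, rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-8)
  }
  # at r = R(s) the density is e^{-3/2} of its r = 0 value
  s <- 100; a <- 3.4; R <- a * sqrt(s)
  expect_equal(loop_contact_probability(R, s, a),
               loop_contact_probability(0, s, a) * exp(-1.5),
               tolerance = 1e-12)
  expect_error(loop_contact_probability(1, 0, 1), "positive")
  expect_error(loop_contact_probability(1, 1, -1), "positive")
})

test_that("cluster concentration is a Gaussian of amplitude kappa", {
  expect_equal(cluster_concentration(0, 0.41, 75), 0.41)
  expect_equal(cluster_concentration(75, 0.41, 75), 0.41 * exp(-0.5))
  expect_equal(cluster_concentration(1e6, 0.41, 75), 0)
  expect_error(cluster_concentration(0, 1.2, 75), "\\[0, 1\\]")
})

test_that("occupancy law matches the quadrature oracle and is monotone", {
  expect_equal(nc_density(0, fp), 0.41)
  grids <- list(
    fp,
    params_vcholerae(),
    model_params(sigma_nm = 50, kuhn_bp = 22, kappa = 0.8,
                 enriched_length_bp = 20000)
  )
  for (p in grids) {
    s <- c(0, 1, 10, 100, 1000, 5000, 15000)
    expect_equal(nc_density(s, p), quadrature_nc(s, p), tolerance = 1e-8)
    dens <- nc_density(seq(0, 15000, by = 50), p)
    expect_true(all(diff(dens) < 0))
  }
  # s chosen so the decay argument equals 3 gives kappa * 4^{-3/2}
  s3 <- 3 * 3 * fp$sigma_nm^2 / fp$kuhn_nm^2 * fp$kuhn_bp
  expect_equal(nc_density(s3, fp), 0.41 * 4^(-1.5), tolerance = 1e-12)
  expect_equal(nc_density(s3, fp), 0.05125, tolerance = 1e-12)
  # asymptotic pure power law: log-log slope -3/2 at large s
  s_big <- c(1e9, 2e9, 4e9)
  slopes <- diff(log(nc_density(s_big, fp))) / diff(log(s_big))
  expect_equal(slopes, rep(-1.5, 2), tolerance = 1e-3)
})

test_that("log density is exactly linear in log(1 + a^2 s/3 sigma^2) with slope -3/2", {
  s <- seq(0, 15000, by = 97)
  x <- log(1 + fp$kuhn_nm^2 * (s / fp$kuhn_bp) / (3 * fp$sigma_nm^2))
  y <- log(nc_density(s, fp))
  co <- coef(lm(y ~ x))
  expect_equal(unname(co[2]), -1.5, tolerance = 1e-12)
  expect_equal(unname(co[1]), log(0.41), tolerance = 1e-12)
})

test_that("kappa/N_t normalization is an exact inverse pair for the F-plasmid geometry", {
  expect_equal(round(total_from_kappa(0.41, fp), -1), 360)
  expect_equal(total_from_kappa(0.41, fp), 360, tolerance = 0.02)
  expect_equal(total_from_kappa(0, fp), 0)
  expect_equal(kappa_from_total(0, fp), 0)
  for (n in c(1, 50, 360, 800)) {
    expect_equal(total_from_kappa(kappa_from_total(n, fp), fp), n,
                 tolerance = 1e-12)
  }
  for (k in c(1e-4, 0.15, 0.41, 1)) {
    expect_equal(kappa_from_total(total_from_kappa(k, fp), fp), k,
                 tolerance = 1e-12)
  }
  expect_equal(kappa_from_total(360, fp), 0.41, tolerance = 0.02)
  expect_error(kappa_from_total(1e6, fp), "infeasible")
  # infinite-chain limit: kappa -> (1/6) (a/sigma)^2 N_t, cross-checked
  # against the numerical integral of the occupancy law over [0, Inf)
  p_long <- model_params(sigma_nm = 75, kuhn_bp = 10, kappa = 0.41,
                         enriched_length_bp = 1e10)
  n_inf <- integrate(function(s) nc_density(s, p_long), 0, Inf,
                     rel.tol = 1e-12)$value / p_long$kuhn_bp
  expect_equal(0.41 / n_inf, (1 / 6) * (p_long$kuhn_nm / 75)^2,
               tolerance = 1e-6)
  expect_equal(kappa_from_total(n_inf, p_long), 0.41, tolerance = 2e-3)
})

test_that("model_params enforces its invariants and links kappa to N_t", {
  p <- model_params(sigma_nm = 75, kuhn_bp = 10, kappa = 0.41)
  expect_equal(p$kuhn_nm, 3.4)
  expect_equal(p$n_monomers, 1500)
  expect_equal(p$n_total, total_from_kappa(0.41, p))
  p2 <- model_params(sigma_nm = 75, kuhn_bp = 10, n_total = p$n_total)
  expect_equal(p2$kappa, 0.41, tolerance = 1e-12)
  expect_error(model_params(sigma_nm = -1, kuhn_bp = 10, kappa = 0.4))
  expect_error(model_params(sigma_nm = 75, kuhn_bp = 10, kappa = 1.5),
               "\\[0, 1\\]")
  expect_error(model_params(sigma_nm = 75, kuhn_bp = 10), "one of")
})

test_that("multi-site density follows the independent-union rule with plateaus", {
  pos <- seq(0, 80000)
  single <- list(pars_site(39990, 40010, center_bp = 40000, weight = 1))
  prof <- multi_site_density(pos, single, fp)
  # outside the repeat the profile reduces to the occupancy law
  right <- pos > 40010
  expect_equal(prof$density[right],
               nc_density(pos[right] - 40000, fp), tolerance = 1e-12)
  # specific plateau at the site weight
  expect_equal(prof$density[pos >= 39990 & pos < 40010], rep(1, 20))

  # three well-separated sites: peak heights in the weight ratio
  pos_w <- seq(0, 3e6, by = 500)
  centers <- c(5e5, 1.5e6, 2.5e6)
  sites3 <- list(pars_site(centers[1] - 500, centers[1] + 500, weight = 1),
                 pars_site(centers[2] - 500, centers[2] + 500, weight = 0.9),
                 pars_site(centers[3] - 500, centers[3] + 500, weight = 0.6))
  prof3 <- multi_site_density(pos_w, sites3, fp)
  peaks <- prof3$density[match(centers, pos_w)]
  expect_equal(peaks / peaks[1], c(1, 0.9, 0.6), tolerance = 2e-3)

  # two coincident half-weight sites combine to 1 - 0.5^2 = 0.75
  twin <- list(pars_site(39990, 40010, center_bp = 40000, weight = 0.5),
               pars_site(39990, 40010, center_bp = 40000, weight = 0.5))
  proft <- multi_site_density(pos, twin, fp)
  expect_equal(proft$density[match(40000, pos)], 0.75)
  expect_true(all(proft$density >= 0 & proft$density <= 1))

  expect_error(multi_site_density(pos, list(), fp), "non-empty")
})

test_that("spreading-and-bridging baseline is triangular with 1/m slope", {
  pos <- seq(-2000, 2000)
  m <- 50; fpb <- 16
  prof <- spreading_bridging_profile(m, pos, footprint_bp = fpb)
  expect_equal(prof$density[match(0, pos)], 1)
  expect_true(all(prof$density[abs(pos) >= m * fpb] == 0))
  # doubling m halves the slope
  prof2 <- spreading_bridging_profile(2 * m, pos, footprint_bp = fpb)
  s1 <- (1 - prof$density[match(400, pos)]) / 400
  s2 <- (1 - prof2$density[match(400, pos)]) / 400
  expect_equal(s1 / s2, 2, tolerance = 1e-9)
  expect_error(spreading_bridging_profile(0, pos), "positive")
})

test_that("1D-spreading baseline plateaus proportionally to m", {
  pos <- seq(0, 20000, by = 10)
  p100 <- one_d_spreading_profile(100, pos)
  p200 <- one_d_spreading_profile(200, pos)
  far <- pos > 10000
  expect_equal(mean(p200$density[far]) / mean(p100$density[far]), 2,
               tolerance = 1e-6)
  expect_equal(p100$density[1], 1)            # parS occupied
  p0 <- one_d_spreading_profile(0, pos)
  expect_true(all(p0$density == 0))           # no ParB, no signal
})

test_that("scenario families discriminate constant size from constant concentration", {
  spec_cs <- scenario_spec("constant_size", reference_m = 360,
                           ratios = c(0.4, 1, 16, 28))
  fam <- scenario_family(spec_cs, fp)
  ref <- fam[[2]]
  for (prof in fam) {
    rescaled <- prof$density / prof$ratio
    expect_true(max(abs(rescaled - ref$density)) < 1e-12)
  }
  # constant concentration: sigma = m^{1/3}, shapes change
  spec_cc <- scenario_spec("constant_concentration", reference_m = 360,
                           ratios = c(1, 8))
  fam_cc <- scenario_family(spec_cc, fp)
  # m x8 doubles sigma: decay argument at fixed s shrinks 4-fold
  d1 <- fam_cc[[1]]$density / fam_cc[[1]]$ratio
  d8 <- fam_cc[[2]]$density / fam_cc[[2]]$ratio
  expect_gt(max(abs(d8 - d1) / d1), 0.5)
  s <- fam_cc[[1]]$offsets_bp
  arg8 <- (d8 / 0.41)^(-2 / 3) - 1
  arg1 <- (d1 / 0.41)^(-2 / 3) - 1
  expect_equal(arg1[-1] / arg8[-1], rep(4, length(s) - 1), tolerance = 1e-9)
  expect_error(scenario_spec("weird", 1, 1))
})
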