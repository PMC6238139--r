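#' Gaussian-polymer looping contact probability
#'
#' Probability density (per unit volume, nm^-3) that two loci of a Gaussian
#' chain separated by `s` monomers of Kuhn length `a` are found at spatial
#' distance `r`:
#' \deqn{P(r, s) = \left(\frac{3}{2\pi R^2}\right)^{3/2}
#'   e^{-3 r^2 / (2 R^2)}, \qquad R^2 = a^2 s.}
#' It integrates to 1 over three-dimensional space.
#'
#' @param r Radial distance, nm (vectorized, >= 0).
#' @param s Genomic separation in monomers (> 0).
#' @param a Kuhn length, nm (> 0).
#' @return Probability density per nm^3.
#' @export
#' @examples
#' loop_contact_probability(0, 1, 1)  # (3/2pi)^(3/2) ~ 0.3299
loop_contact_probability <- function(r, s, a) {
  if (any(s <= 0)) stop("`s` must be positive (R(s) undefined)", call. = FALSE)
  if (any(a <= 0)) stop("`a` must be positive", call. = FALSE)
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  R2 <- a^2 * s
  (3 / (2 * pi * R2))^1.5 * exp(-3 * r^2 / (2 * R2))
}

#' Gaussian cluster concentration profile
#'
#' Probability that a ParB is available for binding at radial distance `r`
#' from the cluster centre: \eqn{C(r) = \kappa e^{-r^2 / (2\sigma^2)}}.
#'
#' @param r Radial distance, nm (vectorized).
#' @param kappa Binding probability at the centre, in \[0, 1\].
#' @param sigma_nm Cluster radius, nm (> 0).
#' @return Binding probability in \[0, kappa\].
#' @export
cluster_concentration <- function(r, kappa, sigma_nm) {
  if (any(kappa < 0) || any(kappa > 1)) {
    stop("`kappa` must be in [0, 1] (probability amplitude)", call. = FALSE)
  }
  if (any(sigma_nm <= 0)) stop("`sigma_nm` must be positive", call. = FALSE)
  kappa * exp(-r^2 / (2 * sigma_nm^2))
}

# beta = a^2/(3 sigma^2): growth rate, per monomer, of the decay argument
.beta_per_monomer <- function(params) {
  params$kuhn_nm^2 / (3 * params$sigma_nm^2)
}

#' Nucleation-and-caging occupancy law
#'
#' Closed-form non-specific ParB occupancy at genomic distance `s_bp` from
#' the nucleation site, obtained by integrating the product of the looping
#' probability and the Gaussian cluster concentration over space:
#' \deqn{P_{NC}(s) = \kappa \left(1 + \frac{a^2 s_m}{3\sigma^2}\right)^{-3/2}}
#' with \eqn{s_m = s_{bp} / a_{bp}} the separation in monomers and \eqn{a}
#' in nm. \eqn{P_{NC}(0) = \kappa}; for \eqn{a^2 s_m \gg 3\sigma^2} it
#' approaches the pure power law \eqn{s^{-3/2}}.
#'
#' @param s_bp Genomic distance from parS, bp (vectorized, >= 0).
#' @param params A [model_params()].
#' @return Dimensionless occupancy in \[0, kappa\].
#' @export
nc_density <- function(s_bp, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(s_bp < 0)) stop("`s_bp` must be non-negative", call. = FALSE)
  s_m <- s_bp / params$kuhn_bp
  params$kappa * (1 + .beta_per_monomer(params) * s_m)^(-1.5)
}

#' Total cluster-bound ParB from kappa
#'
#' One-sided integral of the occupancy law over the enriched length,
#' evaluated in closed form:
#' \deqn{N_t = \int_0^N P_{NC}(s)\,ds
#'   = \kappa \frac{2}{\beta}\left[1 - (1 + \beta N)^{-1/2}\right]},
#' with \eqn{\beta = a^2/(3\sigma^2)} per monomer and
#' \eqn{N} the monomer count of the enriched length. Exact inverse of
#' [kappa_from_total()].
#'
#' @param kappa Cluster-centre binding probability in \[0, 1\].
#' @param params A [model_params()] supplying geometry (its own `kappa`
#'   field is ignored).
#' @return Total bound ParB count.
#' @export
#' @examples
#' total_from_kappa(0.41, params_f_plasmid())  # ~ 360
total_from_kappa <- function(kappa, params) {
  stopifnot(inherits(params, "model_params"))
  if (kappa < 0 || kappa > 1) stop("`kappa` must be in [0, 1]", call. = FALSE)
  beta <- .beta_per_monomer(params)
  N <- params$n_monomers
  kappa * (2 / beta) * (1 - (1 + beta * N)^(-0.5))
}

#' Kappa from the total cluster-bound ParB
#'
#' Analytic inverse of [total_from_kappa()]. In the limit of an infinite
#' chain it reduces to \eqn{\kappa = \frac{1}{6}(a/\sigma)^2 N_t}. Since
#' kappa is a probability amplitude the result must satisfy
#' \eqn{0 \le \kappa \le 1}; a larger requested `n_total` is geometrically
#' infeasible (the polymer does not return to the cluster often enough).
#'
#' @param n_total Total bound ParB count (>= 0).
#' @param params A [model_params()] supplying geometry.
#' @return kappa in \[0, 1\].
#' @export
kappa_from_total <- function(n_total, params) {
  stopifnot(inherits(params, "model_params"))
  if (n_total < 0) stop("`n_total` must be non-negative", call. = FALSE)
  beta <- .beta_per_monomer(params)
  N <- params$n_monomers
  kappa <- n_total * beta / (2 * (1 - (1 + beta * N)^(-0.5)))
  if (kappa > 1 + 1e-12) {
    stop(sprintf(paste0("infeasible: n_total = %g requires kappa = %.3g > 1 ",
                        "for this geometry (too many proteins for the ",
                        "cluster size / Kuhn length)"), n_total, kappa),
         call. = FALSE)
  }
  min(kappa, 1)
}

#' Combined occupancy profile for multiple parS sites
#'
#' Each site k contributes an occupancy
#' \eqn{p_k(x) = w_k} inside its repeat interval (the specific plateau) and
#' \eqn{p_k(x) = w_k \, P_{NC}(|x - c_k|)} elsewhere; the non-interacting
#' clusters combine by the independent-union rule
#' \eqn{1 - \prod_k (1 - p_k(x))}, which keeps the result a probability for
#' any geometry, including overlapping clusters.
#'
#' @param positions_bp Strictly increasing genomic coordinates at which to
#'   evaluate, bp.
#' @param sites List of [pars_site()] objects (at least one).
#' @param params A [model_params()].
#' @return A [binding_profile()] anchored at the centre of the
#'   highest-weight site, in genomic offsets from that anchor.
#' @export
multi_site_density <- function(positions_bp, sites, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.list(sites) || length(sites) == 0L) {
    stop("`sites` must be a non-empty list of pars_site objects", call. = FALSE)
  }
  if (inherits(sites, "pars_site")) sites <- list(sites)
  lapply(sites, function(s) stopifnot(inherits(s, "pars_site")))
  surv <- rep(1, length(positions_bp))
  for (site in sites) {
    p <- site$weight * nc_density(abs(positions_bp - site$center_bp), params)
    in_repeat <- positions_bp >= site$repeat_start_bp &
      positions_bp < site$repeat_end_bp
    p[in_repeat] <- site$weight
    surv <- surv * (1 - p)
  }
  anchor <- sites[[which.max(vapply(sites, `[[`, numeric(1), "weight"))]]$center_bp
  binding_profile(positions_bp - anchor, 1 - surv, anchor_bp = anchor)
}

#' Spreading-and-bridging baseline profile
#'
#' Competing-model prediction in the strong-coupling limit: all m ParB
#' cluster along the DNA in contact with parS, giving a triangular profile
#' of unit height at parS that decreases linearly to 0 once the m protein
#' footprints are exhausted — a slope proportional to 1/m.
#'
#' @param m ParB count (> 0).
#' @param positions_bp Signed genomic offsets from parS, bp.
#' @param footprint_bp DNA covered per ParB, bp (default 16, one binding
#'   motif).
#' @return A [binding_profile()] in offsets from parS.
#' @export
spreading_bridging_profile <- function(m, positions_bp, footprint_bp = 16) {
  if (m <= 0) stop("`m` must be positive", call. = FALSE)
  dens <- pmax(0, 1 - abs(positions_bp) / (m * footprint_bp))
  binding_profile(positions_bp, dens)
}

#' 1D-spreading baseline profile
#'
#' Competing-model prediction for nearest-neighbour 1D filaments: a sharp
#' (exponential-type) drop of ParB density immediately after parS followed
#' by a homogeneous plateau along the DNA whose height is proportional to
#' the ParB amount m (no 1D phase transition, hence no clustering).
#'
#' @param m ParB count (>= 0).
#' @param positions_bp Signed genomic offsets from parS, bp.
#' @param plateau_per_parb Plateau density contributed per ParB; the plateau
#'   is `min(1, m * plateau_per_parb)`.
#' @param decay_bp Length scale of the initial drop, bp.
#' @return A [binding_profile()] in offsets from parS.
#' @export
one_d_spreading_profile <- function(m, positions_bp, plateau_per_parb = 1e-3,
                                    decay_bp = 100) {
  if (m < 0) stop("`m` must be non-negative", call. = FALSE)
  plateau <- min(1, m * plateau_per_parb)
  if (plateau < 0 || plateau > 1) stop("plateau must be in [0, 1]", call. = FALSE)
  scale <- min(1, m * plateau_per_parb * 50) # amplitude vanishes with m -> 0
  dens <- plateau + (scale - plateau) * exp(-abs(positions_bp) / decay_bp)
  binding_profile(positions_bp, pmax(0, dens))
}

#' Family of profiles under ParB-amount variation
#'
#' Evaluates the occupancy profile at each ParB/parS ratio in `spec` under
#' one of two cluster-response scenarios. In `constant_size` mode the
#' cluster radius stays fixed and only the amplitude scales with m, so all
#' profiles collapse onto one curve after amplitude rescaling. In
#' `constant_concentration` mode a compact cluster grows as
#' \eqn{\sigma(m) = \sigma_{ref} (m/m_{ref})^{1/3}}, changing the decay
#' shape itself, so rescaled profiles do not overlap.
#'
#' Amplitudes are reported proportional to m (relative occupancy units, not
#' clamped to 1) since amplitude rescaling is the point of the comparison.
#'
#' @param spec A [scenario_spec()].
#' @param params Reference [model_params()].
#' @param positions_bp Genomic distances at which to evaluate (default
#'   0..enriched length, 10-bp steps).
#' @return Named list of [binding_profile()]s, one per ratio.
#' @export
scenario_family <- function(spec, params, positions_bp = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(params, "model_params"))
  if (is.null(positions_bp)) {
    positions_bp <- seq(0, params$enriched_length_bp, by = 10)
  }
  out <- lapply(spec$ratios, function(rho) {
    if (spec$mode == "constant_size") {
      p <- params
    } else {
      p <- params
      p$sigma_nm <- params$sigma_nm * rho^(1 / 3)
    }
    dens <- rho * nc_density(positions_bp, p)
    prof <- binding_profile(positions_bp, dens)
    prof$ratio <- rho
    prof
  })
  names(out) <- paste0("ratio_", spec$ratios)
  out
}
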