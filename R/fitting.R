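#' Fit the nucleation-and-caging trial function to a decay profile
#'
#' Bounded nonlinear least squares of
#' \deqn{P(s) = A_0 (1 + A_1 \ell(s))^{-3/2}}
#' to the normalized decay profile over `window_bp`, where
#' \eqn{\ell(s) = } `nm_per_bp` \eqn{\times s} is the contour length in nm
#' (so that A1 carries units of nm^-1). The fitted amplitudes map onto the
#' physical parameters as \eqn{\kappa = A_0} and \eqn{a = 3\sigma^2 A_1};
#' the total cluster-bound ParB follows from [total_from_kappa()] over the
#' enriched length.
#'
#' @param profile A normalized [binding_profile()] covering the window.
#' @param sigma_nm Cluster radius, nm (known from microscopy; fixed during
#'   the fit).
#' @param window_bp Length-2 fit range in offsets, bp (default 0 to
#'   10000).
#' @param enriched_length_bp One-sided enriched length used to derive N_t
#'   (default 15000).
#' @param nm_per_bp Contour conversion, nm per bp (default 0.34).
#' @param log_scale If `TRUE`, minimize squared error of log density
#'   (requires positive densities in the window); default is unweighted
#'   squared error on the linear scale.
#' @param mask_offsets Optional offsets to exclude (e.g. dips flagged by
#'   [detect_dips()]).
#' @param start Optional named list with starting values `A0`, `A1`;
#'   defaults to the profile value nearest offset 0 and 2e-4 nm^-1.
#' @return An object of class `fit_result`: fields `A0`, `A1` (nm^-1),
#'   `kappa`, `kuhn_nm`, `kuhn_bp`, `n_total`, `window_bp`, `sse`,
#'   `sigma_nm`, `nm_per_bp`, `n_points`.
#' @export
fit_nc <- function(profile, sigma_nm = 75, window_bp = c(0, 10000),
                   enriched_length_bp = 15000, nm_per_bp = 0.34,
                   log_scale = FALSE, mask_offsets = NULL, start = NULL) {
  stopifnot(inherits(profile, "binding_profile"), sigma_nm > 0)
  sel <- profile$offsets_bp >= window_bp[1L] &
    profile$offsets_bp <= window_bp[2L]
  if (!is.null(mask_offsets)) {
    sel <- sel & !(profile$offsets_bp %in% mask_offsets)
  }
  s <- profile$offsets_bp[sel]
  y <- profile$density[sel]
  if (length(s) < 3L) stop("too few points in the fit window", call. = FALSE)
  ell <- nm_per_bp * s
  if (log_scale) {
    if (any(y <= 0)) {
      stop("log-scale fit requires positive densities in the window",
           call. = FALSE)
    }
  }
  a0_start <- if (!is.null(start)) start$A0 else {
    min(1, max(1e-3, y[which.min(abs(s))]))
  }
  a1_start <- if (!is.null(start)) start$A1 else 2e-4
  d <- data.frame(ell = ell,
                  y = if (log_scale) log(y) else y)
  fml <- if (log_scale) {
    y ~ log(A0) - 1.5 * log(1 + A1 * ell)
  } else {
    y ~ A0 * (1 + A1 * ell)^(-1.5)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d,
                      start = list(A0 = a0_start, A1 = a1_start),
                      lower = c(A0 = 1e-12, A1 = 1e-12),
                      upper = c(A0 = 1, A1 = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop(sprintf("trial-function fit failed to converge: %s",
                   conditionMessage(e)), call. = FALSE)
    })
  cf <- stats::coef(fit)
  A0 <- unname(cf["A0"]); A1 <- unname(cf["A1"])
  if (A0 <= 0 || A0 > 1) {
    stop(sprintf("fitted A0 = %.3g outside (0, 1]", A0), call. = FALSE)
  }
  kuhn_nm <- 3 * sigma_nm^2 * A1
  kuhn_bp <- kuhn_nm / nm_per_bp
  params <- model_params(sigma_nm = sigma_nm, kuhn_bp = max(1, kuhn_bp),
                         kappa = A0, enriched_length_bp = enriched_length_bp,
                         nm_per_bp = nm_per_bp)
  resid_lin <- y - A0 * (1 + A1 * ell)^(-1.5)
  structure(
    list(A0 = A0, A1 = A1, kappa = A0, kuhn_nm = kuhn_nm, kuhn_bp = kuhn_bp,
         n_total = params$n_total, window_bp = window_bp,
         sse = sum(resid_lin^2), sigma_nm = sigma_nm, nm_per_bp = nm_per_bp,
         n_points = length(s)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nucleation-and-caging fit\n")
  cat(sprintf("  A0 (= kappa) = %.4g\n", x$A0))
  cat(sprintf("  A1           = %.4g nm^-1\n", x$A1))
  cat(sprintf("  Kuhn length  = %.3g nm (%.3g bp)\n", x$kuhn_nm, x$kuhn_bp))
  cat(sprintf("  N_t          = %.4g ParB\n", x$n_total))
  cat(sprintf("  window       = %g-%g bp, SSE = %.3g (%d points)\n",
              x$window_bp[1L], x$window_bp[2L], x$sse, x$n_points))
  invisible(x)
}

#' Assemble model parameters from a fit
#'
#' Maps the fitted amplitudes onto the physical parameter set: kappa = A0,
#' Kuhn length a = 3 sigma^2 A1, and N_t via the closed-form occupancy
#' integral over `enriched_length_bp`.
#'
#' @param fit A `fit_result` from [fit_nc()].
#' @param sigma_nm Cluster radius, nm (default: the one stored in the fit).
#' @param enriched_length_bp One-sided enriched length, bp.
#' @return A [model_params()].
#' @export
derive_params <- function(fit, sigma_nm = fit$sigma_nm,
                          enriched_length_bp = 15000) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$A0 > 1) stop("kappa > 1 is infeasible", call. = FALSE)
  kuhn_nm <- 3 * sigma_nm^2 * fit$A1
  model_params(sigma_nm = sigma_nm,
               kuhn_bp = max(1, kuhn_nm / fit$nm_per_bp),
               kappa = fit$A0, enriched_length_bp = enriched_length_bp,
               nm_per_bp = fit$nm_per_bp)
}

#' Fit the union model to a multi-parS profile
#'
#' Site weights are fixed from the observed peak heights at each site
#' centre relative to the tallest (as read off the profile), then
#' (kappa, a) are fitted as in [fit_nc()] on the union model
#' \eqn{1 - \prod_k (1 - w_k A_0 (1 + A_1 \ell(|x - c_k|))^{-3/2})},
#' excluding the repeat intervals themselves. Semi-quantitative by
#' construction.
#'
#' @param profile A [binding_profile()] whose offsets are genomic
#'   coordinates relative to its anchor.
#' @param sites List of >= 2 [pars_site()] objects in the same genomic
#'   coordinates as `profile$anchor_bp + offsets`.
#' @param sigma_nm Cluster radius, nm.
#' @param nm_per_bp Contour conversion.
#' @param enriched_length_bp One-sided enriched length for N_t.
#' @param fragment_bp If > 0 and any inter-site distance is smaller than
#'   this fragment width, the peaks are flagged as unresolvable.
#' @return A list with `params` ([model_params()]), `weights` (per site,
#'   tallest = 1), `fit` (`fit_result`-like amplitudes) and
#'   `resolvable` (logical).
#' @export
fit_multi_pars <- function(profile, sites, sigma_nm, nm_per_bp = 0.34,
                           enriched_length_bp = 15000, fragment_bp = 0) {
  stopifnot(inherits(profile, "binding_profile"), length(sites) >= 2L)
  pos <- profile$anchor_bp + profile$offsets_bp
  centers <- vapply(sites, `[[`, numeric(1), "center_bp")
  peak <- vapply(centers, function(cc) {
    profile$density[which.min(abs(pos - cc))]
  }, numeric(1))
  weights <- peak / max(peak)
  resolvable <- TRUE
  if (fragment_bp > 0 && length(centers) > 1L) {
    if (min(diff(sort(centers))) < fragment_bp) {
      warning("inter-site distance smaller than the fragment width; ",
              "peak heights are not resolvable")
      resolvable <- FALSE
    }
  }
  # exclude the specific plateaus and, when a fragment size is given, the
  # fragment-smeared neighbourhood of each peak (smearing is not part of
  # the union model)
  in_repeat <- rep(FALSE, length(pos))
  for (st in sites) {
    in_repeat <- in_repeat | (pos >= st$repeat_start_bp &
                                pos < st$repeat_end_bp)
    if (fragment_bp > 0) {
      in_repeat <- in_repeat | abs(pos - st$center_bp) <= fragment_bp
    }
  }
  d <- data.frame(y = profile$density[!in_repeat])
  dist_mat <- vapply(centers, function(cc) abs(pos[!in_repeat] - cc),
                     numeric(sum(!in_repeat)))
  union_model <- function(A0, A1) {
    surv <- rep(1, nrow(dist_mat))
    for (k in seq_along(centers)) {
      surv <- surv * (1 - weights[k] * A0 *
                        (1 + A1 * nm_per_bp * dist_mat[, k])^(-1.5))
    }
    1 - surv
  }
  # small multi-start: the union model is weakly identified when started at
  # the A0 bound, so try a few amplitudes/decay rates and keep the best
  starts <- expand.grid(A0 = c(0.15, 0.5, 0.9), A1 = c(2e-4, 1e-3, 3e-3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ union_model(A0, A1), data = d,
        start = as.list(starts[i, ]),
        lower = c(A0 = 1e-12, A1 = 1e-12), upper = c(A0 = 1, A1 = 1),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(best) || sum(stats::resid(f)^2) < sum(stats::resid(best)^2))) {
      best <- f
    }
  }
  if (is.null(best)) stop("union-model fit failed to converge", call. = FALSE)
  cf <- stats::coef(best)
  A0 <- unname(cf["A0"]); A1 <- unname(cf["A1"])
  kuhn_nm <- 3 * sigma_nm^2 * A1
  params <- model_params(sigma_nm = sigma_nm,
                         kuhn_bp = max(1, kuhn_nm / nm_per_bp),
                         kappa = A0, enriched_length_bp = enriched_length_bp,
                         nm_per_bp = nm_per_bp)
  list(params = params, weights = weights,
       fit = list(A0 = A0, A1 = A1, kuhn_nm = kuhn_nm,
                  kuhn_bp = kuhn_nm / nm_per_bp),
       resolvable = resolvable)
}

#' Power-law exponent diagnostic
#'
#' Ordinary least-squares slope of log(density) against
#' \eqn{\log(1 + a^2 s_m / 3\sigma^2)} over the window. Data generated by
#' the nucleation-and-caging law give slope -3/2 up to noise; the
#' 1D-spreading plateau gives a slope near 0 at large s.
#'
#' @param profile A [binding_profile()] with positive densities in the
#'   window.
#' @param params A [model_params()] supplying a and sigma for the abscissa.
#' @param window_bp Length-2 offset range, bp.
#' @return The fitted slope.
#' @export
fit_powerlaw_exponent <- function(profile, params, window_bp = c(0, 10000)) {
  stopifnot(inherits(profile, "binding_profile"),
            inherits(params, "model_params"))
  sel <- profile$offsets_bp >= window_bp[1L] &
    profile$offsets_bp <= window_bp[2L]
  s <- profile$offsets_bp[sel]
  y <- profile$density[sel]
  if (any(y <= 0)) {
    stop("non-positive densities in the window; cannot take logs",
         call. = FALSE)
  }
  xarg <- log(1 + .beta_per_monomer(params) * s / params$kuhn_bp)
  unname(stats::coef(stats::lm(log(y) ~ xarg))[2L])
}
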