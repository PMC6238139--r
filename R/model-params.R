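#' Nucleation-and-caging model parameters
#'
#' Bundles the physical parameters of the nucleation-and-caging occupancy
#' model: the ParB cluster radius `sigma_nm`, the Kuhn length of the DNA
#' polymer (in bp, with a fixed contour conversion `nm_per_bp`), the
#' cluster-centre binding probability `kappa`, the total number of
#' cluster-bound ParB per DNA molecule `n_total`, and the one-sided
#' enrichment length over which the occupancy integral is taken.
#'
#' Exactly one of `kappa` and `n_total` may be left `NULL`; the missing one
#' is computed from the other through the closed-form normalization
#' ([total_from_kappa()] / [kappa_from_total()]).
#'
#' @param sigma_nm Cluster radius (Gaussian width of the ParB concentration),
#'   nm. Must be positive.
#' @param kuhn_bp Kuhn length in bp (about twice the DNA persistence length
#'   in the worm-like-chain picture). Must be >= 1.
#' @param kappa Binding probability at the cluster centre, in \[0, 1\];
#'   equals the occupancy drop height between specific and non-specific
#'   signal.
#' @param n_total Total number of ParB bound to one DNA molecule via the
#'   cluster. Non-negative.
#' @param enriched_length_bp One-sided length of the ChIP-enriched region
#'   (the upper limit of the occupancy integral), bp.
#' @param nm_per_bp Contour length per bp, nm. Default 0.34.
#'
#' @return An object of class `model_params` (a named list) with fields
#'   `sigma_nm`, `kuhn_bp`, `kuhn_nm`, `kappa`, `n_total`,
#'   `enriched_length_bp`, `n_monomers`, `nm_per_bp`.
#' @export
#' @examples
#' p <- model_params(sigma_nm = 75, kuhn_bp = 10, kappa = 0.41)
#' p$n_total   # ~ 360 cluster-bound ParB over 15 kbp
model_params <- function(sigma_nm, kuhn_bp, kappa = NULL, n_total = NULL,
                         enriched_length_bp = 15000, nm_per_bp = 0.34) {
  stopifnot(is.numeric(sigma_nm), length(sigma_nm) == 1L, sigma_nm > 0)
  stopifnot(is.numeric(kuhn_bp), length(kuhn_bp) == 1L, kuhn_bp >= 1)
  stopifnot(is.numeric(enriched_length_bp), enriched_length_bp > 0)
  stopifnot(is.numeric(nm_per_bp), nm_per_bp > 0)
  if (is.null(kappa) && is.null(n_total)) {
    stop("one of `kappa` or `n_total` must be given", call. = FALSE)
  }
  p <- structure(
    list(
      sigma_nm = as.numeric(sigma_nm),
      kuhn_bp = as.numeric(kuhn_bp),
      kuhn_nm = as.numeric(kuhn_bp * nm_per_bp),
      kappa = NA_real_,
      n_total = NA_real_,
      enriched_length_bp = as.numeric(enriched_length_bp),
      n_monomers = as.numeric(enriched_length_bp / kuhn_bp),
      nm_per_bp = as.numeric(nm_per_bp)
    ),
    class = "model_params"
  )
  if (!is.null(kappa)) {
    if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0 || kappa > 1) {
      stop("`kappa` must be a single number in [0, 1]", call. = FALSE)
    }
    p$kappa <- as.numeric(kappa)
    p$n_total <- total_from_kappa(p$kappa, p)
    if (!is.null(n_total)) {
      stopifnot(is.numeric(n_total), n_total >= 0)
      if (abs(p$n_total - n_total) > 1e-6 * max(1, n_total)) {
        stop("`kappa` and `n_total` are inconsistent under the normalization relation",
             call. = FALSE)
      }
    }
  } else {
    stopifnot(is.numeric(n_total), length(n_total) == 1L, n_total >= 0)
    p$n_total <- as.numeric(n_total)
    p$kappa <- kappa_from_total(p$n_total, p)
  }
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Nucleation-and-caging model parameters\n")
  cat(sprintf("  sigma   = %g nm (cluster radius)\n", x$sigma_nm))
  cat(sprintf("  a       = %g bp = %g nm (Kuhn length)\n", x$kuhn_bp, x$kuhn_nm))
  cat(sprintf("  kappa   = %.4g (cluster-centre binding probability)\n", x$kappa))
  cat(sprintf("  N_t     = %.4g ParB (total cluster-bound, one-sided over %g kbp)\n",
              x$n_total, x$enriched_length_bp / 1000))
  invisible(x)
}

#' F-plasmid parameter preset
#'
#' The parameter set describing the ParB/parS partition complex of the
#' Escherichia coli F plasmid: sigma = 75 nm (super-resolution microscopy),
#' Kuhn length 10 bp, kappa = 0.41 (fitted from the ChIP-seq decay), with a
#' one-sided enriched length of 15 kbp, giving N_t ~ 360.
#'
#' @return A [model_params()] object.
#' @export
params_f_plasmid <- function() {
  model_params(sigma_nm = 75, kuhn_bp = 10, kappa = 0.41,
               enriched_length_bp = 15000)
}

#' Vibrio cholerae chromosome 1 parameter preset
#'
#' Semi-quantitative parameter set for the three-parS region of V. cholerae
#' chromosome 1: sigma = 25 nm, Kuhn length 16 bp (one ParB footprint),
#' kappa = 0.15, 2000-monomer chain (32 kbp).
#'
#' @return A [model_params()] object.
#' @export
params_vcholerae <- function() {
  model_params(sigma_nm = 25, kuhn_bp = 16, kappa = 0.15,
               enriched_length_bp = 32000)
}

#' A parS nucleation site
#'
#' A genomic interval of specific ParB binding repeats with the coordinate of
#' the cluster centre it nucleates and a relative occupancy weight (the
#' probability that the site carries an assembled cluster).
#'
#' @param repeat_start_bp,repeat_end_bp 0-based half-open interval of the
#'   specific binding repeats.
#' @param center_bp Cluster-centre coordinate; defaults to the interval
#'   midpoint. Must lie within or immediately adjacent to the repeat
#'   interval.
#' @param weight Relative site occupancy in (0, 1].
#'
#' @return An object of class `pars_site`.
#' @export
pars_site <- function(repeat_start_bp, repeat_end_bp, center_bp = NULL,
                      weight = 1) {
  stopifnot(is.numeric(repeat_start_bp), is.numeric(repeat_end_bp))
  if (repeat_start_bp >= repeat_end_bp) {
    stop("repeat interval must be non-empty (start < end)", call. = FALSE)
  }
  if (!is.numeric(weight) || weight <= 0 || weight > 1) {
    stop("`weight` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(center_bp)) {
    center_bp <- floor((repeat_start_bp + repeat_end_bp) / 2)
  }
  if (center_bp < repeat_start_bp - 1 || center_bp > repeat_end_bp) {
    stop("`center_bp` must lie within or adjacent to the repeat interval",
         call. = FALSE)
  }
  structure(
    list(repeat_start_bp = as.numeric(repeat_start_bp),
         repeat_end_bp = as.numeric(repeat_end_bp),
         center_bp = as.numeric(center_bp),
         weight = as.numeric(weight)),
    class = "pars_site"
  )
}

#' Cluster-size scenario specification
#'
#' Describes how the ParB cluster responds to a change in the number m of
#' available ParB: either the cluster keeps a constant protein concentration
#' (compact cluster, radius growing as sigma = m^(1/3)) or a constant size
#' (fixed sigma, density growing with m).
#'
#' @param mode `"constant_size"` or `"constant_concentration"`.
#' @param reference_m ParB count at the reference condition (> 0).
#' @param ratios Positive ParB/parS ratios (relative to the reference) at
#'   which to evaluate profiles.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(mode = c("constant_size", "constant_concentration"),
                          reference_m, ratios) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(reference_m), reference_m > 0)
  if (!is.numeric(ratios) || length(ratios) < 1L || any(ratios <= 0)) {
    stop("`ratios` must be positive numbers", call. = FALSE)
  }
  structure(list(mode = mode, reference_m = as.numeric(reference_m),
                 ratios = as.numeric(ratios)),
            class = "scenario_spec")
}
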