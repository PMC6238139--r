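#' Ground truth for a synthetic ChIP-seq dataset
#'
#' Describes the generating process for a synthetic IP/input pair: the
#' occupancy model, nucleation sites, roadblock loci (intervals where
#' occupancy is multiplicatively suppressed), sequencing depth, flat
#' background, fragment smoothing and seed.
#'
#' @param params A [model_params()] (default the F-plasmid preset).
#' @param sites List of [pars_site()]s in genomic coordinates (default: one
#'   site with a 160-bp repeat region centred in the window).
#' @param roadblocks List of `list(start_bp, end_bp, factor)` with
#'   suppression factors in \[0, 1).
#' @param depth Mean IP reads per bp at full occupancy (> background).
#' @param background Mean background reads per bp (>= 0).
#' @param fragment_bp Average library fragment size for triangular
#'   smoothing of the expected signal (default 280; 0 disables).
#' @param seed RNG seed.
#' @param window_bp Length-2 genomic window of the generated tracks
#'   (default +/- 40 kbp around the first site's centre).
#' @param chrom Sequence name.
#' @param overdispersion `NULL` for Poisson reads; a positive number for
#'   negative-binomial reads with that `size` parameter (smaller = more
#'   overdispersed).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params = params_f_plasmid(), sites = NULL,
                            roadblocks = list(), depth = 100, background = 10,
                            fragment_bp = 280, seed = 1, window_bp = NULL,
                            chrom = "synthetic_1", overdispersion = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(sites)) {
    sites <- list(pars_site(40000 - 80, 40000 + 80, center_bp = 40000))
  }
  if (inherits(sites, "pars_site")) sites <- list(sites)
  if (is.null(window_bp)) {
    c0 <- sites[[1L]]$center_bp
    window_bp <- c(max(0, c0 - 40000), c0 + 40000)
  }
  if (!(depth >= 0 && background >= 0 && (depth == 0 || depth > background))) {
    stop("`depth` must be 0 (background-only data) or exceed `background`",
         call. = FALSE)
  }
  for (rb in roadblocks) {
    if (rb$factor < 0 || rb$factor >= 1) {
      stop("roadblock suppression factors must be in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(params = params, sites = sites, roadblocks = roadblocks,
         depth = depth, background = background, fragment_bp = fragment_bp,
         seed = seed, window_bp = window_bp, chrom = chrom,
         overdispersion = overdispersion, barrier = NULL),
    class = "synthetic_truth"
  )
}

# Expected (noise-free) IP signal over the truth window, reads per bp.
.expected_ip_signal <- function(truth) {
  pos <- seq(truth$window_bp[1L], truth$window_bp[2L] - 1)
  occ <- multi_site_density(pos, truth$sites, truth$params)$density
  # enrichment is confined to the modeled chain: no occupancy beyond the
  # enriched length L from every nucleation site (the flank signal merges
  # into background there, as in the real propagation zones)
  dmin <- rep(Inf, length(pos))
  for (st in truth$sites) {
    dmin <- pmin(dmin, abs(pos - st$center_bp))
  }
  occ[dmin > truth$params$enriched_length_bp] <- 0
  for (rb in truth$roadblocks) {
    in_rb <- pos >= rb$start_bp & pos < rb$end_bp
    occ[in_rb] <- occ[in_rb] * rb$factor
  }
  if (!is.null(truth$barrier)) {
    if (truth$barrier$side == "left") {
      occ[pos < truth$barrier$barrier_bp] <- 0
    } else {
      occ[pos >= truth$barrier$barrier_bp] <- 0
    }
  }
  sig <- truth$depth * occ
  if (truth$fragment_bp > 0) {
    # unit-sum (weighted-average) form of the fragment triangle keeps
    # `depth` in reads-per-bp units
    ker <- triangular_kernel(truth$fragment_bp)
    ker <- ker / sum(ker)
    sm <- as.numeric(stats::filter(sig, ker, sides = 2))
    half <- (length(ker) - 1L) %/% 2L
    n <- length(sig)
    for (i in which(is.na(sm))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      kidx <- (lo - i + half + 1L):(hi - i + half + 1L)
      sm[i] <- sum(sig[lo:hi] * ker[kidx]) / sum(ker[kidx])
    }
    sig <- sm
  }
  list(pos = pos, mean = sig + truth$background)
}

#' Generate a synthetic IP/input ChIP-seq dataset
#'
#' The expected IP signal is depth x multi-site occupancy x roadblock
#' suppressions, smoothed with the triangular fragment kernel, plus a flat
#' background; per-bp counts are drawn from a Poisson law (or negative
#' binomial when `overdispersion` is set). The input track is flat
#' background noise. Bit-identical across runs for a fixed seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with elements `ip` and `input` ([coverage_track()]s),
#'   `expected_ip` (the noise-free mean signal) and `truth`.
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ex <- .expected_ip_signal(truth)
  set.seed(truth$seed)
  n <- length(ex$mean)
  draw <- function(mu) {
    if (is.null(truth$overdispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), size = truth$overdispersion, mu = mu)
    }
  }
  ip <- draw(ex$mean)
  input <- draw(rep(truth$background, n))
  list(
    ip = coverage_track(truth$chrom, truth$window_bp[1L], truth$window_bp[2L],
                        ip),
    input = coverage_track(truth$chrom, truth$window_bp[1L],
                           truth$window_bp[2L], input),
    expected_ip = ex$mean,
    truth = truth
  )
}

#' Barrier variant: one flank truncated by a nucleoprotein complex
#'
#' Emulates a large nucleoprotein complex (e.g. replication-initiator
#' iteron arrays or an rRNA operon) that excludes ParB beyond a barrier
#' coordinate: the chosen flank's occupancy is set to background past the
#' barrier, the other flank is unchanged.
#'
#' @param truth A [synthetic_truth()].
#' @param side `"left"` or `"right"` flank to truncate.
#' @param barrier_bp Genomic coordinate of the barrier; `NULL` means no
#'   barrier (identical to [generate_dataset()]).
#' @return As [generate_dataset()].
#' @export
generate_barrier_variant <- function(truth, side = c("left", "right"),
                                     barrier_bp = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  side <- match.arg(side)
  if (!is.null(barrier_bp)) {
    truth$barrier <- list(side = side, barrier_bp = barrier_bp)
  }
  generate_dataset(truth)
}

#' Write a synthetic dataset to disk
#'
#' bedGraph for the IP and input tracks, BED for parS repeats and
#' roadblocks, and a JSON truth file (parameters, sites, depth, seed).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- dataset$truth
  paths <- c(
    ip = file.path(dir, paste0(prefix, "_ip.bedgraph")),
    input = file.path(dir, paste0(prefix, "_input.bedgraph")),
    sites = file.path(dir, paste0(prefix, "_pars.bed")),
    roadblocks = file.path(dir, paste0(prefix, "_roadblocks.bed")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_bedgraph(dataset$ip, paths[["ip"]])
  write_bedgraph(dataset$input, paths[["input"]])
  writeLines(vapply(seq_along(truth$sites), function(i) {
    s <- truth$sites[[i]]
    sprintf("%s\t%d\t%d\tparS%d\t%g", truth$chrom,
            as.integer(s$repeat_start_bp), as.integer(s$repeat_end_bp), i,
            s$weight)
  }, character(1)), paths[["sites"]])
  writeLines(vapply(seq_along(truth$roadblocks), function(i) {
    rb <- truth$roadblocks[[i]]
    sprintf("%s\t%d\t%d\troadblock%d\t%g", truth$chrom,
            as.integer(rb$start_bp), as.integer(rb$end_bp), i, rb$factor)
  }, character(1)), paths[["roadblocks"]])
  meta <- list(
    params = truth$params[c("sigma_nm", "kuhn_bp", "kappa", "n_total",
                            "enriched_length_bp", "nm_per_bp")],
    sites = lapply(truth$sites, unclass),
    roadblocks = truth$roadblocks,
    depth = truth$depth, background = truth$background,
    fragment_bp = truth$fragment_bp, seed = truth$seed,
    window_bp = truth$window_bp, chrom = truth$chrom
  )
  jsonlite::write_json(meta, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
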