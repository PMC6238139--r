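#' Per-bp coverage track
#'
#' Raw per-bp read counts (IP or input) over a 0-based half-open genomic
#' interval.
#'
#' @param chrom Sequence name.
#' @param start_bp,end_bp 0-based half-open interval.
#' @param counts Non-negative per-bp counts, length `end_bp - start_bp`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, start_bp, end_bp, counts) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  stopifnot(start_bp >= 0, end_bp >= start_bp)
  if (length(counts) != end_bp - start_bp) {
    stop("`counts` length must equal end_bp - start_bp", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(chrom = chrom, start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp), counts = as.numeric(counts)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track %s:%g-%g (%g bp, mean %.2f reads/bp)\n",
              x$chrom, x$start_bp, x$end_bp, x$end_bp - x$start_bp,
              mean(x$counts)))
  invisible(x)
}

#' Read a bedGraph file into a per-bp coverage track
#'
#' Expects the standard 4-column bedGraph (chrom, start, end, value;
#' 0-based half-open). Records are expanded to per-bp counts over the
#' requested window; uncovered positions are 0. Overlapping records,
#' malformed lines and negative coordinates raise an error naming the
#' offending line.
#'
#' @param path bedGraph file path.
#' @param chrom Restrict to this sequence (default: the single sequence
#'   present; an error if several and none specified).
#' @param start_bp,end_bp Window to expand (defaults: the span of the
#'   records).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom = NULL, start_bp = NULL, end_bp = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(coverage_track(chrom %||% "chr", start_bp %||% 0, end_bp %||% 0,
                          numeric(0)))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed bedGraph line %d: fewer than 4 fields", idx[bad[1L]]),
         call. = FALSE)
  }
  ch <- vapply(fields, `[[`, character(1), 1L)
  st <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  va <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- which(is.na(st) | is.na(en) | is.na(va))
  if (length(bad)) {
    stop(sprintf("malformed bedGraph line %d: non-numeric field", idx[bad[1L]]),
         call. = FALSE)
  }
  bad <- which(st < 0 | en <= st)
  if (length(bad)) {
    stop(sprintf("malformed bedGraph line %d: invalid interval", idx[bad[1L]]),
         call. = FALSE)
  }
  if (is.null(chrom)) {
    u <- unique(ch)
    if (length(u) > 1L) {
      stop("bedGraph contains several sequences; pass `chrom`", call. = FALSE)
    }
    chrom <- u
  }
  sel <- ch == chrom
  ch <- ch[sel]; st <- st[sel]; en <- en[sel]; va <- va[sel]; idx <- idx[sel]
  o <- order(st)
  st <- st[o]; en <- en[o]; va <- va[o]; idx <- idx[o]
  if (length(st) > 1L) {
    ov <- which(st[-1L] < en[-length(en)])
    if (length(ov)) {
      stop(sprintf("overlapping bedGraph records at line %d", idx[ov[1L] + 1L]),
           call. = FALSE)
    }
  }
  if (is.null(start_bp)) start_bp <- min(st)
  if (is.null(end_bp)) end_bp <- max(en)
  counts <- numeric(end_bp - start_bp)
  for (i in seq_along(st)) {
    lo <- max(st[i], start_bp); hi <- min(en[i], end_bp)
    if (lo < hi) counts[(lo - start_bp + 1):(hi - start_bp)] <- va[i]
  }
  coverage_track(chrom, start_bp, end_bp, counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coverage track as bedGraph
#'
#' Runs of equal counts are collapsed into single records; zero-count runs
#' are written too, so a write/read roundtrip is lossless.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  n <- length(track$counts)
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0L) {
    r <- rle(track$counts)
    ends <- track$start_bp + cumsum(r$lengths)
    starts <- c(track$start_bp, ends[-length(ends)])
    writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(starts),
                       as.integer(ends), format(r$values, trim = TRUE,
                                                scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read parS repeat (or roadblock) intervals from a BED file
#'
#' Minimal 3+ column BED reader; column 4 (name) and 5 (score, used as the
#' site weight when present) are kept if available.
#'
#' @param path BED file path.
#' @return A data.frame with columns `chrom`, `start_bp`, `end_bp` and
#'   optionally `name`, `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 3L)) stop("malformed BED line", call. = FALSE)
  d <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start_bp = as.numeric(vapply(fields, `[[`, character(1), 2L)),
    end_bp = as.numeric(vapply(fields, `[[`, character(1), 3L))
  )
  if (all(lengths(fields) >= 4L)) d$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(lengths(fields) >= 5L)) {
    d$score <- as.numeric(vapply(fields, `[[`, character(1), 5L))
  }
  d
}

#' Normalize an input track to the IP sequencing depth
#'
#' Cognate IP and input samples are made directly comparable by scaling the
#' input counts by (total IP reads) / (total input reads); the IP track is
#' unchanged.
#'
#' @param ip,input [coverage_track()]s over the same interval.
#' @return The scaled input [coverage_track()].
#' @export
normalize_input <- function(ip, input) {
  stopifnot(inherits(ip, "coverage_track"), inherits(input, "coverage_track"))
  if (ip$start_bp != input$start_bp || ip$end_bp != input$end_bp) {
    stop("IP and input tracks must cover the same interval", call. = FALSE)
  }
  tot_in <- sum(input$counts)
  if (tot_in == 0) stop("input track has zero total reads", call. = FALSE)
  scale <- sum(ip$counts) / tot_in
  coverage_track(input$chrom, input$start_bp, input$end_bp,
                 input$counts * scale)
}

#' Estimate the background read level
#'
#' Median per-bp count outside +/- `exclusion_bp` of the site's cluster
#' centre — distal flanks assumed free of parS-driven enrichment.
#'
#' @param ip A [coverage_track()].
#' @param site A [pars_site()] (genomic coordinates).
#' @param exclusion_bp One-sided exclusion radius, bp (default 25000).
#' @return Background level, reads per bp.
#' @export
estimate_background <- function(ip, site, exclusion_bp = 25000) {
  stopifnot(inherits(ip, "coverage_track"), inherits(site, "pars_site"))
  pos <- seq(ip$start_bp, ip$end_bp - 1)
  outside <- abs(pos - site$center_bp) > exclusion_bp
  if (!any(outside)) {
    stop("track does not extend beyond the exclusion zone", call. = FALSE)
  }
  stats::median(ip$counts[outside])
}

#' Build a normalized decay profile from an IP track
#'
#' Subtracts the background (clamping at zero), then normalizes to 1 at the
#' anchor — by default the first bp downstream of the parS repeat interval
#' on the chosen side — with offsets measured from the anchor and
#' increasing away from parS.
#'
#' @param ip A [coverage_track()].
#' @param site A [pars_site()] in the track's coordinates.
#' @param background Per-bp background level to subtract (see
#'   [estimate_background()]).
#' @param side `"right"` or `"left"` flank of parS.
#' @param anchor_convention `"downstream"`: first bp past the repeat
#'   interval (default); `"last_repeat_bp"`: the last bp of the repeat
#'   interval itself (the two differ by 1 bp).
#' @return A normalized [binding_profile()] (offset 0 at the anchor).
#' @export
make_decay_profile <- function(ip, site, background = 0,
                               side = c("right", "left"),
                               anchor_convention = c("downstream",
                                                     "last_repeat_bp")) {
  stopifnot(inherits(ip, "coverage_track"), inherits(site, "pars_site"))
  side <- match.arg(side)
  anchor_convention <- match.arg(anchor_convention)
  anchor <- switch(side,
    right = if (anchor_convention == "downstream") site$repeat_end_bp
            else site$repeat_end_bp - 1,
    left  = if (anchor_convention == "downstream") site$repeat_start_bp - 1
            else site$repeat_start_bp
  )
  if (anchor < ip$start_bp || anchor >= ip$end_bp) {
    stop("anchor falls outside the coverage track", call. = FALSE)
  }
  pos <- if (side == "right") seq(anchor, ip$end_bp - 1)
         else seq(anchor, ip$start_bp, by = -1)
  vals <- pmax(0, ip$counts[pos - ip$start_bp + 1] - background)
  if (vals[1L] <= 0) {
    stop("anchor value does not exceed the background; cannot normalize",
         call. = FALSE)
  }
  binding_profile(offsets_bp = abs(pos - anchor), density = vals / vals[1L],
                  anchor_bp = anchor, normalized = TRUE, chrom = ip$chrom)
}

#' Least-squares amplitude rescaling factor
#'
#' The scalar c > 0 minimizing sum over the window of
#' (c * target - reference)^2, i.e. c = sum(t r) / sum(t^2) — the
#' reproducible analogue of manually rescaling curves to overlap with the
#' highest-amplitude profile.
#'
#' @param target,reference [binding_profile()]s sharing offsets in the
#'   window.
#' @param window_bp Length-2 offset range (default the common span).
#' @return The scale factor c.
#' @export
rescale_overlap <- function(target, reference, window_bp = NULL) {
  stopifnot(inherits(target, "binding_profile"),
            inherits(reference, "binding_profile"))
  common <- intersect(target$offsets_bp, reference$offsets_bp)
  if (!is.null(window_bp)) {
    common <- common[common >= window_bp[1L] & common <= window_bp[2L]]
  }
  if (length(common) == 0L) stop("no common offsets in window", call. = FALSE)
  t <- target$density[match(common, target$offsets_bp)]
  r <- reference$density[match(common, reference$offsets_bp)]
  if (all(t == 0)) stop("target profile is identically zero in the window",
                        call. = FALSE)
  sum(t * r) / sum(t^2)
}

#' Correlation between two density vectors
#'
#' Pearson product-moment correlation computed directly from its defining
#' sum formula,
#' \deqn{r = \frac{\sum (x-\bar x)(y-\bar y)}
#'   {\sqrt{\sum (x-\bar x)^2 \sum (y-\bar y)^2}}.}
#'
#' @param x,y Equal-length numeric vectors (length >= 2, non-zero
#'   variance).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) stop("zero variance in `x` or `y`", call. = FALSE)
  sum(dx * dy) / den
}

#' Detect occupancy dips relative to the model prediction
#'
#' Flags maximal runs of offsets where the observed/model density ratio
#' falls below `depth_threshold`, keeping only runs at least
#' `min_width_bp` wide — candidate roadblock loci (promoter-bound
#' complexes, iterons) that locally exclude ParB.
#'
#' @param profile A normalized [binding_profile()].
#' @param params A [model_params()] giving the model curve
#'   (`nc_density` at the profile offsets, normalized at the anchor).
#' @param depth_threshold Ratio below which a position is in a dip
#'   (default 0.5).
#' @param min_width_bp Minimum dip width, bp (default 50).
#' @return A data.frame with columns `start_offset_bp`, `end_offset_bp`
#'   (half-open, in profile offsets) and `min_ratio`; zero rows when no
#'   dip qualifies.
#' @export
detect_dips <- function(profile, params, depth_threshold = 0.5,
                        min_width_bp = 50) {
  stopifnot(inherits(profile, "binding_profile"),
            inherits(params, "model_params"))
  model <- nc_density(abs(profile$offsets_bp), params)
  model <- model / model[which.min(abs(profile$offsets_bp))]
  ratio <- profile$density / model
  below <- depth_threshold > 0 & ratio < depth_threshold
  out <- data.frame(start_offset_bp = numeric(0), end_offset_bp = numeric(0),
                    min_ratio = numeric(0))
  if (!any(below)) return(out)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  spacing <- if (length(profile$offsets_bp) > 1L) {
    stats::median(diff(profile$offsets_bp))
  } else 1
  for (j in which(r$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    width <- profile$offsets_bp[i2] - profile$offsets_bp[i1] + spacing
    if (width >= min_width_bp) {
      out <- rbind(out, data.frame(
        start_offset_bp = profile$offsets_bp[i1],
        end_offset_bp = profile$offsets_bp[i2] + spacing,
        min_ratio = min(ratio[i1:i2])))
    }
  }
  out
}
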