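#' Normalized binding profile
#'
#' Per-bp (or per-monomer) ParB density as a function of signed genomic
#' offset from an anchor coordinate. When `normalized` is `TRUE` the density
#' at the offset closest to 0 is 1.
#'
#' @param offsets_bp Strictly increasing signed genomic offsets from the
#'   anchor, bp.
#' @param density Non-negative dimensionless occupancy, same length as
#'   `offsets_bp`.
#' @param anchor_bp Genomic coordinate of the normalization point (offset 0).
#' @param normalized Logical flag; if `TRUE` the density at the offset
#'   closest to 0 must equal 1 (within floating tolerance).
#' @param chrom Optional sequence name; attaching one allows bedGraph export.
#'
#' @return An object of class `binding_profile`.
#' @export
binding_profile <- function(offsets_bp, density, anchor_bp = 0,
                            normalized = FALSE, chrom = NULL) {
  stopifnot(is.numeric(offsets_bp), is.numeric(density),
            length(offsets_bp) == length(density))
  if (length(offsets_bp) > 1L && any(diff(offsets_bp) <= 0)) {
    stop("`offsets_bp` must be strictly increasing", call. = FALSE)
  }
  if (any(density < 0)) {
    stop("`density` must be non-negative", call. = FALSE)
  }
  if (isTRUE(normalized)) {
    i0 <- which.min(abs(offsets_bp))
    if (abs(density[i0] - 1) > 1e-8) {
      stop("normalized profile must have density 1 at the offset closest to 0",
           call. = FALSE)
    }
  }
  structure(
    list(offsets_bp = as.numeric(offsets_bp),
         density = as.numeric(density),
         anchor_bp = as.numeric(anchor_bp),
         normalized = isTRUE(normalized),
         chrom = chrom),
    class = "binding_profile"
  )
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("Binding profile: %d points, offsets %g..%g bp, anchor at %g%s\n",
              length(x$offsets_bp), min(x$offsets_bp), max(x$offsets_bp),
              x$anchor_bp,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @export
as.data.frame.binding_profile <- function(x, ...) {
  data.frame(offset_bp = x$offsets_bp, density = x$density)
}

#' Write a binding profile as two-column TSV
#'
#' Columns `offset_bp` and `density`.
#'
#' @param profile A [binding_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "binding_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding profile from two-column TSV
#'
#' @param path TSV with columns `offset_bp` and `density`.
#' @param anchor_bp,normalized,chrom Passed to [binding_profile()].
#' @return A [binding_profile()].
#' @export
read_profile_tsv <- function(path, anchor_bp = 0, normalized = FALSE,
                             chrom = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  binding_profile(d$offset_bp, d$density, anchor_bp = anchor_bp,
                  normalized = normalized, chrom = chrom)
}

#' Convert a profile with genomic coordinates to a coverage track
#'
#' Only possible when a sequence name is attached and offsets are
#' consecutive integers; used for bedGraph export of model profiles.
#'
#' @param profile A [binding_profile()] with non-`NULL` `chrom`.
#' @return A [coverage_track()].
#' @export
profile_to_track <- function(profile) {
  stopifnot(inherits(profile, "binding_profile"))
  if (is.null(profile$chrom)) {
    stop("profile has no sequence name attached", call. = FALSE)
  }
  if (length(profile$offsets_bp) > 1L && any(diff(profile$offsets_bp) != 1)) {
    stop("profile offsets must be consecutive integers for track export",
         call. = FALSE)
  }
  start <- profile$anchor_bp + profile$offsets_bp[1L]
  coverage_track(profile$chrom, start, start + length(profile$density),
                 profile$density)
}
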