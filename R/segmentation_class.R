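#' Construct a Segmentation
#'
#' An exhaustive partition of the chromosome into contiguous,
#' non-overlapping topological domains. Internally, domains are
#' inclusive 1-based bin ranges `[s, e]`; file output is 0-based
#' half-open bp (BED).
#'
#' @param starts,ends integer vectors of domain start/end bins
#'   (1-based, inclusive), in genome order.
#' @param n_bins total bin count; the domains must tile `1..n_bins`.
#' @param chrom chromosome label.
#' @param resolution bin size in bp.
#' @return an object of class `Segmentation`.
#' @export
segmentation <- function(starts, ends, n_bins, chrom = "chr1",
                         resolution = 40000L) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) == length(ends), length(starts) >= 1)
  if (starts[1] != 1L || ends[length(ends)] != n_bins ||
      any(starts > ends) ||
      (length(starts) > 1 &&
       any(starts[-1] != ends[-length(ends)] + 1L)))
    stop("domains must tile bins 1..", n_bins,
         " contiguously and without overlap")
  structure(
    list(starts = starts, ends = ends, n_bins = as.integer(n_bins),
         chrom = as.character(chrom), resolution = as.integer(resolution)),
    class = "Segmentation")
}

#' Number of domains in a Segmentation
#' @param seg a `Segmentation`.
#' @export
n_domains <- function(seg) length(seg$starts)

#' Per-bin domain index
#' @param seg a `Segmentation`.
#' @return integer vector mapping each bin to its domain (1..n_domains).
#' @export
domain_ids <- function(seg) {
  rep(seq_along(seg$starts), seg$ends - seg$starts + 1L)
}

#' @export
print.Segmentation <- function(x, ...) {
  len <- x$ends - x$starts + 1L
  cat(sprintf(
    "Segmentation: %s, %d domains over %d bins (sizes %d-%d, median %.0f)\n",
    x$chrom, n_domains(x), x$n_bins, min(len), max(len),
    stats::median(len)))
  invisible(x)
}

#' Build a Segmentation from boundary positions
#'
#' @param boundaries bins after which a domain ends (subset of
#'   `1..n_bins-1`), possibly empty.
#' @inheritParams segmentation
#' @export
segmentation_from_boundaries <- function(boundaries, n_bins,
                                         chrom = "chr1",
                                         resolution = 40000L) {
  b <- sort(unique(as.integer(boundaries)))
  b <- b[b >= 1 & b < n_bins]
  starts <- c(1L, b + 1L)
  ends <- c(b, as.integer(n_bins))
  segmentation(starts, ends, n_bins, chrom, resolution)
}
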