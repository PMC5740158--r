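#' Construct a ContactMatrix
#'
#' Container for a normalized, symmetric, single-chromosome Hi-C contact
#' map at fixed bin resolution, together with a per-bin validity mask.
#' Bins whose marginal (row sum) is zero are marked invalid and excluded
#' from every downstream estimation, score, fit and test.
#'
#' @param counts numeric n x n matrix of non-negative interaction counts.
#'   Normalized (non-integer) values are accepted. An asymmetric input is
#'   symmetrized as (M + t(M))/2 with a warning; NA entries are set to 0.
#' @param chrom chromosome label.
#' @param resolution bin size in bp.
#' @param valid optional logical vector of length n; defaults to
#'   `rowSums(counts) > 0`.
#' @return an object of class `ContactMatrix`: a list with elements
#'   `chrom`, `resolution`, `counts`, `valid`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", resolution = 40000L,
                           valid = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("contact matrix must be square, got ", nrow(counts), " x ",
         ncol(counts))
  storage.mode(counts) <- "double"
  if (anyNA(counts)) counts[is.na(counts)] <- 0
  if (any(counts < 0))
    stop("contact matrix contains negative entries")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    warning("input matrix is not symmetric; symmetrizing as (M + t(M))/2")
    counts <- (counts + t(counts)) / 2
  }
  n <- nrow(counts)
  if (is.null(valid)) {
    valid <- rowSums(counts) > 0
  } else {
    valid <- as.logical(valid)
    stopifnot(length(valid) == n)
    valid <- valid & rowSums(counts) > 0
  }
  dimnames(counts) <- NULL
  structure(
    list(chrom = as.character(chrom), resolution = as.integer(resolution),
         counts = counts, valid = valid),
    class = "ContactMatrix")
}

#' Number of bins of a ContactMatrix
#' @param cm a `ContactMatrix`.
#' @return integer bin count.
#' @export
n_bins <- function(cm) nrow(cm$counts)

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %d bp (%d valid), total %.4g\n",
              x$chrom, n_bins(x), x$resolution, sum(x$valid),
              sum(x$counts)))
  invisible(x)
}

#' Read a dense whitespace-delimited Hi-C matrix
#'
#' @param path file with an n x n whitespace-delimited numeric grid.
#' @inheritParams contact_matrix
#' @return a `ContactMatrix`. Asymmetric inputs are symmetrized with a
#'   warning; rows/columns that are entirely zero are marked invalid.
#' @export
read_dense_matrix <- function(path, chrom = "chr1", resolution = 40000L) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  if (nrow(m) != ncol(m))
    stop("dense matrix in '", path, "' is not square (",
         nrow(m), " x ", ncol(m), ")")
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Read a sparse-triplet Hi-C matrix
#'
#' Lines are `i j value` with 0-based bin indices; upper or lower
#' triangle (or both) is accepted, duplicates are summed and the mirror
#' cell is filled.
#'
#' @inheritParams read_dense_matrix
#' @param n_bins number of bins of the chromosome segment.
#' @return a `ContactMatrix`.
#' @export
read_sparse_triplets <- function(path, chrom = "chr1", resolution = 40000L,
                                 n_bins) {
  n <- as.integer(n_bins)
  counts <- matrix(0, n, n)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    trip <- utils::read.table(path, header = FALSE,
                              col.names = c("i", "j", "value"))
    if (nrow(trip)) {
      if (any(trip$i < 0 | trip$j < 0 | trip$i >= n | trip$j >= n))
        stop("triplet bin index out of range [0, ", n - 1, "]")
      if (any(trip$value < 0)) stop("negative triplet value")
      # 0-based on disk -> 1-based internally; accumulate duplicates
      lo <- pmin(trip$i, trip$j) + 1L
      hi <- pmax(trip$i, trip$j) + 1L
      key <- paste(lo, hi)
      agg <- rowsum(trip$value, key)
      kk <- strsplit(rownames(agg), " ", fixed = TRUE)
      ii <- vapply(kk, function(x) as.integer(x[1]), integer(1))
      jj <- vapply(kk, function(x) as.integer(x[2]), integer(1))
      counts[cbind(ii, jj)] <- agg[, 1]
      counts[cbind(jj, ii)] <- agg[, 1]
    }
  }
  contact_matrix(counts, chrom = chrom, resolution = resolution)
}

#' Write a ContactMatrix as dense text
#' @param cm a `ContactMatrix`.
#' @param path output file.
#' @export
write_dense_matrix <- function(cm, path) {
  utils::write.table(format(cm$counts, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Aggregate a ContactMatrix to a coarser resolution
#'
#' Sum-aggregation rebinning: each `factor` x `factor` block of bins is
#' summed into one coarse bin (the convention used when down-sampling
#' high-resolution maps for higher per-cell coverage).
#'
#' @param cm a `ContactMatrix`.
#' @param factor integer number of fine bins per coarse bin.
#' @return a `ContactMatrix` at `resolution * factor`.
#' @export
rebin_matrix <- function(cm, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(cm)
  n <- n_bins(cm)
  nc <- ceiling(n / factor)
  grp <- rep(seq_len(nc), each = factor)[seq_len(n)]
  agg <- rowsum(t(rowsum(cm$counts, grp)), grp)
  contact_matrix(agg, chrom = cm$chrom,
                 resolution = cm$resolution * factor)
}
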