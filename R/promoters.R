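#' Construct a PromoterSet
#'
#' Promoter/TSS annotation used to anchor virtual-4C profiles and
#' enrichment tests. Strand is carried but ignored by the caller (only
#' the promoter locus matters). A gene may appear with several distinct
#' TSS positions (each is tested separately); exact duplicate
#' (gene, position) entries are rejected.
#'
#' @param gene character gene ids.
#' @param chrom chromosome labels.
#' @param position TSS positions in bp (0-based).
#' @param strand "+", "-" or "." (optional).
#' @param resolution bin size in bp used to derive the TSS bin index.
#' @param n_bins number of bins of the chromosome segment; positions
#'   outside `[0, n_bins * resolution)` are an error.
#' @return data.frame of class `PromoterSet` with columns `gene`,
#'   `chrom`, `position`, `strand`, `bin` (1-based bin index).
#' @export
promoter_set <- function(gene, chrom, position, strand = NULL,
                         resolution, n_bins) {
  gene <- as.character(gene)
  position <- as.numeric(position)
  if (is.null(strand)) strand <- rep(".", length(gene))
  if (anyDuplicated(paste(gene, position)))
    stop("duplicate (gene, position) promoter entries")
  if (any(position < 0 | position >= n_bins * resolution))
    stop("TSS position outside chromosome extent")
  ps <- data.frame(gene = gene, chrom = as.character(chrom),
                   position = position, strand = as.character(strand),
                   bin = floor(position / resolution) + 1L,
                   stringsAsFactors = FALSE)
  class(ps) <- c("PromoterSet", "data.frame")
  ps
}

#' Read a promoter annotation (BED or TSV)
#'
#' BED: `chrom start end name [score strand]` (TSS taken as the interval
#' start). TSV: `gene chrom position strand` with or without a header.
#'
#' @param path annotation file.
#' @param format "auto", "bed" or "tsv".
#' @inheritParams promoter_set
#' @return a `PromoterSet`.
#' @export
read_promoters <- function(path, resolution, n_bins, format = "auto") {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t| +")[[1]]
  if (format == "auto") {
    format <- if (grepl("^(chr|[0-9XY])", fields[1]) &&
                  !is.na(suppressWarnings(as.numeric(fields[2]))))
      "bed" else "tsv"
  }
  if (format == "bed") {
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE)
    promoter_set(gene = tab[[4]], chrom = tab[[1]], position = tab[[2]],
                 strand = if (ncol(tab) >= 6) tab[[6]] else NULL,
                 resolution = resolution, n_bins = n_bins)
  } else {
    has_header <- is.na(suppressWarnings(as.numeric(fields[3])))
    tab <- utils::read.table(path, header = has_header, sep = "",
                             stringsAsFactors = FALSE)
    names(tab)[1:3] <- c("gene", "chrom", "position")
    promoter_set(gene = tab$gene, chrom = tab$chrom,
                 position = tab$position,
                 strand = if (ncol(tab) >= 4) tab[[4]] else NULL,
                 resolution = resolution, n_bins = n_bins)
  }
}
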