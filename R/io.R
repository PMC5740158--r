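# Writers/readers for domains (BED), interaction calls (BEDPE),
# mixture-model parameter tables (TSV) and merge forests (JSON).
# All genomic file output is 0-based half-open bp.

fmt_num <- function(x) {
  # locale-independent, round-trip-stable numeric formatting
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write domains (and optionally merged regions) as BED
#'
#' One row per region: `chrom start end name level`. Leaf TADs carry
#' level 0; when a `MergeForest` is supplied, every merged span is also
#' written with its hierarchical merge level (1 for a merge of two
#' leaves, etc.) in the score column.
#'
#' @param seg a `Segmentation`.
#' @param path output file.
#' @param forest optional `MergeForest` from [build_hierarchy()].
#' @export
write_domains_bed <- function(seg, path, forest = NULL) {
  res <- seg$resolution
  rows <- data.frame(chrom = seg$chrom,
                     start = (seg$starts - 1L) * res,
                     end = seg$ends * res,
                     name = sprintf("TAD_%d", seq_along(seg$starts)),
                     level = 0L)
  if (!is.null(forest)) {
    for (nd in forest$nodes) {
      if (nd$level == 0L) next
      rows <- rbind(rows, data.frame(
        chrom = seg$chrom, start = (nd$s - 1L) * res, end = nd$e * res,
        name = sprintf("MERGE_%d", nd$id), level = nd$level))
    }
  }
  utils::write.table(rows, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a domain BED file back into a Segmentation
#'
#' Only level-0 rows (or all rows of a plain 3+ column BED without a
#' level column) are used. Interval edges are snapped to bins; the
#' unique internal edges become domain boundaries, so a non-exhaustive
#' BED still yields a valid exhaustive partition (gaps become domains).
#'
#' @param path BED file.
#' @inheritParams segmentation
#' @export
read_domains_bed <- function(path, n_bins, resolution, chrom = "chr1") {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) >= 5) tab <- tab[tab[[5]] == 0, , drop = FALSE]
  edges <- sort(unique(c(tab[[2]], tab[[3]])))
  b <- unique(round(edges / resolution))
  b <- b[b >= 1 & b < n_bins]
  segmentation_from_boundaries(b, n_bins, chrom, resolution)
}

#' Write promoter-enhancer interaction calls as BEDPE
#'
#' One row per call: both anchors as 0-based half-open bins, then gene
#' id, residual, p and q (>= 6 significant digits, round-trip stable).
#' An empty call set yields a header-only file.
#'
#' @param calls data.frame from [call_interactions()].
#' @param path output file.
#' @param resolution bin size in bp.
#' @param chrom chromosome label.
#' @export
write_interactions_bedpe <- function(calls, path, resolution,
                                     chrom = "chr1") {
  header <- paste("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "gene", "residual", "p", "q", "same_tad",
                  "same_first_merge", sep = "\t")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  if (!is.null(calls) && nrow(calls)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t%s\t%s\t%d\t%d",
                     chrom,
                     (calls$promoter_bin - 1L) * resolution,
                     calls$promoter_bin * resolution,
                     chrom,
                     (calls$enhancer_bin - 1L) * resolution,
                     calls$enhancer_bin * resolution,
                     calls$gene, fmt_num(calls$residual),
                     fmt_num(calls$p), fmt_num(calls$q),
                     as.integer(calls$same_tad),
                     as.integer(calls$same_first_merge))
    writeLines(lines, con)
  }
  invisible(NULL)
}

#' Read a BEDPE call file written by [write_interactions_bedpe()]
#' @param path BEDPE file.
#' @param resolution bin size in bp.
#' @return data.frame of calls (1-based bins), empty if header-only.
#' @export
read_interactions_bedpe <- function(path, resolution) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(gene = character(), promoter_bin = integer(),
                      enhancer_bin = integer(), residual = numeric(),
                      p = numeric(), q = numeric(),
                      same_tad = logical(), same_first_merge = logical()))
  tab <- utils::read.table(text = lines, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(gene = tab[[7]],
             promoter_bin = tab[[2]] %/% resolution + 1L,
             enhancer_bin = tab[[5]] %/% resolution + 1L,
             residual = tab[[8]], p = tab[[9]], q = tab[[10]],
             same_tad = tab[[11]] == 1, same_first_merge = tab[[12]] == 1,
             stringsAsFactors = FALSE)
}

#' Serialize a DistanceMixtureModel to TSV (7 columns)
#' @param model a `DistanceMixtureModel`.
#' @param path output file.
#' @export
write_mixture_tsv <- function(model, path) {
  tab <- model$params
  out <- data.frame(d = tab$d, lapply(tab[-1], fmt_num))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pseudocount=%s h=%d", fmt_num(model$pseudocount),
                     model$h), con)
  suppressWarnings(utils::write.table(out, con, quote = FALSE, sep = "\t",
                                      row.names = FALSE))
  invisible(NULL)
}

#' Read a DistanceMixtureModel from TSV
#' @param path TSV written by [write_mixture_tsv()].
#' @export
read_mixture_tsv <- function(path) {
  meta <- readLines(path, n = 1L)
  pc <- as.numeric(sub(".*pseudocount=([^ ]+).*", "\\1", meta))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  mixture_model(tab, pseudocount = pc)
}

#' Serialize a MergeForest to JSON
#' @param forest a `MergeForest`.
#' @param path output file.
#' @export
write_forest_json <- function(forest, path) {
  nodes <- lapply(forest$nodes, function(nd) {
    list(id = nd$id, span = c(nd$s, nd$e), level = nd$level,
         alpha = if (is.null(nd$alpha)) NULL else nd$alpha,
         alpha_raw = if (is.null(nd$alpha_raw)) NULL else nd$alpha_raw,
         children = if (length(nd$children)) nd$children else NULL)
  })
  jsonlite::write_json(list(n_bins = forest$n_bins, roots = forest$roots,
                            nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(NULL)
}
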