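# Pipeline orchestration: fit-model -> segment -> hierarchy ->
# background -> call, each stage also usable standalone.

#' Default run configuration
#'
#' All tunables of the pipeline with their default values: horizon
#' h = 5 Mb, minimal domain size 3 bins, pseudocount 1, LPR clip 50,
#' insulation initializer (window 10 bins), EM off, maximal merge
#' span 5 Mb, no minimal merge alpha, FDR threshold 1e-2, test window
#' +/- 1 Mb, fit window +/- 2 Mb.
#'
#' @param resolution bin size in bp (used to convert bp settings).
#' @param ... overrides of any listed field.
#' @return named list of class `RunConfig`.
#' @export
default_config <- function(resolution = 40000L, ...) {
  cfg <- list(resolution = as.integer(resolution),
              h_bp = 5e6, min_tad_bins = 3L, pseudocount = 1,
              lpr_clip = 50,
              initializer = "insulation", window_bins = 10L,
              init_seed = 1L,
              em = FALSE, em_max_iter = 10L,
              max_merge_bp = 5e6, min_alpha = 0,
              fdr = 0.01, test_window_bp = 1e6, fit_window_bp = 2e6,
              min_fit_cells = 30L, min_dist_bins = 2L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

h_bins <- function(cfg) max(1L, floor(cfg$h_bp / cfg$resolution))

#' Fit the mixture model stage
#' @param cm a `ContactMatrix`.
#' @param init initial `Segmentation` (from
#'   [initialize_segmentation()], a BED file, or
#'   [random_segmentation()]).
#' @param cfg a `RunConfig`.
#' @export
stage_fit_model <- function(cm, init, cfg) {
  estimate_mixture(cm, init, h_bins(cfg), cfg$pseudocount)
}

#' Segmentation stage (optionally EM-refined)
#' @inheritParams stage_fit_model
#' @param model a `DistanceMixtureModel`.
#' @param init initial segmentation (needed when `cfg$em` is TRUE).
#' @return list with `segmentation`, `score`, `model` (re-estimated
#'   when EM is on), `em_iterations`.
#' @export
stage_segment <- function(cm, model, cfg, init = NULL) {
  if (isTRUE(cfg$em)) {
    stopifnot(!is.null(init))
    em <- em_refine(cm, init, h_bins(cfg), cfg$pseudocount,
                    cfg$em_max_iter, cfg$min_tad_bins, cfg$lpr_clip)
    lm_ <- lpr_matrix(cm, em$model, cfg$lpr_clip)
    list(segmentation = em$segmentation,
         score = sum(vapply(seq_len(n_domains(em$segmentation)),
                            function(k) tad_score(
                              lm_, em$segmentation$starts[k],
                              em$segmentation$ends[k], h_bins(cfg)),
                            numeric(1))),
         model = em$model, em_iterations = em$iterations)
  } else {
    lm_ <- lpr_matrix(cm, model, cfg$lpr_clip)
    fit <- optimal_segmentation(lm_, h_bins(cfg), cfg$min_tad_bins,
                                cm$chrom, cm$resolution)
    list(segmentation = fit$segmentation, score = fit$score,
         model = model, em_iterations = 0L)
  }
}

#' Hierarchy stage
#' @inheritParams stage_fit_model
#' @param seg the leaf `Segmentation`.
#' @export
stage_hierarchy <- function(cm, seg, cfg) {
  build_hierarchy(cm, seg,
                  max_merge_bins = max(1L, floor(cfg$max_merge_bp /
                                                   cfg$resolution)),
                  h = h_bins(cfg), min_alpha = cfg$min_alpha)
}

#' Background-model stage
#' @inheritParams stage_hierarchy
#' @param forest a `MergeForest`.
#' @export
stage_background <- function(cm, forest, cfg) {
  build_background(cm, forest, h_bins(cfg), cfg$pseudocount)
}

#' Interaction-calling stage
#' @inheritParams stage_background
#' @param bg a `BackgroundModel`.
#' @param promoters a `PromoterSet`.
#' @export
stage_call <- function(cm, bg, forest, promoters, cfg) {
  call_interactions(cm, bg, forest, promoters,
                    fdr_threshold = cfg$fdr,
                    test_window_bp = cfg$test_window_bp,
                    fit_window_bp = cfg$fit_window_bp,
                    min_fit_cells = cfg$min_fit_cells,
                    min_dist_bins = cfg$min_dist_bins)
}

.initial_segmentation <- function(cm, cfg, init_bed = NULL) {
  if (!is.null(init_bed))
    return(read_domains_bed(init_bed, n_bins(cm), cm$resolution,
                            cm$chrom))
  switch(cfg$initializer,
         insulation = initialize_segmentation(cm, cfg$window_bins,
                                              cfg$min_tad_bins),
         random = random_segmentation(cm, min_tad_bins = cfg$min_tad_bins,
                                      seed = cfg$init_seed),
         stop("unknown initializer '", cfg$initializer, "'"))
}

#' Run the full pipeline
#'
#' fit-model, segment (optionally with EM), hierarchy, background and
#' call, in order; optionally writing all artifacts (mixture TSV,
#' domain BED, forest JSON, call BEDPE/TSV, resolved config and run
#' summary JSON) to `outdir`. Identical inputs and configuration give
#' byte-identical artifacts.
#'
#' @param cm a `ContactMatrix`.
#' @param promoters a `PromoterSet` (or `NULL` to stop after the
#'   background stage).
#' @param cfg a `RunConfig`.
#' @param outdir output directory (created), or `NULL` for no files.
#' @param init_bed optional BED file with the initial segmentation.
#' @return list with `model`, `segmentation`, `score`, `forest`,
#'   `background`, `calls`, `summary`.
#' @export
run_pipeline <- function(cm, promoters = NULL, cfg = default_config(),
                         outdir = NULL, init_bed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  init <- .initial_segmentation(cm, cfg, init_bed)
  model <- stage_fit_model(cm, init, cfg)
  segres <- stage_segment(cm, model, cfg, init = init)
  seg <- segres$segmentation
  forest <- stage_hierarchy(cm, seg, cfg)
  bg <- stage_background(cm, forest, cfg)
  calls <- if (!is.null(promoters))
    stage_call(cm, bg, forest, promoters, cfg) else NULL
  lv <- vapply(forest$nodes, `[[`, integer(1), "level")
  summary <- list(
    chrom = cm$chrom, n_bins = n_bins(cm), n_valid = sum(cm$valid),
    n_domains = n_domains(seg), segmentation_score = segres$score,
    em_iterations = segres$em_iterations,
    n_merges = sum(lv > 0), max_merge_level = max(lv),
    n_promoters = if (is.null(promoters)) 0L else nrow(promoters),
    n_tests = if (is.null(calls)) 0L else attr(calls, "n_tests"),
    n_skipped_promoters = if (is.null(calls)) 0L else
      nrow(attr(calls, "skipped")),
    n_calls = if (is.null(calls)) 0L else nrow(calls),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_mixture_tsv(segres$model, file.path(outdir, "model.tsv"))
    write_domains_bed(seg, file.path(outdir, "domains.bed"), forest)
    write_forest_json(forest, file.path(outdir, "forest.json"))
    if (!is.null(calls))
      write_interactions_bedpe(calls, file.path(outdir, "calls.bedpe"),
                               cm$resolution, cm$chrom)
    jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(summary[names(summary) != "elapsed_s"],
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = segres$model, segmentation = seg, score = segres$score,
       forest = forest, background = bg, calls = calls,
       summary = summary)
}
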