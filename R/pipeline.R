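#' Configuration for the end-to-end screening pipeline
#'
#' Collects every tunable constant of the analysis chain in one validated
#' object: binning, detection and filtering thresholds, the synthetic
#' healthy cohort, the tumor cohort, and the power-analysis axes.
#'
#' @param bin_size Bin width in bp (default 10 kb).
#' @param read_length Read length in bp (default 100).
#' @param grid_size Profile grid segment size, 5 Mb or 100 Mb (must be a
#'   multiple of `bin_size`).
#' @param p_threshold Detection p-value threshold (default 0.01).
#' @param af_threshold Germline allele-frequency threshold (default 0.01).
#' @param mcd_distance_threshold Outlier masking distance (default 15).
#' @param loess_span GC-correction smoother span.
#' @param seed Master seed; stage seeds are derived from it.
#' @param healthy [healthy_sim_params()] for the donor simulation.
#' @param cohort_types Cancer type labels for the tumor cohort (a "normal"
#'   class is always added).
#' @param n_per_type Samples per cancer type (and for normal).
#' @param events_per_type Signature segments per type.
#' @param signature_delta Copy change at signature segments.
#' @param passenger_rate Random passenger events per tumor sample.
#' @param n_germline Germline resource size.
#' @param depths,fractions,copy_deltas Power-analysis axes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_size = 1e4,
                            read_length = 100,
                            grid_size = 5e6,
                            p_threshold = 0.01,
                            af_threshold = 0.01,
                            mcd_distance_threshold = 15,
                            loess_span = 0.3,
                            seed = 1,
                            healthy = healthy_sim_params(n_bins = 20000,
                                                         n_samples = 6),
                            cohort_types = c("typeA", "typeB", "typeC", "typeD"),
                            n_per_type = 20,
                            events_per_type = 2,
                            signature_delta = 2,
                            passenger_rate = 1,
                            n_germline = 50,
                            depths = c(0.3, 1, 3, 10, 30),
                            fractions = c(0.001, 0.005, 0.01, 0.05, 0.1),
                            copy_deltas = c(1, 4)) {
  stopifnot(bin_size > 0, read_length > 0, p_threshold > 0, af_threshold > 0,
            mcd_distance_threshold > 0)
  if (grid_size %% bin_size != 0) {
    stop("grid_size must be a multiple of bin_size", call. = FALSE)
  }
  structure(
    list(bin_size = bin_size, read_length = read_length, grid_size = grid_size,
         p_threshold = p_threshold, af_threshold = af_threshold,
         mcd_distance_threshold = mcd_distance_threshold,
         loess_span = loess_span, seed = seed, healthy = healthy,
         cohort_types = cohort_types, n_per_type = n_per_type,
         events_per_type = events_per_type, signature_delta = signature_delta,
         passenger_rate = passenger_rate, n_germline = n_germline,
         depths = depths, fractions = fractions, copy_deltas = copy_deltas),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full in-silico screening pipeline
#'
#' Chains every stage on synthetic inputs: healthy-donor bin counts ->
#' outlier masking -> GC correction -> count-model fit and goodness of fit
#' -> limit-of-detection grid; tumor cohort + germline resource ->
#' detectable copy profiles -> KNN and random-forest classification with
#' metric, ROC and misclassification-similarity reports. All artifacts are
#' written to `out_dir` as TSV/JSON plus a run log recording every
#' parameter; outputs are deterministic for a fixed config seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  log_lines <- c(sprintf("ctdnascreen pipeline, master seed %d", config$seed))
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # -- healthy cfDNA model ---------------------------------------------
  tbl <- stage("simulate-healthy",
               sim_healthy_bins(config$healthy, seed = config$seed))
  write_bincounts(tbl, pth("bincounts.tsv"))
  tbl <- stage("preprocess", {
    t2 <- mask_outlier_bins(tbl,
                            distance_threshold = config$mcd_distance_threshold)
    gc_correct(t2, span = config$loess_span)
  })
  logf("masked bins: %d of %d", sum(!tbl$mask), nrow(tbl))
  model <- stage("fit-model",
                 fit_count_model(tbl, bin_size = config$bin_size,
                                 read_length = config$read_length))
  logf("NB fit: m = %.4f, r = %.4f, depth = %.4fx", model$m, model$r,
       model$depth)
  write_model_json(model, pth("model.json"))
  gof <- dplyr::bind_rows(gof_chisq(tbl, model, "nb"),
                          gof_chisq(tbl, model, "poisson"))
  readr::write_tsv(gof, pth("gof.tsv"))

  # -- theoretical limit of detection ----------------------------------
  lod <- stage("power",
               lod_grid(config$depths, config$fractions, config$copy_deltas,
                        model, p_threshold = config$p_threshold))
  readr::write_tsv(lod, pth("lod.tsv"))

  # -- tumor cohort and detectable profiles ----------------------------
  grid <- genome_grid(segment_size = config$grid_size)
  sigs <- separable_signatures(config$cohort_types, grid,
                               events_per_type = config$events_per_type,
                               delta = config$signature_delta,
                               passenger_rate = config$passenger_rate)
  sigs$normal <- cancer_signature("normal")
  n_per <- setNames(rep(config$n_per_type, length(sigs)), names(sigs))
  cohort <- stage("simulate-cohort",
                  sim_tumor_cohort(sigs, n_per, grid, seed = config$seed + 1))
  write_seg(cohort$records, pth("cohort.seg"))
  readr::write_tsv(cohort$labels, pth("labels.tsv"))
  germ <- sim_germline_af(n_events = config$n_germline,
                          seed = config$seed + 2)
  write_germline(germ, pth("germline.bed"))
  profiles <- stage("profile",
                    build_copy_profiles(cohort$records, grid,
                                        af_resource = germ,
                                        af_threshold = config$af_threshold,
                                        sample_ids = cohort$labels$sample_id))
  write_profiles(profiles, pth("profiles_category.tsv"),
                 pth("profiles_avgdev.tsv"))
  det <- cohort_detectable_fraction(profiles, cohort$labels)
  readr::write_tsv(det, pth("detectable_fraction.tsv"))

  # -- classification ---------------------------------------------------
  knn <- stage("classify-knn", knn_loo(profiles, cohort$labels))
  readr::write_tsv(knn$predictions, pth("knn_predictions.tsv"))
  rf <- stage("classify-rf",
              rf_model(profiles, cohort$labels, seed = config$seed + 3))
  readr::write_tsv(rf$metrics$per_class, pth("rf_metrics.tsv"))
  readr::write_tsv(tibble::as_tibble(as.data.frame(rf$confusion)),
                   pth("rf_confusion.tsv"))
  readr::write_tsv(rf$importances, pth("rf_importances.tsv"))
  sim <- misclass_similarity(rf)
  readr::write_tsv(sim$pairs, pth("similarity.tsv"))
  logf("KNN LOO accuracy: %.4f (k = %d)", knn$accuracy, knn$extra$k)
  logf("RF CV accuracy: %.4f +/- %.4f (mtry = %d)", rf$accuracy,
       rf$accuracy_sd, rf$extra$mtry)
  logf("thresholds: p < %g, AF > %g, MCD distance > %g, span %g",
       config$p_threshold, config$af_threshold,
       config$mcd_distance_threshold, config$loess_span)
  writeLines(log_lines, pth("run_log.txt"))

  invisible(setNames(
    file.path(out_dir,
              c("bincounts.tsv", "model.json", "gof.tsv", "lod.tsv",
                "cohort.seg", "labels.tsv", "germline.bed",
                "profiles_category.tsv", "profiles_avgdev.tsv",
                "detectable_fraction.tsv", "knn_predictions.tsv",
                "rf_metrics.tsv", "rf_confusion.tsv", "rf_importances.tsv",
                "similarity.tsv", "run_log.txt")),
    c("bincounts", "model", "gof", "lod", "cohort_seg", "labels", "germline",
      "profiles_category", "profiles_avgdev", "detectable_fraction",
      "knn_predictions", "rf_metrics", "rf_confusion", "rf_importances",
      "similarity", "run_log")))
}
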