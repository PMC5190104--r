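## End-to-end orchestration: simulate -> extract -> distill -> survival,
## with per-stage logging, seeds and a config hash embedded in every output.

#' Assemble a pipeline run configuration
#'
#' One flat configuration object consumed by the `run_*` stages; all
#' defaults mirror the package's standard settings (15 fields per section,
#' 5000-tree forests, 10-fold CART self-test, 1000 permutations, the
#' validated dichotomization cut-offs).
#'
#' @param image_root directory of per-patient field TIFF triplets.
#' @param cohort_csv CSV of patient records (id, time, event, covariates).
#' @param output_dir where stages write their artifacts.
#' @param fields_per_section fields of view per patient section.
#' @param seg a [seg_config()].
#' @param classes a [feature_class_config()].
#' @param cutoffs a [cutoff_config()].
#' @param n_trees,folds,n_sim distillation / cut-point settings.
#' @param seed master seed recorded in all outputs.
#' @return list of class `RunConfig` with a `config_hash` field.
#' @export
run_config <- function(image_root = NULL, cohort_csv = NULL,
                       output_dir = NULL, fields_per_section = 15L,
                       seg = seg_config(), classes = feature_class_config(),
                       cutoffs = cutoff_config(), n_trees = 5000L,
                       folds = 10L, n_sim = 1000L, seed = 1L) {
  cfg <- list(image_root = image_root, cohort_csv = cohort_csv,
              output_dir = output_dir,
              fields_per_section = as.integer(fields_per_section),
              seg = seg, classes = classes, cutoffs = cutoffs,
              n_trees = as.integer(n_trees), folds = as.integer(folds),
              n_sim = as.integer(n_sim), seed = as.integer(seed))
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg[setdiff(names(cfg), "output_dir")], tf,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg$config_hash <- unname(tools::md5sum(tf))
  class(cfg) <- "RunConfig"
  cfg
}

field_ids_of <- function(image_root) {
  fs <- list.files(image_root, pattern = "_dapi\\.tif$")
  if (!length(fs)) stop("no *_dapi.tif files under ", image_root)
  stems <- sub("_dapi\\.tif$", "", fs)
  patient <- sub("_[^_]+$", "", stems)
  field <- sub("^.*_", "", stems)
  split(field, patient)
}

#' Extract the per-patient feature table from field images on disk
#'
#' Reads each patient's TIFF triplets, runs the segmentation hierarchy,
#' classification and feature extraction on every field, and collates the
#' fields into one 123-parameter vector per patient.  A malformed patient
#' (missing channel file, unreadable TIFF) is skipped with a logged reason
#' rather than aborting the cohort run.
#'
#' @param config a [run_config()] with `image_root` set.
#' @param pixel_size_um physical pixel size of the stored rasters.
#' @return list: `features` (data frame, `id` + one column per manifest
#'   entry), `qc` (per-field scalar summaries), `skipped` (named reasons).
#'   Written as CSV under `output_dir` when configured.
#' @export
run_extract <- function(config, pixel_size_um = 0.5) {
  stopifnot(inherits(config, "RunConfig"), !is.null(config$image_root))
  manifest <- manifest_default()
  by_patient <- field_ids_of(config$image_root)
  rows <- list(); qc <- list(); skipped <- list()
  for (p in names(by_patient)) {
    res <- tryCatch({
      vecs <- list()
      for (f in sort(by_patient[[p]])) {
        img <- read_field(config$image_root, p, f, pixel_size_um)
        h <- segment_field(img, config$seg)
        cf <- classify_objects(h, config$classes)
        vecs[[f]] <- extract_field_features(h, cf, img, manifest)
        qc[[paste(p, f, sep = "_")]] <- data.frame(
          patient = p, field = f, n_buds = cf$n_buds, n_pdc = cf$n_pdc,
          n_lvi = cf$n_lvi, n_minimal_lvi = cf$n_minimal_lvi,
          n_vessels = cf$n_vessels, area_pdc_um2 = cf$area_pdc_um2,
          tumor_stroma_pct = cf$tumor_stroma_pct,
          n_no_tissue_nuclei = h$qc$n_no_tissue_nuclei)
      }
      pv <- collate_patient(vecs, manifest)
      cbind(data.frame(id = p), as.data.frame(t(as.numeric(pv))) |>
              stats::setNames(manifest$name))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("run_extract: skipping patient ", p, ": ", conditionMessage(res))
      skipped[[p]] <- conditionMessage(res)
    } else rows[[p]] <- res
  }
  features <- do.call(rbind, rows)
  qc <- do.call(rbind, qc)
  rownames(features) <- rownames(qc) <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features,
                     file.path(config$output_dir, "patient_features.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(config$output_dir, "field_qc.csv"),
                     row.names = FALSE)
  }
  list(features = features, qc = qc, skipped = skipped,
       config_hash = config$config_hash)
}

#' Distill the feature table: RF elimination then CART
#'
#' Runs [rf_iterative_reduce()] on the full feature table, then [cart_fit()]
#' on the surviving subset, and writes the ranking trace, the tree and a
#' metrics report (with seed and config hash) as JSON.
#'
#' @param feature_table data frame with `id` plus feature columns.
#' @param outcomes data frame with `id` and binary `event`.
#' @param config a [run_config()].
#' @return list: `ranking` (`FeatureRanking`), `cart` (`CARTModel`),
#'   `report`.
#' @export
run_distill <- function(feature_table, outcomes, config = run_config()) {
  missing_ids <- setdiff(feature_table$id, outcomes$id)
  extra_ids <- setdiff(outcomes$id, feature_table$id)
  if (length(missing_ids) || length(extra_ids))
    stop("feature table / outcome id mismatch; offenders: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  if (nrow(feature_table) == 0L) stop("empty feature table")
  y <- outcomes$event[match(feature_table$id, outcomes$id)]
  X <- feature_table[, setdiff(names(feature_table), "id"), drop = FALSE]
  keep <- vapply(X, function(col) stats::sd(col) > 0, TRUE)
  X <- X[, keep, drop = FALSE]
  ranking <- rf_iterative_reduce(X, y, cfg = list(
    n_trees = config$n_trees, seed = config$seed))
  cart <- cart_fit(X[, ranking$selected, drop = FALSE], y, cfg = list(
    folds = config$folds, seed = config$seed))
  report <- list(seed = config$seed, config_hash = config$config_hash,
                 n_features_in = ncol(X),
                 n_features_selected = length(ranking$selected),
                 best_oob_auc = ranking$best_auc,
                 root_feature = cart$root_feature,
                 root_threshold = cart$root_threshold,
                 self_test = cart$metrics)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(ranking$trace,
                         file.path(config$output_dir, "rf_ranking_trace.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(cart$tree)),
               file.path(config$output_dir, "cart_tree.txt"))
    jsonlite::write_json(report,
                         file.path(config$output_dir, "distill_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(ranking = ranking, cart = cart, report = report)
}

#' Survival analysis stage: dichotomized KM/Cox tables and the prognostic index
#'
#' Dichotomizes each configured feature at its validated cut-off, computes
#' Kaplan-Meier/log-rank per feature with Benjamini-Hochberg correction
#' across the family, a univariate Cox table, a multivariate
#' backward-elimination model over the significant parameters, and the
#' composite prognostic index with its own KM/Cox summary.
#'
#' @param feature_table data frame with `id` plus feature columns.
#' @param cohort data frame with `id`, `time_months`, `event` and clinical
#'   covariates (`pt_stage`, `differentiation`).
#' @param config a [run_config()].
#' @return list: `km` (per-feature log-rank table with `p_fdr`),
#'   `cox_univariate`, `multivariate` (`CoxBackwardResult`), `npi`
#'   (per-patient groups plus its KM and Cox rows).
#' @export
run_survival <- function(feature_table, cohort, config = run_config()) {
  dat <- merge(cohort, feature_table, by = "id")
  if (sum(dat$event) < 2L) stop("need at least 2 events")
  groups <- dichotomize(dat, config$cutoffs)
  feat <- sub("_group$", "", names(groups))
  km_rows <- list(); cox_rows <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (nlevels(droplevels(g)) < 2L) {
      km_rows[[i]] <- data.frame(feature = feat[i], chisq = NA, p = NA)
      next
    }
    km <- km_logrank(g, dat$time_months, dat$event)
    km_rows[[i]] <- data.frame(feature = feat[i], chisq = km$chisq, p = km$p)
    cx <- cox_univariate(as.integer(g == "high"), dat$time_months, dat$event)
    cox_rows[[i]] <- cbind(feature = feat[i], cx)
  }
  km_tab <- do.call(rbind, km_rows)
  ok <- !is.na(km_tab$p)
  km_tab$p_fdr <- NA_real_
  km_tab$p_fdr[ok] <- bh_adjust(km_tab$p[ok])
  cox_tab <- do.call(rbind, cox_rows)

  ## multivariate backward elimination over significant parameters +
  ## clinical covariates (ordinal codes)
  mv_dat <- data.frame(row.names = seq_len(nrow(dat)))
  sig <- cox_tab$feature[cox_tab$p < 0.05]
  for (f in sig) mv_dat[[f]] <- as.integer(groups[[paste0(f, "_group")]] == "high")
  if ("pt_stage" %in% names(dat))
    mv_dat$pt_stage <- as.integer(dat$pt_stage == "pT4")
  if ("differentiation" %in% names(dat))
    mv_dat$differentiation <- match(dat$differentiation,
                                    c("well", "moderate", "poor")) - 1L
  multivariate <- if (ncol(mv_dat) >= 2L)
    cox_backward_aic(mv_dat, names(mv_dat), dat$time_months, dat$event)
  else NULL

  ## composite prognostic index
  npi <- NULL
  if (all(c("area_pdc_um2", "pt_stage", "differentiation") %in% names(dat))) {
    grp <- vapply(seq_len(nrow(dat)), function(i)
      build_npi(dat[i, ], config$cutoffs)$group, "")
    npi_km <- if (length(unique(grp)) > 1L)
      km_logrank(grp, dat$time_months, dat$event) else NULL
    npi_cox <- if (length(unique(grp)) > 1L)
      cox_univariate(as.integer(grp == "high"), dat$time_months, dat$event)
    else NULL
    npi <- list(group = grp, km = npi_km, cox = npi_cox)
  }
  out <- list(km = km_tab, cox_univariate = cox_tab,
              multivariate = multivariate, npi = npi,
              config_hash = config$config_hash, seed = config$seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(km_tab, file.path(config$output_dir, "km_logrank.csv"),
                     row.names = FALSE)
    utils::write.csv(cox_tab,
                     file.path(config$output_dir, "cox_univariate.csv"),
                     row.names = FALSE)
  }
  out
}
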