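# End-to-end orchestration: template -> displacement -> lobe attribution
# -> cohort statistics -> classifier evaluation, as one reproducible run.

#' Run the full quantification and evaluation pipeline
#'
#' Reads (or builds) the GM density template, quantifies displaced GM and
#' lobe attribution for every lesion in the manifest, computes the
#' group-comparison statistics and the threshold-classifier evaluation,
#' and writes a report bundle (`per_patient.csv`, `stats.json`,
#' `eval.json`, `config.json`) to `out_dir`.
#'
#' @param config a named list, or the path of a YAML/JSON file holding
#'   one, with fields:
#'   \describe{
#'     \item{template}{path to the template NIfTI (or `template_maps`, a
#'       character vector of control GM map paths to average).}
#'     \item{masks_manifest}{CSV with columns `patient_id`, `mask_path`
#'       and binary `label` (1 = seizure).}
#'     \item{atlas, merge}{optional: label-volume NIfTI plus JSON merge
#'       table (raw region -> merged lobe).}
#'     \item{threshold}{displaced-GM %% cutoff; when absent, selected by
#'       Youden's J on the cohort.}
#'     \item{prevalence}{population prevalence for the predicted PPV
#'       (default 0.37).}
#'     \item{bootstrap}{bootstrap resamples B (default 2000; 0 disables).}
#'     \item{seed}{integer seed, mandatory when bootstrap > 0.}
#'     \item{out_dir}{optional output directory.}
#'   }
#' @return Invisibly, a list with `per_patient`, `stats`, `eval` and the
#'   echoed `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  template <- if (!is.null(cfg$template)) {
    read_volume(cfg$template, "density")
  } else {
    maps <- lapply(cfg$template_maps, read_volume, expected_kind = "density")
    build_template(maps)
  }
  manifest <- utils::read.csv(cfg$masks_manifest,
                              stringsAsFactors = FALSE)
  need <- c("patient_id", "mask_path", "label")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("masks_manifest lacks columns: ", paste(miss, collapse = ", "))

  atlas <- merge_tab <- NULL
  if (!is.null(cfg$atlas)) {
    if (is.null(cfg$merge))
      stop("config field 'merge' (merge-table JSON) required with 'atlas'")
    merge_raw <- jsonlite::read_json(cfg$merge, simplifyVector = TRUE)
    merge_tab <- lobe_merge_table(unlist(merge_raw))
    label_names <- NULL
    if (!is.null(cfg$atlas_labels))
      label_names <- unlist(jsonlite::read_json(cfg$atlas_labels,
                                                simplifyVector = TRUE))
    atlas <- read_volume(cfg$atlas, "labels", label_names = label_names)
  }

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    mask <- read_volume(manifest$mask_path[i], "mask")
    disp <- quantify_displacement(mask, template)
    row <- data.frame(patient_id = manifest$patient_id[i],
                      label = manifest$label[i],
                      nd_ccm = disp$nd_ccm, n_ccm = disp$n_ccm,
                      sum_density = disp$sum_density,
                      volume_ml = disp$volume_ml,
                      proportion_pct = disp$proportion_pct,
                      stringsAsFactors = FALSE)
    if (!is.null(atlas)) {
      prof <- lobe_proportions(mask, atlas, merge_tab)
      loc <- assign_location_class(prof)
      row$dominant_lobe <- prof$dominant_lobe
      row$coverage <- prof$coverage
      row$tentorial <- loc$tentorial
      row$temporal_class <- loc$temporal_class
    }
    row
  })
  per_patient <- do.call(rbind, rows)

  stats_out <- cohort_stats(per_patient)
  eval_out <- evaluate_cohort(per_patient$proportion_pct,
                              per_patient$label,
                              threshold = cfg$threshold,
                              prevalence = cfg$prevalence,
                              B = cfg$bootstrap, seed = cfg$seed)

  result <- list(per_patient = per_patient, stats = stats_out,
                 eval = eval_out, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_patient,
                     file.path(cfg$out_dir, "per_patient.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(eval_out, file.path(cfg$out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  invisible(result)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(prevalence = 0.37, bootstrap = 2000L,
                   threshold = NULL, seed = NULL, out_dir = NULL,
                   template = NULL, template_maps = NULL,
                   atlas = NULL, merge = NULL, atlas_labels = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$template) && is.null(cfg$template_maps))
    stop("config needs 'template' or 'template_maps'")
  if (is.null(cfg$masks_manifest))
    stop("config needs 'masks_manifest'")
  for (f in c("template", "masks_manifest", "atlas", "merge",
              "atlas_labels"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "': file not found: ", cfg[[f]])
  if (!is.null(cfg$threshold) &&
      (cfg$threshold <= 0 || cfg$threshold >= 100))
    stop("threshold must lie in (0, 100)")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  if (cfg$bootstrap > 0 && is.null(cfg$seed))
    stop("seed is mandatory when bootstrap > 0")
  cfg
}

#' Group-comparison statistics for a quantified cohort
#'
#' Wilcoxon rank-sum tests of displaced-GM volume and proportion between
#' outcome groups, plus per-lobe 2x2 odds ratios (exposure = dominant
#' lobe) and the temporal vs extratemporal subgroup OR when lobe columns
#' are present.
#'
#' @param per_patient data.frame with `label`, `volume_ml`,
#'   `proportion_pct` and optionally `dominant_lobe`, `tentorial`,
#'   `temporal_class`.
#' @return Nested list of test results.
#' @export
cohort_stats <- function(per_patient) {
  y <- per_patient$label
  out <- list(
    n = nrow(per_patient),
    n_cases = sum(y == 1), n_controls = sum(y == 0),
    volume_wilcoxon = wilcoxon_rank_sum(
      per_patient$volume_ml[y == 1], per_patient$volume_ml[y == 0]),
    proportion_wilcoxon = wilcoxon_rank_sum(
      per_patient$proportion_pct[y == 1],
      per_patient$proportion_pct[y == 0]),
    group_means = list(
      cases = list(volume_ml = mean(per_patient$volume_ml[y == 1]),
                   proportion_pct = mean(per_patient$proportion_pct[y == 1])),
      controls = list(volume_ml = mean(per_patient$volume_ml[y == 0]),
                      proportion_pct = mean(per_patient$proportion_pct[y == 0]))))
  if (!is.null(per_patient$dominant_lobe)) {
    out$lobe_or <- lapply(stats::setNames(MERGED_LOBES, MERGED_LOBES),
                          function(l) {
      exp_ <- per_patient$dominant_lobe == l
      t <- contingency_2x2(sum(exp_ & y == 1), sum(exp_ & y == 0),
                           sum(!exp_ & y == 1), sum(!exp_ & y == 0))
      or <- tryCatch(odds_ratio(t), error = function(e) NULL)
      list(table = unclass(t), or = if (!is.null(or)) unclass(or),
           fisher_p = fisher_exact(t))
    })
    supra <- per_patient$tentorial == "supratentorial"
    if (any(supra) && !all(is.na(per_patient$temporal_class))) {
      tc <- per_patient$temporal_class[supra]
      ys <- y[supra]
      exp_ <- tc == "temporal"
      t <- contingency_2x2(sum(exp_ & ys == 1, na.rm = TRUE),
                           sum(exp_ & ys == 0, na.rm = TRUE),
                           sum(!exp_ & ys == 1, na.rm = TRUE),
                           sum(!exp_ & ys == 0, na.rm = TRUE))
      out$temporal_subgroup <- tryCatch(
        list(table = unclass(t), or = unclass(odds_ratio(t)),
             fisher_p = fisher_exact(t)),
        error = function(e) list(table = unclass(t),
                                 error = conditionMessage(e)))
    }
  }
  out
}

#' Threshold-classifier evaluation of a scored cohort
#'
#' ROC/AUC on the scores, operating threshold (given, or Youden-selected),
#' the full metric battery with optional stratified bootstrap CIs, the
#' prevalence-adjusted predicted PPV, and the logistic-model diagnostics
#' (Hosmer-Lemeshow, calibration slope, pseudo-R2).
#'
#' @param scores per-patient displaced-GM proportion (%).
#' @param labels binary outcomes.
#' @param threshold operating cutoff; `NULL` selects by Youden's J.
#' @param prevalence population prevalence for the predicted PPV.
#' @param B bootstrap resamples (0 disables CIs).
#' @param seed integer seed (required when `B > 0`).
#' @return Nested list of evaluation results.
#' @export
evaluate_cohort <- function(scores, labels, threshold = NULL,
                            prevalence = 0.37, B = 2000, seed = NULL) {
  roc <- roc_auc(scores, labels)
  thr <- if (is.null(threshold)) select_threshold(roc) else threshold
  cm <- confusion_at_threshold(scores, labels, thr)
  met <- classifier_metrics(cm)
  out <- list(threshold = thr,
              threshold_rule = if (is.null(threshold)) "youden" else "fixed",
              confusion = unclass(cm),
              metrics = unclass(met)[c("sensitivity", "specificity",
                                       "ppv", "npv", "f1", "dor",
                                       "mcc", "kappa")],
              auc = roc$auc,
              roc = list(thresholds = roc$thresholds,
                         sensitivity = roc$sensitivity, fpr = roc$fpr),
              predicted_ppv = predicted_ppv(met$sensitivity,
                                            met$specificity, prevalence),
              prevalence = prevalence)
  if (B > 0) {
    if (is.null(seed)) stop("seed required for bootstrap")
    out$metric_ci <- lapply(
      stats::setNames(names(out$metrics), names(out$metrics)),
      function(m) bootstrap_ci(m, scores, labels, thr, B = B,
                               seed = seed)[c("low", "high")])
  }
  fit <- fit_logistic(data.frame(proportion_pct = scores), labels)
  p_hat <- stats::fitted(fit$fit)
  out$logistic <- list(
    coefficients = as.list(fit$coefficients),
    or_per_unit = unname(fit$or[1]),
    or_ci = as.numeric(fit$or_ci[1, ]),
    separation = fit$separation,
    pseudo_r2 = as.list(pseudo_r2(fit)),
    hosmer_lemeshow = hosmer_lemeshow(p_hat, labels)[
      c("chi2", "df", "p_value", "g")],
    calibration = calibration_slope(p_hat, labels))
  out
}
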