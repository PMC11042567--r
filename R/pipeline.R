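# End-to-end orchestration: simulate -> preprocess -> (denoise) -> features ->
# select -> classify -> group stats, with a manifest and JSON/TSV reports.

#' Default pipeline configuration
#'
#' Nested list of every stage's settings. Stage toggles: `denoise$enabled`
#' (CEEMDAN-WPT on every channel; slow for large cohorts) and
#' `select$enabled`, `classify$enabled`, `group_stats$enabled`.
#'
#' @param seed Global seed.
#' @return Named list of stage configs.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, n_severe = 82, n_mild = 58, n_channels = 18,
                    effect_size = 1.0),
    input_dir = NULL,
    preprocess = list(detrend_order = 3, tddr = TRUE, filter = TRUE,
                      passband_hz = 0.01, stopband_hz = 0.2, atten_db = 30),
    denoise = list(enabled = FALSE, ensemble_size = 100, noise_scale = 0.2,
                   wavelet = "db4", level = 3, rule = "soft"),
    features = list(families = c("tf", "cf"), ssa_embed = 50),
    select = list(enabled = TRUE, cv_folds = 5, step = 1, cost = 1),
    classify = list(enabled = TRUE, models = c("svm", "lr", "rf", "mlp"),
                    train_fraction = 0.6, inner_folds = 5, nested = FALSE,
                    outer_folds = 5),
    group_stats = list(enabled = TRUE, alpha = 0.05)
  )
}

validate_config <- function(config) {
  assert_that(is.list(config) && !is.null(config$seed), "config must have a seed")
  if (isTRUE(config$simulate$enabled)) {
    # constructing the spec validates it
    cohort_spec(config$simulate$n_severe, config$simulate$n_mild,
                config$simulate$n_channels, config$simulate$effect_size,
                seed = config$seed)
  } else {
    assert_that(!is.null(config$input_dir) && dir.exists(config$input_dir),
                "input_dir must exist when simulation is disabled")
  }
  if (isTRUE(config$preprocess$filter)) {
    filter_spec(config$preprocess$passband_hz, config$preprocess$stopband_hz,
                config$preprocess$atten_db)
  }
  invisible(TRUE)
}

read_cohort_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  recs <- lapply(manifest$files, function(f) read_recording(file.path(dir, f)))
  subjects <- lapply(seq_along(recs), function(i) {
    structure(list(label = manifest$labels[i], recording = recs[[i]],
                   ground_truth = NULL), class = "synthetic_subject")
  })
  structure(subjects, labels = manifest$labels, class = "fnirs_cohort")
}

#' Run the full pipeline
#'
#' Executes the stages in their fixed order and writes every intermediate
#' table and report plus a `manifest.json` (config and seed) into `out_dir`.
#' Feature selection is fitted on the training split only; the held-out test
#' subjects are reduced to the selected columns afterwards.
#'
#' @param config A config list as from [default_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`cohort`, `tables`,
#'   `selection`, `evaluation`, `activation`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("nirsrun")) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # --- data ---
  if (isTRUE(config$simulate$enabled)) {
    spec <- cohort_spec(config$simulate$n_severe, config$simulate$n_mild,
                        config$simulate$n_channels, config$simulate$effect_size,
                        seed = config$seed)
    cohort <- simulate_cohort(spec)
  } else {
    cohort <- read_cohort_dir(config$input_dir)
  }
  labels <- cohort_labels(cohort)
  # --- preprocess (+ optional denoise) ---
  pp <- config$preprocess
  filt <- if (isTRUE(pp$filter)) filter_spec(pp$passband_hz, pp$stopband_hz, pp$atten_db)
          else NULL
  den <- config$denoise
  processed <- lapply(seq_along(cohort), function(i) {
    rec <- preprocess_recording(cohort[[i]]$recording, pp$detrend_order, filt,
                                tddr = isTRUE(pp$tddr))
    if (isTRUE(den$enabled)) {
      cc <- ceemdan_config(den$ensemble_size, den$noise_scale,
                           seed = config$seed + i)
      wc <- wpt_config(den$wavelet, den$level, den$rule)
      for (sp in c("hbo", "hbr")) {
        rec[[sp]] <- apply(rec[[sp]], 2, function(x) {
          ceemdan_wpt_denoise(x, cc, wc, rec$sampling_hz)$signal
        })
      }
    }
    rec
  })
  # --- features ---
  fam <- config$features$families
  tables <- list()
  if ("tf" %in% fam) tables$TF <- build_feature_table(processed, "tf", labels,
                                                      config$features$ssa_embed)
  if ("cf" %in% fam) tables$CF <- build_feature_table(processed, "cf", labels)
  if (length(tables) == 2) tables$TCF <- fuse_tables(tables$TF, tables$CF)
  for (nm in names(tables)) {
    write_feature_table(tables[[nm]], file.path(out_dir, paste0("features_", nm, ".tsv")))
  }
  selection <- NULL; evaluation <- NULL; activation <- NULL
  # --- split, selection (training subjects only), classification ---
  if (isTRUE(config$classify$enabled)) {
    cl <- config$classify
    split <- stratified_split(labels, cl$train_fraction, config$seed)
    eval_tables <- tables
    if (isTRUE(config$select$enabled) && length(tables) >= 3) {
      se <- config$select
      sel <- two_pass_select(subset_table(tables$TF, subjects = split$train),
                             subset_table(tables$CF, subjects = split$train),
                             se$cv_folds, se$step, se$cost, config$seed)
      selection <- sel
      keep <- colnames(sel$table$features)
      eval_tables$TCF <- subset_table(tables$TCF, features = keep)
      jsonlite::write_json(
        list(n_tf = sel$tf$n_selected, n_cf = sel$cf$n_selected,
             n_fused = sel$fused$n_selected, features = keep),
        file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    }
    evaluation <- run_model_comparison(eval_tables, cl$models,
                                       train_fraction = cl$train_fraction,
                                       inner_folds = cl$inner_folds,
                                       nested = isTRUE(cl$nested),
                                       outer_folds = cl$outer_folds,
                                       seed = config$seed)
    write_eval_report(evaluation, file.path(out_dir, "evaluation.json"))
  }
  # --- group stats ---
  if (isTRUE(config$group_stats$enabled)) {
    betas <- do.call(rbind, lapply(processed, function(r) glm_beta(r)))
    act <- channel_activation_test(betas, config$group_stats$alpha)
    contrast <- group_activation_contrast(betas[labels == "mild", , drop = FALSE],
                                          betas[labels == "severe", , drop = FALSE],
                                          config$group_stats$alpha)
    activation <- list(activation = act, contrast = contrast)
    utils::write.table(act, file.path(out_dir, "activation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(contrast, file.path(out_dir, "group_contrast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(stats::setNames(as.list(act$significant), act$channel),
                         file.path(out_dir, "activation_significance.json"),
                         auto_unbox = TRUE)
  }
  invisible(list(cohort = cohort, processed = processed, tables = tables,
                 selection = selection, evaluation = evaluation,
                 activation = activation, out_dir = out_dir))
}
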