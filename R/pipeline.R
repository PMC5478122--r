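# Config-driven pipeline wiring: synth -> train-filters -> predict -> cv ->
# evaluate, with one global seed expanded per stage so every stage is
# independently reproducible.

run_config_defaults <- function() {
  list(
    window_sec = 60, step_sec = 30,
    spectrum = "magnitude", log_order = "pre",
    method = "ds", scope = "per_channel", pairing = "independent_moments",
    tol = 1e-9, max_iter = 1000L,
    k = 40L, standardize = TRUE,
    dialect = "native",
    seed = 1L,
    clip_dir = NULL, manifest = NULL, filters = NULL, predictions = NULL,
    out = NULL, truth = NULL, compare = NULL,
    synth = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path; unknown keys are rejected,
#' defaults filled in, and basic type/range checks applied before any stage
#' runs.
#'
#' @param config Named list of options, or path to a YAML file.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  if (!cfg$method %in% c("pbf", "dm", "var", "tvm", "ds", "sqd")) {
    abort(sprintf("invalid method '%s'", cfg$method))
  }
  if (!cfg$scope %in% c("per_channel", "joint")) abort("invalid scope")
  if (!cfg$pairing %in% c("independent_moments", "sampled_pairs")) {
    abort("invalid pairing policy")
  }
  if (!cfg$spectrum %in% c("magnitude", "power")) abort("invalid spectrum option")
  if (!cfg$log_order %in% c("pre", "post")) abort("invalid log_order option")
  if (cfg$k < 1) abort("invalid K")
  if (!(cfg$window_sec > 0 && cfg$step_sec > 0 && cfg$step_sec <= cfg$window_sec)) {
    abort("invalid window spec")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

# per-stage seeds derived from the global seed (documented derivation:
# seed * 7919 + stage offset, reduced mod 2^31 - 1)
stage_seed <- function(config, stage) {
  offsets <- c(synth = 1L, filters = 2L, predict = 3L, cv = 4L, evaluate = 5L)
  as.integer((as.double(config$seed) * 7919 + offsets[[stage]]) %% (2^31 - 1))
}

config_hash <- function(config) {
  keys <- sort(setdiff(names(config), character(0)))
  flat <- paste(keys, vapply(config[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small deterministic FNV-style hash; enough to fingerprint a config
  h <- 2166136261
  for (b in utf8ToInt(flat)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

artifact_header <- function(config, stage) {
  sprintf("# seizecast stage=%s config_hash=%s seed=%d", stage,
          config_hash(config), stage_seed(config, stage))
}

read_labeled_clips <- function(config) {
  manifest <- read_manifest(config$manifest)
  clips <- lapply(manifest$path, read_clip, dialect = config$dialect)
  list(manifest = manifest, clips = clips)
}

pipeline_features <- function(clips, weights, spec) {
  lapply(clips, function(cl) {
    apply_filters(log_spectrum(sliding_windows(cl, spec),
                               spectrum = weights$spectrum,
                               log_order = weights$log_order), weights)
  })
}

#' Run one pipeline stage
#'
#' Commands: `"synth"` writes a synthetic subject's clips + manifest +
#' planted-truth JSON to `out`; `"train-filters"` estimates a filter bank
#' from the labeled clips in `manifest` and writes it to `filters`;
#' `"predict"` scores clips with a trained bank + KNN training set and writes
#' the contest CSV to `predictions`; `"cv"` runs leave-one-seizure-out
#' cross-validation and writes per-fold predictions; `"evaluate"` reports
#' per-subject and pooled AUC (optionally a DeLong comparison against
#' `compare`).
#'
#' @param command One of `"synth"`, `"train-filters"`, `"predict"`, `"cv"`,
#'   `"evaluate"`.
#' @param config A [run_config()] (or list/YAML path coerced through it).
#' @return The stage's main result, invisibly where the stage's purpose is
#'   its artifact files.
#' @export
run_pipeline <- function(command = c("synth", "train-filters", "predict",
                                     "cv", "evaluate"),
                         config = run_config()) {
  command <- match.arg(command)
  if (!inherits(config, "run_config")) config <- run_config(config)
  spec <- window_spec(config$window_sec, config$step_sec)
  switch(command,
    "synth" = {
      if (is.null(config$out)) abort("synth: config$out directory required")
      sc <- do.call(synth_config, config$synth %||% list())
      dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
      paths <- character(0)
      subj <- generate_subject(sc, stage_seed(config, "synth"),
                               on_clip = function(cl) {
        p <- file.path(config$out, clip_filename(cl, config$dialect))
        write_clip(cl, p, config$dialect)
        paths[[length(paths) + 1L]] <<- p
      })
      manifest <- dplyr::mutate(subj$manifest, path = paths,
                                subject_id = sc$subject_id) |>
        dplyr::select("path", "subject_id", "segment_kind", "segment_index",
                      "sequence_index")
      mp <- file.path(config$out, "manifest.csv")
      writeLines(artifact_header(config, "synth"), mp)
      readr::write_csv(manifest, mp, append = TRUE, col_names = TRUE)
      truth_payload <- list(
        header = artifact_header(config, "synth"),
        sampling_rate_hz = sc$sampling_rate_hz,
        effects = as.data.frame(
          dplyr::mutate(sc$effects,
                        channels = vapply(.data$channels, paste,
                                          character(1), collapse = ",")))
      )
      jsonlite::write_json(truth_payload, file.path(config$out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(manifest)
    },
    "train-filters" = {
      if (is.null(config$manifest)) abort("train-filters: config$manifest required")
      if (is.null(config$filters)) abort("train-filters: config$filters output path required")
      lab <- read_labeled_clips(config)
      kinds <- lab$manifest$segment_kind
      tens <- lapply(lab$clips, function(cl)
        log_spectrum(sliding_windows(cl, spec), spectrum = config$spectrum,
                     log_order = config$log_order))
      fw <- estimate_filter(
        tens[kinds == "interictal"], tens[kinds == "preictal"],
        method = config$method, scope = config$scope,
        pairing = pair_stream(config$pairing, seed = stage_seed(config, "filters")),
        tol = config$tol, max_iter = config$max_iter
      )
      write_filter_weights(fw, config$filters)
      invisible(fw)
    },
    "predict" = {
      for (f in c("manifest", "filters", "predictions")) {
        if (is.null(config[[f]])) abort(sprintf("predict: config$%s required", f))
      }
      lab <- read_labeled_clips(config)
      fw <- read_filter_weights(config$filters)
      kinds <- lab$manifest$segment_kind
      train_idx <- which(kinds %in% c("interictal", "preictal"))
      feats <- pipeline_features(lab$clips[train_idx], fw, spec)
      labels <- rep(as.integer(kinds[train_idx] == "preictal"),
                    vapply(feats, nrow, integer(1)))
      if (config$k > sum(vapply(feats, nrow, integer(1)))) {
        abort(sprintf("K = %d exceeds the %d training windows", config$k,
                      sum(vapply(feats, nrow, integer(1)))))
      }
      model <- knn_model(do.call(rbind, feats), labels, k = config$k,
                         standardize = config$standardize)
      preds <- predict_clips(lab$clips, fw, model, spec)
      write_predictions(preds, config$predictions)
      jsonlite::write_json(
        list(header = artifact_header(config, "predict")),
        paste0(config$predictions, ".meta.json"), auto_unbox = TRUE)
      invisible(preds)
    },
    "cv" = {
      for (f in c("manifest", "predictions")) {
        if (is.null(config[[f]])) abort(sprintf("cv: config$%s required", f))
      }
      lab <- read_labeled_clips(config)
      subject <- lab$manifest$subject_id[1L]
      folds <- loso_folds(lab$manifest, subject)
      seqs <- sequence_table(lab$manifest)
      tens <- lapply(lab$clips, function(cl)
        log_spectrum(sliding_windows(cl, spec), spectrum = config$spectrum,
                     log_order = config$log_order))
      kinds <- lab$manifest$segment_kind
      rows <- list()
      for (f in unique(folds$fold)) {
        fold_tbl <- dplyr::filter(folds, .data$fold == f)
        assign_role <- dplyr::left_join(seqs, fold_tbl,
                                        by = c("segment_kind", "seq_id"))
        tr <- which(assign_role$role == "training")
        va <- which(assign_role$role == "validation")
        fw <- estimate_filter(
          tens[intersect(tr, which(kinds == "interictal"))],
          tens[intersect(tr, which(kinds == "preictal"))],
          method = config$method, scope = config$scope,
          pairing = pair_stream(config$pairing,
                                seed = stage_seed(config, "cv")),
          tol = config$tol, max_iter = config$max_iter
        )
        feats <- lapply(tens[tr], apply_filters, weights = fw)
        labels <- rep(as.integer(kinds[tr] == "preictal"),
                      vapply(feats, nrow, integer(1)))
        model <- knn_model(do.call(rbind, feats), labels,
                           k = min(config$k, length(labels)),
                           standardize = config$standardize)
        prob <- vapply(tens[va], function(tn)
          aggregate_windows(knn_posterior(model, apply_filters(tn, fw))),
          numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fold = f,
          clip = sub("\\.[A-Za-z0-9]+$", "", basename(lab$manifest$path[va])),
          label = as.integer(kinds[va] == "preictal"),
          preictal = prob
        )
      }
      out <- dplyr::bind_rows(rows)
      writeLines(artifact_header(config, "cv"), config$predictions)
      readr::write_csv(out, config$predictions, append = TRUE, col_names = TRUE)
      invisible(out)
    },
    "evaluate" = {
      for (f in c("predictions", "truth")) {
        if (is.null(config[[f]])) abort(sprintf("evaluate: config$%s required", f))
      }
      preds <- readr::read_csv(config$predictions, comment = "#",
                               show_col_types = FALSE)
      manifest <- read_manifest(config$truth)
      truth_tbl <- dplyr::mutate(
        manifest,
        clip = sub("\\.[A-Za-z0-9]+$", "", basename(.data$path)),
        label = as.integer(.data$segment_kind == "preictal")
      )
      joined <- dplyr::inner_join(preds, truth_tbl, by = "clip")
      report <- report_auc(dplyr::transmute(joined, subject_id = .data$subject_id,
                                            score = .data$preictal,
                                            label = .data$label))
      if (!is.null(config$compare)) {
        other <- readr::read_csv(config$compare, comment = "#",
                                 show_col_types = FALSE)
        j2 <- dplyr::inner_join(joined, other, by = "clip",
                                suffix = c("", "_b"))
        cmp <- delong_test(j2$preictal, j2$preictal_b, j2$label)
        attr(report, "delong") <- cmp
      }
      if (!is.null(config$out)) {
        writeLines(artifact_header(config, "evaluate"), config$out)
        readr::write_csv(report, config$out, append = TRUE, col_names = TRUE)
      }
      report
    }
  )
}
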