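# Convenience wrappers chaining the pipeline stages: trials -> 0g signals
# -> segments -> feature table -> scaled/selected table -> model.

#' Segment a collection of trials
#'
#' @param trials list of [imu_trial()]s (or `simulate_squat_trial()`
#'   results, whose `$trial` is used).
#' @param gains,params forwarded to [simulate_microgravity()] /
#'   [segment_repetitions()].
#' @return list with `segments` (pooled) and `provenance` (data.frame:
#'   trial id, repetition number within trial).
#' @export
segment_trials <- function(trials, gains = mahony_gains(),
                           params = segmentation_params()) {
  segments <- list(); prov <- NULL
  ids <- names(trials) %||% as.character(seq_along(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (!inherits(tr, "imu_trial") && !is.null(tr$trial)) tr <- tr$trial
    zt <- simulate_microgravity(tr, gains)
    segs <- segment_repetitions(zt, params)
    if (length(segs)) {
      segments <- c(segments, segs)
      prov <- rbind(prov, data.frame(trial_id = ids[i],
                                     rep = seq_along(segs)))
    }
  }
  list(segments = segments, provenance = prov)
}

#' Build the raw feature table of a trial collection
#'
#' @inheritParams segment_trials
#' @param inventory a [feature_inventory()].
#' @return a raw [feature_table()] with provenance.
#' @export
pipeline_feature_table <- function(trials, gains = mahony_gains(),
                                   params = segmentation_params(),
                                   inventory = feature_inventory()) {
  st <- segment_trials(trials, gains, params)
  feature_table(st$segments, inventory, provenance = st$provenance)
}

#' Restrict a feature table to a selected feature set
#'
#' @param table a [feature_table()].
#' @param selection a [select_features_rfe()] result (or character vector).
#' @return the subset [feature_table()].
#' @export
subset_features <- function(table, selection) {
  feats <- if (is.character(selection)) selection else selection$features
  missing <- setdiff(feats, table$features)
  if (length(missing)) stop("table lacks selected feature(s): ",
                            paste(head(missing, 3), collapse = ", "))
  out <- table
  out$x <- table$x[, feats, drop = FALSE]
  out$features <- feats
  out
}

#' Fit the full classification pipeline on labelled trials
#'
#' Scales with the robust scaler (training rows only), runs recursive
#' feature elimination, and trains the requested classifier, returning a
#' deployable model bundle (scaler + selection + fit) ready for
#' [predict_report()] and [online_monitor()].
#'
#' @param trials list of labelled trials.
#' @param algo classifier family.
#' @param target_count RFE target feature count.
#' @param seed RNG seed.
#' @param gains,params,inventory pipeline stage parameters.
#' @return a `squat_model` bundle.
#' @export
fit_pipeline <- function(trials, algo = "MLP", target_count = 100, seed = 1,
                         gains = mahony_gains(),
                         params = segmentation_params(),
                         inventory = feature_inventory()) {
  ft <- pipeline_feature_table(trials, gains, params, inventory)
  scaler <- fit_scaler(ft)
  fts <- apply_scaler(ft, scaler)
  sel <- select_features_rfe(fts, target_count = target_count, seed = seed)
  train(subset_features(fts, sel), algo = algo, seed = seed,
        scaler = scaler, selection = sel)
}

#' Persist / restore a model bundle
#'
#' The bundle directory holds the serialized fit plus a JSON metadata
#' sidecar (algorithm, class order, seed, feature names).
#'
#' @param model a `squat_model`.
#' @param dir destination directory.
#' @return the directory, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(algo = model$algo, classes = model$classes,
               seed = model$seed, n_features = length(model$features),
               features = model$features)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @param dir bundle directory written by [save_model()].
#' @export
load_model <- function(dir) {
  m <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(m, "squat_model"))
  m
}
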