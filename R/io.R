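#' Write / read a wavelength trace as CSV
#'
#' Columns `time_s`, `wavelength_nm`, `label`; comma delimiter, `.` decimal
#' separator, UTF-8, mandatory header.
#'
#' @param trace A `wavelength_trace`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a `wavelength_trace` (reader).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "wavelength_trace"))
  n <- length(trace$samples)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) / trace$sampling_rate_hz,
    wavelength_nm = trace$samples,
    label = trace$labels)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    numeric = c("time_s", "wavelength_nm"), character = "label"))
  need <- c("time_s", "wavelength_nm", "label")
  if (!all(need %in% names(dt)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  if (!nrow(dt)) stop("empty trace file: ", path)
  fs <- if (nrow(dt) > 1) 1 / stats::median(diff(dt$time_s)) else 1000
  wavelength_trace(dt$wavelength_nm, round(fs, 6), dt$label)
}

#' Write / read a feature dataset as CSV
#'
#' Header `a1,...,aP,label`, one row per instance; values round-trip at full
#' double precision.
#'
#' @param dataset A `chew_dataset`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `chew_dataset` (reader).
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "chew_dataset"))
  dt <- data.table::as.data.table(dataset$X)
  dt[["label"]] <- as.character(dataset$y)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  dt <- data.table::fread(path)
  if (!"label" %in% names(dt)) stop("dataset CSV lacks a label column")
  if (!nrow(dt)) stop("empty dataset file: ", path)
  y <- as.character(dt[["label"]])
  dt[["label"]] <- NULL
  chew_dataset(as.matrix(dt), y)
}

# Nested-list form of a tree node for JSON serialization.
node_to_list <- function(node) {
  if (node$type == "leaf")
    list(leaf_class = node$class, counts = as.list(node$counts))
  else
    list(attr = node$attribute_index, threshold = node$threshold,
         counts = as.list(node$counts),
         left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(lst) {
  counts <- unlist(lst$counts)
  if (!is.null(lst$leaf_class))
    list(type = "leaf", class = lst$leaf_class, counts = counts)
  else
    list(type = "split", attribute_index = as.integer(lst$attr),
         threshold = lst$threshold, counts = counts,
         left = node_from_list(lst$left), right = node_from_list(lst$right))
}

#' Serialize / restore a C4.5 tree as JSON
#'
#' Nested `{attr, threshold, left, right}` / `{leaf_class, counts}` nodes
#' with the class order, attribute names and induction parameters alongside.
#'
#' @param tree A `c45_tree`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `c45_tree` (reader).
#' @export
write_model_json <- function(tree, path) {
  stopifnot(inherits(tree, "c45_tree"))
  doc <- list(model = "c45",
              classes = tree$classes,
              n_attr = tree$n_attr,
              attr_names = tree$attr_names,
              pruned = tree$pruned,
              params = unclass(tree$params),
              root = node_to_list(tree$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  p <- doc$params
  structure(list(root = node_from_list(doc$root),
                 classes = unlist(doc$classes),
                 n_attr = as.integer(doc$n_attr),
                 attr_names = if (length(doc$attr_names))
                   unlist(doc$attr_names) else NULL,
                 params = induction_params(p$min_leaf, p$confidence_factor,
                                           p$use_average_gain_guard),
                 pruned = isTRUE(doc$pruned)),
            class = "c45_tree")
}

#' Write the rule set of a tree to plain text
#'
#' @param tree A `c45_tree` (or a character vector of rules).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rules_txt <- function(tree, path) {
  rules <- if (is.character(tree)) tree else extract_rules(tree)
  writeLines(sprintf("R%d: %s", seq_along(rules), rules), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its documented default:
#' sensor model, class profiles, session layout, segmentation, feature
#' construction, induction and cross-validation. Serializable to YAML with
#' [write_config_yaml()]; unknown keys are rejected on construction.
#'
#' @param sensor A [sensor_model()].
#' @param profiles Named list of [class_profile()] objects.
#' @param movements_per_class Movements per class in the simulated session.
#' @param sampling_rate_hz Session sampling rate (S/s).
#' @param inter_movement_gap_s Baseline gap between movements (s).
#' @param tail_s Trailing baseline tail (s).
#' @param seed Master seed (session generation and fold assignment).
#' @param segmentation A [segmentation_params()].
#' @param features A [feature_params()].
#' @param induction An [induction_params()].
#' @param k Cross-validation fold count.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sensor = sensor_model(),
                            profiles = default_profiles(),
                            movements_per_class = 200L,
                            sampling_rate_hz = 1000,
                            inter_movement_gap_s = 0.1,
                            tail_s = 2,
                            seed = 1L,
                            segmentation = segmentation_params(),
                            features = feature_params(),
                            induction = induction_params(),
                            k = 10L) {
  structure(list(sensor = sensor, profiles = profiles,
                 movements_per_class = as.integer(movements_per_class),
                 sampling_rate_hz = sampling_rate_hz,
                 inter_movement_gap_s = inter_movement_gap_s,
                 tail_s = tail_s, seed = as.integer(seed),
                 segmentation = segmentation, features = features,
                 induction = induction, k = as.integer(k)),
            class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration as YAML
#'
#' The document round-trips exactly: `read_config_yaml(write_config_yaml(x))`
#' reproduces `x`. Unknown keys in the document are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `path`, invisibly (writer); a `pipeline_config` (reader).
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  doc <- list(
    sensor = unclass(config$sensor),
    profiles = lapply(config$profiles, unclass),
    session = list(movements_per_class = config$movements_per_class,
                   sampling_rate_hz = config$sampling_rate_hz,
                   inter_movement_gap_s = config$inter_movement_gap_s,
                   tail_s = config$tail_s,
                   seed = config$seed),
    segmentation = unclass(config$segmentation),
    features = unclass(config$features),
    induction = unclass(config$induction),
    cv = list(k = config$k))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("sensor", "profiles", "session", "segmentation", "features",
             "induction", "cv")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  profiles <- lapply(doc$profiles, function(p) do.call(class_profile, p))
  names(profiles) <- vapply(profiles, function(p) p$label, character(1))
  pipeline_config(
    sensor = do.call(sensor_model, doc$sensor),
    profiles = profiles,
    movements_per_class = doc$session$movements_per_class,
    sampling_rate_hz = doc$session$sampling_rate_hz,
    inter_movement_gap_s = doc$session$inter_movement_gap_s,
    tail_s = doc$session$tail_s,
    seed = doc$session$seed,
    segmentation = do.call(segmentation_params, doc$segmentation),
    features = do.call(feature_params, doc$features),
    induction = do.call(induction_params, doc$induction),
    k = doc$cv$k)
}

#' File-to-file pipeline drivers
#'
#' Thin command-style wrappers chaining the pipeline stages through files:
#' `cmd_simulate` writes a labeled wavelength-trace CSV (plus a small JSON
#' manifest with the seed and per-class movement counts), `cmd_featurize`
#' segments a trace CSV and writes the feature dataset CSV, and
#' `cmd_train_eval` cross-validates a dataset CSV and writes the best model
#' (JSON), its rule set (text) and an evaluation report (JSON). Progress
#' messages go to standard error; results only to files.
#'
#' @param config A [pipeline_config()].
#' @param trace_path,dataset_path,model_path,rules_path,report_path File
#'   paths.
#' @param manifest_path Optional manifest path for `cmd_simulate`.
#' @return The written primary path, invisibly; `cmd_train_eval` returns the
#'   `chew_cv` result invisibly.
#' @export
cmd_simulate <- function(config, trace_path, manifest_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- session_spec(
    data.frame(class = names(config$profiles),
               count = config$movements_per_class),
    sampling_rate_hz = config$sampling_rate_hz,
    inter_movement_gap_s = config$inter_movement_gap_s,
    tail_s = config$tail_s, seed = config$seed)
  trace <- encode_wavelength(generate_session(spec, config$profiles),
                             config$sensor)
  write_trace_csv(trace, trace_path)
  counts <- spec$segments$count
  names(counts) <- spec$segments$class
  message("simulated ", sum(counts), " movements: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      list(seed = config$seed,
           sampling_rate_hz = config$sampling_rate_hz,
           movements = as.list(counts),
           total_movements = sum(counts),
           profile_hash = profile_hash(config$profiles)),
      manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(trace_path)
}

profile_hash <- function(profiles) {
  s <- paste(vapply(profiles, function(p)
    paste(unlist(p), collapse = ","), character(1)), collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' @rdname cmd_simulate
#' @export
cmd_featurize <- function(trace_path, config, dataset_path) {
  stopifnot(inherits(config, "pipeline_config"))
  trace <- read_trace_csv(trace_path)
  movements <- segment_movements(trace, config$segmentation)
  dataset <- build_dataset(movements,
                           per_class_cap = config$movements_per_class,
                           params = config$features)
  write_dataset_csv(dataset, dataset_path)
  counts <- dataset$per_class_counts
  message("featurized ", nrow(dataset$X), " instances x ", ncol(dataset$X),
          " attributes: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  invisible(dataset_path)
}

#' @rdname cmd_simulate
#' @export
cmd_train_eval <- function(dataset_path, config, model_path, rules_path,
                           report_path) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- read_dataset_csv(dataset_path)
  cv <- cross_validate(dataset, config$induction, k = config$k,
                       seed = config$seed)
  write_model_json(cv$best_tree, model_path)
  write_rules_txt(cv$best_tree, rules_path)
  stats <- tree_stats(cv$best_tree)
  report <- list(
    confusion = unclass(cv$confusion),
    per_class_accuracy_pct = as.list(cv$per_class_accuracy),
    overall_accuracy_pct = cv$overall_accuracy,
    fold_accuracy_pct = cv$fold_accuracy,
    best_fold = cv$best_fold,
    tree_stats = as.list(stats),
    n_rules = unname(stats["n_leaves"]))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message(sprintf("cross-validated accuracy %.1f%% (best fold %d: %.1f%%)",
                  cv$overall_accuracy, cv$best_fold,
                  cv$fold_accuracy[cv$best_fold]))
  invisible(cv)
}
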