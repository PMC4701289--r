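#' End-to-end chewing-classification pipeline
#'
#' Convenience driver chaining all in-memory stages: simulate a balanced
#' labeled session, encode it to Bragg wavelength, segment it into chew
#' movements, build the feature dataset and run stratified k-fold
#' cross-validation of the C4.5 learner. One seed reproduces the whole run.
#'
#' @param movements_per_class Simulated movements per class.
#' @param seed Master seed (session generation and fold assignment).
#' @param profiles Named list of [class_profile()] objects.
#' @param sensor A [sensor_model()].
#' @param segmentation A [segmentation_params()].
#' @param features A [feature_params()].
#' @param induction An [induction_params()].
#' @param k Fold count.
#' @param keep_trace Keep the (large) simulated trace in the result?
#' @return List with `dataset` (`chew_dataset`), `cv` (`chew_cv`),
#'   `movements` (count of segmented movements) and optionally `trace`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(movements_per_class = 30, seed = 1)
#' res$cv$overall_accuracy
#' }
run_pipeline <- function(movements_per_class = 200L,
                         seed = 1L,
                         profiles = default_profiles(),
                         sensor = sensor_model(),
                         segmentation = segmentation_params(),
                         features = feature_params(),
                         induction = induction_params(),
                         k = 10L,
                         keep_trace = FALSE) {
  spec <- session_spec(
    data.frame(class = names(profiles), count = movements_per_class),
    seed = seed)
  trace <- encode_wavelength(generate_session(spec, profiles), sensor)
  movements <- segment_movements(trace, segmentation)
  dataset <- build_dataset(movements, per_class_cap = movements_per_class,
                           params = features)
  cv <- cross_validate(dataset, induction, k = k, seed = seed)
  out <- list(dataset = dataset, cv = cv, movements = length(movements))
  if (keep_trace) out$trace <- trace
  out
}
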