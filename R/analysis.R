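# The analysis specification: study + tasklist + interfaces + parameters +
# model, the single object from which an execution plan is built.

#' Create an analysis specification
#'
#' Binds a tasklist to a study and to the layered parameter sources. The
#' returned object is customized with [set_parameter()] /
#' [set_tasksetting()] / [add_event()] / [add_contrast()] /
#' [connect_remote()] and executed with [run_pipeline()].
#'
#' @param defaults general settings: a nested list, or a path/text of a
#'   parameter-defaults XML document (inclusions resolved).
#' @param tasklist a [parse_tasklist()] result, or a document/path.
#' @param study a [study_description()] or a path/list accepted by it.
#' @param interfaces named list from [load_interfaces()]; defaults to the
#'   bundled toy modules.
#' @param registry module implementation registry; defaults to the bundled
#'   toy implementations ([default_registry()]).
#' @param tree a [domain_tree()].
#' @return object of class `analysis_spec`.
#' @examples
#' \donttest{
#' study <- generate_synthetic_study(synthetic_study_config(
#'   n_subjects = 1, root = tempfile()))
#' an <- new_analysis(tasklist = toy_tasklist(), study = study)
#' an <- set_tasksetting(an, "smooth", "FWHM", 8)
#' }
#' @export
new_analysis <- function(defaults = list(), tasklist, study,
                         interfaces = toy_interfaces(),
                         registry = default_registry(),
                         tree = domain_tree()) {
  if (is.character(defaults)) defaults <- parse_parameter_defaults(defaults)
  if (!inherits(tasklist, "tasklist")) tasklist <- parse_tasklist(tasklist)
  if (!inherits(study, "study_description")) study <- study_description(study)
  structure(list(defaults = defaults, tasklist = tasklist, study = study,
                 interfaces = interfaces, registry = registry, tree = tree,
                 user_overrides = list(), model = fmri_model(),
                 remote = NULL),
            class = "analysis_spec")
}

#' Override a general analysis parameter
#'
#' @param analysis an `analysis_spec`.
#' @param path dotted path into the general settings, e.g.
#'   `"acq_details.numdummies"`.
#' @param value new value.
#' @return the modified analysis.
#' @export
set_parameter <- function(analysis, path, value) {
  stopifnot(inherits(analysis, "analysis_spec"))
  analysis$user_overrides <- set_nested(analysis$user_overrides,
                                        paste0("global.", path), value)
  analysis
}

#' Override one setting of one pipeline stage
#'
#' @param analysis an `analysis_spec`.
#' @param stage stage key: the module name for its first occurrence,
#'   `name_0000k` for repeats.
#' @param setting setting name declared by the module's interface.
#' @param value new value.
#' @return the modified analysis.
#' @export
set_tasksetting <- function(analysis, stage, setting, value) {
  stopifnot(inherits(analysis, "analysis_spec"))
  analysis$user_overrides <- set_nested(
    analysis$user_overrides, paste("tasksettings", stage, setting, sep = "."),
    value)
  analysis
}

#' @export
print.analysis_spec <- function(x, ...) {
  cat("<analysis_spec>\n")
  print(x$study)
  cat(sprintf("  %d main entr%s, %d initialisation module(s)\n",
              length(x$tasklist$main),
              if (length(x$tasklist$main) == 1) "y" else "ies",
              length(x$tasklist$initialisation)))
  if (!is.null(x$remote)) cat("  connected to remote:", x$remote$root, "\n")
  invisible(x)
}

#' Build the execution plan of an analysis
#'
#' Expands the tasklist, merges parameters, binds any remote connection,
#' and computes the instance-level dependency map. Unconnected streams are
#' reported here, at the start of an analysis, not at dispatch time.
#'
#' @param analysis an `analysis_spec`.
#' @return object of class `pipeline_plan`.
#' @export
build_plan <- function(analysis) {
  stopifnot(inherits(analysis, "analysis_spec"))
  pipeline <- expand_tasklist(analysis$tasklist, analysis$interfaces)
  params <- merge_parameters(analysis$defaults, pipeline, analysis$interfaces,
                             analysis$user_overrides)
  for (inv in analysis$tasklist$initialisation) {
    if (is.null(analysis$interfaces[[inv$module_name]])) {
      abort_aq(sprintf("no interface for initialisation module '%s'",
                       inv$module_name), "aqueduct_schema_error")
    }
  }
  remote <- NULL
  if (!is.null(analysis$remote)) {
    remote <- bind_remote(analysis, pipeline)
    pipeline$stages <- c(remote$stages, pipeline$stages)
    # renumber so $order equals list position (pseudo stages first)
    for (i in seq_along(pipeline$stages)) pipeline$stages[[i]]$order <- i
  }
  map <- build_dependency_map(pipeline, analysis$study, analysis$tree)
  structure(list(analysis = analysis, pipeline = pipeline, params = params,
                 study = analysis$study, map = map, tree = analysis$tree,
                 remote = remote),
            class = "pipeline_plan")
}

#' @export
print.pipeline_plan <- function(x, ...) {
  cat("<pipeline_plan>\n")
  print(x$map)
  invisible(x)
}

analysis_trunk_dir <- function(study) {
  file.path(study$analysis_root, study$analysis_id)
}
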