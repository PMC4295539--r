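# Layered analysis parameters.
#
# A merged ParameterSet records the full state of an analysis: general
# settings (acq_details, directory_conventions, options, ...) and one
# settings map per pipeline stage. Values come from three sources with
# increasing precedence: the module interface defaults, per-invocation
# settings in the tasklist, and user overrides.

#' Parse a parameter-defaults document
#'
#' The general-settings document groups defaults under namespaces such as
#' `acq_details` (e.g. `numdummies`), `directory_conventions`
#' (`analysisid`), and `options` (`wheretoprocess`). Inclusions are resolved
#' first (see [resolve_inclusion()]).
#'
#' @param document XML text or path.
#' @param resolver passed to [resolve_inclusion()].
#' @return nested named list of general settings.
#' @export
parse_parameter_defaults <- function(document, resolver = NULL) {
  text <- resolve_inclusion(document, resolver)
  xml_to_settings(xml2::xml_root(xml2::read_xml(text)))
}

new_parameter_set <- function(global = list(), tasksettings = list()) {
  structure(list(global = global, tasksettings = tasksettings),
            class = "parameter_set")
}

#' Merge analysis parameters from their three sources
#'
#' Precedence, lowest to highest: interface setting defaults, per-invocation
#' tasklist settings, user overrides. General settings from the defaults
#' document can likewise be overridden by the user (`user_overrides$global`
#' or any top-level name other than `tasksettings`). The result is
#' self-contained: it records the full merged state for every stage, keyed
#' by stage name (first occurrence) or `name_0000k` (repeats), suitable for
#' provenance.
#'
#' Merging an already-merged `parameter_set` with empty overrides is the
#' identity.
#'
#' @param defaults nested list of general settings (from
#'   [parse_parameter_defaults()]) or a previous `parameter_set`.
#' @param pipeline an [expand_tasklist()] result (or a `tasklist`, which is
#'   expanded with `interfaces`).
#' @param interfaces named list of `module_interface`s.
#' @param user_overrides list: general-setting overrides at the top level
#'   (e.g. `list(acq_details = list(numdummies = 3))`) plus
#'   `tasksettings = list(<stage-key> = list(<setting> = value))`.
#' @return object of class `parameter_set` with `$global` and
#'   `$tasksettings` (one entry per stage).
#' @examples
#' iface <- parse_module_interface('
#'   <interface><currenttask name="smooth" domain="session" desc="">
#'   <FWHM>10</FWHM>
#'   <inputstreams><stream>epi</stream></inputstreams>
#'   <outputstreams><stream>epi</stream></outputstreams>
#'   </currenttask></interface>')
#' tl <- parse_tasklist("main: [{name: smooth}]")
#' ps <- merge_parameters(list(), tl, list(smooth = iface),
#'                        list(tasksettings = list(smooth = list(FWHM = 8))))
#' ps$tasksettings$smooth$FWHM  # 8
#' @export
merge_parameters <- function(defaults, pipeline, interfaces,
                             user_overrides = list()) {
  prior_task <- list()
  if (inherits(defaults, "parameter_set")) {
    prior_task <- defaults$tasksettings
    defaults <- defaults$global
  }
  if (inherits(pipeline, "tasklist")) {
    pipeline <- expand_tasklist(pipeline, interfaces)
  }
  global_over <- user_overrides[setdiff(names(user_overrides), "tasksettings")]
  if (!is.null(user_overrides$global)) {
    global_over <- merge_nested(global_over[setdiff(names(global_over),
                                                    "global")],
                                user_overrides$global)
  }
  global <- merge_nested(defaults, global_over)

  user_task <- user_overrides$tasksettings %||% list()
  keys <- vapply(pipeline$stages, function(s)
    stage_settings_key(s$name, s$index), "")
  unknown_stage <- setdiff(names(user_task), keys)
  if (length(unknown_stage)) {
    abort_aq(sprintf("tasksettings override for unknown stage(s): %s",
                     paste(unknown_stage, collapse = ", ")),
             "aqueduct_unknown_setting_error")
  }
  tasksettings <- list()
  for (i in seq_along(pipeline$stages)) {
    stage <- pipeline$stages[[i]]
    iface <- stage$interface %||% interfaces[[stage$name]]
    if (is.null(iface)) {
      abort_aq(sprintf("no interface for stage '%s'", stage$name),
               "aqueduct_schema_error")
    }
    key <- keys[[i]]
    merged <- merge_nested(iface$settings, stage$settings)
    # an already-merged set takes precedence over re-applied tasklist
    # settings, so re-merging with empty overrides is the identity
    if (!is.null(prior_task[[key]])) {
      merged <- merge_nested(merged, prior_task[[key]])
    }
    over <- user_task[[key]]
    if (!is.null(over)) {
      unknown <- setdiff(names(over), names(iface$settings))
      if (length(unknown)) {
        abort_aq(sprintf("override for stage '%s' names unknown setting(s): %s",
                         key, paste(unknown, collapse = ", ")),
                 "aqueduct_unknown_setting_error")
      }
      merged <- merge_nested(merged, over)
    }
    tasksettings[[key]] <- merged
  }
  new_parameter_set(global, tasksettings)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d general namespace(s), %d stage(s)\n",
              length(x$global), length(x$tasksettings)))
  invisible(x)
}
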