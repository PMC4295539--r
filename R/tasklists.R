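# Tasklists: the ordered declaration of what should be done.
#
# XML layout:
#
#   <tasklist>
#     <initialisation>
#       <module><name>check_parameters</name></module>
#     </initialisation>
#     <main>
#       <module><name>realign</name></module>
#       <module>
#         <name>smooth</name>
#         <settings><FWHM>8</FWHM></settings>
#         <input stream="epi" source="realign.epi"/>
#       </module>
#       <branch>
#         <alternative analysisid_suffix="_smo8"> ...modules... </alternative>
#         <alternative analysisid_suffix="_smo12"> ... </alternative>
#       </branch>
#     </main>
#   </tasklist>
#
# <input stream=... source="module.stream"/> is a fully qualified stream
# reference overriding the last-producer default. The YAML dialect mirrors
# this (main: list of {name, settings, inputs} or {branch: [{
# analysisid_suffix, modules: [...]}]}).

parse_invocation_xml <- function(node) {
  name <- xml2::xml_text(xml2::xml_find_first(node, "name"))
  if (is.na(name) || !nzchar(trimws(name))) {
    abort_aq("tasklist module entry lacks a <name>", "aqueduct_schema_error")
  }
  settings <- list()
  snode <- xml2::xml_find_first(node, "settings")
  if (!inherits(snode, "xml_missing")) settings <- xml_to_settings(snode)
  qualified <- list()
  for (inp in xml2::xml_find_all(node, "input")) {
    qualified[[xml2::xml_attr(inp, "stream")]] <- xml2::xml_attr(inp, "source")
  }
  list(module_name = trimws(name), local_settings = settings,
       qualified_inputs = qualified)
}

parse_invocation_yaml <- function(entry) {
  if (is.character(entry)) entry <- list(name = entry)
  list(module_name = entry$name, local_settings = entry$settings %||% list(),
       qualified_inputs = as.list(entry$inputs %||% list()))
}

#' Parse a tasklist document
#'
#' A tasklist has an `initialisation` section, run unconditionally on every
#' invocation, and a `main` section of module invocations, possibly with
#' branches. Each branch holds two or more alternatives, each an ordered
#' module list with an `analysisid_suffix` that separates the branch output
#' into its own analysis directory.
#'
#' @param document XML or YAML text, or a file path.
#' @return object of class `tasklist`: `initialisation` and `main` lists.
#'   Main entries are invocations (`module_name`, `local_settings`,
#'   `qualified_inputs`) or branches (`alternatives`).
#' @export
parse_tasklist <- function(document) {
  from_file <- length(document) == 1L && !grepl("\n", document) &&
    file.exists(document)
  is_yaml <- (from_file && grepl("\\.ya?ml$", document)) ||
    (!from_file && !grepl("^\\s*<", paste(document, collapse = "\n")))
  if (is_yaml) {
    y <- if (from_file) yaml::read_yaml(document) else
      yaml::yaml.load(paste(document, collapse = "\n"))
    init <- lapply(y$initialisation %||% list(), parse_invocation_yaml)
    main <- lapply(y$main %||% list(), function(entry) {
      if (!is.null(entry$branch)) {
        alts <- lapply(entry$branch, function(a) {
          list(analysisid_suffix = a$analysisid_suffix %||% "",
               entries = lapply(a$modules %||% list(), parse_invocation_yaml))
        })
        new_branch(alts)
      } else parse_invocation_yaml(entry)
    })
  } else {
    doc <- if (from_file) xml2::read_xml(document) else
      xml2::read_xml(paste(document, collapse = "\n"))
    init_node <- xml2::xml_find_first(doc, "//initialisation")
    init <- if (inherits(init_node, "xml_missing")) list() else
      lapply(xml2::xml_find_all(init_node, "module"), parse_invocation_xml)
    main_node <- xml2::xml_find_first(doc, "//main")
    main <- list()
    if (!inherits(main_node, "xml_missing")) {
      for (node in xml2::xml_children(main_node)) {
        nm <- xml2::xml_name(node)
        if (nm == "module") {
          main[[length(main) + 1L]] <- parse_invocation_xml(node)
        } else if (nm == "branch") {
          alts <- lapply(xml2::xml_find_all(node, "alternative"), function(a) {
            sfx <- xml2::xml_attr(a, "analysisid_suffix")
            list(analysisid_suffix = if (is.na(sfx)) "" else sfx,
                 entries = lapply(xml2::xml_find_all(a, "module"),
                                  parse_invocation_xml))
          })
          main[[length(main) + 1L]] <- new_branch(alts)
        }
      }
    }
  }
  structure(list(initialisation = init, main = main), class = "tasklist")
}

new_branch <- function(alternatives) {
  if (length(alternatives) < 2L) {
    abort_aq("a branch must contain at least 2 alternatives",
             "aqueduct_schema_error")
  }
  suffixes <- vapply(alternatives, function(a) a$analysisid_suffix, "")
  if (anyDuplicated(suffixes)) {
    abort_aq("branch alternatives must carry distinct analysisid_suffix values",
             "aqueduct_schema_error")
  }
  structure(list(alternatives = alternatives), class = "tasklist_branch")
}

#' Expand a tasklist into a linear, indexed pipeline
#'
#' Branches are flattened alternative-by-alternative in declaration order.
#' Every stage receives an occurrence index: 1 plus the number of earlier
#' occurrences of the same module name in the expanded order, so repeated
#' modules (including duplicates across branch alternatives) get `_00001`,
#' `_00002`, ... directory suffixes. Branch stages carry their alternative's
#' `analysisid_suffix`; trunk stages carry the empty suffix.
#'
#' @param tasklist a [parse_tasklist()] result.
#' @param interfaces named list of `module_interface`s; when supplied, each
#'   stage is bound to its interface and per-invocation settings are checked
#'   against the interface's declared settings.
#' @return object of class `expanded_pipeline` with `stages` (each:
#'   `name`, `index`, `interface`, `settings` (local overrides only),
#'   `branch_suffix`, `qualified_inputs`, `branch`, `alt`, `order`) and
#'   `initialisation`.
#' @export
expand_tasklist <- function(tasklist, interfaces = NULL) {
  stopifnot(inherits(tasklist, "tasklist"))
  stages <- list()
  counts <- new.env(parent = emptyenv())
  add_stage <- function(inv, branch, alt, suffix) {
    n <- (get0(inv$module_name, envir = counts) %||% 0L) + 1L
    assign(inv$module_name, n, envir = counts)
    iface <- NULL
    if (!is.null(interfaces)) {
      iface <- interfaces[[inv$module_name]]
      if (is.null(iface)) {
        abort_aq(sprintf("no interface for invoked module '%s'",
                         inv$module_name), "aqueduct_schema_error")
      }
      unknown <- setdiff(names(inv$local_settings), names(iface$settings))
      if (length(unknown)) {
        abort_aq(sprintf(
          "invocation of '%s' sets unknown setting(s): %s",
          inv$module_name, paste(unknown, collapse = ", ")),
          "aqueduct_unknown_setting_error")
      }
    }
    stages[[length(stages) + 1L]] <<- list(
      name = inv$module_name, index = n, interface = iface,
      settings = inv$local_settings, branch_suffix = suffix,
      qualified_inputs = inv$qualified_inputs,
      branch = branch, alt = alt, order = length(stages) + 1L)
  }
  branch_no <- 0L
  for (entry in tasklist$main) {
    if (inherits(entry, "tasklist_branch")) {
      branch_no <- branch_no + 1L
      for (a in seq_along(entry$alternatives)) {
        alt <- entry$alternatives[[a]]
        for (inv in alt$entries) {
          add_stage(inv, branch_no, a, alt$analysisid_suffix)
        }
      }
    } else {
      add_stage(entry, 0L, 0L, "")
    }
  }
  structure(list(stages = stages, initialisation = tasklist$initialisation),
            class = "expanded_pipeline")
}

#' @export
print.expanded_pipeline <- function(x, ...) {
  cat(sprintf("<expanded_pipeline> %d stage(s)\n", length(x$stages)))
  for (s in x$stages) {
    cat(sprintf("  %s%s%s\n", stage_dirname(s$name, s$index),
                if (nzchar(s$branch_suffix))
                  paste0("  [branch ", s$branch, ".", s$alt, " '",
                         s$branch_suffix, "']") else "",
                if (!is.null(s$interface))
                  paste0("  (", s$interface$domain, ")") else ""))
  }
  invisible(x)
}

# key under which a stage's settings live in ParameterSet$tasksettings:
# plain name for the first occurrence, name_0000k for later ones.
stage_settings_key <- function(name, index) {
  if (index == 1L) name else paste0(name, "_", stage_index_label(index))
}

# stages visible to `stage` for backward stream resolution: earlier in the
# expanded order, and either on the trunk or in the same branch alternative
# (never a sibling branch).
visible_predecessors <- function(pipeline, stage) {
  Filter(function(s) {
    s$order < stage$order &&
      (s$branch == 0L || (s$branch == stage$branch && s$alt == stage$alt))
  }, pipeline$stages)
}
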