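# Module interfaces: the declarative description of one processing stage.
#
# Canonical format is XML, mirroring the classic layout:
#
#   <interface>
#     <currenttask name="smooth" domain="session" desc="Smooth EPI"
#                  modality="MRI">
#       <qsub><memoryBase>0.5</memoryBase><timeBase>1</timeBase></qsub>
#       <permanenceofoutput>1</permanenceofoutput>
#       <FWHM>10</FWHM>
#       <inputstreams><stream>epi</stream></inputstreams>
#       <outputstreams><stream>epi</stream></outputstreams>
#     </currenttask>
#   </interface>
#
# Any child of <currenttask> other than qsub / permanenceofoutput /
# inputstreams / outputstreams is a module setting (leaf elements give
# values; nested elements give nested maps). An optional impl_alias
# attribute names the implementation when it differs from the interface
# name. Unknown attributes are preserved in $extra but otherwise ignored.

RESERVED_INTERFACE_ELEMENTS <- c("qsub", "permanenceofoutput",
                                 "inputstreams", "outputstreams")

xml_to_settings <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 0L) {
    return(coerce_setting_value(xml2::xml_text(node)))
  }
  out <- list()
  for (k in kids) out[[xml2::xml_name(k)]] <- xml_to_settings(k)
  out
}

read_stream_names <- function(task, block) {
  node <- xml2::xml_find_first(task, block)
  if (inherits(node, "xml_missing")) return(character(0))
  streams <- xml2::xml_text(xml2::xml_find_all(node, "stream"))
  streams <- trimws(streams)
  if (anyDuplicated(streams)) {
    abort_aq(sprintf("duplicate stream names in %s: %s", block,
                     paste(streams[duplicated(streams)], collapse = ", ")),
             "aqueduct_schema_error")
  }
  streams
}

new_module_interface <- function(name, domain, description = "",
                                 modality = "", settings = list(),
                                 input_streams = character(0),
                                 output_streams = character(0),
                                 resource_estimates = list(),
                                 permanence_of_output = 0L,
                                 impl_alias = NULL, extra = list(),
                                 tree = domain_tree()) {
  if (is.null(name) || !nzchar(name)) {
    abort_aq("module interface must carry a nonempty name",
             "aqueduct_schema_error")
  }
  if (!domain %in% names(tree)) {
    abort_aq(sprintf("interface '%s': unknown domain '%s'", name, domain),
             "aqueduct_domain_error")
  }
  if (permanence_of_output < 0) {
    abort_aq(sprintf("interface '%s': permanenceofoutput must be >= 0", name),
             "aqueduct_schema_error")
  }
  structure(list(
    name = name, domain = domain, description = description,
    modality = modality, settings = settings,
    input_streams = input_streams, output_streams = output_streams,
    resource_estimates = resource_estimates,
    permanence_of_output = as.integer(permanence_of_output),
    impl_alias = impl_alias, extra = extra
  ), class = "module_interface")
}

#' Parse a module interface document
#'
#' Reads the declarative description of one processing stage: its domain,
#' settings (with defaults), input and output stream names, resource
#' estimates for parallel schedulers, and the permanence rank used by
#' garbage collection. XML is canonical; a YAML dialect with the same
#' information content is accepted (top-level keys `name`, `domain`,
#' `desc`, `modality`, `settings`, `inputstreams`, `outputstreams`,
#' `qsub`, `permanenceofoutput`, `impl_alias`).
#'
#' @param document XML or YAML text, or a path to a `.xml`/`.yaml` file.
#'   When read from a file with no `name` attribute, the file stem is used
#'   as the module name.
#' @param name overrides the module name.
#' @param tree [domain_tree()] used to validate the domain.
#' @return object of class `module_interface`.
#' @examples
#' iface <- parse_module_interface('
#'  <interface><currenttask name="smooth" domain="session" desc="Smooth">
#'    <FWHM>10</FWHM>
#'    <inputstreams><stream>epi</stream></inputstreams>
#'    <outputstreams><stream>epi</stream></outputstreams>
#'  </currenttask></interface>')
#' iface$settings$FWHM
#' @export
parse_module_interface <- function(document, name = NULL, tree = domain_tree()) {
  from_file <- length(document) == 1L && !grepl("\n", document) &&
    file.exists(document)
  if (from_file && is.null(name)) {
    name <- sub("\\.(xml|ya?ml)$", "", basename(document))
  }
  is_yaml <- (from_file && grepl("\\.ya?ml$", document)) ||
    (!from_file && !grepl("^\\s*<", paste(document, collapse = "\n")))
  if (is_yaml) {
    y <- if (from_file) yaml::read_yaml(document) else
      yaml::yaml.load(paste(document, collapse = "\n"))
    return(new_module_interface(
      name = y$name %||% name, domain = y$domain %||%
        abort_aq("interface document lacks a domain", "aqueduct_schema_error"),
      description = y$desc %||% "", modality = y$modality %||% "",
      settings = y$settings %||% list(),
      input_streams = as.character(unlist(y$inputstreams %||% character(0))),
      output_streams = as.character(unlist(y$outputstreams %||% character(0))),
      resource_estimates = y$qsub %||% list(),
      permanence_of_output = y$permanenceofoutput %||% 0L,
      impl_alias = y$impl_alias, tree = tree))
  }
  doc <- if (from_file) xml2::read_xml(document) else
    xml2::read_xml(paste(document, collapse = "\n"))
  task <- xml2::xml_find_first(doc, "//currenttask")
  if (inherits(task, "xml_missing")) task <- xml2::xml_root(doc)
  attrs <- as.list(xml2::xml_attrs(task))
  if (is.null(attrs$domain)) {
    abort_aq(sprintf("interface document%s lacks a domain attribute",
                     if (from_file) paste0(" '", document, "'") else ""),
             "aqueduct_schema_error")
  }
  settings <- list()
  qsub <- list()
  permanence <- 0L
  for (child in xml2::xml_children(task)) {
    nm <- xml2::xml_name(child)
    if (nm == "qsub") qsub <- xml_to_settings(child)
    else if (nm == "permanenceofoutput")
      permanence <- as.integer(xml2::xml_text(child))
    else if (!nm %in% RESERVED_INTERFACE_ELEMENTS)
      settings[[nm]] <- xml_to_settings(child)
  }
  new_module_interface(
    name = attrs$name %||% name, domain = attrs$domain,
    description = attrs$desc %||% "", modality = attrs$modality %||% "",
    settings = settings,
    input_streams = read_stream_names(task, "inputstreams"),
    output_streams = read_stream_names(task, "outputstreams"),
    resource_estimates = qsub, permanence_of_output = permanence,
    impl_alias = attrs$mfile_alias %||% attrs$impl_alias,
    extra = attrs[setdiff(names(attrs), c("name", "domain", "desc",
                                          "modality", "mfile_alias",
                                          "impl_alias"))],
    tree = tree)
}

settings_to_xml <- function(parent, settings) {
  for (nm in names(settings)) {
    val <- settings[[nm]]
    node <- xml2::xml_add_child(parent, nm)
    if (is.list(val)) {
      settings_to_xml(node, val)
    } else {
      txt <- if (is.logical(val)) ifelse(val, "true", "false") else
        format(val, scientific = FALSE, trim = TRUE)
      xml2::xml_text(node) <- paste(txt, collapse = " ")
    }
  }
}

#' Serialize a module interface back to XML
#'
#' Round-trips with [parse_module_interface()]: parsing the serialized text
#' reproduces the same fields.
#'
#' @param interface a `module_interface`.
#' @return XML text.
#' @export
serialize_module_interface <- function(interface) {
  doc <- xml2::xml_new_root("interface")
  task <- xml2::xml_add_child(doc, "currenttask",
                              name = interface$name,
                              domain = interface$domain,
                              desc = interface$description,
                              modality = interface$modality)
  if (!is.null(interface$impl_alias)) {
    xml2::xml_set_attr(task, "impl_alias", interface$impl_alias)
  }
  for (nm in names(interface$extra)) {
    xml2::xml_set_attr(task, nm, interface$extra[[nm]])
  }
  if (length(interface$resource_estimates)) {
    settings_to_xml(xml2::xml_add_child(task, "qsub"),
                    interface$resource_estimates)
  }
  poo <- xml2::xml_add_child(task, "permanenceofoutput")
  xml2::xml_text(poo) <- as.character(interface$permanence_of_output)
  settings_to_xml(task, interface$settings)
  ins <- xml2::xml_add_child(task, "inputstreams")
  for (s in interface$input_streams) {
    node <- xml2::xml_add_child(ins, "stream")
    xml2::xml_text(node) <- s
  }
  outs <- xml2::xml_add_child(task, "outputstreams")
  for (s in interface$output_streams) {
    node <- xml2::xml_add_child(outs, "stream")
    xml2::xml_text(node) <- s
  }
  as.character(doc)
}

#' @export
print.module_interface <- function(x, ...) {
  cat(sprintf("<module_interface> %s [%s] %s\n", x$name, x$domain,
              x$description))
  cat(sprintf("  settings: %s\n",
              if (length(x$settings)) paste(names(x$settings), collapse = ", ")
              else "(none)"))
  cat(sprintf("  in: %s | out: %s\n",
              paste(x$input_streams, collapse = ", "),
              paste(x$output_streams, collapse = ", ")))
  invisible(x)
}

#' Load all module interfaces in a directory
#'
#' @param dir directory of `.xml`/`.yaml` interface documents; the file stem
#'   names each module unless the document carries a name attribute.
#' @param tree [domain_tree()].
#' @return named list of `module_interface` objects.
#' @export
load_interfaces <- function(dir, tree = domain_tree()) {
  files <- list.files(dir, pattern = "\\.(xml|ya?ml)$", full.names = TRUE)
  ifaces <- lapply(files, parse_module_interface, tree = tree)
  stats::setNames(ifaces, vapply(ifaces, function(i) i$name, ""))
}
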