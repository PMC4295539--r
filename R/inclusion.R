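# XML inclusion with a local-override section.
#
# Parameter-defaults documents may import a base document via W3C XInclude
# (<xi:include href="..."/>) and redefine a few elements inside a <local>
# section; the local elements replace same-named elements from the included
# content, so a site or study file states only what differs.

XI_NS <- "http://www.w3.org/2001/XInclude"

#' Resolve XML inclusions and local overrides
#'
#' Splices `<xi:include href="..."/>` targets (fetched through `resolver`)
#' into the document in order, recursively, with cycle detection; then
#' applies the document's `<local>` section, whose elements replace the
#' same-named elements (matched by path) of the included content. A document
#' with no includes and no local section is returned unchanged apart from
#' serialization.
#'
#' @param document XML text or a file path.
#' @param resolver function mapping an `href` to XML text; the default reads
#'   files relative to the including document (or the working directory).
#' @return merged XML text.
#' @examples
#' base <- "<parameters><a>1</a><b>2</b></parameters>"
#' site <- paste0('<parameters xmlns:xi="http://www.w3.org/2001/XInclude">',
#'                '<xi:include href="base.xml"/>',
#'                '<local><b>9</b></local></parameters>')
#' merged <- resolve_inclusion(site, resolver = function(h) base)
#' @export
resolve_inclusion <- function(document, resolver = NULL) {
  from_file <- length(document) == 1L && !grepl("\n", document) &&
    file.exists(document)
  base_dir <- if (from_file) dirname(document) else "."
  if (is.null(resolver)) {
    resolver <- function(href) {
      path <- if (file.exists(href)) href else file.path(base_dir, href)
      if (!file.exists(path)) {
        abort_aq(sprintf("cannot resolve inclusion target '%s'", href),
                 "aqueduct_inclusion_error")
      }
      paste(readLines(path, warn = FALSE), collapse = "\n")
    }
  }
  text <- if (from_file) paste(readLines(document, warn = FALSE),
                               collapse = "\n") else
    paste(document, collapse = "\n")
  doc <- splice_includes(text, resolver,
                         seen = if (from_file) normalizePath(document) else
                           character(0))
  apply_local_overrides(xml2::xml_root(doc))
  as.character(doc)
}

splice_includes <- function(text, resolver, seen = character(0)) {
  doc <- xml2::read_xml(text)
  repeat {
    inc <- xml2::xml_find_first(
      doc, ".//xi:include", ns = c(xi = XI_NS))
    if (inherits(inc, "xml_missing")) {
      # also accept unprefixed <include href=...> for hand-written fixtures
      inc <- xml2::xml_find_first(doc, ".//include[@href]")
      if (inherits(inc, "xml_missing")) break
    }
    href <- xml2::xml_attr(inc, "href")
    if (href %in% seen) {
      abort_aq(sprintf("inclusion cycle: %s",
                       paste(c(seen, href), collapse = " -> ")),
               "aqueduct_inclusion_error")
    }
    child_doc <- splice_includes(resolver(href), resolver, c(seen, href))
    root <- xml2::xml_root(child_doc)
    # splice the included root's children in place of the include element
    for (kid in rev(xml2::xml_children(root))) {
      xml2::xml_add_sibling(inc, kid, .where = "after")
    }
    xml2::xml_remove(inc)
  }
  doc
}

# Replace, under `node`, every element matched by path inside a <local>
# section: <local><a><b>v</b></a></local> overrides element a/b among the
# node's non-local children (appending when absent), then drops <local>.
apply_local_overrides <- function(node) {
  locals <- xml2::xml_find_all(node, "./local")
  if (length(locals) == 0L) return(invisible(node))
  for (loc in locals) {
    for (ov in xml2::xml_children(loc)) override_element(node, ov)
    xml2::xml_remove(loc)
  }
  invisible(node)
}

override_element <- function(parent, override) {
  nm <- xml2::xml_name(override)
  target <- xml2::xml_find_first(parent, paste0("./", nm, "[not(self::local)]"))
  if (inherits(target, "xml_missing")) {
    xml2::xml_add_child(parent, override)
    return(invisible(NULL))
  }
  if (length(xml2::xml_children(override)) == 0L) {
    # leaf: replace wholesale
    xml2::xml_add_sibling(target, override, .where = "after")
    xml2::xml_remove(target)
  } else {
    for (kid in xml2::xml_children(override)) override_element(target, kid)
  }
  invisible(NULL)
}
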