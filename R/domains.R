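# Domain hierarchy: the granularity at which modules instantiate.
#
# The default tree is study -> subject -> session; further session-like
# leaves (e.g. diffusion_session) can be registered as siblings of session.

#' Construct a domain tree
#'
#' Domains form a rooted tree: a stage with domain `"study"` runs once, a
#' `"subject"` stage once per subject, and a `"session"` stage once per
#' (subject, session). Extra session-like domains can be added as children
#' of `"subject"`; each must have a matching per-subject enumerator in the
#' study description (`extra_sessions`).
#'
#' @param extra_session_domains character vector of additional domain names
#'   attached under `"subject"`.
#' @return an object of class `domain_tree`: a named character vector mapping
#'   each node to its parent (`NA` for the root).
#' @examples
#' tr <- domain_tree()
#' domain_path(tr, "session")
#' @export
domain_tree <- function(extra_session_domains = character()) {
  parents <- c(study = NA_character_, subject = "study", session = "subject")
  for (d in extra_session_domains) {
    if (d %in% names(parents)) next
    parents[[d]] <- "subject"
  }
  structure(parents, class = "domain_tree")
}

#' Path from the root to a domain node
#'
#' @param tree a [domain_tree()].
#' @param domain node name.
#' @return character vector of node names from `"study"` down to `domain`.
#' @export
domain_path <- function(tree, domain) {
  if (!domain %in% names(tree)) {
    abort_aq(sprintf("unknown domain '%s'", domain), "aqueduct_domain_error")
  }
  path <- domain
  while (!is.na(tree[[path[1]]])) path <- c(tree[[path[1]]], path)
  path
}

# A domain coordinate is a named character vector of identifiers along the
# path below the root, e.g. c(subject = "S1", session = "movie"); the study
# level is the empty coordinate character(0).

new_coordinate <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- character(0)
  x
}

#' Relation between two domain coordinates
#'
#' Coordinates live on the same domain tree; one is an *ancestor* of another
#' when its identifier path is a proper prefix. `"disjoint"` covers sideways
#' coordinates (e.g. two sessions of the same subject), between which streams
#' may never flow.
#'
#' @param a,b named character vectors of identifiers below the root
#'   (`character(0)` is the study level).
#' @return one of `"equal"`, `"ancestor"`, `"descendant"`, `"disjoint"`,
#'   where `"ancestor"` means `a` is an ancestor of `b`.
#' @examples
#' coordinate_relation(c(subject = "S1"), c(subject = "S1", session = "movie"))
#' @export
coordinate_relation <- function(a, b) {
  na <- length(a); nb <- length(b)
  k <- min(na, nb)
  if (k > 0 && !identical(unname(a[seq_len(k)]), unname(b[seq_len(k)]))) {
    return("disjoint")
  }
  if (na == nb) "equal" else if (na < nb) "ancestor" else "descendant"
}

coordinate_key <- function(coord) {
  if (length(coord) == 0L) "study" else paste(coord, collapse = "/")
}

#' Read or build a study description
#'
#' The study description separates the data from the method: it names the
#' analysis root and id, the subjects, the sessions of each subject, and the
#' locations of the raw input series (4D EPI per session, 3D structural per
#' subject).
#'
#' @param x path to a YAML or JSON file, or a list with the same fields.
#' @return object of class `study_description` with elements `analysis_root`,
#'   `analysis_id`, `subjects` (character), `sessions_per_subject` (named
#'   list), `input_locations` (named list: `"S1"` or `"S1/movie"` to a path),
#'   `numdummies`, and optional `extra_sessions`.
#' @export
study_description <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.json$", x)) read_json_file(x) else yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  subjects <- character(0)
  sessions <- list()
  locations <- as.list(x$input_locations %||% list())
  if (!is.null(x$subjects) && is.list(x$subjects) && !is.null(x$subjects[[1]]$id)) {
    # nested form: subjects: [{id:, sessions: [{id:, epi:}], structural:}]
    for (sub in x$subjects) {
      subjects <- c(subjects, sub$id)
      ids <- vapply(sub$sessions %||% list(), function(s) s$id, "")
      sessions[[sub$id]] <- ids
      if (!is.null(sub$structural)) locations[[sub$id]] <- sub$structural
      for (s in sub$sessions %||% list()) {
        if (!is.null(s$epi)) locations[[paste(sub$id, s$id, sep = "/")]] <- s$epi
      }
    }
  } else {
    subjects <- as.character(unlist(x$subjects %||% character(0)))
    sessions <- x$sessions_per_subject %||%
      stats::setNames(rep(list(character(0)), length(subjects)), subjects)
    sessions <- lapply(sessions, function(s) as.character(unlist(s)))
  }
  for (sub in names(sessions)) {
    if (!sub %in% subjects) {
      abort_aq(sprintf("sessions listed for unknown subject '%s'", sub),
               "aqueduct_study_error")
    }
  }
  id <- x$analysis_id %||% "analysis"
  if (!nzchar(id)) abort_aq("analysis_id must be nonempty", "aqueduct_study_error")
  structure(list(
    analysis_root = x$analysis_root %||% ".",
    analysis_id = id,
    subjects = subjects,
    sessions_per_subject = sessions,
    input_locations = locations,
    numdummies = as.integer(x$numdummies %||% 0L),
    extra_sessions = x$extra_sessions %||% list()
  ), class = "study_description")
}

#' @export
print.study_description <- function(x, ...) {
  cat(sprintf("Study '%s' at %s\n", x$analysis_id, x$analysis_root))
  cat(sprintf("  %d subject(s); sessions: %s\n", length(x$subjects),
              paste(vapply(x$subjects, function(s)
                sprintf("%s[%d]", s, length(x$sessions_per_subject[[s]])), ""),
                collapse = ", ")))
  invisible(x)
}

# identifiers available at one tree level, below a given parent coordinate
level_ids <- function(study, domain, coord) {
  switch(domain,
    subject = study$subjects,
    session = study$sessions_per_subject[[coord[["subject"]]]] %||% character(0),
    # extra session-like domains: per-subject enumerators
    (study$extra_sessions[[domain]] %||% list())[[coord[["subject"]]]] %||%
      character(0)
  )
}

#' Enumerate the instances of a stage
#'
#' A stage at study domain yields one instance; subject domain one per
#' subject; session(-like) domain one per (subject, session), in subject
#' order then session order.
#'
#' @param stage a stage of an [expand_tasklist()] pipeline, or any list with
#'   `name`, `index`, and an `interface` carrying `domain`.
#' @param study a [study_description()].
#' @param tree a [domain_tree()].
#' @return list of instance keys: `list(stage = list(name, index),
#'   coordinate = <named character>)`.
#' @export
enumerate_instances <- function(stage, study, tree = domain_tree()) {
  domain <- stage$interface$domain
  path <- domain_path(tree, domain)[-1]  # drop the study root
  coords <- list(new_coordinate())
  for (level in path) {
    coords <- unlist(lapply(coords, function(co) {
      lapply(level_ids(study, level, co), function(id) {
        c(co, stats::setNames(id, level))
      })
    }), recursive = FALSE)
    if (is.null(coords)) coords <- list()
  }
  lapply(coords, function(co) {
    list(stage = list(name = stage$name, index = stage$index), coordinate = co)
  })
}

instance_label <- function(instance) {
  paste0(stage_dirname(instance$stage$name, instance$stage$index), "@",
         coordinate_key(instance$coordinate))
}

#' Output directory of an instance
#'
#' The analysis tree is one directory per stage (`<name>_<00001>`), then one
#' per subject, then one per session, truncated at the stage's domain level;
#' a branch suffix is appended to the analysis id so branches separate into
#' sibling analysis directories.
#'
#' @param instance an instance key from [enumerate_instances()].
#' @param study a [study_description()].
#' @param branch_suffix suffix appended to the analysis id (`""` on the trunk).
#' @return absolute or root-relative path (not created).
#' @export
instance_directory <- function(instance, study, branch_suffix = "") {
  parts <- c(study$analysis_root,
             paste0(study$analysis_id, branch_suffix),
             stage_dirname(instance$stage$name, instance$stage$index),
             unname(instance$coordinate))
  do.call(file.path, as.list(parts))
}
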