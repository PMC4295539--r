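# Stream wiring: which stage supplies each input stream, and which instance
# supplies each instance, across domains.
#
# Rules: an input stream comes from the nearest preceding visible stage that
# declares it as an output (a fully qualified reference "module.stream"
# instead names an explicit earlier module). At the instance level, equal
# domains connect matching coordinates; an ancestor-domain source (e.g. a
# subject-level structural feeding session-level work) supplies all its
# descendants; a descendant-domain source fans in (e.g. per-session
# contrasts into a study-level test). Sideways reads never happen.

#' Resolve the producing stage of an input stream
#'
#' Searches backwards from `target_stage` over the stages visible to it
#' (its own branch alternative, then the shared trunk before the branch
#' point — never a sibling branch), returning the nearest stage whose
#' declared outputs contain `stream`. A fully qualified reference
#' `"module.stream"` on the invocation overrides the last-producer default
#' and selects the nearest prior occurrence of the named module.
#'
#' @param pipeline an [expand_tasklist()] result with bound interfaces.
#' @param target_stage one of `pipeline$stages`.
#' @param stream input stream name.
#' @return the source stage (an element of `pipeline$stages`), with
#'   attribute `source_stream` naming the stream on the source side.
#' @export
resolve_stream_source <- function(pipeline, target_stage, stream) {
  preds <- rev(visible_predecessors(pipeline, target_stage))
  qualified <- target_stage$qualified_inputs[[stream]]
  if (!is.null(qualified)) {
    parts <- strsplit(qualified, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      abort_aq(sprintf(
        "qualified reference '%s' must have the form module.stream",
        qualified), "aqueduct_schema_error")
    }
    for (s in preds) {
      if (s$name == parts[[1]]) {
        if (!parts[[2]] %in% s$interface$output_streams) {
          abort_aq(sprintf(
            "qualified source %s does not declare output stream '%s'",
            stage_dirname(s$name, s$index), parts[[2]]),
            "aqueduct_unconnected_stream_error")
        }
        return(structure(s, source_stream = parts[[2]]))
      }
    }
    abort_aq(sprintf(
      "qualified reference '%s' for stage %s: no prior occurrence of '%s'",
      qualified, stage_dirname(target_stage$name, target_stage$index),
      parts[[1]]), "aqueduct_unconnected_stream_error")
  }
  for (s in preds) {
    if (stream %in% s$interface$output_streams) {
      return(structure(s, source_stream = stream))
    }
  }
  abort_aq(sprintf("unconnected stream: stage %s consumes '%s' but no earlier stage produces it",
                   stage_dirname(target_stage$name, target_stage$index),
                   stream), "aqueduct_unconnected_stream_error")
}

# check that two domains lie on one root-to-leaf path of the tree;
# "sideways" domain pairs (e.g. session vs diffusion_session) cannot
# exchange streams.
assert_domains_related <- function(tree, d1, d2, context) {
  p1 <- domain_path(tree, d1); p2 <- domain_path(tree, d2)
  k <- min(length(p1), length(p2))
  if (!identical(p1[seq_len(k)], p2[seq_len(k)])) {
    abort_aq(sprintf("illegal sideways stream read between domains '%s' and '%s' (%s)",
                     d1, d2, context), "aqueduct_illegal_read_error")
  }
}

#' Build the instance-level dependency map of a pipeline
#'
#' For every (target stage, input stream) pair the producing stage is
#' resolved, instances of every stage are enumerated for the study, and
#' dependency edges are computed instance-by-instance: equal domains give
#' one edge between matching coordinates; an ancestor-domain source gives
#' each target instance one edge from its unique ancestor instance; a
#' descendant-domain source gives a fan-in of all source instances beneath
#' the target's coordinate. No edge ever connects disjoint coordinates.
#'
#' @param pipeline an [expand_tasklist()] result with bound interfaces.
#' @param study a [study_description()].
#' @param tree a [domain_tree()].
#' @return object of class `dependency_map`: `instances` (per stage order, a
#'   list of instance keys), `edges` (list of `list(source, target, stream,
#'   source_stream)` where source/target are instance labels),
#'   `instance_index` (label to instance), and `stage_sources`.
#' @export
build_dependency_map <- function(pipeline, study, tree = domain_tree()) {
  stages <- pipeline$stages
  instances <- lapply(stages, enumerate_instances, study = study, tree = tree)
  labels <- lapply(instances, function(ii) vapply(ii, instance_label, ""))
  instance_index <- list()
  for (i in seq_along(stages)) {
    for (j in seq_along(instances[[i]])) {
      inst <- instances[[i]][[j]]
      inst$stage_order <- i
      inst$dir <- if (!is.null(stages[[i]]$remote_root)) {
        do.call(file.path, as.list(c(stages[[i]]$remote_root,
                                     stages[[i]]$remote_dirname,
                                     unname(inst$coordinate))))
      } else {
        instance_directory(inst, study, stages[[i]]$branch_suffix)
      }
      inst$remote <- !is.null(stages[[i]]$remote_root)
      instance_index[[labels[[i]][[j]]]] <- inst
      instances[[i]][[j]] <- inst
    }
  }
  edges <- list()
  stage_sources <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    target <- stages[[i]]
    streams <- target$interface$input_streams
    src_info <- list()
    for (stream in streams) {
      source <- resolve_stream_source(pipeline, target, stream)
      src_stream <- attr(source, "source_stream")
      assert_domains_related(tree, source$interface$domain,
                             target$interface$domain,
                             sprintf("stream '%s' into %s", stream,
                                     stage_dirname(target$name, target$index)))
      src_info[[stream]] <- list(stage_order = source$order,
                                 stream = src_stream)
      src_instances <- instances[[source$order]]
      for (tj in seq_along(instances[[i]])) {
        tgt_inst <- instances[[i]][[tj]]
        for (sj in seq_along(src_instances)) {
          rel <- coordinate_relation(src_instances[[sj]]$coordinate,
                                     tgt_inst$coordinate)
          if (rel == "disjoint") next
          edges[[length(edges) + 1L]] <- list(
            source = labels[[source$order]][[sj]],
            target = labels[[i]][[tj]],
            stream = stream, source_stream = src_stream)
        }
      }
    }
    stage_sources[[i]] <- src_info
  }
  # invariant: no disjoint-coordinate edge (guaranteed above, asserted cheap)
  structure(list(instances = instances, edges = edges,
                 instance_index = instance_index,
                 stage_sources = stage_sources, stages = stages),
            class = "dependency_map")
}

#' @export
print.dependency_map <- function(x, ...) {
  cat(sprintf("<dependency_map> %d stage(s), %d instance(s), %d edge(s)\n",
              length(x$stages), length(x$instance_index), length(x$edges)))
  invisible(x)
}

# ---- stream records -------------------------------------------------------

OUTPUT_MANIFEST <- "output_manifest.json"
INPUT_MANIFEST <- "input_manifest.json"

record_files <- function(dir, paths) {
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                              normalizePath(dir)), "/?"), "",
             normalizePath(paths))
  lapply(seq_along(paths), function(i) {
    list(path = rel[[i]], digest = unname(file_digests(paths[[i]])),
         size = file.size(paths[[i]]))
  })
}

#' Register the outputs of a completed instance
#'
#' One stream record is created per declared output stream; files must lie
#' inside the instance's own directory (a module may write at its domain
#' level or below, never sideways). Files the module produced but did not
#' declare under any stream are ignored and never passed on. The records
#' are persisted to `output_manifest.json` in the instance directory.
#'
#' @param instance instance key (from the dependency map, with `$dir`).
#' @param produced named list: stream name to character vector of file
#'   paths.
#' @param declared character vector of declared output stream names.
#' @return list of stream records (`stream`, `producer`, `files` with path /
#'   digest / size, `created_at`).
#' @export
register_outputs <- function(instance, produced, declared) {
  dir <- normalizePath(instance$dir)
  records <- list()
  for (stream in declared) {
    files <- produced[[stream]]
    if (is.null(files) || length(files) == 0L) {
      abort_aq(sprintf("instance %s declared output stream '%s' but produced no files",
                       instance_label(instance), stream),
               "aqueduct_missing_output_error")
    }
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      abort_aq(sprintf("instance %s: declared output file(s) do not exist: %s",
                       instance_label(instance),
                       paste(missing, collapse = ", ")),
               "aqueduct_missing_output_error")
    }
    norm <- normalizePath(files)
    outside <- norm[!startsWith(norm, paste0(dir, "/")) & norm != dir]
    if (length(outside)) {
      abort_aq(sprintf("instance %s wrote stream '%s' outside its own directory: %s",
                       instance_label(instance), stream,
                       paste(outside, collapse = ", ")),
               "aqueduct_illegal_write_error")
    }
    records[[stream]] <- list(
      stream = stream, producer = instance_label(instance),
      files = record_files(dir, files),
      created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  write_json_atomic(records, file.path(dir, OUTPUT_MANIFEST))
  records
}

#' Read the registered output records of an instance directory
#'
#' @param dir instance directory.
#' @return named list of stream records, or `NULL` when none registered.
#' @export
read_output_records <- function(dir) {
  path <- file.path(dir, OUTPUT_MANIFEST)
  if (!file.exists(path)) return(NULL)
  read_json_file(path)
}

fan_in_key <- function(source_coord, target_coord) {
  extra <- source_coord[setdiff(seq_along(source_coord),
                                seq_along(target_coord))]
  paste0("src_", paste(extra, collapse = "_"))
}

#' Place the input data of an instance into its directory
#'
#' Materializes exactly the files of the requested streams (hard link with
#' copy fallback, or copy) under the instance directory; data the instance
#' did not request are not there and cannot accidentally be used. Sources
#' at the instance's own coordinate or above place files at the directory
#' root; fan-in sources (descendant coordinates) are placed in per-source
#' subdirectories keyed by the source coordinate. A manifest of provenance
#' digests is written to `input_manifest.json`.
#'
#' @param instance instance key with `$dir`.
#' @param edges_in the dependency edges targeting this instance.
#' @param records named list: source instance label to its stream records.
#' @param instance_index map from instance label to instance key (for
#'   source coordinates).
#' @param link hard-link instead of copy when possible.
#' @return the manifest: per stream, a list of source entries with placed
#'   relative paths and digests.
#' @export
place_inputs <- function(instance, edges_in, records, instance_index,
                         link = TRUE) {
  dir <- instance$dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (edge in edges_in) {
    src_records <- records[[edge$source]]
    rec <- src_records[[edge$source_stream]]
    if (is.null(rec)) {
      abort_aq(sprintf("dependency not ready: %s has no record for stream '%s' needed by %s",
                       edge$source, edge$source_stream, edge$target),
               "aqueduct_dependency_error")
    }
    src_inst <- instance_index[[edge$source]]
    rel <- coordinate_relation(src_inst$coordinate, instance$coordinate)
    subdir <- if (rel == "descendant") {
      fan_in_key(src_inst$coordinate, instance$coordinate)
    } else ""
    placed <- list()
    for (f in rec$files) {
      src_path <- file.path(src_inst$dir, f$path)
      if (!file.exists(src_path)) {
        abort_aq(sprintf("dependency not ready: file '%s' of %s is missing",
                         f$path, edge$source), "aqueduct_dependency_error")
      }
      dest_rel <- if (nzchar(subdir)) file.path(subdir, f$path) else f$path
      dest <- file.path(dir, dest_rel)
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      if (file.exists(dest)) unlink(dest)
      ok <- if (link) suppressWarnings(file.link(src_path, dest)) else FALSE
      if (!ok) file.copy(src_path, dest, overwrite = TRUE)
      placed[[length(placed) + 1L]] <- list(path = dest_rel,
                                            digest = f$digest, size = f$size)
    }
    manifest[[edge$stream]] <- c(manifest[[edge$stream]] %||% list(),
                                 list(list(source = edge$source,
                                           source_stream = edge$source_stream,
                                           files = placed)))
  }
  write_json_atomic(manifest, file.path(dir, INPUT_MANIFEST))
  manifest
}
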