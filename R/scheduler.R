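# Incremental, dependency-driven execution.
#
# Each completed instance leaves a flag file done_<module>_<index> in its
# directory; the flag holds a snapshot of the input digests the instance
# ran with. An instance is done iff its flag exists AND the current
# upstream digests equal the snapshot; anything else re-runs, and deleting
# a flag transitively deletes the flags of all downstream dependents.

ENGINE_VERSION <- "0.1.0"
PROVENANCE_FILE <- "provenance.json"

flag_path <- function(instance) {
  file.path(instance$dir, done_flag_name(instance$stage$name,
                                         instance$stage$index))
}

# canonical digest snapshot of one instance's inputs: per input stream, the
# sorted multiset of "source|path|digest" strings over its incoming edges.
input_digest_snapshot <- function(edges_in, records) {
  snap <- list()
  for (edge in edges_in) {
    rec <- records[[edge$source]][[edge$source_stream]]
    entries <- if (is.null(rec)) "<missing>" else
      vapply(rec$files, function(f)
        paste(edge$source, f$path, f$digest, sep = "|"), "")
    snap[[edge$stream]] <- sort(c(snap[[edge$stream]] %||% character(0),
                                  entries))
  }
  snap
}

write_flag <- function(instance, snapshot) {
  write_json_atomic(list(instance = instance_label(instance),
                         input_digest_snapshot = snapshot,
                         completed_at = format(Sys.time(),
                                               "%Y-%m-%dT%H:%M:%S%z")),
                    flag_path(instance))
}

read_flag <- function(instance) {
  p <- flag_path(instance)
  if (!file.exists(p)) return(NULL)
  read_json_file(p)
}

snapshot_equal <- function(a, b) {
  norm <- function(s) {
    s <- lapply(s, function(v) sort(as.character(unlist(v))))
    if (length(s) == 0L) return(stats::setNames(list(), character(0)))
    s[order(names(s))]
  }
  identical(norm(a), norm(b))
}

# live output records of every instance, keyed by label. Remote instances
# are re-digested from file bytes so out-of-band mutation is detected.
collect_records <- function(map) {
  records <- list()
  for (label in names(map$instance_index)) {
    inst <- map$instance_index[[label]]
    recs <- read_output_records(inst$dir)
    if (is.null(recs)) next
    if (isTRUE(inst$remote)) {
      for (s in names(recs)) {
        recs[[s]]$files <- lapply(recs[[s]]$files, function(f) {
          p <- file.path(inst$dir, f$path)
          if (file.exists(p)) f$digest <- unname(file_digests(p))
          f
        })
      }
    }
    records[[label]] <- recs
  }
  records
}

edges_by_target <- function(map) {
  idx <- list()
  for (edge in map$edges) idx[[edge$target]] <- c(idx[[edge$target]],
                                                  list(edge))
  idx
}

# downstream reachability over instance labels
downstream_closure <- function(map, labels) {
  adj <- list()
  for (edge in map$edges) adj[[edge$source]] <- c(adj[[edge$source]],
                                                  edge$target)
  seen <- character(0)
  frontier <- unique(labels)
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- setdiff(nxt, c(seen, frontier))
    seen <- union(seen, frontier)
    frontier <- nxt
  }
  seen
}

#' Is an instance complete?
#'
#' True iff the instance's completion flag exists and the current upstream
#' digests equal the snapshot recorded in the flag (so adding a subject,
#' changing a setting-driven output, or touching a remote input upstream
#' makes the instance incomplete again).
#'
#' @param instance instance key (with `$dir`), e.g. from a plan's
#'   `map$instance_index`.
#' @param map the plan's `dependency_map`.
#' @param records live records from all instances; recomputed when `NULL`.
#' @return logical.
#' @export
is_done <- function(instance, map, records = NULL) {
  flag <- read_flag(instance)
  if (is.null(flag)) return(FALSE)
  if (is.null(records)) records <- collect_records(map)
  ebt <- edges_by_target(map)
  current <- input_digest_snapshot(ebt[[instance_label(instance)]] %||% list(),
                                   records)
  snapshot_equal(current, flag$input_digest_snapshot %||% list())
}

#' Invalidate an instance and its downstream dependents
#'
#' Deletes the instance's completion flag and, transitively, the flags of
#' every instance that depends on it; upstream instances are untouched.
#' Idempotent: absent flags are simply reported as part of the closed set.
#'
#' @param plan a [build_plan()] result (or an `analysis_spec`).
#' @param stage stage name.
#' @param index stage occurrence index (default 1).
#' @param coordinate named character coordinate to restrict to one
#'   instance; `NULL` invalidates every instance of the stage.
#' @return character vector: labels of the closed invalidated set.
#' @export
invalidate <- function(plan, stage, index = 1L, coordinate = NULL) {
  if (inherits(plan, "analysis_spec")) plan <- build_plan(plan)
  map <- plan$map
  seeds <- Filter(function(inst) {
    inst$stage$name == stage && inst$stage$index == index &&
      (is.null(coordinate) ||
         identical(unname(inst$coordinate), unname(coordinate)))
  }, map$instance_index)
  if (length(seeds) == 0L) {
    abort_aq(sprintf("no instance matches stage '%s' index %d", stage, index),
             "aqueduct_schema_error")
  }
  labels <- vapply(seeds, instance_label, "")
  closed <- union(labels, downstream_closure(map, labels))
  for (label in closed) {
    inst <- map$instance_index[[label]]
    if (!isTRUE(inst$remote)) unlink(flag_path(inst))
  }
  sort(closed)
}

# Decide which instances must run: flag/digest invalidation closed
# downstream, then (fixpoint) producers whose payload files were garbage
# collected but are needed by a pending dependent.
plan_execution <- function(map, records) {
  ebt <- edges_by_target(map)
  labels <- names(map$instance_index)
  run <- stats::setNames(logical(length(labels)), labels)
  for (label in labels) {
    inst <- map$instance_index[[label]]
    if (isTRUE(inst$remote)) next
    flag <- read_flag(inst)
    stale <- is.null(flag) ||
      !snapshot_equal(input_digest_snapshot(ebt[[label]] %||% list(), records),
                      flag$input_digest_snapshot %||% list())
    run[[label]] <- stale
  }
  run[downstream_closure(map, labels[run])] <- TRUE
  # gc re-materialization: a done producer whose files are gone must re-run
  # when a running dependent needs them (transitively)
  repeat {
    changed <- FALSE
    for (label in labels[run]) {
      for (edge in ebt[[label]] %||% list()) {
        src <- map$instance_index[[edge$source]]
        if (isTRUE(src$remote) || run[[edge$source]]) next
        recs <- records[[edge$source]]
        rec <- recs[[edge$source_stream]]
        missing <- is.null(rec) ||
          !all(vapply(rec$files, function(f)
            file.exists(file.path(src$dir, f$path)), TRUE))
        if (missing) {
          run[[edge$source]] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # eager flag deletion for everything scheduled to run
  for (label in labels[run]) {
    inst <- map$instance_index[[label]]
    if (!isTRUE(inst$remote)) unlink(flag_path(inst))
  }
  run
}

module_context <- function(plan, inst, manifest) {
  stage <- plan$pipeline$stages[[inst$stage_order]]
  key <- stage_settings_key(stage$name, stage$index)
  inputs <- list()
  inputs_by_source <- list()
  for (stream in names(manifest)) {
    for (entry in manifest[[stream]]) {
      paths <- vapply(entry$files, function(f)
        file.path(inst$dir, f$path), "")
      inputs[[stream]] <- c(inputs[[stream]], paths)
      inputs_by_source[[stream]] <-
        c(inputs_by_source[[stream]],
          list(list(source = entry$source, files = paths)))
    }
  }
  list(instance = inst, coordinate = inst$coordinate, dir = inst$dir,
       settings = plan$params$tasksettings[[key]] %||% list(),
       global = plan$params$global, study = plan$study,
       inputs = inputs, inputs_by_source = inputs_by_source,
       model = plan$analysis$model, tree = plan$tree)
}

#' Run one instance of a module
#'
#' Places the instance's inputs, invokes the module implementation (looked
#' up under the interface's `impl_alias` when present, else its name)
#' restricted to the instance's coordinate, registers the declared output
#' streams, and writes the completion flag with the input-digest snapshot.
#' An error in the implementation marks the instance failed; no flag is
#' written.
#'
#' @param plan a [build_plan()] result.
#' @param instance instance key from the plan's map.
#' @param records live records of upstream instances.
#' @return the instance's new stream records.
#' @export
run_instance <- function(plan, instance, records = NULL) {
  map <- plan$map
  if (is.null(records)) records <- collect_records(map)
  stage <- plan$pipeline$stages[[instance$stage_order]]
  ebt <- edges_by_target(map)
  label <- instance_label(instance)
  manifest <- place_inputs(instance, ebt[[label]] %||% list(), records,
                           map$instance_index,
                           link = !isTRUE(plan$params$global$options$copyinputs))
  impl_name <- stage$interface$impl_alias %||% stage$name
  impl <- get_module_impl(plan$analysis$registry, impl_name)
  ctx <- module_context(plan, instance, manifest)
  log_file <- file.path(instance$dir,
                        paste0("log_", stage_dirname(stage$name, stage$index),
                               ".txt"))
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%OS2 "), ...,
                                "\n", sep = "", file = log_file, append = TRUE)
  log_line("start ", label)
  produced <- impl(ctx)
  out_records <- register_outputs(instance, produced,
                                  stage$interface$output_streams)
  snapshot <- input_digest_snapshot(ebt[[label]] %||% list(), records)
  write_flag(instance, snapshot)
  log_line("done ", label)
  out_records
}

run_initialisation <- function(plan) {
  for (inv in plan$analysis$tasklist$initialisation) {
    iface <- plan$analysis$interfaces[[inv$module_name]]
    impl <- get_module_impl(plan$analysis$registry,
                            iface$impl_alias %||% inv$module_name)
    ctx <- list(settings = merge_nested(iface$settings, inv$local_settings),
                global = plan$params$global, study = plan$study,
                model = plan$analysis$model, tree = plan$tree)
    impl(ctx)
  }
  invisible(NULL)
}

#' Execute an analysis pipeline
#'
#' Builds the instance map and dependency edges, runs the initialisation
#' modules unconditionally, then executes every main instance that is not
#' already done, each only after all its dependency sources have
#' completed. With the `"parallel"` backend, an instance becomes eligible
#' the moment its own dependencies complete, independent of unrelated
#' instances; outputs are identical to the serial backend for
#' deterministic modules. A failed instance blocks its dependents;
#' independent subtrees continue (unless `fail_fast`). The run is recorded
#' in a provenance document at the analysis root.
#'
#' @param analysis an `analysis_spec` (or a prebuilt `pipeline_plan`).
#' @param backend `"localsingle"` (serial, the default) or `"parallel"`
#'   (in-process fork pool).
#' @param width worker-pool width for the parallel backend.
#' @param fail_fast stop at the first failed instance.
#' @return (invisibly) the provenance record: per-instance `status`
#'   (`"ran"`, `"skipped"`, `"failed"`, `"blocked"`), timings, merged
#'   parameters, expanded pipeline, study.
#' @export
run_pipeline <- function(analysis, backend = c("localsingle", "parallel"),
                         width = 2L, fail_fast = FALSE) {
  backend <- match.arg(backend)
  plan <- if (inherits(analysis, "pipeline_plan")) analysis else
    build_plan(analysis)
  map <- plan$map
  run_initialisation(plan)
  records <- collect_records(map)
  # remote sources must be readable before anything depends on them
  if (!is.null(plan$remote)) check_remote_records(plan, records)
  run <- plan_execution(map, records)
  labels <- names(run)
  status <- stats::setNames(ifelse(run, "pending", "skipped"), labels)
  for (label in labels) {
    if (isTRUE(map$instance_index[[label]]$remote)) status[[label]] <- "external"
  }
  timings <- stats::setNames(numeric(length(labels)), labels)
  ebt <- edges_by_target(map)

  deps_ok <- function(label) {
    all(vapply(ebt[[label]] %||% list(), function(e)
      status[[e$source]] %in% c("skipped", "ran", "external"), TRUE))
  }
  deps_failed <- function(label) {
    any(vapply(ebt[[label]] %||% list(), function(e)
      status[[e$source]] %in% c("failed", "blocked"), TRUE))
  }
  exec_one <- function(label) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      list(ok = TRUE, records = run_instance(plan, map$instance_index[[label]],
                                             records)),
      error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    res$elapsed <- proc.time()[["elapsed"]] - t0
    res
  }

  if (backend == "localsingle") {
    for (label in labels) {
      if (status[[label]] != "pending") next
      if (deps_failed(label)) { status[[label]] <- "blocked"; next }
      res <- exec_one(label)
      timings[[label]] <- res$elapsed
      if (res$ok) {
        status[[label]] <- "ran"
        records[[label]] <- res$records
      } else {
        status[[label]] <- "failed"
        attr(status, "errors") <- c(attr(status, "errors"),
                                    stats::setNames(res$error, label))
        if (fail_fast) break
      }
    }
  } else {
    repeat {
      pending <- labels[status == "pending"]
      if (length(pending) == 0L) break
      blocked <- pending[vapply(pending, deps_failed, TRUE)]
      status[blocked] <- "blocked"
      pending <- setdiff(pending, blocked)
      ready <- pending[vapply(pending, deps_ok, TRUE)]
      if (length(ready) == 0L) {
        if (length(pending)) status[pending] <- "blocked"
        break
      }
      results <- parallel::mclapply(ready, exec_one,
                                    mc.cores = max(1L, as.integer(width)))
      for (i in seq_along(ready)) {
        res <- results[[i]]
        label <- ready[[i]]
        if (inherits(res, "try-error") || !isTRUE(res$ok)) {
          status[[label]] <- "failed"
          msg <- if (is.list(res)) res$error else as.character(res)
          attr(status, "errors") <- c(attr(status, "errors"),
                                      stats::setNames(msg, label))
        } else {
          status[[label]] <- "ran"
          records[[label]] <- res$records
          timings[[label]] <- res$elapsed
        }
      }
      if (fail_fast && any(status == "failed")) break
    }
    if (fail_fast && any(status == "failed")) {
      status[status == "pending"] <- "blocked"
    }
  }

  prov <- build_provenance(plan, status, timings, backend)
  trunk <- analysis_trunk_dir(plan$study)
  dir.create(trunk, recursive = TRUE, showWarnings = FALSE)
  write_json_atomic(unclass(prov), file.path(trunk, PROVENANCE_FILE))
  n_failed <- sum(status == "failed")
  if (n_failed > 0) {
    warning(sprintf("pipeline finished with %d failed / %d blocked instance(s)",
                    n_failed, sum(status == "blocked")), call. = FALSE)
  }
  invisible(prov)
}

build_provenance <- function(plan, status, timings, backend) {
  stages <- lapply(plan$pipeline$stages, function(s) {
    list(name = s$name, index = s$index,
         dirname = stage_dirname(s$name, s$index),
         domain = s$interface$domain,
         branch_suffix = s$branch_suffix,
         permanence_of_output = s$interface$permanence_of_output,
         output_streams = as.list(s$interface$output_streams),
         settings_key = stage_settings_key(s$name, s$index),
         remote = !is.null(s$remote_root))
  })
  inst <- lapply(names(status), function(label) {
    i <- plan$map$instance_index[[label]]
    list(label = label, stage = stage_dirname(i$stage$name, i$stage$index),
         coordinate = as.list(i$coordinate), dir = i$dir,
         status = unname(status[[label]]),
         elapsed_s = unname(timings[[label]]))
  })
  errs <- attr(status, "errors")
  structure(list(
    engine_version = ENGINE_VERSION, backend = backend,
    created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    study = unclass(plan$study), parameters = unclass(plan$params),
    stages = stages, instances = inst,
    errors = as.list(errs %||% stats::setNames(list(), character(0))),
    n_ran = sum(status == "ran"), n_skipped = sum(status == "skipped"),
    n_failed = sum(status == "failed"), n_blocked = sum(status == "blocked")
  ), class = "aqueduct_provenance")
}

#' @export
print.aqueduct_provenance <- function(x, ...) {
  cat(sprintf("<provenance> backend=%s ran=%d skipped=%d failed=%d blocked=%d\n",
              x$backend, x$n_ran, x$n_skipped, x$n_failed, x$n_blocked))
  invisible(x)
}

#' Load the provenance record of a completed analysis
#'
#' @param analysis_root the analysis directory (root/analysisid) holding
#'   `provenance.json`.
#' @return the provenance record.
#' @export
load_provenance <- function(analysis_root) {
  path <- file.path(analysis_root, PROVENANCE_FILE)
  if (!file.exists(path)) {
    abort_aq(sprintf("no provenance record at %s", analysis_root),
             "aqueduct_connection_error")
  }
  structure(read_json_file(path), class = "aqueduct_provenance")
}

#' Per-instance status table of an analysis
#'
#' Reads completion flags on disk (and the provenance record when present)
#' and reports one row per instance.
#'
#' @param x an `analysis_spec`, a `pipeline_plan`, or an analysis directory.
#' @return data.frame with columns `stage`, `coordinate`, `done`, `status`.
#' @export
pipeline_status <- function(x) {
  if (is.character(x)) {
    prov <- load_provenance(x)
    df <- do.call(rbind, lapply(prov$instances, function(i) {
      data.frame(stage = i$stage,
                 coordinate = coordinate_key(unlist(i$coordinate) %||%
                                               character(0)),
                 done = file.exists(file.path(
                   i$dir, done_flag_name(sub("_[0-9]{5}$", "", i$stage),
                                         as.integer(sub(".*_", "", i$stage))))),
                 status = i$status, stringsAsFactors = FALSE)
    }))
    return(df)
  }
  plan <- if (inherits(x, "pipeline_plan")) x else build_plan(x)
  records <- collect_records(plan$map)
  do.call(rbind, lapply(names(plan$map$instance_index), function(label) {
    inst <- plan$map$instance_index[[label]]
    data.frame(stage = stage_dirname(inst$stage$name, inst$stage$index),
               coordinate = coordinate_key(inst$coordinate),
               done = isTRUE(inst$remote) ||
                 is_done(inst, plan$map, records),
               status = if (isTRUE(inst$remote)) "external" else
                 if (is_done(inst, plan$map, records)) "done" else "pending",
               stringsAsFactors = FALSE)
  }))
}

#' Export the dependency map as a DOT graph
#'
#' @param plan a `pipeline_plan` (or an `analysis_spec`).
#' @param level `"instance"` (one node per instance) or `"stage"`.
#' @return character scalar of DOT text.
#' @export
export_graph_dot <- function(plan, level = c("instance", "stage")) {
  level <- match.arg(level)
  if (inherits(plan, "analysis_spec")) plan <- build_plan(plan)
  map <- plan$map
  q <- function(x) paste0('"', gsub('"', "'", x), '"')
  lines <- c("digraph pipeline {", "  rankdir=LR;")
  if (level == "instance") {
    for (label in names(map$instance_index)) {
      lines <- c(lines, sprintf("  %s;", q(label)))
    }
    for (e in map$edges) {
      lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                                q(e$source), q(e$target), q(e$stream)))
    }
  } else {
    seen <- character(0)
    for (e in map$edges) {
      s <- sub("@.*", "", e$source); t <- sub("@.*", "", e$target)
      key <- paste(s, t, e$stream)
      if (key %in% seen) next
      seen <- c(seen, key)
      lines <- c(lines, sprintf("  %s -> %s [label=%s];", q(s), q(t),
                                q(e$stream)))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
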