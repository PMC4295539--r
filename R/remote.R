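# Connecting to a remote analysis: bind local input streams to the output
# stream records of an analysis tree elsewhere (e.g. a lab's central
# preprocessing), without duplicating its modules or data. By default a
# stream attaches to the terminal producer of the remote pipeline; explicit
# bindings select an earlier remote stage. Remote digests are re-read on
# every local run, so changed remote data invalidate exactly the dependent
# local instances.

#' Connect an analysis to a remote pipeline
#'
#' @param analysis an `analysis_spec`.
#' @param remote_analysis_root the remote analysis directory
#'   (`<root>/<analysisid>`) containing a provenance record and instance
#'   output manifests.
#' @param bindings optional named list, stream name to remote stage name,
#'   to take a stream from an earlier remote stage than the terminal
#'   producer (e.g. the EPI stream before normalization).
#' @return the modified analysis; binding happens at plan build.
#' @export
connect_remote <- function(analysis, remote_analysis_root, bindings = list()) {
  stopifnot(inherits(analysis, "analysis_spec"))
  analysis$remote <- list(root = remote_analysis_root, bindings = bindings)
  analysis
}

# Build pseudo-stages (negative order, never executed) for every locally
# consumed stream that the remote pipeline should supply.
bind_remote <- function(analysis, pipeline) {
  root <- analysis$remote$root
  bindings <- analysis$remote$bindings
  if (!dir.exists(root)) {
    abort_aq(sprintf("remote analysis root '%s' is not readable", root),
             "aqueduct_connection_error")
  }
  prov <- load_provenance(root)
  remote_stages <- prov$stages

  # streams consumed locally with no visible local producer
  wanted <- character(0)
  for (stage in pipeline$stages) {
    for (stream in stage$interface$input_streams) {
      ok <- tryCatch({
        resolve_stream_source(pipeline, stage, stream); TRUE
      }, aqueduct_unconnected_stream_error = function(e) FALSE)
      if (!ok) wanted <- union(wanted, stream)
    }
  }
  wanted <- union(wanted, names(bindings))

  pseudo <- list()
  order0 <- -length(wanted)
  for (stream in wanted) {
    pick <- NULL
    if (!is.null(bindings[[stream]])) {
      hits <- Filter(function(s) s$name == bindings[[stream]] &&
                       stream %in% unlist(s$output_streams), remote_stages)
      if (length(hits) == 0L) {
        abort_aq(sprintf(
          "remote pipeline has no stage '%s' producing stream '%s'",
          bindings[[stream]], stream), "aqueduct_unconnected_stream_error")
      }
      pick <- hits[[length(hits)]]
    } else {
      hits <- Filter(function(s) stream %in% unlist(s$output_streams),
                     remote_stages)
      if (length(hits) == 0L) {
        abort_aq(sprintf("stream '%s' is absent from the remote pipeline",
                         stream), "aqueduct_unconnected_stream_error")
      }
      pick <- hits[[length(hits)]]  # terminal end of the remote pipeline
    }
    order0 <- order0 + 1L
    pseudo[[length(pseudo) + 1L]] <- list(
      name = paste0("remote.", pick$name), index = pick$index,
      interface = structure(list(
        name = paste0("remote.", pick$name), domain = pick$domain,
        description = sprintf("remote binding of stream '%s'", stream),
        modality = "", settings = list(),
        input_streams = character(0),
        output_streams = stream,
        resource_estimates = list(), permanence_of_output = 0L,
        impl_alias = NULL, extra = list()), class = "module_interface"),
      settings = list(), branch_suffix = "", qualified_inputs = list(),
      branch = 0L, alt = 0L, order = order0,
      remote_root = root, remote_dirname = pick$dirname)
  }
  # merge pseudo stages providing several streams from the same remote stage
  merged <- list()
  for (p in pseudo) {
    key <- paste(p$name, p$index)
    if (!is.null(merged[[key]])) {
      merged[[key]]$interface$output_streams <-
        union(merged[[key]]$interface$output_streams,
              p$interface$output_streams)
    } else merged[[key]] <- p
  }
  merged <- unname(merged)
  # renumber orders below zero, keep remote pipeline order
  for (i in seq_along(merged)) merged[[i]]$order <- i - length(merged) - 1L
  # local stage orders shift to stay above the pseudo stages
  list(stages = merged, provenance = prov)
}

check_remote_records <- function(plan, records) {
  for (label in names(plan$map$instance_index)) {
    inst <- plan$map$instance_index[[label]]
    if (!isTRUE(inst$remote)) next
    if (is.null(records[[label]])) {
      abort_aq(sprintf(
        "remote instance %s carries no output manifest (unreadable remote?)",
        label), "aqueduct_connection_error")
    }
  }
  invisible(NULL)
}
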