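Package: aqueduct
Title: Stream-Based Workflow Engine for Neuroimaging Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative pipeline engine for biological image analysis.
    Processing stages are described by XML (or YAML) module interfaces that
    declare a domain (study, subject, session), settings, and named input and
    output data streams; tasklists compose stages, optionally with branches
    that fork an analysis while sharing an upstream trunk. The engine expands
    a tasklist into indexed stages, wires every input stream to its most
    recent producer, computes instance-level dependency edges across domains,
    and executes instances incrementally: completion flags with input-digest
    snapshots make re-runs skip finished work, while upstream changes
    invalidate exactly the downstream-reachable set. Serial and parallel
    backends, connection to a remote analysis tree, diagnostics collection,
    and permanence-ranked garbage collection are included, together with a
    set of self-contained toy fMRI modules (realignment, smoothing,
    time-series diagnostics, first- and second-level GLM) and a synthetic
    4D study generator used to exercise the engine end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite,
    RNifti,
    parallel,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
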