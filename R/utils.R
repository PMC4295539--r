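# Internal helpers shared across the engine.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Zero-padded stage suffix
#'
#' Stage directories and completion flags carry a five-digit, one-based
#' occurrence index (`_00001`, `_00002`, ...).
#'
#' @param index positive integer occurrence index.
#' @return character scalar such as `"00001"`.
#' @keywords internal
stage_index_label <- function(index) {
  stopifnot(is.numeric(index), index >= 1)
  sprintf("%05d", as.integer(index))
}

stage_dirname <- function(name, index) paste0(name, "_", stage_index_label(index))

done_flag_name <- function(name, index) {
  paste0("done_", name, "_", stage_index_label(index))
}

# MD5 content digest of one or more files (named by path).
file_digests <- function(paths) {
  if (length(paths) == 0L) return(character(0))
  d <- tools::md5sum(paths)
  if (anyNA(d)) {
    stop("cannot digest missing file(s): ",
         paste(paths[is.na(d)], collapse = ", "))
  }
  unname(d)
}

# Atomic write of a JSON document: write temp file then rename.
write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# Coerce XML text content to R values: decimal-looking strings become numbers,
# "true"/"false" become logicals; anything else stays character.
coerce_setting_value <- function(x) {
  if (!is.character(x) || length(x) != 1L) return(x)
  x <- trimws(x)
  if (x %in% c("true", "false")) return(x == "true")
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num) && grepl("^[-+]?[0-9.eE+-]+$", x)) return(num)
  # whitespace-separated numeric vectors ("1 -1 0") are common in contrasts
  if (grepl("^[-+0-9. eE]+$", x) && grepl(" ", x)) {
    parts <- strsplit(x, "[[:space:]]+")[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) return(nums)
  }
  x
}

# Deep merge two nested named lists; values in `over` win. Setting a value to
# NULL in `over` removes it.
merge_nested <- function(base, over) {
  if (!is.list(base) || !is.list(over)) return(over)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_nested(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

# Fetch a dotted path ("acq_details.numdummies") from a nested list.
get_nested <- function(x, path) {
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(x) || is.null(x[[key]])) return(NULL)
    x <- x[[key]]
  }
  x
}

set_nested <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  head <- keys[[1]]
  if (!is.list(x[[head]])) x[[head]] <- list()
  x[[head]] <- set_nested(x[[head]], paste(keys[-1], collapse = "."), value)
  x
}

abort_aq <- function(msg, class) {
  stop(structure(class = c(class, "aqueduct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
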