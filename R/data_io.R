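#' Construct a measurement table of scales
#'
#' A measurement table holds one row per scale with length variables
#' `L1`..`L8` in millimetres, plus optional body-position metadata
#' (`area_label`, one of the 16 squamation areas, and `lateral_line`).
#'
#' @param data data.frame with a `scale_id` column, length-variable columns
#'   drawn from `L1`..`L8`, and optionally `specimen_id`, `area_label`,
#'   `lateral_line`.
#' @param provenance free-text description of where the measurements came from.
#' @return An object of class `measurement_table` with elements `data`,
#'   `variables` (the length variables present, in `L1`..`L8` order),
#'   `units` (always `"mm"`) and `provenance`.
#' @export
measurement_table <- function(data, provenance = "") {
  stopifnot(is.data.frame(data))
  if (!"scale_id" %in% names(data))
    stop_scalemorph("schema", "measurement table requires a 'scale_id' column")
  data$scale_id <- as.character(data$scale_id)
  if (anyDuplicated(data$scale_id))
    stop_scalemorph("integrity", "duplicate scale_id: %s",
                    paste(unique(data$scale_id[duplicated(data$scale_id)]),
                          collapse = ", "))
  vars <- intersect(paste0("L", 1:8), names(data))
  for (v in vars) {
    x <- data[[v]]
    if (!is.numeric(x))
      stop_scalemorph("schema", "column %s is not numeric", v)
    bad <- which(!is.na(x) & (!is.finite(x) | x < 0))
    if (length(bad))
      stop_scalemorph("data", "column %s has negative or non-finite values in rows %s",
                      v, paste(bad, collapse = ", "))
  }
  if ("area_label" %in% names(data)) {
    known <- squamation_area_ids()
    bad <- setdiff(stats::na.omit(unique(as.character(data$area_label))), known)
    if (length(bad))
      stop_scalemorph("schema", "unknown area_label value(s): %s",
                      paste(bad, collapse = ", "))
  }
  structure(list(data = data, variables = vars, units = "mm",
                 provenance = provenance),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d scales, variables: %s (mm)\n",
              nrow(x$data), paste(x$variables, collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.data.frame.measurement_table <- function(x, ...) x$data

#' Number of scales in a measurement table
#' @param table a `measurement_table`.
#' @return integer row count.
#' @export
n_scales <- function(table) nrow(table$data)

#' Read a CSV measurement table
#'
#' Reads a comma-separated table of scale measurements ("." decimal, header
#' row required). The `schema` argument maps canonical column names to the
#' file's own headers, absorbing whatever layout a supplementary table uses.
#' Columns `scale_id`, `L1`, `L3`, `L4`, `L5`, `L6` must be resolvable;
#' `L2`, `L7`, `L8`, `specimen_id`, `area_label` and `lateral_line` are
#' optional. Malformed numeric cells abort with the offending row and column
#' named, so no row is ever silently dropped.
#'
#' @param path CSV file path.
#' @param schema named character vector, canonical name -> file column name.
#'   Unmapped canonical names default to themselves.
#' @return a [measurement_table()].
#' @export
read_measurement_table <- function(path, schema = NULL) {
  if (!file.exists(path))
    stop_scalemorph("io", "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  canon <- c("scale_id", "specimen_id", paste0("L", 1:8),
             "area_label", "lateral_line")
  map <- stats::setNames(canon, canon)
  if (!is.null(schema)) map[names(schema)] <- schema
  required <- c("scale_id", "L1", "L3", "L4", "L5", "L6")
  for (cn in required) {
    if (!map[[cn]] %in% names(raw))
      stop_scalemorph("schema", "required column '%s' (mapped to '%s') missing from %s",
                      cn, map[[cn]], basename(path))
  }
  out <- data.frame(scale_id = raw[[map[["scale_id"]]]],
                    stringsAsFactors = FALSE)
  if (map[["specimen_id"]] %in% names(raw))
    out$specimen_id <- raw[[map[["specimen_id"]]]]
  for (v in paste0("L", 1:8)) {
    col <- map[[v]]
    if (!col %in% names(raw)) next
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(trimws(txt)) & is.na(num))
    if (length(bad))
      stop_scalemorph("parse", "malformed numeric cell(s) in column %s, row(s) %s of %s",
                      v, paste(bad, collapse = ", "), basename(path))
    out[[v]] <- num
  }
  if (map[["area_label"]] %in% names(raw)) {
    al <- raw[[map[["area_label"]]]]
    al[!nzchar(trimws(al))] <- NA_character_
    out$area_label <- al
  }
  if (map[["lateral_line"]] %in% names(raw))
    out$lateral_line <- as.logical(raw[[map[["lateral_line"]]]])
  measurement_table(out, provenance = path)
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurement_table()]: `read(write(T))` reproduces every
#' value (to full double precision as printed with 15 significant digits).
#'
#' @param table a `measurement_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  df <- table$data
  for (v in table$variables) df[[v]] <- format(df[[v]], digits = 15,
                                               trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Parses the community-standard TPS dialect: per specimen one `LM=<n>` line,
#' `n` whitespace-separated coordinate lines, then optional `ID=`, `IMAGE=`
#' and `SCALE=` lines. Coordinates are multiplied by `SCALE` when present.
#' Blocks whose landmark count differs from 11 are parsed and returned but
#' flagged non-conforming (attribute `conforming = FALSE`) with a warning;
#' downstream morphometry accepts only conforming configurations.
#'
#' @param path TPS file path.
#' @return list of [landmark_config()] objects, one per specimen block.
#' @export
read_tps <- function(path) {
  if (!file.exists(path))
    stop_scalemorph("io", "file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lm_at <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(lm_at))
    stop_scalemorph("format", "no LM= line found in %s", basename(path))
  if (lm_at[1] != 1)
    stop_scalemorph("format", "content before first LM= line in %s", basename(path))
  bounds <- c(lm_at, length(lines) + 1L)
  configs <- vector("list", length(lm_at))
  for (b in seq_along(lm_at)) {
    block <- lines[bounds[b]:(bounds[b + 1] - 1L)]
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1],
                                            ignore.case = TRUE)))
    if (is.na(n_lm))
      stop_scalemorph("format", "unreadable LM= line in block %d", b)
    coord_lines <- block[-1][!grepl("^[A-Za-z]+\\s*=", block[-1])]
    if (length(coord_lines) != n_lm)
      stop_scalemorph("format",
                      "block %d declares LM=%d but has %d coordinate lines",
                      b, n_lm, length(coord_lines))
    xy <- do.call(rbind, lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 2 || anyNA(v))
        stop_scalemorph("format", "bad coordinate line in block %d: '%s'", b, l)
      v
    }))
    keyval <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), block, ignore.case = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", block[hit[1]],
                           ignore.case = TRUE) else NA_character_
    }
    sc <- suppressWarnings(as.numeric(keyval("SCALE")))
    if (!is.na(sc)) xy <- xy * sc
    id <- keyval("ID")
    if (is.na(id)) id <- sprintf("block_%d", b)
    conforming <- n_lm == 11L
    if (!conforming)
      warning(sprintf("TPS block %d ('%s') has LM=%d, not 11; excluded from morphometry",
                      b, id, n_lm), call. = FALSE)
    cfg <- if (conforming) landmark_config(xy, scale_id = id)
           else structure(list(points = xy, scale_id = id, view = "crown"),
                          class = "landmark_config")
    attr(cfg, "conforming") <- conforming
    configs[[b]] <- cfg
  }
  configs
}

#' Write a pipeline result as a structured JSON report
#'
#' Serializes every stage of a pipeline run (correlation report, dendrogram
#' merge list, partition, classification history, morphotype summary, group
#' to morphotype mapping, squamation map) with stable key order and full
#' float precision, so write -> load -> write is byte-identical.
#'
#' @param result a `pipeline_result` from [run_pipeline()] (or any list of
#'   serializable pieces).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  payload <- report_payload(result)
  ser <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      pretty = TRUE, na = "null",
                                      null = "null")
  # one parse/serialize round canonicalises container shapes, so that
  # write -> read -> write is byte-identical
  canon <- ser(jsonlite::fromJSON(ser(payload), simplifyVector = TRUE))
  writeLines(canon, path)
  invisible(path)
}

#' Read back a JSON report
#' @param path JSON path written by [write_report()].
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# flatten S3 pieces into plain lists/data.frames jsonlite can serialize stably
report_payload <- function(result) {
  strip <- function(x) {
    if (is.function(x))
      stop_scalemorph("internal", "unserializable field of class function")
    if (inherits(x, "measurement_table"))
      return(list(n = nrow(x$data), variables = x$variables,
                  provenance = x$provenance))
    if (is.environment(x))
      stop_scalemorph("internal", "unserializable field of class environment")
    if (is.data.frame(x)) return(x)
    if (is.matrix(x)) return(as.data.frame(x))
    if (is.list(x)) {
      x <- unclass(x)
      return(lapply(x, strip))
    }
    x
  }
  lapply(result, strip)
}
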