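# On-disk formats. Two dialects for trace bundles:
#   csv_sidecar    one numeric CSV per sweep (columns time_s, command,
#                  response, full double precision) plus one JSON sidecar
#                  with the cell metadata and the sweep manifest -- flat
#                  and inspectable;
#   hdf5_container a single HDF5 file with one group per sweep and the
#                  metadata stored as HDF5 attributes -- compact for
#                  multi-sweep cells.
# Canonical units (mV, nA, s, Hz) are assumed on disk; a `time_unit` of
# "ms" in a sidecar is converted on read. Missing values are written as
# empty CSV fields, never 0.

protocol_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  c(list(type = if (inherits(p, "ramp_spec")) "ramp" else "step"), unclass(p))
}

protocol_from_list <- function(l) {
  if (is.null(l) || is.null(l$type)) return(NULL)
  if (l$type == "ramp")
    ramp_spec(l$start_level, l$peak_level, l$speed, l$baseline_duration)
  else
    step_spec(l$baseline_level, l$step_level, l$step_duration,
              l$baseline_duration)
}

require_fields <- function(meta, fields, where) {
  for (f in fields)
    if (is.null(meta[[f]]))
      pq_stop(sprintf("missing metadata field '%s' in %s", f, where),
              "picquant_metadata_error")
  invisible(TRUE)
}

#' Write a cell's trace bundle
#'
#' @param cell a [cell_record()].
#' @param path for `csv_sidecar`, a directory (created if needed); for
#'   `hdf5_container`, the `.h5` file path.
#' @param dialect `"csv_sidecar"` or `"hdf5_container"`.
#' @return the path of the sidecar JSON (csv dialect) or the HDF5 file,
#'   invisibly usable by [read_trace_bundle()].
#' @export
write_trace_bundle <- function(cell, path,
                               dialect = c("csv_sidecar", "hdf5_container")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv_sidecar") write_bundle_csv(cell, path)
  else write_bundle_hdf5(cell, path)
}

write_bundle_csv <- function(cell, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) pq_stop(paste("unwritable path:", dir), "picquant_io_error")
  sweep_meta <- list()
  for (i in seq_along(cell$sweeps)) {
    sw <- cell$sweeps[[i]]
    fn <- sprintf("%s_sweep%02d.csv", cell$cell_id, i)
    con <- file(file.path(dir, fn), "w", encoding = "UTF-8")
    writeLines("time_s,command,response", con)
    writeLines(sprintf("%.17g,%.17g,%.17g", sw$time, sw$command, sw$response), con)
    close(con)
    sweep_meta[[i]] <- list(file = fn, mode = sw$mode,
                            sampling_rate_hz = sw$sampling_rate,
                            protocol = protocol_to_list(sw$protocol))
  }
  sidecar <- file.path(dir, paste0(cell$cell_id, ".json"))
  meta <- list(cell_id = cell$cell_id, animal_id = cell$animal_id,
               genotype = cell$genotype, age_days = cell$age_days,
               rmp = if (is.na(cell$rmp)) NULL else cell$rmp,
               sweeps = sweep_meta)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(sidecar)
}

write_bundle_hdf5 <- function(cell, path) {
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) pq_stop(paste("unwritable path:", path), "picquant_io_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(cell$cell_id, fid, "cell_id")
  rhdf5::h5writeAttribute(cell$animal_id, fid, "animal_id")
  rhdf5::h5writeAttribute(cell$genotype, fid, "genotype")
  rhdf5::h5writeAttribute(as.integer(cell$age_days), fid, "age_days")
  rhdf5::h5writeAttribute(as.numeric(cell$rmp), fid, "rmp")
  rhdf5::H5Fclose(fid)
  rhdf5::h5createGroup(path, "sweeps")
  for (i in seq_along(cell$sweeps)) {
    sw <- cell$sweeps[[i]]
    g <- sprintf("sweeps/sweep%02d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(sw$time, path, paste0(g, "/time"))
    rhdf5::h5write(sw$command, path, paste0(g, "/command"))
    rhdf5::h5write(sw$response, path, paste0(g, "/response"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(sw$mode, gid, "mode")
    rhdf5::h5writeAttribute(sw$sampling_rate, gid, "sampling_rate_hz")
    rhdf5::h5writeAttribute(
      as.character(jsonlite::toJSON(protocol_to_list(sw$protocol),
                                    auto_unbox = TRUE, digits = NA, null = "null")),
      gid, "protocol_json")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read a cell's trace bundle
#'
#' @param path the sidecar JSON path or bundle directory (`csv_sidecar`),
#'   or the `.h5` file (`hdf5_container`).
#' @param dialect `"csv_sidecar"` or `"hdf5_container"`.
#' @return a [cell_record()].
#' @export
read_trace_bundle <- function(path,
                              dialect = c("csv_sidecar", "hdf5_container")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    pq_stop(paste("path does not exist:", path), "picquant_io_error")
  if (dialect == "csv_sidecar") read_bundle_csv(path) else read_bundle_hdf5(path)
}

read_sweep_csv <- function(csv_path, meta, where) {
  require_fields(meta, c("mode", "sampling_rate_hz"), where)
  d <- utils::read.csv(csv_path, na.strings = "", fileEncoding = "UTF-8")
  need <- c("time_s", "command", "response")
  if (!all(need %in% names(d)))
    pq_stop(sprintf("sweep file %s lacks columns %s", basename(csv_path),
                    paste(setdiff(need, names(d)), collapse = ", ")),
            "picquant_format_error")
  if (anyNA(d$time_s) || anyNA(d$command) || anyNA(d$response))
    pq_stop(sprintf("length mismatch / missing values in %s", basename(csv_path)),
            "picquant_format_error")
  tt <- d$time_s
  rate <- meta$sampling_rate_hz
  if (identical(meta$time_unit, "ms")) { tt <- tt / 1000 }
  trace_sweep(tt, d$command, d$response, meta$mode, rate,
              protocol_from_list(meta$protocol))
}

read_bundle_csv <- function(path) {
  if (dir.exists(path)) {
    js <- list.files(path, pattern = "\\.json$", full.names = TRUE)
    if (length(js) != 1L)
      pq_stop(sprintf("expected exactly one JSON sidecar in %s, found %d",
                      path, length(js)), "picquant_io_error")
    path <- js
  }
  meta <- jsonlite::read_json(path)
  dir <- dirname(path)
  require_fields(meta, c("cell_id", "animal_id", "genotype", "age_days"),
                 basename(path))
  if (is.null(meta$sweeps)) {
    # minimal single-sweep layout: one CSV next to the sidecar
    csv <- sub("\\.json$", ".csv", path)
    if (!file.exists(csv))
      pq_stop(paste("sweep CSV not found:", csv), "picquant_io_error")
    sweeps <- list(read_sweep_csv(csv, meta, basename(path)))
  } else {
    sweeps <- lapply(meta$sweeps, function(sm) {
      require_fields(sm, "file", basename(path))
      read_sweep_csv(file.path(dir, sm$file), sm, basename(path))
    })
  }
  cell_record(meta$cell_id, meta$animal_id, meta$genotype, meta$age_days,
              sweeps, rmp = if (is.null(meta$rmp)) NA_real_ else meta$rmp)
}

read_bundle_hdf5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  meta <- rhdf5::h5readAttributes(path, "/")
  require_fields(meta, c("cell_id", "animal_id", "genotype", "age_days"), path)
  names_in <- rhdf5::h5ls(path)
  gnames <- sort(names_in$name[names_in$group == "/sweeps" & names_in$otype == "H5I_GROUP"])
  sweeps <- lapply(gnames, function(g) {
    full <- paste0("sweeps/", g)
    a <- rhdf5::h5readAttributes(path, full)
    require_fields(a, c("mode", "sampling_rate_hz"), full)
    proto <- if (!is.null(a$protocol_json))
      protocol_from_list(jsonlite::fromJSON(a$protocol_json))
    trace_sweep(as.numeric(rhdf5::h5read(path, paste0(full, "/time"))),
                as.numeric(rhdf5::h5read(path, paste0(full, "/command"))),
                as.numeric(rhdf5::h5read(path, paste0(full, "/response"))),
                a$mode, a$sampling_rate_hz, proto)
  })
  rmp <- if (is.null(meta$rmp) || is.na(meta$rmp)) NA_real_ else as.numeric(meta$rmp)
  cell_record(meta$cell_id, meta$animal_id, meta$genotype,
              as.integer(meta$age_days), sweeps, rmp = rmp)
}

feature_table_schema <- function() {
  list(meta = c("cell_id", "animal_id", "genotype", "age_days"),
       features = canonical_features(),
       optional = c("age_group", "firing_class"))
}

#' Write the feature table as delimited text
#'
#' Header uses the canonical column names; missing values are written as
#' empty fields.
#'
#' @param table a feature table (may be empty: header-only file).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  sch <- feature_table_schema()
  known <- c(sch$meta, sch$optional, sch$features)
  unknown <- setdiff(names(table), known)
  if (length(unknown))
    pq_stop(paste("unknown feature-table column(s):",
                  paste(unknown, collapse = ", ")), "picquant_schema_error")
  missing_cols <- setdiff(c(sch$meta, sch$features), names(table))
  if (length(missing_cols))
    pq_stop(paste("feature-table column(s) missing:",
                  paste(missing_cols, collapse = ", ")), "picquant_schema_error")
  cols <- c(sch$meta, intersect(sch$optional, names(table)), sch$features)
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame of class `feature_table`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  sch <- feature_table_schema()
  unknown <- setdiff(names(tab), c(sch$meta, sch$optional, sch$features))
  if (length(unknown))
    pq_stop(paste("unknown feature-table column(s):",
                  paste(unknown, collapse = ", ")), "picquant_schema_error")
  class(tab) <- c("feature_table", "data.frame")
  tab
}
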