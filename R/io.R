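# Plain-text readers and writers shared by all stages.  Spectra travel as
# two-column CSV plus a JSON sidecar with the acquisition settings;
# kinetic series as CSV with the temperature in a header comment; oil
# records as CSV with a units row.  A minimal JCAMP-DX (XYDATA) reader is
# provided for interchange.

#' Write / read a spectrum as CSV with a JSON settings sidecar
#'
#' `write_spectrum()` writes `field_G,intensity` rows to `path` and the
#' acquisition settings to `<path>.json`; `read_spectrum()` reverses it
#' (the sidecar is optional on read).
#'
#' @param spectrum an `epr_spectrum`.
#' @param path CSV file path.
#' @return `write_spectrum()` the path, invisibly; `read_spectrum()` the
#'   spectrum.
#' @export
write_spectrum <- function(spectrum, path) {
  .check_spectrum(spectrum)
  utils::write.csv(
    data.frame(field_G = spectrum$field, intensity = spectrum$intensity),
    path, row.names = FALSE)
  meta <- spectrum$meta
  class(meta) <- NULL
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("field_G", "intensity") %in% names(df)))
    stop("spectrum CSV needs columns field_G, intensity")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    raw <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    do.call(acquisition_settings,
            raw[intersect(names(raw), names(formals(acquisition_settings)))])
  } else {
    acquisition_settings(
      center_field = mean(range(df$field_G)),
      sweep_width = diff(range(df$field_G)),
      n_points = nrow(df))
  }
  meta$center_field <- mean(range(df$field_G))
  meta$sweep_width <- diff(range(df$field_G))
  meta$n_points <- nrow(df)
  .check_spectrum(structure(list(field = df$field_G, intensity = df$intensity,
                                 meta = meta),
                            class = "epr_spectrum"))
}

#' Read a minimal JCAMP-DX record with tabular XYDATA
#'
#' Supports `##XYDATA=(XY..XY)` point tables (one `x[,;\\s]y` pair per
#' line) and the `##XYDATA=(X++(Y..Y))` affine form via `FIRSTX`,
#' `LASTX`, `NPOINTS` and `YFACTOR`.  Compression schemes (DIF/DUP/SQZ)
#' are not supported.
#'
#' @param path JCAMP-DX file path.
#' @return An `epr_spectrum` (acquisition settings reconstructed from the
#'   axis; frequency defaults to 9.4 GHz unless a `.OBSERVE FREQUENCY`
#'   field is present).
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field1 <- function(tag) {
    hit <- grep(paste0("^##", tag, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(paste0("^##", tag, "="), "", hit[1]))
  }
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block found")
  form <- sub("^##XYDATA=", "", lines[start[1]])
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) - 1L else length(lines)
  body <- lines[(start[1] + 1L):end]
  body <- body[!grepl("^##", body) & nzchar(trimws(body))]
  if (grepl("X\\+\\+", form)) {
    firstx <- field1("FIRSTX"); lastx <- field1("LASTX")
    npts <- field1("NPOINTS")
    yfac <- field1("YFACTOR"); if (is.na(yfac)) yfac <- 1
    ys <- unlist(lapply(body, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[[:space:],;]+")[[1]])
      v[-1]  # first token per line is the X start value
    }))
    if (is.na(npts)) npts <- length(ys)
    if (length(ys) != npts) stop("XYDATA Y count does not match NPOINTS")
    x <- seq(firstx, lastx, length.out = npts)
    y <- ys * yfac
  } else {
    pairs <- do.call(rbind, lapply(body, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[[:space:],;]+")[[1]])
      matrix(v, ncol = 2, byrow = TRUE)
    }))
    x <- pairs[, 1]; y <- pairs[, 2]
  }
  freq <- field1(".OBSERVE FREQUENCY"); if (is.na(freq)) freq <- 9.4
  meta <- acquisition_settings(microwave_frequency = freq,
                               center_field = mean(range(x)),
                               sweep_width = diff(range(x)),
                               n_points = length(x))
  .check_spectrum(structure(list(field = x, intensity = y, meta = meta),
                            class = "epr_spectrum"))
}

#' Write / read a kinetic series as CSV
#'
#' Columns `time_min,intensity`; the temperature travels in a
#' `# temperature_C:` header comment.
#'
#' @param series a [kinetic_series()].
#' @param path CSV file path.
#' @return `write_kinetic_series()` the path, invisibly;
#'   `read_kinetic_series()` the series.
#' @export
write_kinetic_series <- function(series, path) {
  stopifnot(inherits(series, "kinetic_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_C: %g", series$temperature), con)
  utils::write.csv(data.frame(time_min = series$time,
                              intensity = series$intensity),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_series
#' @export
read_kinetic_series <- function(path) {
  first <- readLines(path, n = 1L)
  temp <- if (grepl("^#\\s*temperature_C:", first))
    as.numeric(sub("^#\\s*temperature_C:\\s*", "", first)) else 90
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_min", "intensity") %in% names(df)))
    stop("kinetic series CSV needs columns time_min, intensity")
  kinetic_series(df$time_min, df$intensity, temperature = temp)
}

.OIL_UNITS <- c(method = "", yield_pct = "%", PV = "ueq_O2/g",
                TPC = "mg_CA/g", RSA = "umol_trolox/g", FFA = "%",
                `C16:0` = "%", `C18:0` = "%", `C18:1` = "%", `C18:2` = "%",
                AUC = "a.u.")

#' Write / read oil records as CSV with a units row
#'
#' The first data row carries unit tags which are validated on read
#' (units are fixed by the model: PV in ueq O2/g, TPC in mg caffeic
#' acid/g, FFA in %).
#'
#' @param records named list of [oil_record()]s.
#' @param path CSV file path.
#' @return `write_oil_records()` the path, invisibly;
#'   `read_oil_records()` a named list of records.
#' @export
write_oil_records <- function(records, path) {
  if (inherits(records, "oil_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    fa <- r$fatty_acids
    data.frame(method = r$method, yield_pct = r$yield_pct, PV = r$PV,
               TPC = r$TPC, RSA = r$RSA, FFA = r$FFA,
               `C16:0` = if (is.null(fa)) NA else fa[["C16:0"]],
               `C18:0` = if (is.null(fa)) NA else fa[["C18:0"]],
               `C18:1` = if (is.null(fa)) NA else fa[["C18:1"]],
               `C18:2` = if (is.null(fa)) NA else fa[["C18:2"]],
               AUC = r$AUC_measured, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  units <- data.frame(as.list(.OIL_UNITS[names(df)]), check.names = FALSE)
  out <- rbind(units, as.data.frame(lapply(df, as.character),
                                    check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oil_records
#' @export
read_oil_records <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  units <- raw[1, , drop = FALSE]
  for (nm in c("PV", "TPC", "FFA")) {
    if (!nm %in% names(units)) stop("missing column: ", nm)
    if (units[[nm]] != .OIL_UNITS[[nm]])
      stop("unit mismatch for ", nm, ": expected '", .OIL_UNITS[[nm]],
           "', got '", units[[nm]], "'")
  }
  df <- raw[-1, , drop = FALSE]
  num <- function(x) suppressWarnings(as.numeric(x))
  recs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    fa_names <- c("C16:0", "C18:0", "C18:1", "C18:2")
    fa <- if (all(fa_names %in% names(r)) && !any(is.na(num(unlist(r[fa_names])))))
      stats::setNames(num(unlist(r[fa_names])), fa_names) else NULL
    oil_record(r$method, PV = num(r$PV), TPC = num(r$TPC), FFA = num(r$FFA),
               AUC_measured = if ("AUC" %in% names(r)) num(r$AUC) else NA,
               yield_pct = if ("yield_pct" %in% names(r)) num(r$yield_pct) else NA,
               RSA = if ("RSA" %in% names(r)) num(r$RSA) else NA,
               fatty_acids = fa)
  })
  stats::setNames(recs, df$method)
}

#' Write / read a feature matrix as CSV
#'
#' Samples in rows; the first columns are `sample_id` plus the
#' sample-info labels (`method`, `bio`, `tech` when present), followed by
#' one column per feature.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file path.
#' @return `write_feature_matrix()` the path, invisibly;
#'   `read_feature_matrix()` the matrix (state `"raw"`).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(data.frame(sample_id = rownames(fm$values)),
              fm$sample_info, as.data.frame(fm$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column")
  info_cols <- intersect(c("method", "bio", "tech"), names(df))
  if (!"method" %in% info_cols) stop("missing method column")
  feat_cols <- setdiff(names(df), c("sample_id", info_cols))
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(values) <- df$sample_id
  feature_matrix(values, df[, info_cols, drop = FALSE])
}
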