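#' Read cytometry events from CSV or FCS
#'
#' CSV files are comma-separated with a header row, one event per row,
#' marker intensities in columns named after the markers and annotation
#' columns prefixed `meta_`. FCS files (3.1, float32 list mode) store
#' annotations as integer-coded channels whose level maps live in custom
#' TEXT keywords, as written by [write_events()].
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @param markers Marker channels that must be present.
#' @return Event tibble (raw scale, untransformed).
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        markers = gd_markers()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  events <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    read_fcs(path)
  }
  missing <- setdiff(markers, names(events))
  if (length(missing) > 0) {
    abort(sprintf("missing marker channel(s) in %s: %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  events <- tibble::as_tibble(events)
  attr(events, "transformed") <- FALSE
  events
}

#' Write cytometry events to CSV or FCS
#'
#' @param events Event tibble.
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(events, path, progress = FALSE)
  } else {
    write_fcs(events, path)
  }
  invisible(path)
}

#' Arcsinh-transform marker intensities
#'
#' Standard cytometry variance-stabilising transform
#' `x -> asinh(x / cofactor)`, applied elementwise to the marker columns.
#' Annotation columns are untouched. Applying it twice is an error.
#'
#' @param events Event tibble on the raw scale.
#' @param cofactor Positive scale cofactor (default 150, conventional for
#'   fluorescence intensities).
#' @param markers Columns to transform.
#' @return Transformed event tibble (flagged via the `transformed`
#'   attribute).
#' @examples
#' ev <- tibble::tibble(CD24 = c(0, 150))
#' arcsinh_transform(ev, markers = "CD24")$CD24  # 0, asinh(1)
#' @export
arcsinh_transform <- function(events, cofactor = 150, markers = gd_markers()) {
  stopifnot(cofactor > 0)
  if (is_transformed(events)) {
    abort("events are already arcsinh-transformed")
  }
  markers <- intersect(markers, names(events))
  out <- dplyr::mutate(events,
                       dplyr::across(dplyr::all_of(markers), ~ asinh(.x / cofactor)))
  attr(out, "transformed") <- TRUE
  attr(out, "cofactor") <- cofactor
  out
}

## ---- minimal FCS 3.1 float32 list-mode reader/writer -----------------------
## Numeric columns are written as float32 channels; character/factor columns
## are integer-coded channels with their level sets recorded in custom
## "GDLEVELS:<name>" TEXT keywords so a round trip restores them.

fcs_delim <- "/"

write_fcs <- function(events, path) {
  df <- as.data.frame(events)
  levels_kw <- list()
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      lv <- sort(unique(as.character(df[[nm]])))
      if (any(grepl(fcs_delim, lv, fixed = TRUE))) {
        abort(sprintf("annotation values in '%s' may not contain '%s'", nm, fcs_delim))
      }
      levels_kw[[nm]] <- lv
      df[[nm]] <- match(as.character(df[[nm]]), lv)
    }
  }
  mat <- as.matrix(df)
  n <- nrow(mat); p <- ncol(mat)
  data_len <- 4L * n * p

  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p))
  for (j in seq_len(p)) {
    kw[sprintf("$P%dN", j)] <- colnames(mat)[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- "262144"
  }
  for (nm in names(levels_kw)) {
    kw[paste0("GDLEVELS:", nm)] <- paste(levels_kw[[nm]], collapse = "|")
  }
  # fixed-width offset keywords so the TEXT length is known up front
  kw["$BEGINDATA"] <- sprintf("%10d", 0)
  kw["$ENDDATA"] <- sprintf("%10d", 0)

  build_text <- function(kw) {
    paste0(fcs_delim,
           paste0(names(kw), fcs_delim, unname(kw), fcs_delim, collapse = ""))
  }
  text <- build_text(kw)
  text_begin <- 58L
  text_end <- text_begin + nchar(text, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + data_len - 1L
  kw["$BEGINDATA"] <- sprintf("%10d", data_begin)
  kw["$ENDDATA"] <- sprintf("%10d", data_end)
  text <- build_text(kw)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0,
                    if (data_end <= 99999999) data_end else 0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!grepl("^FCS3", header)) {
    abort(sprintf("%s is not an FCS 3.x file", basename(path)))
  }
  off <- as.integer(trimws(substring(header,
                                     10 + 8 * (0:3) + 1, 10 + 8 * (1:4))))
  text_begin <- off[1]; text_end <- off[2]
  seek(con, text_begin)
  raw_text <- readChar(con, text_end - text_begin + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  parts <- strsplit(substring(raw_text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 parts[seq(1, length(parts), 2)])

  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  if (!identical(kw[["$DATATYPE"]], "F")) {
    abort("only float ($DATATYPE F) FCS data are supported")
  }
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  data_begin <- as.integer(trimws(kw[["$BEGINDATA"]]))
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n = n * p, size = 4, endian = endian)
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]],
                          character(1))
  out <- tibble::as_tibble(mat)
  for (key in grep("^GDLEVELS:", names(kw), value = TRUE)) {
    nm <- sub("^GDLEVELS:", "", key)
    lv <- strsplit(kw[[key]], "|", fixed = TRUE)[[1]]
    out[[nm]] <- lv[as.integer(round(out[[nm]]))]
  }
  out
}
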