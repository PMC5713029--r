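# --- File readers/writers --------------------------------------------------
#
# The record dialects are (a) the IEEE Signal Processing Cup layout: a
# MATLAB level-5 MAT-file holding a numeric signal matrix whose rows are
# (ECG, PPG1, PPG2, ACCX, ACCY, ACCZ), and (b) plain CSV with a header.
# No installed R package reads MAT level-5 files, so a minimal reader for
# numeric-matrix variables (compressed and uncompressed elements) is
# implemented here with readBin/memDecompress.

MI_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                   `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_numeric <- function(raw, type, nbytes, endian) {
  n <- nbytes %/% MI_TYPE_SIZES[[as.character(type)]]
  what <- if (type %in% c(7L, 9L)) "double" else "integer"
  size <- MI_TYPE_SIZES[[as.character(type)]]
  signed <- !(type %in% c(2L, 4L, 6L, 13L))
  readBin(raw, what = what, n = n, size = size, signed = signed,
          endian = endian)
}

# One data element: returns list(type, data(raw), next_offset). Handles the
# small-element format (type and byte count packed into 4 bytes).
read_mat_element <- function(buf, off, endian) {
  tag <- readBin(buf[off + 1:8], "integer", n = 2L, size = 4L, endian = endian)
  type <- tag[1L]
  small_bytes <- bitwAnd(bitwShiftR(type, 16L), 0xFFFFL)
  if (small_bytes > 0L) {
    list(type = bitwAnd(type, 0xFFFFL), data = buf[off + 5:8],
         nbytes = small_bytes, next_off = off + 8L)
  } else {
    nb <- tag[2L]
    pad <- (8L - nb %% 8L) %% 8L
    list(type = type, data = buf[off + 8L + seq_len(nb)], nbytes = nb,
         next_off = off + 8L + nb + pad)
  }
}

# Parse one miMATRIX payload into a named numeric matrix (or NULL for
# unsupported classes such as cells/structs/char).
parse_mi_matrix <- function(payload, endian) {
  off <- 0L
  flags_el <- read_mat_element(payload, off, endian)
  off <- flags_el$next_off
  flags <- readBin(flags_el$data, "integer", n = 2L, size = 4L, endian = endian)
  cls <- bitwAnd(flags[1L], 0xFFL)
  if (cls < 6L || cls > 15L) return(NULL)  # not a numeric array
  dims_el <- read_mat_element(payload, off, endian)
  off <- dims_el$next_off
  dims <- read_mi_numeric(dims_el$data, dims_el$type, dims_el$nbytes, endian)
  name_el <- read_mat_element(payload, off, endian)
  off <- name_el$next_off
  nm <- rawToChar(name_el$data[seq_len(name_el$nbytes)])
  pr_el <- read_mat_element(payload, off, endian)
  vals <- read_mi_numeric(pr_el$data, pr_el$type, pr_el$nbytes, endian)
  if (length(dims) != 2L) dims <- c(length(vals), 1L)
  m <- matrix(as.numeric(vals), nrow = dims[1L], ncol = dims[2L])
  stats::setNames(list(m), nm)
}

#' Read numeric matrices from a MATLAB level-5 MAT-file
#'
#' Minimal reader covering real numeric matrix variables, including
#' zlib-compressed elements; other variable classes are skipped.
#'
#' @param path file path.
#' @return named list of numeric matrices.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128L) stop("not a MATLAB level-5 file (truncated): ", path)
  endian_tag <- rawToChar(buf[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI")
    "big" else stop("not a MATLAB level-5 file (bad endian tag): ", path)
  out <- list()
  off <- 128L
  while (off + 8L <= length(buf)) {
    el <- read_mat_element(buf, off, endian)
    payload <- el$data
    type <- el$type
    if (type == 15L) {  # miCOMPRESSED: zlib stream wrapping one element
      payload <- memDecompress(payload, type = "gzip")
      inner <- read_mat_element(payload, 0L, endian)
      type <- inner$type
      payload <- inner$data
    }
    if (type == 14L) {  # miMATRIX
      parsed <- parse_mi_matrix(payload, endian)
      if (!is.null(parsed)) out <- c(out, parsed)
    }
    off <- el$next_off
  }
  out
}

#' Load a Signal-Processing-Cup-layout record
#'
#' Reads the first numeric matrix with at least six rows from a MAT-file and
#' interprets the rows as (ECG, PPG1, PPG2, ACCX, ACCY, ACCZ) — the
#' documented dataset convention, overridable through `row_map`. The ECG row
#' is not used (ground truth is consumed as a BPM trace, not computed from
#' ECG); one of the two PPG rows is selected.
#'
#' @param path MAT-file path.
#' @param ppg_channel which PPG row feeds the single-channel algorithm
#'   (1 or 2, default 1).
#' @param fs sampling rate in Hz (default 125, the dataset convention).
#' @param truth_path optional companion MAT-file holding the per-window
#'   ground-truth BPM trace (its first numeric variable is used).
#' @param row_map named integer vector mapping `ppg1`, `ppg2`, `acc_x`,
#'   `acc_y`, `acc_z` to matrix rows.
#' @return an `nfeemd_record`.
#' @export
load_spcup_record <- function(path, ppg_channel = 1L, fs = 125,
                              truth_path = NULL,
                              row_map = c(ppg1 = 2L, ppg2 = 3L, acc_x = 4L,
                                          acc_y = 5L, acc_z = 6L)) {
  if (!ppg_channel %in% c(1L, 2L)) stop("ppg_channel must be 1 or 2")
  vars <- read_mat5(path)
  need <- max(row_map)
  sig <- NULL
  for (v in vars) if (is.matrix(v) && nrow(v) >= need) { sig <- v; break }
  if (is.null(sig)) {
    stop("no signal matrix with >= ", need, " rows found in ", path)
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    tv <- read_mat5(truth_path)
    if (length(tv) == 0L) stop("no BPM trace found in ", truth_path)
    truth <- as.numeric(tv[[1L]])
  }
  ppg_row <- row_map[[if (ppg_channel == 1L) "ppg1" else "ppg2"]]
  new_record(ppg = sig[ppg_row, ],
             acc_x = sig[row_map[["acc_x"]], ],
             acc_y = sig[row_map[["acc_y"]], ],
             acc_z = sig[row_map[["acc_z"]], ],
             fs = fs, truth_bpm = truth, id = basename(path))
}

#' Load a record from CSV
#'
#' Expects a header naming at least `ppg`, `acc_x`, `acc_y`, `acc_z`;
#' unrelated columns are ignored. An optional `truth_bpm` column carries the
#' per-window ground-truth sequence in its leading non-NA entries (there are
#' fewer analysis windows than samples, so the column is NA-padded).
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz.
#' @return an `nfeemd_record`.
#' @export
load_csv_record <- function(path, fs) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  df <- utils::read.csv(path)
  required <- c("ppg", "acc_x", "acc_y", "acc_z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  truth <- NULL
  if ("truth_bpm" %in% names(df)) {
    tv <- df$truth_bpm[!is.na(df$truth_bpm)]
    if (length(tv) > 0L) truth <- as.numeric(tv)
  }
  new_record(df$ppg, df$acc_x, df$acc_y, df$acc_z, fs = fs,
             truth_bpm = truth, id = basename(path))
}

#' Write a record to CSV
#'
#' Inverse of [load_csv_record()]; the ground-truth BPM trace, when present,
#' is stored NA-padded in a `truth_bpm` column.
#'
#' @param record an `nfeemd_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  stopifnot(inherits(record, "nfeemd_record"))
  df <- data.frame(ppg = record$ppg, acc_x = record$acc_x,
                   acc_y = record$acc_y, acc_z = record$acc_z)
  if (!is.null(record$truth_bpm)) {
    tb <- rep(NA_real_, nrow(df))
    tb[seq_along(record$truth_bpm)] <- record$truth_bpm
    df$truth_bpm <- tb
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an estimated heart-rate series to CSV
#'
#' Columns: `window_index` (0-based), `time_s` (window start), `bpm_est`,
#' and `bpm_true` when ground truth is available.
#'
#' @param result a pipeline result data frame (see [run_pipeline()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(result, path) {
  keep <- intersect(c("window_index", "time_s", "bpm_est", "bpm_true"),
                    names(result))
  utils::write.csv(result[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
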