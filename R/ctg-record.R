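#' @useDynLib ctgforesee, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor kmeans median pnorm predict qnorm quantile rnorm
#'   rpois runif sd setNames
#' @importFrom utils head read.csv tail write.csv combn
NULL

# Sampling rate of all CTG signals handled by this package (samples/second).
CTG_HZ <- 4

#' Construct a cardiotocography (CTG) record
#'
#' A CTG record pairs a fetal heart rate (FHR) trace in beats/min with a
#' uterine contraction (UC) activity trace in arbitrary pressure units, both
#' sampled at 4 Hz, plus an optional umbilical cord pH measured at delivery.
#' An FHR value of 0 (the transducer-loss sentinel) or `NA` marks signal loss;
#' lost samples are stored as `NA` and flagged in `missing_mask`.
#'
#' @param fhr numeric vector, beats/min. Non-missing values must lie in
#'   \[30, 250\].
#' @param uc numeric vector of the same length, uterine activity units (>= 0).
#' @param ph optional cord pH (single number, roughly 6.8--7.5) or `NA`.
#' @param record_id identifier string.
#'
#' @return An object of class `ctg_record` with fields `record_id`, `fhr`,
#'   `uc`, `ph` and `missing_mask`.
#' @export
ctg_record <- function(fhr, uc, ph = NA_real_, record_id = "record") {
  fhr <- as.numeric(fhr)
  uc <- as.numeric(uc)
  if (length(fhr) < 1L)
    stop("ctg_record: empty signal", call. = FALSE)
  if (length(fhr) != length(uc))
    stop("ctg_record: fhr and uc must have equal length (",
         length(fhr), " vs ", length(uc), ")", call. = FALSE)
  missing <- is.na(fhr) | fhr == 0 | is.na(uc)
  fhr[missing] <- NA_real_
  uc[missing] <- NA_real_
  ok <- !missing
  if (any(fhr[ok] < 30 | fhr[ok] > 250))
    stop("ctg_record: non-missing FHR outside [30, 250] bpm", call. = FALSE)
  if (any(uc[ok] < 0))
    stop("ctg_record: negative UC values", call. = FALSE)
  if (!is.na(ph) && (!is.numeric(ph) || ph < 6 || ph > 8))
    stop("ctg_record: implausible pH ", ph, call. = FALSE)
  structure(
    list(record_id = as.character(record_id)[1L],
         fhr = fhr, uc = uc, ph = as.numeric(ph)[1L],
         missing_mask = missing),
    class = "ctg_record")
}

#' @export
print.ctg_record <- function(x, ...) {
  n <- length(x$fhr)
  cat("CTG record '", x$record_id, "'\n", sep = "")
  cat(sprintf("  %d samples at %d Hz (%.1f min), %.1f%% signal loss\n",
              n, CTG_HZ, n / CTG_HZ / 60, 100 * mean(x$missing_mask)))
  if (!is.na(x$ph))
    cat(sprintf("  cord pH %.2f (%s)\n", x$ph,
                if (x$ph < 7.2) "acidotic" else "non-acidotic"))
  invisible(x)
}

#' @export
summary.ctg_record <- function(object, ...) {
  f <- object$fhr[!object$missing_mask]
  u <- object$uc[!object$missing_mask]
  out <- list(record_id = object$record_id,
              n = length(object$fhr),
              duration_s = length(object$fhr) / CTG_HZ,
              missing_fraction = mean(object$missing_mask),
              fhr_range = range(f), fhr_mean = mean(f),
              uc_range = range(u), ph = object$ph)
  class(out) <- "summary.ctg_record"
  out
}

#' @export
print.summary.ctg_record <- function(x, ...) {
  cat("CTG record '", x$record_id, "': ", x$n, " samples (",
      sprintf("%.1f min", x$duration_s / 60), ")\n", sep = "")
  cat(sprintf("  FHR %.0f-%.0f bpm (mean %.1f), UC %.0f-%.0f units, %.1f%% missing\n",
              x$fhr_range[1], x$fhr_range[2], x$fhr_mean,
              x$uc_range[1], x$uc_range[2], 100 * x$missing_fraction))
  if (!is.na(x$ph)) cat(sprintf("  cord pH %.2f\n", x$ph))
  invisible(x)
}

#' @export
plot.ctg_record <- function(x, ...) {
  t_min <- seq_along(x$fhr) / CTG_HZ / 60
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(t_min, x$fhr, type = "l", xlab = "time (min)", ylab = "FHR (bpm)",
       main = x$record_id, ...)
  plot(t_min, x$uc, type = "l", xlab = "time (min)", ylab = "UC (units)", ...)
  invisible(x)
}

#' Read a CTG record from CSV
#'
#' Reads the plain-text dialect written by [write_ctg()]: optional metadata
#' comment lines (`#id=...`, `#ph=...`) followed by a header `time_s,fhr,uc`
#' (the `time_s` column is optional in the `two_column_csv` dialect). FHR
#' values of 0 denote transducer signal loss and are flagged as missing.
#'
#' @param path file path.
#' @param dialect `"annotated_csv"` (metadata comments honoured, default) or
#'   `"two_column_csv"` (bare `fhr,uc` columns).
#' @return A [ctg_record()].
#' @export
read_ctg <- function(path, dialect = c("annotated_csv", "two_column_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_ctg: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(body) <= 1L)
    stop("read_ctg: ", path, " has no data rows", call. = FALSE)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (!all(c("fhr", "uc") %in% header))
    stop("read_ctg: header must name 'fhr' and 'uc' columns", call. = FALSE)
  ncol_expect <- length(header)
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) != ncol_expect)
  if (length(bad))
    stop("read_ctg: malformed row at line ",
         which(lines == body[bad[1L] + 1L])[1L], " of ", path, call. = FALSE)
  dat <- do.call(rbind, lapply(rows, function(r) suppressWarnings(as.numeric(r))))
  colnames(dat) <- header
  fhr <- dat[, "fhr"]
  uc <- dat[, "uc"]
  bad_num <- which(is.na(fhr) &
                     !vapply(rows, function(r) {
                       v <- r[match("fhr", header)]
                       v %in% c("", "NA", "0")
                     }, TRUE))
  if (length(bad_num))
    stop("read_ctg: non-numeric FHR value at data row ", bad_num[1L],
         " of ", path, call. = FALSE)
  ph <- NA_real_
  id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "annotated_csv" && length(meta)) {
    get_meta <- function(key) {
      hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
      if (length(hit)) sub(paste0("^#", key, "="), "", hit[1L]) else NA_character_
    }
    ph_chr <- get_meta("ph")
    if (!is.na(ph_chr)) ph <- as.numeric(ph_chr)
    id_chr <- get_meta("id")
    if (!is.na(id_chr)) id <- id_chr
  }
  ctg_record(fhr = fhr, uc = uc, ph = ph, record_id = id)
}

#' Write a CTG record to CSV
#'
#' Writes metadata comment lines (`#id=`, `#ph=` when known), a
#' `time_s,fhr,uc` header and one row per sample. Missing samples are written
#' with the FHR transducer-loss sentinel 0 so that [read_ctg()] restores the
#' missing mask exactly.
#'
#' @param record a [ctg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ctg <- function(record, path) {
  stopifnot(inherits(record, "ctg_record"))
  if (length(record$fhr) < 1L)
    stop("write_ctg: empty record", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#id=", record$record_id), con)
  if (!is.na(record$ph)) writeLines(sprintf("#ph=%.15g", record$ph), con)
  fhr <- record$fhr
  uc <- record$uc
  fhr[record$missing_mask] <- 0
  uc[record$missing_mask] <- 0
  writeLines("time_s,fhr,uc", con)
  t_s <- (seq_along(fhr) - 1L) / CTG_HZ
  writeLines(sprintf("%.15g,%.15g,%.15g", t_s, fhr, uc), con)
  invisible(path)
}

#' Write or read a ground-truth annotation sidecar
#'
#' Annotations are typed intervals on the FHR axis (accelerations,
#' deceleration subtypes) or the UC axis (contractions), with times in
#' seconds. `peak_s` carries the contraction peak (or event extremum) time.
#'
#' @param annotations data frame with columns `record_id`, `channel`, `type`,
#'   `onset_s`, `offset_s`, `peak_s`.
#' @param path file path.
#' @return For the reader, the annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  need <- c("record_id", "channel", "type", "onset_s", "offset_s", "peak_s")
  stopifnot(all(need %in% names(annotations)))
  write.csv(annotations[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
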