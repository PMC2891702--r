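#' Read a time-course MS1 peak list from CSV
#'
#' Expected columns: `mz`, `rt_min`, `intensity`, `digestion_time` (the
#' digestion duration label in consistent units, e.g. hours; `t = 0` is the
#' undigested control). Aliases `m/z` and `rt` are accepted.
#'
#' @param path CSV file path.
#' @return data.frame with columns `mz`, `rt_min`, `intensity`,
#'   `digestion_time`.
#' @export
read_peaklist_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(names(d))
  nm[nm %in% c("m/z", "mz")] <- "mz"
  nm[nm %in% c("rt", "rt_min", "retention_time")] <- "rt_min"
  names(d) <- nm
  need <- c("mz", "rt_min", "intensity", "digestion_time")
  if (!all(need %in% names(d)))
    stop("peak list must have columns mz, rt_min, intensity, digestion_time",
         call. = FALSE)
  d <- d[, need]
  if (any(d$intensity < 0) || any(d$rt_min < 0))
    stop("negative intensity or retention time in ", path, call. = FALSE)
  d
}

#' Write a time-course MS1 peak list as CSV
#'
#' @param peaks data.frame with columns `mz`, `rt_min`, `intensity`,
#'   `digestion_time`.
#' @param path Output path.
#' @export
write_peaklist_csv <- function(peaks, path) {
  utils::write.csv(peaks[, c("mz", "rt_min", "intensity", "digestion_time")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS1 pseudo-spectra from an MGF file
#'
#' Each `BEGIN IONS` block is interpreted as the centroided MS1 scan of one
#' digestion time point: `TITLE` carries `digestion_time=<t>`, `RTINSECONDS`
#' the retention time, and the body lines are `mz intensity` pairs.
#'
#' @param path MGF file path.
#' @return data.frame as in [read_peaklist_csv()].
#' @export
read_peaklist_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  inside <- FALSE
  dt <- NA_real_; rt <- NA_real_
  buf <- character()
  flush <- function() {
    if (!length(buf)) return(NULL)
    m <- do.call(rbind, strsplit(trimws(buf), "[ \t]+"))
    data.frame(mz = as.numeric(m[, 1L]), rt_min = rt,
               intensity = as.numeric(m[, 2L]), digestion_time = dt)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      inside <- TRUE; buf <- character(); dt <- NA_real_; rt <- NA_real_
    } else if (ln == "END IONS") {
      out[[length(out) + 1L]] <- flush()
      inside <- FALSE
    } else if (inside && startsWith(ln, "TITLE=")) {
      m <- regmatches(ln, regexpr("digestion_time=[0-9.eE+-]+", ln))
      if (length(m)) dt <- as.numeric(sub("digestion_time=", "", m))
    } else if (inside && startsWith(ln, "RTINSECONDS=")) {
      rt <- as.numeric(sub("RTINSECONDS=", "", ln)) / 60
    } else if (inside && grepl("^[0-9]", ln)) {
      buf <- c(buf, ln)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no ion blocks in ", path, call. = FALSE)
  res
}

#' Write MS1 pseudo-spectra as MGF
#'
#' Inverse of [read_peaklist_mgf()]: one `BEGIN IONS` block per
#' (digestion_time, rt_min) combination.
#'
#' @inheritParams write_peaklist_csv
#' @export
write_peaklist_mgf <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  key <- paste(peaks$digestion_time, peaks$rt_min)
  for (grp in split(peaks, key)) {
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=ms1 digestion_time=%g", grp$digestion_time[1L]),
                 sprintf("RTINSECONDS=%g", grp$rt_min[1L] * 60),
                 sprintf("%.5f %.6g", grp$mz, grp$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read a peak list, dispatching on file extension
#'
#' `.mgf` files go through [read_peaklist_mgf()], everything else through
#' [read_peaklist_csv()].
#'
#' @param path File path.
#' @export
read_peaklist <- function(path) {
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) read_peaklist_mgf(path)
  else read_peaklist_csv(path)
}
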