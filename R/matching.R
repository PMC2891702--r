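#' Kinetic-filter and matching parameters
#'
#' @param max_t0 Intensity ceiling at digestion time 0 ("MAX"): traces whose
#'   t = 0 intensity is not strictly below this are treated as contaminants
#'   (default 1e7, matching the target ion-trap's typical contaminant level).
#' @param delta Signal-to-noise threshold for chromatographic peak detection
#'   (default 2).
#' @param mz_tolerance Match tolerance between theoretical cluster m/z and
#'   observed peaks, in Da (default 0.5, the mass accuracy of the ESI ion
#'   trap).
#' @param epsilon Relative dip tolerated within a "monotone" rise or decline
#'   (default 0.05).
#' @param allow_reentry Accept rise-then-fall kinetics, i.e. re-degradation
#'   of a released product (default `TRUE`).
#' @param rt_window Half-width in minutes of the retention-time window used
#'   to collect a trace around a detected apex and for inclusion-list
#'   entries (default 1).
#' @param rt_binwidth Retention-time grid step in minutes for extracted ion
#'   chromatograms (default 0.1).
#' @param noise_floor Lower bound on the noise estimate used in S/N, so
#'   all-quiet chromatograms do not divide by zero (default 1 intensity
#'   unit).
#' @return Object of class `"filter_params"`.
#' @export
filter_params <- function(max_t0 = 1e7, delta = 2, mz_tolerance = 0.5,
                          epsilon = 0.05, allow_reentry = TRUE,
                          rt_window = 1, rt_binwidth = 0.1,
                          noise_floor = 1) {
  if (max_t0 <= 0 || delta <= 0 || mz_tolerance < 0 || rt_window <= 0 ||
      rt_binwidth <= 0 || noise_floor <= 0)
    stop("filter parameters must be positive", call. = FALSE)
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  structure(list(max_t0 = max_t0, delta = delta,
                 mz_tolerance = mz_tolerance, epsilon = epsilon,
                 allow_reentry = isTRUE(allow_reentry),
                 rt_window = rt_window, rt_binwidth = rt_binwidth,
                 noise_floor = noise_floor),
            class = "filter_params")
}

#' Match theoretical clusters against observed MS1 peaks
#'
#' A cluster matches if any observation in any peak list lies within
#' `tolerance` of its representative m/z. Unmatched clusters are dropped -
#' the first shrinkage of the candidate set.
#'
#' @param db A [build_database()] result.
#' @param peaks Peak-list data.frame (see [read_peaklist_csv()]).
#' @param tolerance m/z tolerance in Da.
#' @return The `clusters` data.frame of `db` restricted to matched clusters.
#' @export
match_clusters <- function(db, peaks, tolerance = 0.5) {
  stopifnot(inherits(db, "psp_db"))
  if (is.null(peaks) || !nrow(peaks))
    stop("no peak lists supplied", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  obs <- sort(unique(peaks$mz))
  rep_mz <- db$clusters$cluster_mz
  lo <- findInterval(rep_mz - tolerance, obs)
  hi <- findInterval(rep_mz + tolerance, obs)
  # any observation in (rep - tol, rep + tol]? also check the left boundary
  matched <- hi > lo |
    (lo >= 1L & abs(obs[pmax(lo, 1L)] - rep_mz) <= tolerance)
  db$clusters[matched, , drop = FALSE]
}

#' Extracted ion chromatogram for one m/z window
#'
#' Pools all digestion time points: intensity per retention-time bin is the
#' maximum observed intensity of peaks within `tolerance` of `mz`.
#'
#' @param peaks Peak-list data.frame.
#' @param mz Centre m/z.
#' @param tolerance m/z half-window in Da.
#' @param binwidth Retention-time bin width in minutes.
#' @param rt_range Optional c(min, max) retention-time range for the grid;
#'   defaults to the range of `peaks$rt_min`.
#' @return data.frame `rt`, `intensity` on a regular grid (zeros where no
#'   peak falls in the bin).
#' @export
extract_xic <- function(peaks, mz, tolerance = 0.5, binwidth = 0.1,
                        rt_range = NULL) {
  if (!nrow(peaks)) stop("empty peak list", call. = FALSE)
  if (is.null(rt_range)) rt_range <- range(peaks$rt_min)
  grid <- seq(floor(rt_range[1L] / binwidth) * binwidth,
              ceiling(rt_range[2L] / binwidth) * binwidth, by = binwidth)
  sel <- abs(peaks$mz - mz) <= tolerance
  xic <- data.frame(rt = grid, intensity = 0)
  if (any(sel)) {
    bin <- findInterval(peaks$rt_min[sel], grid + binwidth / 2) + 1L
    bin <- pmin(bin, length(grid))
    agg <- tapply(peaks$intensity[sel], bin, max)
    xic$intensity[as.integer(names(agg))] <- as.numeric(agg)
  }
  xic
}

#' Detect chromatographic peaks in an XIC
#'
#' Local maxima whose apex exceeds `delta` times the noise, where noise is
#' the median intensity of the chromatogram (bounded below by
#' `noise_floor`). A flat or empty chromatogram yields no peaks; several
#' resolved apexes yield several peaks.
#'
#' @param xic data.frame `rt`, `intensity` (from [extract_xic()]).
#' @param delta S/N threshold.
#' @param noise_floor Lower bound for the noise estimate.
#' @return data.frame `rt`, `intensity` of detected apexes (possibly empty).
#' @export
detect_peaks <- function(xic, delta = 2, noise_floor = 1) {
  if (!nrow(xic)) stop("empty chromatogram", call. = FALSE)
  y <- xic$intensity
  noise <- max(stats::median(y), noise_floor)
  n <- length(y)
  if (n == 1L) {
    is_max <- y > 0
  } else {
    left <- c(-Inf, y[-n])
    right <- c(y[-1L], -Inf)
    # plateau apexes: strictly greater than the next distinct value on one side
    is_max <- y >= left & y > right | (y > left & y >= right)
  }
  keep <- is_max & y > delta * noise
  out <- xic[keep, , drop = FALSE]
  names(out) <- c("rt", "intensity")
  rownames(out) <- NULL
  out
}

#' Build kinetic traces for matched clusters
#'
#' For each matched cluster, peaks from all time points are pooled into an
#' XIC; each detected retention-time apex defines one trace: intensity per
#' digestion time is the maximum intensity of observations within the m/z
#' tolerance and within `rt_window` of the apex (zero where nothing was
#' observed, including the t = 0 control).
#'
#' @param clusters data.frame from [match_clusters()] (columns `cluster_id`,
#'   `cluster_mz`).
#' @param peaks Peak-list data.frame; must contain digestion time 0.
#' @param params A [filter_params()].
#' @return data.frame in long form: `cluster_id`, `cluster_mz`, `rt`,
#'   `digestion_time`, `intensity`; one trace = one (`cluster_id`, `rt`).
#' @export
build_traces <- function(clusters, peaks, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  times <- sort(unique(peaks$digestion_time))
  if (!0 %in% times)
    stop("peak lists must include the digestion time 0 control",
         call. = FALSE)
  rt_range <- range(peaks$rt_min)
  out <- vector("list", nrow(clusters))
  for (ci in seq_len(nrow(clusters))) {
    cmz <- clusters$cluster_mz[ci]
    sel <- abs(peaks$mz - cmz) <= params$mz_tolerance
    if (!any(sel)) next
    sub <- peaks[sel, , drop = FALSE]
    xic <- extract_xic(sub, cmz, params$mz_tolerance, params$rt_binwidth,
                       rt_range)
    apexes <- detect_peaks(xic, params$delta, params$noise_floor)
    if (!nrow(apexes)) next
    tr <- vector("list", nrow(apexes))
    for (ai in seq_len(nrow(apexes))) {
      rsel <- abs(sub$rt_min - apexes$rt[ai]) <= params$rt_window
      ints <- vapply(times, function(t) {
        v <- sub$intensity[rsel & sub$digestion_time == t]
        if (length(v)) max(v) else 0
      }, 0)
      tr[[ai]] <- data.frame(cluster_id = clusters$cluster_id[ci],
                             cluster_mz = cmz, rt = apexes$rt[ai],
                             digestion_time = times, intensity = ints)
    }
    out[[ci]] <- do.call(rbind, tr)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster_id = integer(), cluster_mz = numeric(),
                      rt = numeric(), digestion_time = numeric(),
                      intensity = numeric())
  rownames(res) <- NULL
  res
}

# decision on a single intensity series (first sample at t = 0)
.kinetic_keep <- function(intensity, times, params) {
  if (length(intensity) < 2L) return(list(keep = FALSE, t_max = NA_real_))
  if (intensity[1L] >= params$max_t0)   # criterion i: contaminant at t = 0
    return(list(keep = FALSE, t_max = NA_real_))
  imax <- which.max(intensity)          # earliest time wins ties
  t_max <- times[imax]
  eps <- params$epsilon
  rise <- intensity[seq_len(imax)]
  rise_ok <- all(diff(rise) >= -eps * rise[-length(rise)])
  if (!rise_ok) return(list(keep = FALSE, t_max = t_max))
  if (imax < length(intensity)) {       # a decline follows the maximum
    fall <- intensity[imax:length(intensity)]
    fall_ok <- all(diff(fall) <= eps * fall[-length(fall)])
    declines <- fall[length(fall)] < (1 - eps) * fall[1L]
    if (!fall_ok) return(list(keep = FALSE, t_max = t_max))
    if (declines && !params$allow_reentry)
      return(list(keep = FALSE, t_max = t_max))
  }
  list(keep = TRUE, t_max = t_max)
}

#' Kinetic filtering of candidate traces
#'
#' Implements the two elimination criteria of the screening method: (i) the
#' t = 0 intensity must be strictly below `max_t0` (otherwise the signal is
#' a contaminant already present before digestion); (ii) the intensity must
#' rise monotonically (within relative tolerance `epsilon`) to its maximum
#' and, if a decline follows, the decline must be monotone and is only
#' accepted when the assay permitted re-entry of released products
#' (`allow_reentry`). Each surviving trace carries `t_max`, the digestion
#' time of maximal intensity (earliest time on ties).
#'
#' @param traces Long-form data.frame from [build_traces()].
#' @param params A [filter_params()].
#' @return data.frame of candidate records: `cluster_id`, `cluster_mz`,
#'   `rt`, `t_max`.
#' @export
kinetic_filter <- function(traces, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (!nrow(traces))
    return(data.frame(cluster_id = integer(), cluster_mz = numeric(),
                      rt = numeric(), t_max = numeric()))
  key <- paste(traces$cluster_id, traces$rt)
  out <- lapply(split(traces, key), function(tr) {
    tr <- tr[order(tr$digestion_time), , drop = FALSE]
    if (tr$digestion_time[1L] != 0)
      stop("trace lacks a t = 0 sample", call. = FALSE)
    if (nrow(tr) < 2L) {
      warning("trace with fewer than 2 time points rejected", call. = FALSE)
      return(NULL)
    }
    dec <- .kinetic_keep(tr$intensity, tr$digestion_time, params)
    if (!dec$keep) return(NULL)
    data.frame(cluster_id = tr$cluster_id[1L],
               cluster_mz = tr$cluster_mz[1L], rt = tr$rt[1L],
               t_max = dec$t_max)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster_id = integer(), cluster_mz = numeric(),
                      rt = numeric(), t_max = numeric())
  res <- res[order(res$t_max, res$cluster_mz, res$rt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Group surviving candidates into an inclusion list
#'
#' Candidates are grouped by `t_max` (one up-scaled digestion assay per
#' group); any group larger than `d_max` is split into
#' `ceiling(D_g / d_max)` balanced subgroups (one targeted MS run per
#' subgroup).
#'
#' @param records Candidate data.frame from [kinetic_filter()].
#' @param d_max Maximal entries per MS run (default 15).
#' @param params A [filter_params()] (supplies the RT window written to the
#'   list).
#' @return Object of class `"inclusion_list"`: list with `entries`
#'   (`mz`, `rt_center_min`, `rt_window_min`, `t_max`, `group_id`,
#'   `subgroup_id`), `n_groups`, `n_subgroups`.
#' @export
group_candidates <- function(records, d_max = 15L, params = filter_params()) {
  d_max <- as.integer(d_max)
  if (is.na(d_max) || d_max < 1L) stop("d_max must be >= 1", call. = FALSE)
  if (!nrow(records)) {
    return(structure(list(entries = data.frame(
      mz = numeric(), rt_center_min = numeric(), rt_window_min = numeric(),
      t_max = numeric(), group_id = integer(), subgroup_id = integer()),
      n_groups = 0L, n_subgroups = 0L), class = "inclusion_list"))
  }
  tvals <- sort(unique(records$t_max))
  entries <- list()
  n_sub_total <- 0L
  for (gi in seq_along(tvals)) {
    grp <- records[records$t_max == tvals[gi], , drop = FALSE]
    grp <- grp[order(grp$cluster_mz, grp$rt), , drop = FALSE]
    Dg <- nrow(grp)
    nsub <- ceiling(Dg / d_max)
    # balanced split: sizes differ by at most one
    sizes <- rep(Dg %/% nsub, nsub) + c(rep(1L, Dg %% nsub),
                                        rep(0L, nsub - Dg %% nsub))
    sub_id <- rep(seq_len(nsub) + n_sub_total, times = sizes)
    entries[[gi]] <- data.frame(
      mz = grp$cluster_mz, rt_center_min = grp$rt,
      rt_window_min = params$rt_window, t_max = grp$t_max,
      group_id = gi, subgroup_id = sub_id)
    n_sub_total <- n_sub_total + nsub
  }
  structure(list(entries = do.call(rbind, entries),
                 n_groups = length(tvals), n_subgroups = n_sub_total),
            class = "inclusion_list")
}

#' @export
print.inclusion_list <- function(x, ...) {
  cat(sprintf("inclusion list: %d entries in %d t_max group(s), %d MS run(s)\n",
              nrow(x$entries), x$n_groups, x$n_subgroups))
  invisible(x)
}

#' Write an inclusion list as CSV
#'
#' Columns: `mz`, `charge` (NA when the precursor charge is ambiguous),
#' `rt_center_min`, `rt_window_min`, `t_max`, `group_id`, `subgroup_id`.
#'
#' @param x An [group_candidates()] result.
#' @param path Output CSV path.
#' @param db Optional [build_database()] result used to annotate the most
#'   common charge among cluster members.
#' @export
write_inclusion_csv <- function(x, path, db = NULL) {
  stopifnot(inherits(x, "inclusion_list"))
  e <- x$entries
  e$charge <- NA_integer_
  if (!is.null(db) && nrow(e)) {
    for (r in seq_len(nrow(e))) {
      zs <- db$ions$z[!is.na(db$ions$cluster_mz) &
                        abs(db$ions$cluster_mz - e$mz[r]) < 1e-9]
      if (length(zs)) {
        tab <- sort(table(zs), decreasing = TRUE)
        e$charge[r] <- as.integer(names(tab)[1L])
      }
    }
  }
  e <- e[, c("mz", "charge", "rt_center_min", "rt_window_min", "t_max",
             "group_id", "subgroup_id")]
  utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Retention-time agreement with a synthetic analogue
#'
#' A candidate is confirmed only if its retention time matches that of the
#' synthetic peptide of the same sequence to within `threshold` minutes
#' (strict inequality).
#'
#' @param candidate_rt,analogue_rt Retention times in minutes (vectorised).
#' @param threshold Maximal absolute difference (default 0.5 min).
#' @return Logical vector.
#' @examples
#' compare_rt(41.3, 41.6)  # TRUE
#' compare_rt(41.3, 42.0)  # FALSE
#' @export
compare_rt <- function(candidate_rt, analogue_rt, threshold = 0.5) {
  abs(candidate_rt - analogue_rt) < threshold
}
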