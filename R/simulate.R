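#' Simulation configuration for synthetic digestion time-courses
#'
#' The simulator emulates the centroided MS1 peak lists of an in vitro
#' proteasomal digestion sampled at several digestion times (grid starting at
#' t = 0, the undigested control). Planted products follow first-order
#' production kinetics, optionally with re-entry decay; contaminants are
#' constant and present at t = 0; decoys occupy random m/z positions away
#' from the planted signals and carry deliberately non-monotone intensity
#' profiles (chemical noise without digestion kinetics).
#'
#' @param substrate A [substrate()] (or list of up to two, e.g. light plus
#'   heavy analogue).
#' @param planted data.frame with one row per planted product: columns `i`,
#'   `j`, `k`, `n` (splice indices; use `NA` for `k`,`n` to plant a PCP),
#'   optional `z` (charge, default 2), `amplitude` (default 5e6), `k_in`
#'   (production rate per time unit, default 0.4), `k_out` (re-entry decay
#'   rate, default 0 = saturating kinetics).
#' @param contaminants Optional data.frame with columns `mz`, `intensity`
#'   (constant over the whole time course) and optional `rt_min`.
#' @param n_decoys Number of decoy m/z positions (default 25).
#' @param noise Relative log-normal intensity jitter applied to planted
#'   signals (default 0.02; 0 disables).
#' @param time_grid Digestion times; must start at 0 (default
#'   `c(0, 1, 2, 4, 8, 24)` hours, spanning the 20 min - 48 h assay range).
#' @param mz_range m/z range for decoys (default c(250, 2000), the MS scan
#'   range).
#' @param rt_gradient c(min, max) retention-time window in minutes of the
#'   LC gradient (default c(5, 60)).
#' @param seed Integer random seed fixing all randomness.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(substrate, planted, contaminants = NULL,
                       n_decoys = 25L, noise = 0.02,
                       time_grid = c(0, 1, 2, 4, 8, 24),
                       mz_range = c(250, 2000), rt_gradient = c(5, 60),
                       seed = 1L) {
  if (inherits(substrate, "substrate")) substrate <- list(substrate)
  stopifnot(all(vapply(substrate, inherits, TRUE, "substrate")))
  if (!length(time_grid)) stop("empty digestion time grid", call. = FALSE)
  if (time_grid[1L] != 0 || is.unsorted(time_grid, strictly = TRUE))
    stop("time_grid must be strictly increasing and start at 0",
         call. = FALSE)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    if (!all(c("i", "j") %in% names(planted)))
      stop("planted needs columns i, j (and k, n for splice products)",
           call. = FALSE)
    if (is.null(planted$k)) planted$k <- NA_integer_
    if (is.null(planted$n)) planted$n <- NA_integer_
    if (is.null(planted$z)) planted$z <- 2L
    if (is.null(planted$amplitude)) planted$amplitude <- 5e6
    if (is.null(planted$k_in)) planted$k_in <- 0.4
    if (is.null(planted$k_out)) planted$k_out <- 0
  }
  structure(list(substrates = substrate, planted = planted,
                 contaminants = contaminants, n_decoys = as.integer(n_decoys),
                 noise = noise, time_grid = as.numeric(time_grid),
                 mz_range = mz_range, rt_gradient = rt_gradient,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Kyte-Doolittle hydropathy, used only to assign plausible retention times
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

.predict_rt <- function(sequence, rt_gradient) {
  kd <- sum(.kd_scale[strsplit(sequence, "")[[1L]]])
  span <- rt_gradient[2L] - rt_gradient[1L]
  # map the plausible hydropathy-sum range [-40, 40] onto the gradient
  rt_gradient[1L] + span * min(max((kd + 40) / 80, 0), 1)
}

#' Planted-product intensity kinetics
#'
#' Saturating production `A (1 - exp(-k_in t))` when `k_out = 0`, otherwise
#' the rise-then-fall form `A (exp(-k_out t) - exp(-k_in t))` modelling
#' re-entry of the released product into the proteasome. Zero at t = 0 in
#' both cases.
#'
#' @param t Digestion times.
#' @param amplitude Scale A in arbitrary intensity units.
#' @param k_in Production rate.
#' @param k_out Re-entry decay rate (0 disables).
#' @export
kinetic_curve <- function(t, amplitude, k_in, k_out = 0) {
  if (k_out > 0) amplitude * (exp(-k_out * t) - exp(-k_in * t))
  else amplitude * (1 - exp(-k_in * t))
}

#' Simulate a digestion time-course peak list
#'
#' Generates one centroided MS1 peak list per digestion time together with a
#' ground-truth manifest of the planted products. Deterministic under a
#' fixed `seed`.
#'
#' @param config A [sim_config()].
#' @return List with `peaks` (data.frame `mz`, `rt_min`, `intensity`,
#'   `digestion_time`) and `manifest` (per planted product: indices, class,
#'   sequence, `mr`, `z`, `mz`, `rt_min` and kinetic parameters).
#' @export
simulate_digest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subs <- config$substrates
  s1 <- subs[[1L]]
  times <- config$time_grid
  rows <- list()

  # ground-truth manifest for the planted products
  pl <- config$planted
  manifest <- NULL
  if (nrow(pl)) {
    seqs <- character(nrow(pl))
    cls <- character(nrow(pl))
    for (r in seq_len(nrow(pl))) {
      if (is.na(pl$k[r])) {
        seqs[r] <- splice_sequence(s1, pl$i[r], pl$j[r])
        cls[r] <- "PCP"
      } else {
        seqs[r] <- splice_sequence(s1, pl$i[r], pl$j[r], pl$k[r], pl$n[r])
        cls[r] <- classify_splice(pl$i[r], pl$j[r], pl$k[r], pl$n[r])
      }
    }
    mr <- vapply(seqs, peptide_mass, 0, USE.NAMES = FALSE)
    manifest <- data.frame(pl[, c("i", "j", "k", "n", "z", "amplitude",
                                  "k_in", "k_out")],
                           class = cls, sequence = seqs, mr = mr)
    manifest$mz <- mz_value(mr, pl$z)
    manifest$rt_min <- vapply(seqs, .predict_rt, 0, config$rt_gradient,
                              USE.NAMES = FALSE)
    for (r in seq_len(nrow(manifest))) {
      ints <- kinetic_curve(times, pl$amplitude[r], pl$k_in[r], pl$k_out[r])
      if (config$noise > 0)
        ints <- ints * exp(stats::rnorm(length(ints), 0, config$noise))
      keep <- ints > 0
      if (any(keep)) {
        rt_jit <- manifest$rt_min[r] +
          stats::rnorm(sum(keep), 0, 0.02)
        rows[[length(rows) + 1L]] <- data.frame(
          mz = manifest$mz[r], rt_min = pmax(rt_jit, 0),
          intensity = ints[keep], digestion_time = times[keep])
      }
    }
  }

  # contaminants: constant intensity, present from t = 0 on
  if (!is.null(config$contaminants) && nrow(config$contaminants)) {
    ct <- as.data.frame(config$contaminants)
    if (is.null(ct$rt_min))
      ct$rt_min <- stats::runif(nrow(ct), config$rt_gradient[1L],
                                config$rt_gradient[2L])
    for (r in seq_len(nrow(ct))) {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = ct$mz[r], rt_min = ct$rt_min[r], intensity = ct$intensity[r],
        digestion_time = times)
    }
  }

  # decoys: random m/z away from every planted signal, zig-zag intensities
  if (config$n_decoys > 0L) {
    avoid <- if (is.null(manifest)) numeric() else manifest$mz
    decoy_mz <- numeric(0)
    guard <- 0L
    while (length(decoy_mz) < config$n_decoys && guard < 10000L) {
      guard <- guard + 1L
      cand <- stats::runif(1, config$mz_range[1L], config$mz_range[2L])
      if (all(abs(cand - c(avoid, decoy_mz)) > 1.5)) # > tol + cluster width
        decoy_mz <- c(decoy_mz, cand)
    }
    decoy_rt <- stats::runif(length(decoy_mz), config$rt_gradient[1L],
                             config$rt_gradient[2L])
    decoy_amp <- stats::runif(length(decoy_mz), 1e5, 5e6)
    zigzag <- rep_len(c(1, 0.4), length(times))
    for (r in seq_along(decoy_mz)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = decoy_mz[r], rt_min = decoy_rt[r],
        intensity = decoy_amp[r] * zigzag, digestion_time = times)
    }
  }

  peaks <- do.call(rbind, rows)
  if (is.null(peaks))
    peaks <- data.frame(mz = numeric(), rt_min = numeric(),
                        intensity = numeric(), digestion_time = numeric())
  peaks <- peaks[order(peaks$digestion_time, peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, manifest = manifest)
}

#' Self-checking end-to-end fixture
#'
#' Builds the theoretical database for `substrate`, plants `n_planted`
#' splice products (chosen deterministically from the enumeration at evenly
#' spaced positions) plus decoys, and returns everything needed to verify
#' the screening pipeline: the simulated peaks, the manifest, the database
#' and the expected candidate m/z values.
#'
#' @param substrate A [substrate()].
#' @param n_planted Number of planted splice products.
#' @param n_decoys Number of decoys.
#' @param seed Random seed.
#' @param db_par A [db_params()].
#' @return List `db`, `peaks`, `manifest`, `expected_mz`.
#' @export
end_to_end_fixture <- function(substrate, n_planted = 3L, n_decoys = 25L,
                               seed = 1L, db_par = db_params()) {
  db <- build_database(substrate, db_par)
  psp <- db$entries[db$entries$kind == "PSP", , drop = FALSE]
  if (n_planted > nrow(psp))
    stop("n_planted exceeds database size", call. = FALSE)
  planted <- NULL
  if (n_planted > 0L) {
    pick <- psp[round(seq(1, nrow(psp), length.out = n_planted)), ,
                drop = FALSE]
    planted <- data.frame(i = pick$i, j = pick$j, k = pick$k, n = pick$n,
                          z = 2L, amplitude = 5e6, k_in = 0.4, k_out = 0)
  } else {
    planted <- data.frame(i = integer(), j = integer())
  }
  cfg <- sim_config(substrate, planted, n_decoys = n_decoys, seed = seed)
  sim <- simulate_digest(cfg)
  list(db = db, peaks = sim$peaks, manifest = sim$manifest,
       expected_mz = if (is.null(sim$manifest)) numeric()
                     else sim$manifest$mz)
}
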