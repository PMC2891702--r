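#' Residue mass table
#'
#' Monoisotopic and average masses (Da) of the 20 canonical amino-acid
#' residues, plus the masses of water, a proton and ammonia used throughout
#' the package.
#'
#' The monoisotopic proton mass is fixed at 1.00728 Da (the package's
#' documented convention for protonated m/z values); neutral-loss masses are
#' water 18.0105646 Da and ammonia 17.0265491 Da.
#'
#' @param mode `"mono"` (monoisotopic, the default) or `"average"`.
#' @return Named numeric vector of residue masses with attributes `water`,
#'   `proton` and `ammonia`.
#' @examples
#' tab <- residue_masses()
#' tab[["G"]]  # glycine residue, 57.021464
#' @export
residue_masses <- function(mode = c("mono", "average")) {
  mode <- match.arg(mode)
  tab <- if (mode == "mono") .mono_residues else .avg_residues
  attr(tab, "water") <- if (mode == "mono") .mass_water else .mass_water_avg
  attr(tab, "proton") <- .mass_proton
  attr(tab, "ammonia") <- .mass_ammonia
  attr(tab, "mode") <- mode
  tab
}

.mono_residues <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.avg_residues <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.mass_water <- 18.0105646
.mass_water_avg <- 18.01528
.mass_proton <- 1.00728
.mass_ammonia <- 17.0265491

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  bad <- setdiff(strsplit(sequence, "")[[1L]], names(.mono_residues))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  invisible(sequence)
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, optionally plus per-position
#' isotope-label mass offsets (e.g. +6.02013 Da for a 13C6-lysine).
#'
#' @param sequence Peptide string over the 20 canonical one-letter codes.
#' @param mode `"mono"` or `"average"`.
#' @param label_offsets Optional numeric vector of mass deltas (Da); either
#'   unnamed (one value, possibly zero, per residue) or named by 1-based
#'   position within `sequence`.
#' @return Neutral mass Mr in Da.
#' @examples
#' peptide_mass("VSRQLVSRQL")  # 1184.699
#' @export
peptide_mass <- function(sequence, mode = c("mono", "average"),
                         label_offsets = NULL) {
  .check_sequence(sequence)
  tab <- residue_masses(match.arg(mode))
  aa <- strsplit(sequence, "")[[1L]]
  m <- sum(tab[aa]) + attr(tab, "water")
  if (!is.null(label_offsets) && length(label_offsets)) {
    if (!is.null(names(label_offsets))) {
      pos <- as.integer(names(label_offsets))
      if (anyNA(pos) || any(pos < 1L) || any(pos > length(aa)))
        stop("label offset positions outside sequence", call. = FALSE)
      m <- m + sum(label_offsets)
    } else {
      if (length(label_offsets) != length(aa))
        stop("unnamed label_offsets must have one entry per residue",
             call. = FALSE)
      m <- m + sum(label_offsets)
    }
  }
  unname(m)
}

#' Mass-to-charge ratio of a protonated peptide
#'
#' m/z = (Mr + z * p) / z with p the proton mass. By default p = 1.00728 Da;
#' `convention = "integer"` reproduces the nominal (Mr + z)/z form sometimes
#' used with low-resolution ion traps (differences are below 0.03 m/z for
#' z <= 3).
#'
#' @param mr Neutral mass in Da (vectorised).
#' @param z Positive integer charge state.
#' @param convention `"proton"` (default) or `"integer"`.
#' @return m/z value(s).
#' @examples
#' mz_value(1184.699, 1)  # 1185.71
#' @export
mz_value <- function(mr, z, convention = c("proton", "integer")) {
  convention <- match.arg(convention)
  if (any(z <= 0) || any(z != as.integer(z)))
    stop("charge z must be a positive integer", call. = FALSE)
  p <- if (convention == "proton") .mass_proton else 1
  (mr + z * p) / z
}

#' Recover a neutral mass from an observed m/z
#'
#' Inverse of [mz_value()]: Mr = z * mz - z * p.
#'
#' @inheritParams mz_value
#' @param mz Observed m/z.
#' @export
neutral_mass <- function(mz, z, convention = c("proton", "integer")) {
  convention <- match.arg(convention)
  p <- if (convention == "proton") .mass_proton else 1
  z * mz - z * p
}

#' Mass of a spliced (ligated) peptide from its fragment masses
#'
#' Transpeptidation condenses two peptides with loss of one water, so
#' Mr(spliced) = Mr(first) + Mr(second) - water. Equals
#' `peptide_mass(paste0(a, b))` exactly; useful when fragment masses are
#' already tabulated for a large database.
#'
#' @param mass_first,mass_second Neutral peptide masses in Da (vectorised).
#' @param mode `"mono"` or `"average"` (selects the water mass).
#' @export
splice_mass <- function(mass_first, mass_second, mode = c("mono", "average")) {
  mode <- match.arg(mode)
  w <- if (mode == "mono") .mass_water else .mass_water_avg
  mass_first + mass_second - w
}

#' b- and y-series fragment ions
#'
#' Singly charged by default: b_i is the N-terminal prefix of length i plus a
#' proton; y_i is the C-terminal suffix of length i plus water and a proton.
#' Neutral losses of water (suffix `"°"`) and ammonia (suffix `"*"`)
#' subtract 18.0105646 and 17.0265491 Da respectively.
#'
#' @param sequence Peptide of length >= 2.
#' @param series Character subset of `c("b", "y")`.
#' @param losses Character subset of `c("none", "water", "ammonia")`.
#' @param z Charge state for the fragment ions (default 1).
#' @param label_offsets Optional per-position mass deltas, named by 1-based
#'   position within `sequence`.
#' @return data.frame with columns `label` (e.g. `"b2"`, `"y3°"`),
#'   `series`, `index`, `loss`, `mz`.
#' @examples
#' head(fragment_ions("RTKQLYPEW"))
#' @export
fragment_ions <- function(sequence, series = c("b", "y"),
                          losses = "none", z = 1L, label_offsets = NULL) {
  .check_sequence(sequence)
  if (!all(series %in% c("b", "y")))
    stop("unsupported ion series: ", paste(setdiff(series, c("b", "y")),
                                           collapse = ", "), call. = FALSE)
  if (!all(losses %in% c("none", "water", "ammonia")))
    stop("unsupported loss type", call. = FALSE)
  aa <- strsplit(sequence, "")[[1L]]
  L <- length(aa)
  if (L < 2L) stop("sequence must have length >= 2", call. = FALSE)
  tab <- residue_masses("mono")
  res <- unname(tab[aa])
  if (!is.null(label_offsets) && length(label_offsets)) {
    pos <- as.integer(names(label_offsets))
    res[pos] <- res[pos] + unname(label_offsets)
  }
  loss_mass <- c(none = 0, water = .mass_water, ammonia = .mass_ammonia)
  loss_tag <- c(none = "", water = "°", ammonia = "*")
  out <- list()
  for (s in series) {
    # b series runs to L-1; y series includes y_L, the intact [M+H]+ ion
    idx <- if (s == "b") seq_len(L - 1L) else seq_len(L)
    # b_i: prefix of length i; y_i: suffix of length i (+ water)
    neutral <- if (s == "b") cumsum(res)[idx]
               else cumsum(rev(res))[idx] + .mass_water
    for (lo in losses) {
      out[[length(out) + 1L]] <- data.frame(
        label = paste0(s, idx, loss_tag[[lo]]),
        series = s, index = idx, loss = lo,
        mz = (neutral - loss_mass[[lo]] + z * .mass_proton) / z,
        stringsAsFactors = FALSE)
    }
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}
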