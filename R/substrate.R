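#' Substrate polypeptide
#'
#' A substrate is the synthetic polypeptide offered to the 20S proteasome.
#' Positions are 1-based along `sequence`; `label_offsets` records per-residue
#' stable-isotope mass deltas for heavy analogues (e.g. 13C6-Lys = +6.02013).
#'
#' @param id Short text label.
#' @param sequence Amino-acid string over the 20 canonical one-letter codes,
#'   length >= 2.
#' @param label_offsets Optional numeric vector of mass deltas in Da, named by
#'   1-based residue position.
#' @return Object of class `"substrate"`.
#' @examples
#' substrate("gp100_40-52", "RTKAWNRQLYPEW")
#' @export
substrate <- function(id, sequence, label_offsets = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  .check_sequence(sequence)
  L <- nchar(sequence)
  if (L < 2L) stop("substrate must have length >= 2", call. = FALSE)
  if (!is.null(label_offsets)) {
    if (is.null(names(label_offsets)))
      stop("label_offsets must be named by residue position", call. = FALSE)
    pos <- as.integer(names(label_offsets))
    if (anyNA(pos) || any(pos < 1L) || any(pos > L))
      stop("label_offsets reference positions outside the sequence",
           call. = FALSE)
    if (any(!is.finite(label_offsets)))
      stop("label_offsets must be finite", call. = FALSE)
    label_offsets <- as.numeric(label_offsets)
    names(label_offsets) <- pos
  }
  structure(list(id = id, sequence = sequence, length = L,
                 label_offsets = label_offsets),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("substrate %s (L = %d): %s\n", x$id, x$length, x$sequence))
  if (!is.null(x$label_offsets)) {
    cat("  label offsets:",
        paste(sprintf("%s%+0.5f", names(x$label_offsets), x$label_offsets),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.substrate <- function(x) x$length

#' Read substrates from FASTA or plain text
#'
#' FASTA files (detected by a leading `>`) are parsed with
#' [Biostrings::readAAStringSet()]. Plain-text files may contain either one
#' raw sequence per line or `id<TAB>sequence` pairs; blank lines and `#`
#' comments are ignored.
#'
#' @param path File path.
#' @return List of [substrate()] objects.
#' @export
read_substrates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), ">")) {
    aas <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, "", 1L)
    return(mapply(substrate, ids, as.character(aas), SIMPLIFY = FALSE))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no sequences in ", path, call. = FALSE)
  out <- vector("list", length(lines))
  for (ii in seq_along(lines)) {
    parts <- strsplit(lines[[ii]], "\t")[[1L]]
    if (length(parts) >= 2L) out[[ii]] <- substrate(parts[[1L]], parts[[2L]])
    else out[[ii]] <- substrate(sprintf("substrate_%d", ii), parts[[1L]])
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Example substrate polypeptides
#'
#' The five synthetic polypeptides used as worked examples throughout the
#' package: two fragments of the human melanocyte protein gp100 (a 13-mer and
#' its N-/C-terminally extended 23-mer), a 30-mer from gp100_201-230, a 30-mer
#' from the HIV gag-pol polyprotein and a 25-mer from the murine
#' cytomegalovirus pp89 protein. Identifiers carry the region within the
#' parental protein; splice indices in this package are local (position 1 =
#' first residue of the substrate).
#'
#' @return Named list of [substrate()] objects.
#' @examples
#' demo_substrates()[["gp100_40-52"]]
#' @export
demo_substrates <- function() {
  list(
    "gp100_40-52"   = substrate("gp100_40-52", "RTKAWNRQLYPEW"),
    "gp100_35-57"   = substrate("gp100_35-57", "VSRQLRTKAWNRQLYPEWTEAQR"),
    "gp100_201-230" = substrate("gp100_201-230",
                                "AHSSSAFTITDQVPFSVSVSQLRALDGGNK"),
    "gagpol_29-58"  = substrate("gagpol_29-58",
                                "YKLKHIVWASRELERFAVNPGLLEVTSEGC"),
    "pp89_16-40"    = substrate("pp89_16-40", "RLMYDMYPHFMPTNLGPSEKRVWMS")
  )
}

#' Heavy-labelled analogue of a substrate
#'
#' Applies a residue-letter -> mass-delta specification (e.g.
#' `c(K = 6.02013, L = 0.99703)` for 13C6-Lys and 15N-Leu) to every matching
#' position, yielding the heavy analogue used in trans-splicing label
#' experiments.
#'
#' @param x A [substrate()].
#' @param label_spec Named numeric vector: residue letter -> delta in Da.
#' @param id Identifier for the heavy analogue (default `<id>_heavy`).
#' @return A new [substrate()] carrying `label_offsets`.
#' @examples
#' heavy_analogue(demo_substrates()[["gp100_40-52"]],
#'                c(K = 6.02013, L = 0.99703))
#' @export
heavy_analogue <- function(x, label_spec, id = paste0(x$id, "_heavy")) {
  stopifnot(inherits(x, "substrate"), is.numeric(label_spec),
            !is.null(names(label_spec)))
  aa <- strsplit(x$sequence, "")[[1L]]
  pos <- which(aa %in% names(label_spec))
  if (!length(pos)) return(substrate(id, x$sequence))
  offs <- unname(label_spec[aa[pos]])
  names(offs) <- pos
  substrate(id, x$sequence, offs)
}
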