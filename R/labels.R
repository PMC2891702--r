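#' Light/heavy label variants of a spliced peptide
#'
#' In a mixed digestion of a substrate and its stable-isotope heavy analogue,
#' each splice product i-j/k-n can arise in four isotopic variants depending
#' on which molecule donated each fragment: light/light, light/heavy,
#' heavy/light and heavy/heavy. Their masses differ from light/light by
#' 0, D2, D1 and D1 + D2, where D1 (D2) is the summed label offset inside the
#' first (second) fragment. The mixed variants (light/heavy, heavy/light)
#' can only come from two distinct substrate molecules and are therefore
#' diagnostic of trans splicing.
#'
#' @param light [substrate()] without label offsets.
#' @param heavy Heavy analogue: same letter sequence, with `label_offsets`
#'   (see [heavy_analogue()]).
#' @param i,j,k,n Splice coordinates (local to the substrate).
#' @param charges Charge states for which m/z columns are added.
#' @return data.frame with one row per variant (`ll`, `lh`, `hl`, `hh`):
#'   `variant`, `first_label`, `second_label`, `delta` (Da vs light/light),
#'   `mr`, `trans_only`, and `mz<z>` columns.
#' @examples
#' s <- demo_substrates()[["gp100_40-52"]]
#' h <- heavy_analogue(s, c(K = 6.02013, L = 0.99703))
#' label_variants(s, h, 1, 3, 8, 13)[, c("variant", "delta", "mz1")]
#' @export
label_variants <- function(light, heavy, i, j, k, n, charges = 1:3) {
  stopifnot(inherits(light, "substrate"), inherits(heavy, "substrate"))
  if (light$sequence != heavy$sequence)
    stop("light and heavy substrates must share the same letter sequence",
         call. = FALSE)
  base_seq <- splice_sequence(light, i, j, k, n)
  base_mr <- peptide_mass(base_seq)
  offs <- heavy$label_offsets
  frag_delta <- function(a, b) {
    if (is.null(offs)) return(0)
    pos <- as.integer(names(offs))
    sum(offs[pos >= a & pos <= b])
  }
  d1 <- frag_delta(i, j)
  d2 <- frag_delta(k, n)
  out <- data.frame(
    variant = c("ll", "lh", "hl", "hh"),
    first_label = c("light", "light", "heavy", "heavy"),
    second_label = c("light", "heavy", "light", "heavy"),
    delta = c(0, d2, d1, d1 + d2),
    stringsAsFactors = FALSE)
  out$sequence <- base_seq
  out$mr <- base_mr + out$delta
  out$trans_only <- out$first_label != out$second_label
  for (z in charges) out[[paste0("mz", z)]] <- mz_value(out$mr, z)
  out
}
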