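# Independent oracles used to cross-check the implementation.

# --- mass oracle: residue masses rebuilt from elemental composition ---------
.elements <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

.residue_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

oracle_peptide_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1L]]
  res <- vapply(aa, function(a) {
    f <- .residue_formulas[[a]]
    sum(.elements[names(f)] * f)
  }, 0)
  sum(res) + 2 * .elements[["H"]] + .elements[["O"]]  # + H2O
}

# --- enumeration oracle: brute force with set-based classification ----------
oracle_counts <- function(L, l_ext) {
  frs <- list()
  for (i in seq_len(L)) for (j in seq_len(L))
    if (j >= i && j - i + 1 >= l_ext) frs[[length(frs) + 1L]] <- c(i, j)
  tally <- c(cis_normal = 0L, cis_reverse = 0L, trans = 0L, adjacent = 0L)
  for (a in frs) for (b in frs) {
    pos_a <- a[1]:a[2]; pos_b <- b[1]:b[2]
    cls <-
      if (length(intersect(pos_a, pos_b)) > 0) "trans"
      else if (min(pos_b) > max(pos_a)) {
        if (min(pos_b) == max(pos_a) + 1) "adjacent" else "cis_normal"
      } else "cis_reverse"
    tally[[cls]] <- tally[[cls]] + 1L
  }
  c(n_pcp = length(frs), tally)
}

random_peptide <- function(len) {
  paste(sample(names(.residue_formulas), len, replace = TRUE), collapse = "")
}
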