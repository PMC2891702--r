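#' Enumeration parameters
#'
#' @param l_ext Minimal fragment length that can take part in a splice
#'   (default 2, the value used throughout the worked examples).
#' @param classes Product classes to emit from [enumerate_psp()].
#' @param include_native_adjacent Re-include pairs with `k = j + 1` on the
#'   same substrate, whose spliced sequence is indistinguishable from the
#'   contiguous cleavage product `i..n` (default `FALSE`).
#' @param allow_self_pairing Allow a fragment to be spliced to a second copy
#'   of itself (trans by definition; default `TRUE`).
#' @return Object of class `"enum_params"`.
#' @export
enum_params <- function(l_ext = 2L,
                        classes = c("cis_normal", "cis_reverse", "trans"),
                        include_native_adjacent = FALSE,
                        allow_self_pairing = TRUE) {
  l_ext <- as.integer(l_ext)
  if (is.na(l_ext) || l_ext < 1L) stop("l_ext must be >= 1", call. = FALSE)
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(l_ext = l_ext, classes = classes,
                 include_native_adjacent = isTRUE(include_native_adjacent),
                 allow_self_pairing = isTRUE(allow_self_pairing)),
            class = "enum_params")
}

#' Enumerate contiguous cleavage products (PCP)
#'
#' All substrings `i..j` of the substrate with length `j - i + 1 >= l_ext`,
#' in lexicographic `(i, j)` order. PCP_ij denotes the peptide spanning
#' residues i through j (1-based, inclusive).
#'
#' @param x A [substrate()].
#' @param params An [enum_params()].
#' @return data.frame with integer columns `i`, `j`.
#' @examples
#' nrow(enumerate_pcp(substrate("s", "RTKAWNRQLYPEW")))  # 78
#' @export
enumerate_pcp <- function(x, params = enum_params()) {
  stopifnot(inherits(x, "substrate"))
  L <- x$length
  le <- params$l_ext
  if (le > L) {
    warning("l_ext exceeds substrate length; no fragments", call. = FALSE)
    return(data.frame(i = integer(), j = integer()))
  }
  i <- rep.int(seq_len(L - le + 1L), (L - le + 1L):1L)
  j <- unlist(lapply(seq_len(L - le + 1L), function(s) seq.int(s + le - 1L, L)),
              use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

#' Classify a splice-index quadruple
#'
#' For fragments `(i, j)` and `(k, n)` of the same substrate:
#' * `cis_normal` - the fragments sit in substrate order with a gap of at
#'   least one residue (`k >= j + 2`);
#' * `cis_reverse` - the second fragment lies entirely N-terminal of the
#'   first (`i >= n + 1`; direct adjacency `i = n + 1` counts);
#' * `trans` otherwise: overlapping coordinates, self-pairing, or native
#'   adjacency `k = j + 1` - all of which require (or are indistinguishable
#'   from products of) two separate substrate molecules. Pairs drawn from two
#'   different substrate molecules are trans regardless of coordinates.
#'
#' @param i,j Start/end of the first spliced fragment (vectorised).
#' @param k,n Start/end of the second spliced fragment.
#' @param same_substrate Logical: do both fragments come from the same
#'   substrate molecule? (default `TRUE`).
#' @return Character vector in `c("cis_normal", "cis_reverse", "trans")`.
#' @examples
#' classify_splice(15, 18, 1, 5)  # "cis_reverse"
#' classify_splice(3, 4, 15, 23)  # "cis_normal"
#' classify_splice(1, 5, 1, 5)    # "trans"
#' @export
classify_splice <- function(i, j, k, n, same_substrate = TRUE) {
  if (any(i > j) || any(k > n) || any(i < 1L) || any(k < 1L))
    stop("invalid fragment coordinates", call. = FALSE)
  same_substrate <- rep_len(same_substrate, length(i))
  ifelse(!same_substrate, "trans",
         ifelse(k >= j + 2L, "cis_normal",
                ifelse(i >= n + 1L, "cis_reverse", "trans")))
}

#' Enumerate spliced products (PSP)
#'
#' Every ordered pair of qualifying fragments, classified with
#' [classify_splice()]. With a single substrate all `n_pcp^2` ordered pairs
#' are considered; native-adjacent pairs (`k = j + 1`, sequence-identical to
#' a PCP) are excluded unless `params$include_native_adjacent`. With two
#' substrates only cross-molecule pairs are enumerated (both orders), all of
#' class trans - the stable-isotope label experiment.
#'
#' @param substrates A single [substrate()] or a list of one or two.
#' @param params An [enum_params()].
#' @return data.frame with columns `sub_first`, `sub_second`, `i`, `j`, `k`,
#'   `n`, `class`, `sequence`, in lexicographic `(i, j, k, n)` order.
#' @examples
#' s <- substrate("s", "ACDE")
#' table(enumerate_psp(s)$class)
#' @export
enumerate_psp <- function(substrates, params = enum_params()) {
  if (inherits(substrates, "substrate")) substrates <- list(substrates)
  if (!length(substrates) %in% 1:2 ||
      !all(vapply(substrates, inherits, TRUE, "substrate")))
    stop("substrates must be one or two substrate objects", call. = FALSE)

  if (length(substrates) == 1L) {
    s <- substrates[[1L]]
    fr <- enumerate_pcp(s, params)
    np <- nrow(fr)
    if (np == 0L) return(.empty_psp())
    a <- rep(seq_len(np), each = np)
    b <- rep.int(seq_len(np), np)
    out <- data.frame(sub_first = s$id, sub_second = s$id,
                      i = fr$i[a], j = fr$j[a], k = fr$i[b], n = fr$j[b],
                      stringsAsFactors = FALSE)
    if (!params$include_native_adjacent)
      out <- out[out$k != out$j + 1L, , drop = FALSE]
    if (!params$allow_self_pairing)
      out <- out[!(out$i == out$k & out$j == out$n), , drop = FALSE]
    out$class <- classify_splice(out$i, out$j, out$k, out$n)
    seqs <- list(first = s, second = s)
  } else {
    s1 <- substrates[[1L]]; s2 <- substrates[[2L]]
    if (s1$id == s2$id)
      stop("cross-enumeration needs two distinct substrate ids",
           call. = FALSE)
    f1 <- enumerate_pcp(s1, params); f2 <- enumerate_pcp(s2, params)
    if (!nrow(f1) || !nrow(f2)) return(.empty_psp())
    a12 <- rep(seq_len(nrow(f1)), each = nrow(f2))
    b12 <- rep.int(seq_len(nrow(f2)), nrow(f1))
    out <- rbind(
      data.frame(sub_first = s1$id, sub_second = s2$id,
                 i = f1$i[a12], j = f1$j[a12], k = f2$i[b12], n = f2$j[b12],
                 stringsAsFactors = FALSE),
      data.frame(sub_first = s2$id, sub_second = s1$id,
                 i = f2$i[a12], j = f2$j[a12], k = f1$i[b12], n = f1$j[b12],
                 stringsAsFactors = FALSE))
    out$class <- "trans"
    seqs <- list(first = s1, second = s2)
  }
  out <- out[out$class %in% params$classes, , drop = FALSE]
  out <- out[order(out$sub_first, out$i, out$j, out$k, out$n), , drop = FALSE]
  rownames(out) <- NULL
  # sequence = first fragment then second fragment
  seq_by_id <- stats::setNames(vapply(substrates, `[[`, "", "sequence"),
                               vapply(substrates, `[[`, "", "id"))
  out$sequence <- paste0(
    substring(unname(seq_by_id[out$sub_first]), out$i, out$j),
    substring(unname(seq_by_id[out$sub_second]), out$k, out$n))
  out
}

.empty_psp <- function() {
  data.frame(sub_first = character(), sub_second = character(),
             i = integer(), j = integer(), k = integer(), n = integer(),
             class = character(), sequence = character(),
             stringsAsFactors = FALSE)
}

#' Sequence of a cleavage or splice product
#'
#' Concatenates the first fragment (`i..j`) and, for splice products, the
#' second fragment (`k..n`) of the given substrate(s).
#'
#' @param first [substrate()] providing the first fragment.
#' @param i,j First fragment coordinates (1-based inclusive).
#' @param k,n Optional second fragment coordinates; omit for a PCP.
#' @param second Substrate providing the second fragment (defaults to
#'   `first`).
#' @return Peptide string.
#' @examples
#' s <- demo_substrates()[["gp100_35-57"]]
#' splice_sequence(s, 15, 18, 1, 5)  # "YPEWVSRQL"
#' @export
splice_sequence <- function(first, i, j, k = NULL, n = NULL, second = first) {
  stopifnot(inherits(first, "substrate"), inherits(second, "substrate"))
  if (i < 1L || j > first$length || i > j)
    stop("first fragment outside substrate", call. = FALSE)
  part1 <- substring(first$sequence, i, j)
  if (is.null(k)) return(part1)
  if (k < 1L || n > second$length || k > n)
    stop("second fragment outside substrate", call. = FALSE)
  paste0(part1, substring(second$sequence, k, n))
}

#' Closed-form product counts
#'
#' Number of cleavage products and spliced products of each class for a
#' substrate of length `L` at minimal fragment length `l_ext`, matching the
#' cardinalities of [enumerate_pcp()]/[enumerate_psp()] exactly. With
#' `M = L - l_ext + 1` and `U = L - 2 l_ext + 1`:
#' `n_pcp = M (M + 1) / 2`, `n_cis_normal = choose(U + 2, 4)`,
#' `n_cis_reverse = choose(U + 3, 4)`, `n_native_adjacent = choose(U + 2, 3)`
#' and `n_trans` is the remainder of the `n_pcp^2` ordered pairs.
#'
#' @param L Substrate length.
#' @param l_ext Minimal fragment length.
#' @return One-row data.frame: `n_pcp`, `n_cis_normal`, `n_cis_reverse`,
#'   `n_trans`, `n_native_adjacent`, `n_psp`, `n_all_pairs`.
#' @examples
#' count_products(13, 2)
#' @export
count_products <- function(L, l_ext = 2L) {
  L <- as.integer(L); l_ext <- as.integer(l_ext)
  if (is.na(L) || is.na(l_ext) || l_ext < 1L)
    stop("L and l_ext must be positive integers", call. = FALSE)
  if (L < l_ext)
    return(data.frame(n_pcp = 0, n_cis_normal = 0, n_cis_reverse = 0,
                      n_trans = 0, n_native_adjacent = 0, n_psp = 0,
                      n_all_pairs = 0))
  M <- L - l_ext + 1L
  U <- max(L - 2L * l_ext + 1L, 0L)
  n_pcp <- M * (M + 1) / 2
  n_cn <- choose(U + 2, 4)
  n_cr <- choose(U + 3, 4)
  n_adj <- choose(U + 2, 3)
  n_all <- n_pcp^2
  n_psp <- n_all - n_adj
  data.frame(n_pcp = n_pcp, n_cis_normal = n_cn, n_cis_reverse = n_cr,
             n_trans = n_psp - n_cn - n_cr, n_native_adjacent = n_adj,
             n_psp = n_psp, n_all_pairs = n_all)
}

#' Write an enumeration table as TSV
#'
#' @param psp data.frame from [enumerate_psp()].
#' @param path Output file.
#' @export
write_enumeration_tsv <- function(psp, path) {
  utils::write.table(psp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
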