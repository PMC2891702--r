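#' Theoretical database parameters
#'
#' @param charges Charge states for which m/z values are tabulated
#'   (default 1:3, the states observable on an ESI ion trap).
#' @param cluster_width Maximal m/z span of one cluster in Da (default 0.2,
#'   matching the resolution of the target instrument).
#' @param mode Mass mode, `"mono"` or `"average"`.
#' @param enum An [enum_params()].
#' @param cluster_method `"greedy"` (span-bounded grouping over sorted
#'   values, the default) or `"bin"` (fixed-width binning from the smallest
#'   value).
#' @param cluster_pcp Include PCP entries in the clustering (default `FALSE`:
#'   clusters are built over splice products only).
#' @param max_length Guardrail: refuse substrates longer than this (default
#'   60) unless `allow_long`.
#' @param allow_long Override the substrate-length guardrail.
#' @return Object of class `"db_params"`.
#' @export
db_params <- function(charges = 1:3, cluster_width = 0.2,
                      mode = c("mono", "average"), enum = enum_params(),
                      cluster_method = c("greedy", "bin"),
                      cluster_pcp = FALSE, max_length = 60L,
                      allow_long = FALSE) {
  if (!length(charges) || any(charges < 1))
    stop("charges must be a non-empty set of positive integers",
         call. = FALSE)
  if (cluster_width <= 0) stop("cluster_width must be > 0", call. = FALSE)
  structure(list(charges = sort(unique(as.integer(charges))),
                 cluster_width = cluster_width, mode = match.arg(mode),
                 enum = enum, cluster_method = match.arg(cluster_method),
                 cluster_pcp = isTRUE(cluster_pcp),
                 max_length = as.integer(max_length),
                 allow_long = isTRUE(allow_long)),
            class = "db_params")
}

#' Cluster sorted m/z values into tolerance groups
#'
#' Greedy left-to-right grouping over the sorted values: a value joins the
#' current cluster while the cluster span (value minus the cluster's first
#' member) stays within `width`; otherwise it starts a new cluster. The
#' representative of each cluster is the arithmetic mean of its members.
#'
#' @param values Numeric m/z values (sorted internally).
#' @param width Maximal span in Da.
#' @param method `"greedy"` or `"bin"` (fixed bins of size `width` anchored
#'   at the smallest value).
#' @return data.frame with one row per input value (in ascending order):
#'   `mz`, `cluster_id`, `cluster_mz` (representative), plus attribute
#'   `clusters`: data.frame `cluster_id`, `cluster_mz`, `n`, `span`.
#' @examples
#' cluster_mz(c(500.00, 500.10, 500.19, 500.60), 0.2)
#' @export
cluster_mz <- function(values, width = 0.2, method = c("greedy", "bin")) {
  method <- match.arg(method)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (!length(values)) {
    out <- data.frame(mz = numeric(), cluster_id = integer(),
                      cluster_mz = numeric())
    attr(out, "clusters") <- data.frame(cluster_id = integer(),
                                        cluster_mz = numeric(),
                                        n = integer(), span = numeric())
    return(out)
  }
  v <- sort(values)
  if (method == "greedy") {
    id <- integer(length(v))
    start <- 1L
    cid <- 0L
    while (start <= length(v)) {
      cid <- cid + 1L
      # last index still within `width` of the cluster's first member
      end <- findInterval(v[start] + width, v)
      id[start:end] <- cid
      start <- end + 1L
    }
  } else {
    id <- as.integer(floor((v - v[1L]) / width)) + 1L
    id <- match(id, unique(id))  # densify ids
  }
  rep_mz <- tapply(v, id, mean)
  out <- data.frame(mz = v, cluster_id = id,
                    cluster_mz = unname(rep_mz[as.character(id)]))
  span <- tapply(v, id, function(x) max(x) - min(x))
  attr(out, "clusters") <- data.frame(
    cluster_id = as.integer(names(rep_mz)), cluster_mz = as.numeric(rep_mz),
    n = as.integer(table(id)), span = as.numeric(span))
  out
}

#' Build the theoretical PCP/PSP m/z database
#'
#' Step one of the screening method: enumerate all cleavage (PCP) and splice
#' (PSP) products of the substrate(s), compute each neutral mass and its m/z
#' at every configured charge state, and cluster the m/z values into groups
#' whose span does not exceed `cluster_width`, each represented by its mean.
#' The cluster representatives are the theoretical values screened against
#' MS1 data.
#'
#' @param substrates A [substrate()] or list of one or two.
#' @param params A [db_params()].
#' @return Object of class `"psp_db"`: list with `entries` (one row per
#'   product: indices, class, sequence, `mr`), `ions` (one row per (entry,
#'   charge): `entry_id`, `z`, `mz`, `cluster_id`, `cluster_mz`), `clusters`
#'   (summary per cluster), `substrates`, `params`.
#' @examples
#' db <- build_database(substrate("s", "RTKAWNRQLYPEW"))
#' db_stats(db)
#' @export
build_database <- function(substrates, params = db_params()) {
  if (inherits(substrates, "substrate")) substrates <- list(substrates)
  stopifnot(inherits(params, "db_params"))
  for (s in substrates) {
    if (s$length > params$max_length && !params$allow_long)
      stop("substrate ", s$id, " has length ", s$length, " > ",
           params$max_length, "; a longer substrate expands the database ",
           "exponentially - pass allow_long = TRUE to override",
           call. = FALSE)
  }
  psp <- enumerate_psp(substrates, params$enum)
  psp$kind <- "PSP"
  pcp_list <- lapply(substrates, function(s) {
    fr <- enumerate_pcp(s, params$enum)
    if (!nrow(fr)) return(NULL)
    data.frame(sub_first = s$id, sub_second = NA_character_,
               i = fr$i, j = fr$j, k = NA_integer_, n = NA_integer_,
               class = "PCP",
               sequence = substring(s$sequence, fr$i, fr$j),
               kind = "PCP", stringsAsFactors = FALSE)
  })
  entries <- rbind(do.call(rbind, pcp_list), psp)
  rownames(entries) <- NULL
  entries$entry_id <- seq_len(nrow(entries))

  tab <- residue_masses(params$mode)
  water <- attr(tab, "water")
  # residue-sum via per-sequence lookup, vectorised over unique sequences
  useq <- unique(entries$sequence)
  umass <- vapply(strsplit(useq, ""), function(a) sum(tab[a]), 0) + water
  entries$mr <- umass[match(entries$sequence, useq)]

  cluster_set <- if (params$cluster_pcp) entries$entry_id
                 else entries$entry_id[entries$kind == "PSP"]
  ions <- data.frame(
    entry_id = rep(entries$entry_id, times = length(params$charges)),
    z = rep(params$charges, each = nrow(entries)))
  ions$mz <- mz_value(entries$mr[ions$entry_id], ions$z)
  ions$cluster_id <- NA_integer_
  ions$cluster_mz <- NA_real_
  sel <- ions$entry_id %in% cluster_set
  cl <- cluster_mz(ions$mz[sel], params$cluster_width,
                   params$cluster_method)
  ord <- order(ions$mz[sel])
  ions$cluster_id[which(sel)[ord]] <- cl$cluster_id
  ions$cluster_mz[which(sel)[ord]] <- cl$cluster_mz

  structure(list(entries = entries, ions = ions,
                 clusters = attr(cl, "clusters"),
                 substrates = substrates, params = params),
            class = "psp_db")
}

#' @export
print.psp_db <- function(x, ...) {
  st <- db_stats(x)
  cat(sprintf(
    "theoretical m/z database: %d substrate(s), %d PCP, %d PSP (%d cis-normal, %d cis-reverse, %d trans), %d m/z clusters\n",
    length(x$substrates), st$n_pcp, st$n_psp, st$n_cis_normal,
    st$n_cis_reverse, st$n_trans, st$n_clusters))
  invisible(x)
}

#' Database summary counts
#'
#' Per-class entry counts and the number of m/z clusters.
#'
#' @param db A [build_database()] result.
#' @return One-row data.frame.
#' @export
db_stats <- function(db) {
  stopifnot(inherits(db, "psp_db"))
  e <- db$entries
  data.frame(
    n_pcp = sum(e$kind == "PCP"),
    n_cis_normal = sum(e$class == "cis_normal"),
    n_cis_reverse = sum(e$class == "cis_reverse"),
    n_trans = sum(e$class == "trans"),
    n_psp = sum(e$kind == "PSP"),
    n_ions = nrow(db$ions),
    n_clusters = nrow(db$clusters))
}

#' Export the database as a searchable FASTA file
#'
#' Headers encode provenance as
#' `substrate|i-j/k-n|class|Mr` (PCP entries as `substrate|i-j|PCP|Mr`).
#' With `dedupe_sequences` identical peptide sequences are merged into one
#' record whose header lists every index provenance separated by `;`.
#'
#' @param db A [build_database()] result.
#' @param path Output FASTA path.
#' @param dedupe_sequences Merge identical sequences (default `FALSE`).
#' @param include_pcp Also export PCP entries (default `TRUE`).
#' @return `path`, invisibly.
#' @export
export_fasta <- function(db, path, dedupe_sequences = FALSE,
                         include_pcp = TRUE) {
  stopifnot(inherits(db, "psp_db"))
  e <- db$entries
  if (!include_pcp) e <- e[e$kind == "PSP", , drop = FALSE]
  idx <- ifelse(e$kind == "PCP",
                sprintf("%d-%d", e$i, e$j),
                sprintf("%d-%d/%d-%d", e$i, e$j, e$k, e$n))
  tag <- sprintf("%s|%s|%s|%.4f", e$sub_first, idx, e$class, e$mr)
  if (dedupe_sequences) {
    grp <- split(tag, e$sequence)
    seqs <- names(grp)
    hdr <- vapply(grp, paste, "", collapse = ";")
  } else {
    seqs <- e$sequence
    hdr <- tag
  }
  if (!length(seqs)) {
    file.create(path)
    return(invisible(path))
  }
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- hdr
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Dump the database ion table as TSV
#'
#' One row per (entry, charge): sequence, indices, class, Mr, z, m/z,
#' cluster assignment.
#'
#' @param db A [build_database()] result.
#' @param path Output TSV path.
#' @export
export_db_tsv <- function(db, path) {
  stopifnot(inherits(db, "psp_db"))
  e <- db$entries[db$ions$entry_id, c("sub_first", "sub_second", "i", "j",
                                      "k", "n", "class", "sequence", "mr")]
  out <- cbind(e, db$ions[, c("z", "mz", "cluster_id", "cluster_mz")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
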