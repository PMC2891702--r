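#' Run the full screening pipeline
#'
#' Chains the four in-silico steps: (1) theoretical database construction
#' with m/z clustering, (2) matching of cluster representatives against the
#' observed MS1 signals, (3) chromatographic peak detection per matched
#' cluster, (4) kinetic filtering and inclusion-list generation. Candidate
#' counts shrink monotonically across the steps; the per-step reduction
#' trail is returned and logged via `message()`.
#'
#' @param substrates A [substrate()] or list of one or two.
#' @param peaks Time-course peak-list data.frame (see
#'   [read_peaklist_csv()]); must include digestion time 0.
#' @param db_par A [db_params()].
#' @param fil_par A [filter_params()].
#' @param d_max Inclusion-list subgroup cap (default 15).
#' @param out_dir Optional directory; when given, writes `database.tsv`,
#'   `database.fasta`, `candidates.tsv` and `inclusion_list.csv` there.
#' @param quiet Suppress progress messages.
#' @return List: `db`, `matched` (clusters), `traces`, `candidates`,
#'   `inclusion`, `counts` (per-step candidate counts).
#' @export
run_pipeline <- function(substrates, peaks, db_par = db_params(),
                         fil_par = filter_params(), d_max = 15L,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  db <- build_database(substrates, db_par)
  st <- db_stats(db)
  say("step 1: %d PSP entries, %d m/z clusters", st$n_psp, st$n_clusters)
  matched <- match_clusters(db, peaks, fil_par$mz_tolerance)
  say("step 2: %d clusters matched in MS1 (%.1f%%)", nrow(matched),
      100 * nrow(matched) / max(st$n_clusters, 1L))
  traces <- build_traces(matched, peaks, fil_par)
  n_traced <- length(unique(traces$cluster_id))
  say("step 3: %d clusters with detected chromatographic peaks", n_traced)
  candidates <- kinetic_filter(traces, fil_par)
  say("step 4: %d candidates pass the kinetic filter", nrow(candidates))
  inclusion <- group_candidates(candidates, d_max, fil_par)
  say("inclusion list: %d group(s), %d MS run(s)", inclusion$n_groups,
      inclusion$n_subgroups)
  counts <- data.frame(
    step = c("clusters", "matched", "peak_detected", "kinetic_filtered"),
    n = c(st$n_clusters, nrow(matched), n_traced, nrow(candidates)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_db_tsv(db, file.path(out_dir, "database.tsv"))
    export_fasta(db, file.path(out_dir, "database.fasta"))
    utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_inclusion_csv(inclusion, file.path(out_dir, "inclusion_list.csv"),
                        db)
  }
  list(db = db, matched = matched, traces = traces, candidates = candidates,
       inclusion = inclusion, counts = counts)
}
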