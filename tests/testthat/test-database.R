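test_that("cluster_mz implements the greedy span-bounded rule", {
  cl <- cluster_mz(c(500.00, 500.10, 500.19, 500.60), 0.2)
  expect_equal(cl$cluster_id, c(1L, 1L, 1L, 2L))
  expect_equal(attr(cl, "clusters")$cluster_mz,
               c(mean(c(500.00, 500.10, 500.19)), 500.60),
               tolerance = 1e-12)
  # empty input, identical values
  expect_equal(nrow(cluster_mz(numeric(), 0.2)), 0L)
  same <- cluster_mz(rep(610.82, 5), 0.2)
  expect_equal(unique(same$cluster_id), 1L)
  expect_equal(unique(same$cluster_mz), 610.82)
  # two values wider than the window split
  expect_equal(max(cluster_mz(c(500.0, 500.5), 0.2)$cluster_id), 2L)
  expect_error(cluster_mz(1:3, 0), "width")
})

test_that("cluster partition and span invariants hold on random data", {
  set.seed(21)
  for (rep in 1:5) {
    v <- sort(runif(500, 300, 320))
    cl <- cluster_mz(v, 0.2)
    info <- attr(cl, "clusters")
    expect_equal(sum(info$n), length(v))           # every value in one cluster
    expect_true(all(info$span <= 0.2 + 1e-12))     # span bound
    expect_true(all(info$cluster_mz >= tapply(cl$mz, cl$cluster_id, min) &
                    info$cluster_mz <= tapply(cl$mz, cl$cluster_id, max)))
    # idempotence: reclustering representatives causes no merges beyond width
    re <- attr(cluster_mz(info$cluster_mz, 0.2), "clusters")
    expect_true(all(re$span <= 0.2 + 1e-12))
  }
})

test_that("build_database entries match enumeration and cover all ions", {
  s <- substrate("s", "RTKAWNRQLYPEW")
  db <- build_database(s)
  st <- db_stats(db)
  cp <- count_products(13, 2)
  expect_equal(st$n_pcp, cp$n_pcp)
  expect_equal(st$n_psp, cp$n_psp)
  expect_equal(st$n_cis_normal, cp$n_cis_normal)
  expect_equal(st$n_cis_reverse, cp$n_cis_reverse)
  expect_equal(st$n_ions, (cp$n_pcp + cp$n_psp) * 3)
  # every PSP ion belongs to exactly one cluster; PCP ions are unclustered
  psp_ids <- db$entries$entry_id[db$entries$kind == "PSP"]
  psp_ions <- db$ions[db$ions$entry_id %in% psp_ids, ]
  expect_false(anyNA(psp_ions$cluster_id))
  expect_true(all(is.na(db$ions$cluster_id[!db$ions$entry_id %in% psp_ids])))
  expect_equal(sum(attr(cluster_mz(psp_ions$mz, 0.2), "clusters")$n),
               nrow(psp_ions))
  # mr column consistent with peptide_mass on a sample of entries
  pick <- db$entries[c(1, 100, 2000), ]
  expect_equal(pick$mr, vapply(pick$sequence, peptide_mass, 0,
                               USE.NAMES = FALSE), tolerance = 1e-9)
})

test_that("degenerate databases behave as documented", {
  # single PSP entry (self-splice of the only fragment), one charge
  db1 <- build_database(substrate("s", "AC"), db_params(charges = 1))
  expect_equal(db_stats(db1)$n_psp, 1L)
  expect_equal(nrow(db1$clusters), 1L)
  expect_equal(db1$clusters$cluster_mz,
               mz_value(peptide_mass("ACAC"), 1), tolerance = 1e-9)
  # two entries 0.5 Da apart end up in two clusters (charges = 1)
  db2 <- build_database(substrate("s", "ACD"), db_params(charges = 1))
  expect_true(nrow(db2$clusters) > 1L)
  # substrate-length guardrail
  long <- substrate("long", random_peptide(61))
  expect_error(build_database(long), "allow_long")
  mid <- substrate("mid", random_peptide(12))
  expect_error(build_database(mid, db_params(max_length = 10)), "allow_long")
  expect_s3_class(build_database(mid, db_params(max_length = 10,
                                                allow_long = TRUE,
                                                charges = 1)), "psp_db")
})

test_that("FASTA export round-trips sequences and provenance", {
  s <- demo_substrates()[["gp100_40-52"]]
  db <- build_database(s)
  fa <- tempfile(fileext = ".fasta")
  export_fasta(db, fa)
  aas <- Biostrings::readAAStringSet(fa)
  expect_equal(length(aas), nrow(db$entries))
  expect_setequal(as.character(aas), db$entries$sequence)
  hdr <- names(aas)
  expect_true(all(grepl("^gp100_40-52\\|", hdr)))
  expect_true(any(grepl("\\|trans\\|", hdr)))
  # dedupe merges identical sequences and concatenates provenance
  fa2 <- tempfile(fileext = ".fasta")
  export_fasta(db, fa2, dedupe_sequences = TRUE)
  aas2 <- Biostrings::readAAStringSet(fa2)
  expect_equal(length(aas2), length(unique(db$entries$sequence)))
  dup_seq <- names(which(table(db$entries$sequence) > 1))[1]
  hdr_dup <- names(aas2)[as.character(aas2) == dup_seq]
  expect_true(grepl(";", hdr_dup))
  # empty database gives an empty valid FASTA
  db0 <- build_database(substrate("s", "AC"), db_params(charges = 1))
  db0$entries <- db0$entries[0, ]
  fa3 <- tempfile(fileext = ".fasta")
  export_fasta(db0, fa3)
  expect_equal(length(Biostrings::readAAStringSet(fa3)), 0L)
})

test_that("database TSV dump round-trips", {
  db <- build_database(substrate("s", "ACDEF"), db_params(charges = 1:2))
  tsv <- tempfile(fileext = ".tsv")
  export_db_tsv(db, tsv)
  d <- read.delim(tsv)
  expect_equal(nrow(d), nrow(db$ions))
  expect_equal(sort(unique(d$z)), 1:2)
  expect_equal(d$mz, db$ions$mz, tolerance = 1e-6)
})

test_that("label variants carry the heavy-isotope mass ladder", {
  s <- demo_substrates()[["gp100_40-52"]]
  h <- heavy_analogue(s, c(K = 6.02013, L = 0.99703))
  lv <- label_variants(s, h, 1, 3, 8, 13)   # [RTK][QLYPEW]
  expect_equal(lv$delta, c(0, 0.99703, 6.02013, 7.01716), tolerance = 1e-9)
  expect_equal(lv$trans_only, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(round(lv$mz1 - lv$mz1[1]), c(0, 1, 6, 7))
  # heavy/heavy minus light/light equals the summed offsets in the product
  expect_equal(lv$mr[4] - lv$mr[1], 6.02013 + 0.99703)
  # unlabeled "heavy" collapses all four variants
  lv0 <- label_variants(s, substrate("h", s$sequence), 1, 3, 8, 13)
  expect_equal(unique(lv0$mr), lv0$mr[1])
  expect_error(label_variants(s, substrate("h", "ACDE"), 1, 2, 3, 4),
               "same letter sequence")
})
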