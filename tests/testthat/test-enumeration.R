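test_that("enumerate_pcp emits exactly the qualifying fragments in order", {
  s <- substrate("s", "ACDE")
  fr <- enumerate_pcp(s, enum_params(l_ext = 2))
  expect_equal(fr, data.frame(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                              j = c(2L, 3L, 4L, 3L, 4L, 4L)))
  expect_equal(nrow(enumerate_pcp(substrate("s", "AC"))), 1L)
  expect_equal(nrow(enumerate_pcp(substrate("s", "RTKAWNRQLYPEW"))), 78L)
  expect_warning(out <- enumerate_pcp(substrate("s", "ACD"),
                                      enum_params(l_ext = 4)), "l_ext")
  expect_equal(nrow(out), 0L)
})

test_that("classify_splice matches the set-based oracle definition", {
  expect_equal(classify_splice(15, 18, 1, 5), "cis_reverse")
  expect_equal(classify_splice(3, 4, 15, 23), "cis_normal")
  expect_equal(classify_splice(1, 5, 1, 5), "trans")
  expect_equal(classify_splice(1, 2, 3, 4), "trans")    # native adjacent
  expect_equal(classify_splice(3, 4, 1, 2), "cis_reverse")  # reverse adjacent
  expect_equal(classify_splice(1, 5, 1, 5, same_substrate = FALSE), "trans")
  expect_error(classify_splice(5, 3, 1, 2), "invalid")
})

test_that("single-substrate enumeration partitions all ordered pairs", {
  s <- substrate("s", "ACDE")
  psp <- enumerate_psp(s)
  cls <- table(psp$class)
  expect_equal(unname(cls[["cis_reverse"]]), 1L)
  expect_false("cis_normal" %in% names(cls))
  rev_row <- psp[psp$class == "cis_reverse", ]
  expect_equal(unlist(rev_row[, c("i", "j", "k", "n")], use.names = FALSE),
               c(3L, 4L, 1L, 2L))
  expect_equal(rev_row$sequence, "DEAC")
  # excluded native-adjacent pairs come back with the flag
  with_adj <- enumerate_psp(s, enum_params(include_native_adjacent = TRUE))
  expect_equal(nrow(with_adj) - nrow(psp), 1L)  # (1,2)+(3,4) for a 4-mer
})

test_that("count_products matches brute-force enumeration over a grid", {
  for (L in c(4, 7, 10, 13, 16)) for (le in 1:3) {
    o <- oracle_counts(L, le)
    cp <- count_products(L, le)
    expect_equal(cp$n_pcp, unname(o[["n_pcp"]]))
    expect_equal(cp$n_cis_normal, unname(o[["cis_normal"]]))
    expect_equal(cp$n_cis_reverse, unname(o[["cis_reverse"]]))
    expect_equal(cp$n_trans, unname(o[["trans"]]))
    expect_equal(cp$n_native_adjacent, unname(o[["adjacent"]]))
    expect_equal(cp$n_all_pairs, cp$n_pcp^2)
  }
  expect_equal(count_products(2, 2)$n_pcp, 1)
  expect_equal(count_products(2, 2)$n_cis_normal, 0)
  expect_equal(count_products(1, 2)$n_pcp, 0)
})

test_that("13-mer enumeration reproduces the frozen oracle counts", {
  s <- substrate("s", "RTKAWNRQLYPEW")
  psp <- enumerate_psp(s)
  cls <- table(psp$class)
  expect_equal(unname(cls[["cis_normal"]]), 495L)
  expect_equal(unname(cls[["cis_reverse"]]), 715L)
  expect_equal(nrow(psp), count_products(13, 2)$n_psp)
})

test_that("class partition + symmetry properties hold across the grid", {
  for (L in c(5, 9, 14)) for (le in 1:3) {
    s <- substrate("s", random_peptide(L))
    psp <- enumerate_psp(s, enum_params(l_ext = le))
    cp <- count_products(L, le)
    expect_equal(nrow(psp) + cp$n_native_adjacent, cp$n_all_pairs)
    # reversing a cis_normal pair yields cis_reverse; the extras are the
    # reverse-adjacent pairs, so n_cis_reverse >= n_cis_normal
    expect_gte(cp$n_cis_reverse, cp$n_cis_normal)
    cn <- psp[psp$class == "cis_normal", ]
    if (nrow(cn)) {
      flipped <- classify_splice(cn$k, cn$n, cn$i, cn$j)
      expect_true(all(flipped == "cis_reverse"))
    }
  }
})

test_that("two-substrate enumeration emits only trans cross pairs", {
  a <- substrate("light", "RTKAW")
  b <- substrate("heavy", "RTKAW")
  psp <- enumerate_psp(list(a, b))
  expect_true(all(psp$class == "trans"))
  expect_true(all(psp$sub_first != psp$sub_second))
  np <- nrow(enumerate_pcp(a))
  expect_equal(nrow(psp), 2 * np^2)
  expect_error(enumerate_psp(list(a, a)), "distinct")
})

test_that("enumeration is deterministic and lexicographically ordered", {
  s <- substrate("s", "AWNRQLYP")
  p1 <- enumerate_psp(s)
  p2 <- enumerate_psp(s)
  expect_identical(p1, p2)
  key <- order(p1$i, p1$j, p1$k, p1$n)
  expect_equal(key, seq_len(nrow(p1)))
})

test_that("splice_sequence concatenates fragments with length arithmetic", {
  g <- demo_substrates()[["gp100_35-57"]]
  expect_equal(splice_sequence(g, 15, 18, 1, 5), "YPEWVSRQL")
  expect_equal(splice_sequence(g, 1, 5, 1, 5), "VSRQLVSRQL")
  expect_equal(nchar(splice_sequence(g, 2, 3, 7, 8)), 4L)
  expect_equal(splice_sequence(g, 1, 5), "VSRQL")
  expect_error(splice_sequence(g, 1, 99), "outside")
})

test_that("substrates read from FASTA and plain text", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">sub1 demo", "RTKAWNRQLYPEW", ">sub2", "ACDEFG"), fa)
  subs <- read_substrates(fa)
  expect_equal(length(subs), 2L)
  expect_equal(subs[[1]]$sequence, "RTKAWNRQLYPEW")
  expect_equal(subs[[2]]$id, "sub2")
  txt <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "mysub\tRTKAW", "ACDE"), txt)
  subs2 <- read_substrates(txt)
  expect_equal(subs2[["mysub"]]$sequence, "RTKAW")
  expect_equal(subs2[[2]]$sequence, "ACDE")
  expect_error(substrate("x", "A"), "length")
  expect_error(substrate("x", "ACB1"), "unknown residue")
})
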