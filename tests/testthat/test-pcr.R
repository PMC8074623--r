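# In-silico PCR engine: constructed hits, mismatch thresholds, degenerate
# matching and agreement with the brute-force full-scan oracle.

test_that("a constructed record yields exactly one hit with the right insert", {
  pair <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV)
  insert <- strrep("A", 100)
  db <- tiny_db(tibble::tibble(
    record_id = "rec1",
    sequence = amplicon_record(insert),
    taxid = 30L
  ))
  tab <- amplify(db, pair, 50, 200)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$insert, insert)
  expect_equal(tab$insert_length_bp, 100L)
  expect_equal(tab$full_length_bp, 140L)
  expect_equal(tab$strand, "+")
  expect_equal(tab$fwd_start, 1L)
})

test_that("mismatch budget gates amplification at the threshold", {
  fwd_mut <- paste0("A", substr(CEPH18S_FWD, 2, 20))  # C->A at position 1
  db <- tiny_db(tibble::tibble(
    record_id = "rec1",
    sequence = amplicon_record(strrep("G", 100), fwd = fwd_mut),
    taxid = 30L
  ))
  pair0 <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV, max_mismatches = 0)
  pair1 <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV, max_mismatches = 1)
  expect_equal(nrow(amplify(db, pair0, 50, 200)), 0)
  tab1 <- amplify(db, pair1, 50, 200)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$fwd_mismatches, 1L)
  expect_equal(tab1$rev_mismatches, 0L)
})

test_that("the 3'-strict region vetoes mismatches near the primer 3' end", {
  # mutate the last base of the forward site
  fwd_mut <- paste0(substr(CEPH18S_FWD, 1, 19), "T")
  db <- tiny_db(tibble::tibble(
    record_id = "rec1",
    sequence = amplicon_record(strrep("G", 100), fwd = fwd_mut),
    taxid = 30L
  ))
  tolerant <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV, max_mismatches = 2)
  strict <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV, max_mismatches = 2,
                        three_prime_strict = 2)
  expect_equal(nrow(amplify(db, tolerant, 50, 200)), 1)
  expect_equal(nrow(amplify(db, strict, 50, 200)), 0)

  # the reverse primer's 3' end faces the insert: mutate the first base of
  # the embedded reverse-complement site
  rc <- revcomp(CEPH18S_REV)
  rc_mut <- paste0(ifelse(substr(rc, 1, 1) == "A", "C", "A"), substr(rc, 2, 20))
  db2 <- tiny_db(tibble::tibble(
    record_id = "rec2",
    sequence = paste0(CEPH18S_FWD, strrep("G", 100), rc_mut),
    taxid = 30L
  ))
  expect_equal(nrow(amplify(db2, tolerant, 50, 200)), 1)
  expect_equal(nrow(amplify(db2, strict, 50, 200)), 0)
})

test_that("hits are found on the minus strand and length bounds enforced", {
  insert <- random_dna(100)
  rec <- amplicon_record(insert, pad5 = random_dna(30), pad3 = random_dna(30))
  db <- tiny_db(tibble::tibble(
    record_id = c("fwd_rec", "rev_rec"),
    sequence = c(rec, revcomp(rec)),
    taxid = c(30L, 31L)
  ))
  pair <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV)
  tab <- amplify(db, pair, 50, 200)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$strand, c("+", "-"))
  expect_equal(unique(tab$insert), insert)
  expect_equal(nrow(amplify(db, pair, 101, 200)), 0)
  expect_equal(nrow(amplify(db, pair, 50, 99)), 0)
  expect_error(amplify(db, pair, 200, 50), "inverted")
})

test_that("degenerate primer bases match their IUPAC set; target N only matches primer N", {
  # primer with W at position 5 must amplify both A and T variants
  fwd_w <- paste0(substr(CEPH18S_FWD, 1, 4), "W", substr(CEPH18S_FWD, 6, 20))
  var_a <- paste0(substr(CEPH18S_FWD, 1, 4), "A", substr(CEPH18S_FWD, 6, 20))
  var_t <- paste0(substr(CEPH18S_FWD, 1, 4), "T", substr(CEPH18S_FWD, 6, 20))
  db <- tiny_db(tibble::tibble(
    record_id = c("ra", "rt"),
    sequence = c(amplicon_record(strrep("C", 80), fwd = var_a),
                 amplicon_record(strrep("C", 80), fwd = var_t)),
    taxid = c(30L, 31L)
  ))
  pair_w <- primer_pair("w", fwd_w, CEPH18S_REV, max_mismatches = 0)
  expect_equal(nrow(amplify(db, pair_w, 50, 200)), 2)

  # a target N under a non-N primer base is a mismatch ...
  rec_n <- amplicon_record(strrep("C", 80))
  substr(rec_n, 3, 3) <- "N"
  dbn <- tiny_db(tibble::tibble(record_id = "rn", sequence = rec_n, taxid = 30L))
  pair0 <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV, max_mismatches = 0)
  expect_equal(nrow(amplify(dbn, pair0, 50, 200)), 0)
  expect_equal(nrow(amplify(dbn, primer_pair("p", CEPH18S_FWD, CEPH18S_REV,
                                             max_mismatches = 1), 50, 200)), 1)
  # ... but a primer N accepts it
  fwd_n <- paste0(substr(CEPH18S_FWD, 1, 2), "N", substr(CEPH18S_FWD, 4, 20))
  expect_equal(nrow(amplify(dbn, primer_pair("n", fwd_n, CEPH18S_REV,
                                             max_mismatches = 0), 50, 200)), 1)
})

test_that("amplify agrees with the brute-force oracle on random databases", {
  set.seed(3)
  pair <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV, max_mismatches = 1)
  recs <- purrr::map_dfr(1:40, function(i) {
    seq <- if (i %% 2 == 0) {
      amplicon_record(random_dna(sample(60:180, 1)),
                      pad5 = random_dna(sample(0:40, 1)),
                      pad3 = random_dna(sample(0:40, 1)))
    } else {
      random_dna(sample(100:300, 1))
    }
    tibble::tibble(record_id = sprintf("r%03d", i), sequence = seq,
                   taxid = sample(c(30L, 31L, 32L, 33L), 1))
  })
  db <- tiny_db(recs)
  got <- sort_hits(amplify(db, pair, 50, 200))
  want <- sort_hits(oracle_amplify(db, pair, 50, 200))
  expect_equal(got, want)
  expect_gt(nrow(got), 0)
})

test_that("duplicating records does not change taxon-level results", {
  sim <- simulate_reference(sim_config(seed = 5))
  pair <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV)
  rep1 <- evaluate(sim$db, amplify(sim$db, pair, 50, 200))
  dup <- sim$db$records
  dup2 <- dup
  dup2$record_id <- paste0(dup2$record_id, "_dup")
  db2 <- new_ref_db(dplyr::bind_rows(dup, dup2), sim$db$taxonomy)
  rep2 <- evaluate(db2, amplify(db2, pair, 50, 200))
  expect_equal(rep1$bc, rep2$bc)
  expect_equal(rep1$bs, rep2$bs)
  expect_equal(rep1$amplified_taxa, rep2$amplified_taxa)
})

test_that("summarize_amplicons counts records and distinct inserts per taxon", {
  db <- tiny_db()
  pair <- primer_pair("p", CEPH18S_FWD, CEPH18S_REV)
  tab <- amplify(db, pair, 50, 200)
  s <- summarize_amplicons(db, tab)
  expect_equal(nrow(s), 4)
  expect_true(all(s$n_records == 1))
  expect_true(all(s$n_amplified_records == 1))
  expect_true(all(s$n_distinct_inserts == 1))
})

test_that("write_amplicons emits TSV and insert FASTA", {
  dir <- withr::local_tempdir()
  db <- tiny_db()
  tab <- amplify(db, primer_pair("p", CEPH18S_FWD, CEPH18S_REV), 50, 200)
  write_amplicons(tab, tsv_path = file.path(dir, "hits.tsv"),
                  fasta_path = file.path(dir, "ins.fasta"))
  hits <- utils::read.delim(file.path(dir, "hits.tsv"))
  expect_equal(nrow(hits), nrow(tab))
  ins <- Biostrings::readBStringSet(file.path(dir, "ins.fasta"))
  expect_equal(length(ins), nrow(tab))
  expect_setequal(as.character(ins), tab$insert)
})
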