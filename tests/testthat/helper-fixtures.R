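# In-code fixtures: a small 3-level taxonomy and reference databases built
# directly as tibbles, plus writers for the file-based loaders.

CEPH18S_FWD <- "CGCGGCGCTACATATTAGAC"
CEPH18S_REV <- "GCACTTAACCGACCGTCGAC"

tiny_taxonomy <- function() {
  tibble::tribble(
    ~taxid, ~parent_taxid, ~rank,      ~name,
    1L,     1L,            "no_rank",  "root",
    10L,    1L,            "family",   "FamA",
    11L,    1L,            "family",   "FamB",
    20L,    10L,           "genus",    "GenA1",
    21L,    10L,           "genus",    "GenA2",
    22L,    11L,           "genus",    "GenB1",
    30L,    20L,           "species",  "GenA1 sp1",
    31L,    20L,           "species",  "GenA1 sp2",
    32L,    21L,           "species",  "GenA2 sp1",
    33L,    22L,           "species",  "GenB1 sp1"
  )
}

# A record amplifiable by the given pair: pad + fwd site + insert + rc(rev) + pad
amplicon_record <- function(insert, fwd = CEPH18S_FWD, rev = CEPH18S_REV,
                            pad5 = "", pad3 = "") {
  paste0(pad5, fwd, insert, revcomp(rev), pad3)
}

tiny_db <- function(records = NULL) {
  if (is.null(records)) {
    records <- tibble::tibble(
      record_id = c("r30", "r31", "r32", "r33"),
      sequence = c(
        amplicon_record(strrep("ACGTT", 20)),
        amplicon_record(strrep("TTGCA", 20)),
        amplicon_record(strrep("GATTA", 20)),
        amplicon_record(strrep("CCGAT", 20))
      ),
      taxid = c(30L, 31L, 32L, 33L)
    )
  }
  new_ref_db(records, tiny_taxonomy())
}

write_db_files <- function(db, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "db.fasta")
  tax <- file.path(dir, "tax.tsv")
  writeLines(
    unlist(purrr::map2(db$records$record_id,
                       paste0(db$records$sequence),
                       ~ c(sprintf(">%s taxid=%d;", .x,
                                   db$records$taxid[db$records$record_id == .x]),
                           .y))),
    fasta
  )
  utils::write.table(db$taxonomy, tax, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, tax = tax, dir = dir)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
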