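# Primer physico-chemistry: melting temperature, sequence properties and the
# pair-level filter rules.

test_that("melting temperature is duplex-symmetric and salt-monotone", {
  set.seed(42)
  for (i in 1:20) {
    s <- random_dna(sample(12:30, 1))
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)),
                 tolerance = 1e-12)
  }
  s <- "CGCGGCGCTACATATTAGAC"
  nas <- c(0.005, 0.02, 0.05, 0.2, 1)
  tms <- vapply(nas, function(na) melting_temperature(s, na_molar = na),
                numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("melting temperature rejects degenerate and too-short input", {
  expect_error(melting_temperature("ACGTACGW"), "non-degenerate")
  expect_error(melting_temperature("ACGTACG"), "too short")
  expect_error(melting_temperature("ACGTACGTACGT", na_molar = 0), "na_molar")
})

test_that("primer properties match an exhaustive sliding-window oracle", {
  # independent oracle: scan every substring for homopolymers and tandem
  # 2-mer repeats
  oracle_homo <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    best <- 1L
    for (i in seq_along(chars)) {
      j <- i
      while (j < length(chars) && chars[j + 1] == chars[i]) j <- j + 1
      best <- max(best, j - i + 1L)
    }
    best
  }
  oracle_dinuc <- function(s) {
    n <- nchar(s)
    best <- if (n >= 2) 1L else 0L
    for (start in seq_len(max(0, n - 1))) {
      unit <- substr(s, start, start + 1)
      k <- 1L
      while (start + 2 * k + 1 <= n &&
             substr(s, start + 2 * k, start + 2 * k + 1) == unit) {
        k <- k + 1L
      }
      best <- max(best, k)
    }
    best
  }
  set.seed(7)
  for (i in 1:300) {
    s <- random_dna(sample(8:40, 1))
    p <- primer_properties(s)
    expect_equal(p$max_homopolymer, oracle_homo(s))
    expect_equal(p$max_dinucleotide_repeat, oracle_dinuc(s))
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    expect_equal(p$gc_fraction, gc)
    expect_equal(p$gc_fraction + (1 - gc), 1)
  }
})

test_that("primer properties handle the documented edge cases", {
  p <- primer_properties("CGCGGCGCTACATATTAGAC")
  expect_equal(p$gc_fraction, 0.55)
  expect_equal(p$max_homopolymer, 2)
  expect_equal(p$max_dinucleotide_repeat, 2)

  expect_equal(primer_properties("AAAA")$max_homopolymer, 4)
  expect_equal(primer_properties("AAAA")$gc_fraction, 0)
  expect_equal(primer_properties("ATATATAT")$max_dinucleotide_repeat, 4)
  expect_equal(primer_properties("ATATAT")$max_dinucleotide_repeat, 3)

  # degenerate primers: no Tm, expected GC content
  pd <- primer_properties("TGCGGTATTWTAACTGTACT")
  expect_true(is.na(pd$tm_celsius))
  expect_equal(pd$gc_fraction, 7 / 20, tolerance = 1e-12)
  expect_error(primer_properties("ACGTX"), "illegal")
})

test_that("self-complementarity equals a brute-force alignment oracle", {
  oracle_selfcomp <- function(a, b) {
    ar <- strsplit(a, "")[[1]]
    br <- strsplit(oracle_revcomp(b), "")[[1]]
    best <- 0L
    for (off in (-(length(br) - 1)):(length(ar) - 1)) {
      run <- 0L
      for (i in seq_along(ar)) {
        j <- i - off
        if (j >= 1 && j <= length(br) &&
            .oracle_matrix[ar[i], br[j]]) {
          run <- run + 1L
          best <- max(best, run)
        } else {
          run <- 0L
        }
      }
    }
    best
  }
  expect_equal(self_complementarity("ACGT", "ACGT"), 4)
  expect_equal(self_complementarity("AAAA", "CCCC"), 0)
  f <- "CGCGGCGCTACATATTAGAC"; r <- "GCACTTAACCGACCGTCGAC"
  expect_equal(self_complementarity(f, r), oracle_selfcomp(f, r))
  set.seed(11)
  for (i in 1:50) {
    a <- random_dna(sample(6:25, 1)); b <- random_dna(sample(6:25, 1))
    expect_equal(self_complementarity(a, b), oracle_selfcomp(a, b))
    expect_equal(self_complementarity(a, b), self_complementarity(b, a))
  }
})

test_that("filter_pair applies the strict rule set to the flagship pair", {
  fp <- primer_properties("CGCGGCGCTACATATTAGAC")
  rp <- primer_properties("GCACTTAACCGACCGTCGAC")
  res <- filter_pair(fp, rp, criteria_preset("genbank_strict"))
  expect_true(res$pass)
  expect_equal(res$violations, "")
  expect_lt(abs(fp$tm_celsius - rp$tm_celsius), 3)
  expect_true(all(c(fp$gc_fraction, rp$gc_fraction) >= 0.50))
  expect_true(all(c(fp$gc_fraction, rp$gc_fraction) <= 0.60))

  # a 4-degree Tm gap violates the delta-Tm rule
  fp2 <- fp; fp2$tm_celsius <- 59.0
  rp2 <- rp; rp2$tm_celsius <- 63.0
  res2 <- filter_pair(fp2, rp2, criteria_preset("genbank_strict"))
  expect_false(res2$pass)
  expect_match(res2$violations, "max_tm_diff")

  # vacuous criteria pass anything
  loose <- filter_criteria(tm_min = -Inf, tm_max = Inf, max_tm_diff = Inf,
                           gc_min = 0, gc_max = 1, max_gc_clamp = Inf,
                           max_homopolymer = Inf, max_dinucleotide_repeat = Inf)
  expect_true(filter_pair(fp2, rp2, loose)$pass)
})

test_that("relaxing every criterion never turns a pass into a fail", {
  set.seed(19)
  relax <- function(cr) {
    filter_criteria(
      tm_min = cr$tm_min - stats::runif(1, 0, 10),
      tm_max = cr$tm_max + stats::runif(1, 0, 10),
      max_tm_diff = cr$max_tm_diff + stats::runif(1, 0, 5),
      gc_min = max(0, cr$gc_min - stats::runif(1, 0, 0.3)),
      gc_max = min(1, cr$gc_max + stats::runif(1, 0, 0.3)),
      max_gc_clamp = cr$max_gc_clamp + sample(0:2, 1),
      max_homopolymer = cr$max_homopolymer + sample(0:2, 1),
      max_dinucleotide_repeat = cr$max_dinucleotide_repeat + sample(0:2, 1)
    )
  }
  for (i in 1:40) {
    fwd <- random_dna(20); rev <- random_dna(20)
    fp <- primer_properties(fwd); rp <- primer_properties(rev)
    strict <- criteria_preset("genbank_strict")
    if (filter_pair(fp, rp, strict)$pass) {
      expect_true(filter_pair(fp, rp, relax(strict))$pass)
    }
    # relaxed database preset is a relaxation of the strict one for Tm/GC
    if (filter_pair(fp, rp, strict)$pass) {
      expect_true(filter_pair(fp, rp, criteria_preset("silva_relaxed"))$pass)
    }
  }
})

test_that("filter_primer_pairs screens a table and reports per-primer columns", {
  pairs <- tibble::tibble(
    name = c("Ceph18S", "polyA"),
    forward = c("CGCGGCGCTACATATTAGAC", "AAAAAAAAAAGCGCGCGCGC"),
    reverse = c("GCACTTAACCGACCGTCGAC", "GCGCGCGCGCAAAAAAAAAA")
  )
  res <- filter_primer_pairs(pairs)
  expect_equal(nrow(res), 2)
  expect_true(res$pass[1])
  expect_false(res$pass[2])
  expect_match(res$violations[2], "homopolymer")
  expect_true(all(c("fwd_tm_celsius", "rev_tm_celsius") %in% names(res)))
})
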