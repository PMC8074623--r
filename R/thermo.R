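# Physico-chemical primer screening: nearest-neighbour melting temperature,
# GC content/clamp, repeat structure, self-complementarity, and the two
# filter-criteria regimes applied to primer pairs.

# SantaLucia (1998) unified nearest-neighbour stacking parameters.
# dH in kcal/mol, dS in cal/(K mol), 1 M NaCl reference state.
.NN_DH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
  TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
  TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9
)
.R_GAS <- 1.987  # cal/(K mol)

#' Nearest-neighbour melting temperature
#'
#' Computes the duplex melting temperature of a non-degenerate primer with
#' the SantaLucia (1998) unified stacking parameters:
#' `Tm = 1000 * dH / (dS + R * ln(C_T / 4)) - 273.15 + 16.6 * log10([Na+])`.
#'
#' The default convention (initiation terms omitted, total oligonucleotide
#' concentration 15 uM) follows the widely used web oligonucleotide
#' properties calculator, so that published primer Tm values computed there
#' are reproduced; set `include_initiation = TRUE` for the full SantaLucia
#' parameterization.
#'
#' @param sequence Non-degenerate A/C/G/T string, length >= 8.
#' @param na_molar Monovalent salt concentration in mol/L (default 0.05).
#' @param strand_conc_molar Total strand concentration C_T in mol/L
#'   (default 1.5e-5).
#' @param include_initiation Include the SantaLucia duplex-initiation
#'   enthalpy/entropy terms (default `FALSE`, the web-calculator convention).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(sequence, na_molar = 0.05,
                                strand_conc_molar = 1.5e-5,
                                include_initiation = FALSE) {
  s <- normalize_sequence(sequence)
  .check_iupac(s, "primer")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    stop("melting_temperature requires a non-degenerate A/C/G/T sequence",
         call. = FALSE)
  }
  if (nchar(s) < 8) stop("sequence too short for nearest-neighbour Tm (need >= 8 nt)",
                         call. = FALSE)
  if (na_molar <= 0 || na_molar > 1) stop("na_molar must be in (0, 1]", call. = FALSE)
  dimers <- paste0(chars[-length(chars)], chars[-1])
  dh <- sum(.NN_DH[dimers])
  ds <- sum(.NN_DS[dimers])
  if (include_initiation) {
    for (terminal in c(chars[1], chars[length(chars)])) {
      if (terminal %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
  }
  1000 * dh / (ds + .R_GAS * log(strand_conc_molar / 4)) - 273.15 +
    16.6 * log10(na_molar)
}

.max_homopolymer <- function(chars) {
  if (length(chars) == 0) return(0L)
  max(rle(chars)$lengths)
}

# Longest tandem repeat count of any 2-mer, over both phases
# (ATATAT -> 3, ATATATAT -> 4).
.max_dinucleotide_repeat <- function(chars) {
  n <- length(chars)
  if (n < 2) return(0L)
  best <- 1L
  for (phase in 0:1) {
    starts <- seq.int(1 + phase, n - 1, by = 2)
    if (length(starts) == 0) next
    pairs <- paste0(chars[starts], chars[starts + 1])
    best <- max(best, max(rle(pairs)$lengths))
  }
  as.integer(best)
}

#' Physico-chemical properties of one primer
#'
#' Computes the properties screened during primer filtering: melting
#' temperature (NA for degenerate primers), GC fraction (expected content
#' for degenerate positions), GC clamp (count of G/C among the five most-3'
#' bases), longest homopolymer, longest tandem dinucleotide repeat, and the
#' self-complementarity score (longest perfectly complementary antiparallel
#' run against itself).
#'
#' @param sequence IUPAC primer string, 5' to 3'.
#' @param ... Passed to [melting_temperature()].
#' @return One-row tibble of properties.
#' @export
primer_properties <- function(sequence, ...) {
  s <- normalize_sequence(sequence)
  if (nchar(s) == 0) stop("empty primer sequence", call. = FALSE)
  .check_iupac(s, "primer")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  degenerate <- any(!chars %in% c("A", "C", "G", "T"))
  tm <- if (degenerate || length(chars) < 8) NA_real_ else melting_temperature(s, ...)
  clamp_window <- chars[max(1, length(chars) - 4):length(chars)]
  tibble::tibble(
    sequence = s,
    length_bp = length(chars),
    tm_celsius = tm,
    gc_fraction = mean(.IUPAC_GC[chars]),
    gc_clamp_count = sum(clamp_window %in% c("G", "C", "S")),
    max_homopolymer = .max_homopolymer(chars),
    max_dinucleotide_repeat = .max_dinucleotide_repeat(chars),
    self_comp_score = self_complementarity(s, s)
  )
}

#' Longest perfectly complementary antiparallel run
#'
#' Slides the two sequences against each other in antiparallel orientation
#' (as in a primer-dimer) and returns the length of the longest run of
#' consecutive complementary base pairs over all offsets. Calling it with
#' the same sequence twice scores self-dimers/hairpin stems. Degenerate
#' positions pair when their IUPAC sets can form at least one Watson-Crick
#' pair.
#'
#' @param sequence_a,sequence_b IUPAC nucleotide strings, 5' to 3'.
#' @return Integer run length (0 when no pairing is possible).
#' @export
self_complementarity <- function(sequence_a, sequence_b) {
  a <- normalize_sequence(sequence_a)
  b <- normalize_sequence(sequence_b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence", call. = FALSE)
  ea <- .encode(a, "primer")
  # antiparallel pairing of a against b == positional identity of a and
  # revcomp(b) under IUPAC set intersection
  eb <- .encode(revcomp(b), "primer")
  na <- length(ea); nb <- length(eb)
  best <- 0L
  for (off in (-(nb - 1)):(na - 1)) {
    ia <- max(1, 1 + off):min(na, nb + off)
    ib <- ia - off
    hit <- bitwAnd(ea[ia], eb[ib]) > 0
    if (any(hit)) {
      r <- rle(hit)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  as.integer(best)
}

#' Filter criteria for primer pairs
#'
#' Container for the rule set applied by [filter_pair()]. The two shipped
#' regimes are available through [criteria_preset()]: `genbank_strict`
#' (lowest Tm 59-69 C, delta-Tm < 3 C, GC 50-60%, GC clamp <= 3,
#' homopolymer < 4, dinucleotide repeat < 4) and `silva_relaxed`
#' (lowest Tm 45-70 C, GC 45-65%, structural rules disabled).
#'
#' @param tm_min,tm_max Bounds (C) tested against the lower of the two
#'   primer Tm values.
#' @param max_tm_diff Maximum allowed |Tm_f - Tm_r| (strict inequality).
#' @param gc_min,gc_max GC-fraction bounds applied to each primer.
#' @param max_gc_clamp Maximum G/C count among the five most-3' bases.
#' @param max_homopolymer Maximum homopolymer run length.
#' @param max_dinucleotide_repeat Maximum tandem 2-mer repeat count.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(tm_min = 59, tm_max = 69, max_tm_diff = 3,
                            gc_min = 0.50, gc_max = 0.60, max_gc_clamp = 3,
                            max_homopolymer = 3, max_dinucleotide_repeat = 3) {
  stopifnot(tm_min <= tm_max, gc_min <= gc_max)
  structure(list(
    tm_min = tm_min, tm_max = tm_max, max_tm_diff = max_tm_diff,
    gc_min = gc_min, gc_max = gc_max, max_gc_clamp = max_gc_clamp,
    max_homopolymer = max_homopolymer,
    max_dinucleotide_repeat = max_dinucleotide_repeat
  ), class = "filter_criteria")
}

#' @rdname filter_criteria
#' @param name Preset name: `"genbank_strict"` or `"silva_relaxed"`.
#' @export
criteria_preset <- function(name = c("genbank_strict", "silva_relaxed")) {
  name <- match.arg(name)
  switch(name,
    genbank_strict = filter_criteria(),
    silva_relaxed = filter_criteria(
      tm_min = 45, tm_max = 70, max_tm_diff = Inf,
      gc_min = 0.45, gc_max = 0.65, max_gc_clamp = Inf,
      max_homopolymer = Inf, max_dinucleotide_repeat = Inf
    )
  )
}

#' Apply filter criteria to a primer pair
#'
#' The "lowest melting temperature" (the smaller of the two primer Tm
#' values) must fall in `[tm_min, tm_max]`; the Tm difference must be
#' strictly below `max_tm_diff`; each primer's GC fraction must lie in
#' `[gc_min, gc_max]`; clamp and repeat rules apply per primer.
#'
#' @param forward_props,reverse_props One-row property tibbles from
#'   [primer_properties()] computed under identical thermodynamic settings.
#' @param criteria A [filter_criteria()] object.
#' @return One-row tibble with `pass` (logical) and `violations`
#'   (comma-separated rule names, empty when passing).
#' @export
filter_pair <- function(forward_props, reverse_props,
                        criteria = criteria_preset("genbank_strict")) {
  v <- character(0)
  tms <- c(forward_props$tm_celsius, reverse_props$tm_celsius)
  if (!anyNA(tms)) {
    lo <- min(tms)
    if (lo < criteria$tm_min || lo > criteria$tm_max) v <- c(v, "tm_range")
    if (abs(tms[1] - tms[2]) >= criteria$max_tm_diff) v <- c(v, "max_tm_diff")
  }
  for (p in list(forward_props, reverse_props)) {
    if (p$gc_fraction < criteria$gc_min || p$gc_fraction > criteria$gc_max) {
      v <- c(v, "gc_range")
    }
    if (p$gc_clamp_count > criteria$max_gc_clamp) v <- c(v, "gc_clamp")
    if (p$max_homopolymer > criteria$max_homopolymer) v <- c(v, "homopolymer")
    if (p$max_dinucleotide_repeat > criteria$max_dinucleotide_repeat) {
      v <- c(v, "dinucleotide_repeat")
    }
  }
  v <- unique(v)
  tibble::tibble(pass = length(v) == 0, violations = paste(v, collapse = ","))
}

#' Screen a table of primer pairs
#'
#' Data-frame-first wrapper: computes properties for both primers of each
#' pair and applies the criteria.
#'
#' @param pairs Data frame with columns `name`, `forward`, `reverse`.
#' @param criteria A [filter_criteria()] object.
#' @param ... Passed to [primer_properties()] (thermodynamic settings).
#' @return Tibble with per-primer properties (prefixed `fwd_` / `rev_`),
#'   `pass` and `violations`.
#' @export
filter_primer_pairs <- function(pairs, criteria = criteria_preset("genbank_strict"),
                                ...) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("name", "forward", "reverse") %in% names(pairs)))
  purrr::pmap_dfr(pairs[, c("name", "forward", "reverse")],
    function(name, forward, reverse) {
      fp <- primer_properties(forward, ...)
      rp <- primer_properties(reverse, ...)
      res <- filter_pair(fp, rp, criteria)
      dplyr::bind_cols(
        tibble::tibble(name = name),
        dplyr::rename_with(fp, ~ paste0("fwd_", .x)),
        dplyr::rename_with(rp, ~ paste0("rev_", .x)),
        res
      )
    })
}
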