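# cache of the per-codon nonsynonymous fraction (standard genetic code)
.neutral_cache <- new.env(parent = emptyenv())

codon_nonsyn_fraction <- function(codon) {
  hit <- .neutral_cache[[codon]]
  if (!is.null(hit)) return(hit)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  aa0 <- code[[codon]]
  nt <- strsplit(codon, "", fixed = TRUE)[[1]]
  allowed <- 0L
  nonsyn <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(bases, nt[pos])) {
      mut <- nt
      mut[pos] <- alt
      aa1 <- code[[paste(mut, collapse = "")]]
      if (aa1 == "*") next  # changes creating stop codons are excluded
      allowed <- allowed + 1L
      if (aa1 != aa0) nonsyn <- nonsyn + 1L
    }
  }
  out <- nonsyn / allowed
  .neutral_cache[[codon]] <- out
  out
}

split_codons <- function(codon_seq, drop_terminal_stop = TRUE) {
  s <- toupper(codon_seq)
  if (nchar(s) %% 3L != 0L) stop("sequence length not divisible by 3")
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGT characters")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  stops <- c("TAA", "TAG", "TGA")
  if (drop_terminal_stop && length(codons) > 0 && codons[length(codons)] %in% stops) {
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% stops)) {
    stop("internal stop codon at codon position ", which(codons %in% stops)[1])
  }
  codons
}

#' Expected nonsynonymous fraction under neutral evolution
#'
#' For each codon of a coding sequence, all nine single-nucleotide changes
#' are enumerated under the standard genetic code; changes creating a stop
#' codon are excluded and the fraction of the remaining changes that alter
#' the encoded amino acid is recorded. The per-codon fractions are averaged
#' over the sequence. This is the expected amino-acid-change fraction per
#' nucleotide change for a sequence evolving without selection (a uniform
#' mutation model, no transition/transversion bias).
#'
#' @param codon_seq Coding sequence (string, length divisible by 3, no
#'   internal stop codons; a terminal stop codon is dropped).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' neutral_expected_fraction("ATG") # 1: every change to Met is nonsynonymous
#' neutral_expected_fraction("GGG") # 2/3: three synonymous third positions
#' @export
neutral_expected_fraction <- function(codon_seq) {
  codons <- split_codons(codon_seq)
  if (length(codons) == 0L) stop("no codons left after dropping terminal stop")
  mean(vapply(codons, codon_nonsyn_fraction, numeric(1)))
}

#' Neutral expectation for the protein-per-nucleotide evolution ratio
#'
#' Under neutral evolution a fraction `f_N` of nucleotide substitutions
#' changes the protein, and protein branch lengths are expressed per
#' amino-acid site (one third the number of nucleotide sites), so the
#' expected protein-per-nucleotide length ratio is `3 * f_N` (as a
#' percentage, `300 * f_N`); the nucleotide-per-protein direction is its
#' reciprocal. Observed ratios below (above, for the reciprocal direction)
#' this line indicate purifying selection.
#'
#' @inheritParams neutral_expected_fraction
#' @inheritParams protein_per_nucleotide_ratio
#' @return Percentage (numeric scalar).
#' @export
neutral_expected_ratio <- function(codon_seq,
                                   direction = c("protein_per_nucleotide",
                                                 "nucleotide_per_protein")) {
  direction <- match.arg(direction)
  f <- neutral_expected_fraction(codon_seq)
  out <- if (direction == "protein_per_nucleotide") 300 * f else 100 / (3 * f)
  attr(out, "direction") <- direction
  out
}

#' Simulate neutral single-nucleotide substitutions on a coding sequence
#'
#' Applies `n_subs` substitutions sequentially: each draws a uniform site and
#' a uniform alternative base, and is rejected (and redrawn) if it would
#' create a stop codon. Realized nucleotide- and amino-acid-change counts are
#' reported; this is the simulation oracle for
#' [neutral_expected_fraction()].
#'
#' @inheritParams neutral_expected_fraction
#' @param n_subs Number of accepted substitutions to apply.
#' @param seed Integer seed (required).
#' @return List with `seq` (mutated sequence), `n_nt_changes` and
#'   `n_aa_changes`.
#' @export
simulate_neutral_codon_substitutions <- function(codon_seq, n_subs, seed) {
  if (missing(seed)) stop("a seed is required")
  codons <- split_codons(codon_seq)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  nt <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]
  L <- length(nt)
  set.seed(seed)
  n_aa <- 0L
  accepted <- 0L
  while (accepted < n_subs) {
    pos <- sample.int(L, 1L)
    alt <- sample(setdiff(bases, nt[pos]), 1L)
    ci <- (pos - 1L) %/% 3L + 1L
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    old_codon <- paste(nt[idx], collapse = "")
    new <- nt[idx]
    new[pos - 3L * (ci - 1L)] <- alt
    new_codon <- paste(new, collapse = "")
    if (new_codon %in% stops) next
    nt[pos] <- alt
    accepted <- accepted + 1L
    if (code[[new_codon]] != code[[old_codon]]) n_aa <- n_aa + 1L
  }
  list(seq = paste(nt, collapse = ""),
       n_nt_changes = accepted,
       n_aa_changes = n_aa)
}
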