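#' Construct a sequence alignment
#'
#' A light container for an equal-length multiple sequence alignment: a named
#' character vector with an `alphabet` attribute. The gap character is `-`.
#'
#' @param x Named character vector of aligned sequences.
#' @param alphabet One of `"nucleotide"`, `"protein"`, `"codon"`. Codon
#'   alignments must have length divisible by 3.
#' @return An object of class `"seq_alignment"`.
#' @export
seq_alignment <- function(x, alphabet = c("nucleotide", "protein", "codon")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x)))) {
    stop("alignment records need unique non-empty ids")
  }
  ids <- names(x)
  x <- toupper(as.character(x))
  names(x) <- ids
  w <- unique(nchar(x))
  if (length(w) > 1L) stop("sequences are not all the same length: ", paste(w, collapse = ", "))
  if (alphabet == "codon" && length(w) == 1L && w %% 3L != 0L) {
    stop("codon alignment length ", w, " is not divisible by 3")
  }
  structure(x, alphabet = alphabet, class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d %s sequences of length %d\n",
              length(x), attr(x, "alphabet"), if (length(x)) nchar(x[[1]]) else 0L))
  invisible(x)
}

aln_alphabet <- function(aln) attr(aln, "alphabet") %||% "nucleotide"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write FASTA
#'
#' @param path FASTA file path.
#' @param alphabet Alphabet of the records (see [seq_alignment()]).
#' @param aligned If `TRUE` (default) the records are validated as an
#'   alignment and a `seq_alignment` is returned; otherwise a plain named
#'   character vector of (possibly unequal-length) sequences.
#' @return A `seq_alignment` or named character vector.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein", "codon"),
                       aligned = TRUE) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  x <- as.character(set)
  names(x) <- sub("\\s.*$", "", names(x))
  if (aligned) seq_alignment(x, alphabet) else toupper(x)
}

#' @rdname read_fasta
#' @param x Sequences to write (`seq_alignment` or named character vector).
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(x)), path)
  invisible(path)
}

# translate an ungapped CDS with the standard code; stops are "*"
translate_cds <- function(cds, id = "<seq>") {
  if (nchar(cds) %% 3L != 0L) stop("CDS length of '", id, "' is not divisible by 3")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    stop("record '", id, "': unrecognised codon '", codons[which(is.na(aa))[1]], "'")
  }
  aa
}

#' Thread coding sequences through a protein alignment
#'
#' Builds a codon alignment by mapping each aligned protein residue to its
#' source codon and each protein gap to `---`. A terminal stop codon on the
#' CDS is tolerated and dropped; internal stops (or any translation mismatch)
#' are errors.
#'
#' @param protein_aln A protein `seq_alignment`.
#' @param cds Named character vector (or unaligned FASTA read with
#'   `aligned = FALSE`) of coding sequences, one per protein record.
#' @return A codon `seq_alignment` on the same record ids.
#' @examples
#' paln <- seq_alignment(c(a = "M-K", b = "MAK"), "protein")
#' thread_codon_alignment(paln, c(a = "ATGAAA", b = "ATGGCTAAA"))
#' @export
thread_codon_alignment <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "seq_alignment"))
  if (aln_alphabet(protein_aln) != "protein") stop("protein alignment required")
  cds <- toupper(unlist(cds))
  missing <- setdiff(names(protein_aln), names(cds))
  if (length(missing) > 0) stop("no CDS for record(s): ", paste(missing, collapse = ", "))
  stops <- c("TAA", "TAG", "TGA")
  out <- vapply(names(protein_aln), function(id) {
    prot <- unclass(protein_aln)[[id]]
    dna <- cds[[id]]
    res <- strsplit(prot, "", fixed = TRUE)[[1]]
    n_res <- sum(res != "-")
    if (nchar(dna) == 3L * (n_res + 1L) &&
        substring(dna, nchar(dna) - 2L) %in% stops) {
      dna <- substring(dna, 1L, nchar(dna) - 3L)
    }
    if (nchar(dna) != 3L * n_res) {
      stop("record '", id, "': CDS length ", nchar(dna),
           " does not match ", n_res, " aligned residues (expected ", 3L * n_res, ")")
    }
    aa <- translate_cds(dna, id)
    prot_res <- res[res != "-"]
    diff <- which(aa != prot_res)
    if (length(diff) > 0) {
      stop("record '", id, "': CDS translation mismatch at residue ", diff[1],
           " (CDS encodes '", aa[diff[1]], "', protein has '", prot_res[diff[1]], "')")
    }
    codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
    filled <- character(length(res))
    filled[res == "-"] <- "---"
    filled[res != "-"] <- codons
    paste(filled, collapse = "")
  }, character(1))
  seq_alignment(out, "codon")
}

#' Remove all columns containing gaps
#'
#' Keeps only ungapped alignment columns. For codon alignments the unit of
#' removal is the whole codon: a codon column is dropped if any of its three
#' nucleotide positions is gapped in any sequence.
#'
#' @param aln A `seq_alignment`.
#' @return A `seq_alignment` of the same alphabet (possibly zero columns,
#'   with a warning).
#' @export
trim_ungapped <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  alphabet <- aln_alphabet(aln)
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(aln))
  gapped <- apply(m == "-", 2L, any)
  if (alphabet == "codon") {
    cod <- matrix(gapped, nrow = 3L)
    keep_cod <- !apply(cod, 2L, any)
    keep <- rep(keep_cod, each = 3L)
  } else {
    keep <- !gapped
  }
  if (!any(keep)) warning("no ungapped columns remain after trimming")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(aln)
  seq_alignment(out, alphabet)
}

#' Drop sequences much shorter than their cohort
#'
#' Removes each sequence whose length is below `min_fraction` of the median
#' length of all *other* sequences in the set (a leave-one-out median), the
#' usual guard against partial or truncated gene models.
#'
#' @param seqs Named character vector of (unaligned) sequences.
#' @param min_fraction Minimum allowed fraction of the leave-one-out median
#'   length (default 0.5).
#' @return The retained subset of `seqs`.
#' @export
length_filter <- function(seqs, min_fraction = 0.5) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("empty sequence set")
  if (length(seqs) == 1L) return(seqs)
  len <- nchar(seqs)
  keep <- vapply(seq_along(len), function(i) {
    len[i] >= min_fraction * stats::median(len[-i])
  }, logical(1))
  seqs[keep]
}

#' Gate on the number of ubiquitously aligned positions
#'
#' `TRUE` iff a trimmed alignment retains strictly more than `min_cols`
#' columns, counted in residues for protein/nucleotide alignments and in
#' codons for codon alignments (an alignment with exactly `min_cols` columns
#' fails the gate).
#'
#' @param aln A trimmed `seq_alignment`.
#' @param min_cols Threshold (default 50).
#' @return Logical scalar.
#' @export
min_columns_gate <- function(aln, min_cols = 50) {
  stopifnot(inherits(aln, "seq_alignment"))
  w <- if (length(aln)) nchar(unclass(aln)[[1]]) else 0L
  ncols <- if (aln_alphabet(aln) == "codon") w %/% 3L else w
  ncols > min_cols
}
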