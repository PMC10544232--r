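# Protein conservation utilities: FASTA I/O, global pairwise alignment,
# percent identity, and residue-conservation checks at given positions.
#
# Alignment is Needleman-Wunsch with affine gaps via
# Biostrings::pairwiseAlignment. Scoring convention (Biostrings'): a gap of
# length L costs gap_open + L * gap_extend. Percent identity is identical
# columns / alignment length * 100 (gapped columns count in the
# denominator), the common web-tool default.

#' Read / write protein FASTA
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named character vector of residue
#'   strings (names = record ids).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of residue strings.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Residue count of a protein sequence, excluding gaps
#'
#' @param s residue string (may contain `-` gap characters).
#' @return Integer residue count.
#' @export
protein_length <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  nchar(gsub("-", "", s, fixed = TRUE))
}

#' Global pairwise protein alignment with percent identity
#'
#' Needleman–Wunsch global alignment with affine gap penalties
#' (a gap of length L costs `gap_open + L * gap_extend`).
#' Identity is computed over all alignment columns:
#' `100 * identical columns / alignment length`.
#'
#' @param a,b residue strings (non-empty; gaps are stripped first).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return An `alignment_result` list: `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score`, `identity_pct`, `alignment_length`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  a <- gsub("-", "", a, fixed = TRUE)
  b <- gsub("-", "", b, fixed = TRUE)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  aa <- as.character(Biostrings::alignedPattern(aln))
  ab <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(aa, "")[[1]]
  cb <- strsplit(ab, "")[[1]]
  len <- length(ca)
  ident <- sum(ca == cb & ca != "-")
  structure(list(aligned_a = aa, aligned_b = ab,
                 score = Biostrings::score(aln),
                 identity_pct = 100 * ident / len,
                 alignment_length = len),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> length %d, score %.1f, identity %.2f%%\n",
              x$alignment_length, x$score, x$identity_pct))
  invisible(x)
}

#' Residue conservation at a reference position across orthologs
#'
#' Maps a 1-based residue position of the reference sequence through the
#' alignment and reports, for every other record, whether it carries the
#' identical residue at that column. Records whose sequence has a gap at the
#' mapped column are flagged `NA` ("unalignable") rather than `FALSE`.
#' Records of equal length are treated as pre-aligned; otherwise each is
#' aligned to the reference with [global_align()].
#'
#' @param records named character vector of residue strings (gapped if
#'   pre-aligned).
#' @param reference_id name of the reference record.
#' @param position_1based residue position in the *ungapped* reference.
#' @param ... passed to [global_align()] when alignment is needed.
#' @return Named logical vector over the non-reference records: `TRUE`
#'   (conserved), `FALSE` (substituted), or `NA` (gap at that column).
#' @export
residue_conserved <- function(records, reference_id, position_1based, ...) {
  stopifnot(is.character(records), length(records) >= 2,
            reference_id %in% names(records))
  ref <- records[[reference_id]]
  if (position_1based < 1 || position_1based > protein_length(ref))
    stop("position beyond reference length")
  others <- records[setdiff(names(records), reference_id)]
  prealigned <- length(unique(nchar(records))) == 1

  ref_residue_at <- function(gapped, pos) {
    ch <- strsplit(gapped, "")[[1]]
    res_idx <- cumsum(ch != "-")
    col <- which(res_idx == pos & ch != "-")[1]
    list(col = col, chars = ch)
  }

  out <- vapply(names(others), function(id) {
    if (prealigned) {
      m <- ref_residue_at(ref, position_1based)
      other_ch <- strsplit(others[[id]], "")[[1]]
    } else {
      aln <- global_align(ref, others[[id]], ...)
      m <- ref_residue_at(aln$aligned_a, position_1based)
      other_ch <- strsplit(aln$aligned_b, "")[[1]]
    }
    oc <- other_ch[m$col]
    if (oc == "-") return(NA)           # unalignable at this position
    oc == m$chars[m$col]
  }, logical(1))
  out
}
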