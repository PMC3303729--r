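#' Homology search configuration
#'
#' Scoring and statistics for the two-step exon homology search: a
#' nucleotide local-alignment pass kept at `nt_evalue_max`, then a
#' translated frame-pair pass, for exons without a nucleotide hit, kept at
#' `translated_evalue_max`.  E-values follow the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with the search space `m * n` taken as
#' query length times subject length of the single comparison (nucleotides
#' for the nucleotide pass, residues of the chosen frames for the
#' translated pass).
#'
#' Defaults use a +1/-2 nucleotide scheme with its standard ungapped
#' statistics (lambda = 1.28, K = 0.46) and BLOSUM62 with gap 11/1 and its
#' usual constants (lambda = 0.267, K = 0.041).  All are overridable; the
#' two e-value thresholds default to 1e-5 (nucleotide) and 1e-3
#' (translated).
#'
#' @param nt_match,nt_mismatch Nucleotide match/mismatch scores.
#' @param nt_gap_open,nt_gap_extend Affine gap penalties (positive); a gap
#'   of length L costs `open + L * extend`.
#' @param nt_K,nt_lambda Karlin-Altschul constants for the nucleotide pass.
#' @param nt_evalue_max Keep nucleotide hits with e-value at or below this.
#' @param aa_gap_open,aa_gap_extend Protein-level gap penalties.
#' @param aa_K,aa_lambda Karlin-Altschul constants for the translated pass.
#' @param translated_evalue_max Keep translated hits at or below this.
#' @return An object of class `search_config`.
#' @export
search_config <- function(nt_match = 1, nt_mismatch = -2,
                          nt_gap_open = 2, nt_gap_extend = 2,
                          nt_K = 0.46, nt_lambda = 1.28,
                          nt_evalue_max = 1e-5,
                          aa_gap_open = 11, aa_gap_extend = 1,
                          aa_K = 0.041, aa_lambda = 0.267,
                          translated_evalue_max = 1e-3) {
  stopifnot(nt_match > 0, nt_mismatch < 0,
            nt_gap_open >= 0, nt_gap_extend > 0,
            aa_gap_open >= 0, aa_gap_extend > 0,
            nt_K > 0, nt_lambda > 0, aa_K > 0, aa_lambda > 0,
            nt_evalue_max > 0, nt_evalue_max < 1,
            translated_evalue_max > 0)
  cfg <- list(nt_match = nt_match, nt_mismatch = nt_mismatch,
              nt_gap_open = nt_gap_open, nt_gap_extend = nt_gap_extend,
              nt_K = nt_K, nt_lambda = nt_lambda,
              nt_evalue_max = nt_evalue_max,
              aa_gap_open = aa_gap_open, aa_gap_extend = aa_gap_extend,
              aa_K = aa_K, aa_lambda = aa_lambda,
              translated_evalue_max = translated_evalue_max)
  class(cfg) <- "search_config"
  cfg
}

# 5-symbol DNA alphabet; N mismatches everything, including N.
.nt_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.encode_nt <- function(seq) {
  v <- .nt_codes[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  v[is.na(v)] <- 5L
  unname(v)
}

.nt_matrix <- function(cfg) {
  m <- matrix(cfg$nt_mismatch, 5, 5)
  diag(m) <- cfg$nt_match
  m[5, ] <- cfg$nt_mismatch
  m[, 5] <- cfg$nt_mismatch
  m
}

.blosum_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

.encode_aa <- function(pep, alphabet) {
  v <- match(strsplit(pep, "", fixed = TRUE)[[1]], alphabet)
  v[is.na(v)] <- match("X", alphabet)
  v
}

#' Best local nucleotide alignment of two sequences
#'
#' Smith-Waterman with affine gaps under the scoring in `cfg`.  Among
#' co-optimal alignments the one with the smallest query start, then the
#' smallest subject start, is returned (fixed preference order in the
#' dynamic program; see the package vignette).
#'
#' @param q,s DNA sequences (character scalars).
#' @param cfg A [search_config()].
#' @return A list with `score`, 1-based inclusive `q_start`, `q_end`,
#'   `s_start`, `s_end` (NA when score is 0), `identity` (matched fraction
#'   of aligned columns), `matches`, `aln_len`, and `evalue`.
#' @export
local_align_nt <- function(q, s, cfg = search_config()) {
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence")
  r <- .sw_align_cpp(.encode_nt(q), .encode_nt(s), .nt_matrix(cfg),
                     cfg$nt_gap_open, cfg$nt_gap_extend)
  r$identity <- if (r$aln_len > 0) r$matches / r$aln_len else NA_real_
  r$evalue <- evalue_of(r$score, nchar(q), nchar(s),
                        K = cfg$nt_K, lambda = cfg$nt_lambda)
  r$method <- "nt"
  r
}

# Peptides of the three forward frames, trimmed to whole codons.
# Ambiguous codons translate to X, stops to *.
.frame_peptides <- function(seq) {
  n <- nchar(seq)
  lapply(0:2, function(f) {
    len <- ((n - f) %/% 3L) * 3L
    if (len < 3L) return("")
    dna <- Biostrings::DNAString(gsub("[^ACGTacgt]", "N", seq))
    as.character(Biostrings::translate(
      Biostrings::subseq(dna, start = f + 1L, width = len),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  })
}

#' Best translated (frame-pair) local alignment
#'
#' Translates both sequences in the three forward frames, locally aligns
#' all nine peptide pairs under BLOSUM62, and returns the best-scoring
#' pair.  Stop codons are retained as `*`, a low-scoring symbol.  Exons are
#' handled in transcript orientation throughout the pipeline, so reverse
#' frames are not searched.  Ties prefer the lower query frame, then the
#' lower subject frame.
#'
#' @inheritParams local_align_nt
#' @return As [local_align_nt()], plus `q_frame`/`s_frame` (0-2) and
#'   nucleotide-coordinate `q_start`/`q_end`/`s_start`/`s_end` spans of the
#'   aligned codons; `identity` is at the amino-acid level.
#' @export
local_align_translated <- function(q, s, cfg = search_config()) {
  if (nchar(q) < 3 || nchar(s) < 3) stop("sequence shorter than one codon")
  if (grepl("^N+$", toupper(q)) || grepl("^N+$", toupper(s)))
    stop("all-N sequence cannot be translated")
  bl <- .blosum62()
  alpha <- rownames(bl)
  qp <- .frame_peptides(q)
  sp <- .frame_peptides(s)
  best <- NULL
  for (qf in 0:2) {
    if (!nzchar(qp[[qf + 1L]])) next
    qv <- .encode_aa(qp[[qf + 1L]], alpha)
    for (sf in 0:2) {
      if (!nzchar(sp[[sf + 1L]])) next
      sv <- .encode_aa(sp[[sf + 1L]], alpha)
      r <- .sw_align_cpp(qv, sv, bl, cfg$aa_gap_open, cfg$aa_gap_extend)
      if (is.null(best) || r$score > best$score) {
        r$q_frame <- qf; r$s_frame <- sf
        r$q_len_aa <- length(qv); r$s_len_aa <- length(sv)
        best <- r
      }
    }
  }
  if (is.null(best)) stop("no translatable frame")
  best$identity <- if (best$aln_len > 0) best$matches / best$aln_len else NA_real_
  best$evalue <- evalue_of(best$score, best$q_len_aa, best$s_len_aa,
                           K = cfg$aa_K, lambda = cfg$aa_lambda)
  if (best$score > 0) {
    # peptide spans back to nucleotide coordinates on the input sequences
    qs <- best$q_start; qe <- best$q_end
    ss <- best$s_start; se <- best$s_end
    best$q_start <- best$q_frame + 3L * (qs - 1L) + 1L
    best$q_end <- best$q_frame + 3L * qe
    best$s_start <- best$s_frame + 3L * (ss - 1L) + 1L
    best$s_end <- best$s_frame + 3L * se
  }
  best$method <- "translated"
  best
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments scoring at least `score` in an `m x n` search space.
#' Strictly decreasing in the score, linear in `m * n`.
#'
#' @param score Alignment score (non-negative).
#' @param m,n Query and subject lengths defining the search space.
#' @param K,lambda Karlin-Altschul constants.
#' @return The e-value (vectorised over `score`).
#' @export
evalue_of <- function(score, m, n, K = 0.46, lambda = 1.28) {
  stopifnot(all(score >= 0), m > 0, n > 0, K > 0, lambda > 0)
  K * m * n * exp(-lambda * score)
}
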