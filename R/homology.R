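.empty_hits <- function() {
  data.frame(pair_id = character(), query_exon = character(),
             subject_exon = character(), direction = character(),
             method = character(), score = numeric(), evalue = numeric(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}

# One directed pass: every query exon vs all subject exons. Nucleotide hits
# kept at cfg$nt_evalue_max; queries with none fall back to the translated
# search at cfg$translated_evalue_max. One (best) alignment per exon pair.
.search_direction <- function(qex, sex, cfg, pair_id, direction) {
  smat <- .nt_matrix(cfg)
  qenc <- lapply(qex$seq, .encode_nt)
  senc <- lapply(sex$seq, .encode_nt)
  rows <- vector("list", nrow(qex))
  for (i in seq_len(nrow(qex))) {
    qseq <- qex$seq[i]
    kept <- list()
    for (j in seq_len(nrow(sex))) {
      a <- .sw_align_cpp(qenc[[i]], senc[[j]], smat,
                         cfg$nt_gap_open, cfg$nt_gap_extend)
      a$evalue <- evalue_of(a$score, nchar(qseq), nchar(sex$seq[j]),
                            K = cfg$nt_K, lambda = cfg$nt_lambda)
      if (a$score > 0 && a$evalue <= cfg$nt_evalue_max)
        kept[[length(kept) + 1L]] <- data.frame(
          pair_id = pair_id, query_exon = qex$exon_id[i],
          subject_exon = sex$exon_id[j], direction = direction,
          method = "nt", score = a$score, evalue = a$evalue,
          q_start = a$q_start, q_end = a$q_end, s_start = a$s_start,
          s_end = a$s_end,
          identity = if (a$aln_len > 0) a$matches / a$aln_len else NA_real_,
          stringsAsFactors = FALSE)
    }
    if (length(kept) == 0 && nchar(qseq) >= 3) {
      for (j in seq_len(nrow(sex))) {
        if (nchar(sex$seq[j]) < 3) next
        a <- tryCatch(local_align_translated(qseq, sex$seq[j], cfg),
                      error = function(e) NULL)
        if (!is.null(a) && a$score > 0 &&
            a$evalue <= cfg$translated_evalue_max)
          kept[[length(kept) + 1L]] <- data.frame(
            pair_id = pair_id, query_exon = qex$exon_id[i],
            subject_exon = sex$exon_id[j], direction = direction,
            method = "translated", score = a$score, evalue = a$evalue,
            q_start = a$q_start, q_end = a$q_end, s_start = a$s_start,
            s_end = a$s_end, identity = a$identity, stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- if (length(kept) > 0) do.call(rbind, kept) else NULL
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) .empty_hits() else do.call(rbind, rows)
}

#' Two-step exon homology search within one gene pair
#'
#' Step 1 aligns every exon of gene A against every exon of gene B (and
#' vice versa — both directions are searched) at the nucleotide level,
#' keeping hits with e-value at or below `cfg$nt_evalue_max` (default
#' 1e-5).  Step 2 re-searches only the exons with no step-1 hit using the
#' translated frame-pair aligner, keeping hits at or below
#' `cfg$translated_evalue_max` (default 1e-3).  An exon therefore never has
#' both nucleotide and translated hits as a query.  The search never
#' crosses gene pairs.
#'
#' @param pair_id Pair identifier carried into the hit table.
#' @param exons_a,exons_b Exon data.frames (`exon_id`, `seq`) of the two
#'   paired genes, sequences in transcript orientation.
#' @param cfg A [search_config()].
#' @return A data.frame of directed hits: `pair_id`, `query_exon`,
#'   `subject_exon`, `direction` (`"ab"` or `"ba"`), `method`, `score`,
#'   `evalue`, aligned spans (1-based inclusive, query and subject) and
#'   `identity`.
#' @export
two_step_search <- function(pair_id, exons_a, exons_b, cfg = search_config()) {
  stopifnot(all(c("exon_id", "seq") %in% names(exons_a)),
            all(c("exon_id", "seq") %in% names(exons_b)))
  if (nrow(exons_a) == 0 || nrow(exons_b) == 0) return(.empty_hits())
  ab <- .search_direction(exons_a, exons_b, cfg, pair_id, "ab")
  ba <- .search_direction(exons_b, exons_a, cfg, pair_id, "ba")
  out <- rbind(ab, ba)
  rownames(out) <- NULL
  out
}

#' Export hits in BLAST tabular (outfmt 6 compatible) layout
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore.  `mismatch`/`gapopen` are derived from the stored
#' alignment summary (aligned columns minus matches, gap opens not tracked
#' and written as 0); `bitscore` is the raw score.
#'
#' @param hits A hit table from [two_step_search()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hits_to_blast_tab <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_exon, sseqid = hits$subject_exon,
    pident = round(hits$identity * 100, 2),
    length = hits$q_end - hits$q_start + 1L,
    mismatch = round((1 - hits$identity) * (hits$q_end - hits$q_start + 1L)),
    gapopen = 0L, qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = hits$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import hits from BLAST tabular output
#'
#' Allows an external BLAST+ run (`-outfmt 6`) to replace the built-in
#' aligner backend.  Hits are filtered at the configured thresholds and
#' tagged with the given method.
#'
#' @param path BLAST tabular file.
#' @param pair_id Pair identifier to stamp on the rows.
#' @param direction `"ab"` or `"ba"`.
#' @param method `"nt"` or `"translated"`.
#' @param cfg A [search_config()] supplying the e-value thresholds.
#' @return A hit table in the [two_step_search()] layout.
#' @export
read_blast_tab <- function(path, pair_id, direction = "ab", method = "nt",
                           cfg = search_config()) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12) stop("expected 12-column BLAST tabular file: ", path)
  thr <- if (method == "nt") cfg$nt_evalue_max else cfg$translated_evalue_max
  out <- data.frame(pair_id = pair_id, query_exon = d[[1]],
                    subject_exon = d[[2]], direction = direction,
                    method = method, score = d[[12]],
                    evalue = as.numeric(d[[11]]), q_start = d[[7]],
                    q_end = d[[8]], s_start = d[[9]], s_end = d[[10]],
                    identity = d[[3]] / 100, stringsAsFactors = FALSE)
  out[out$evalue <= thr, , drop = FALSE]
}
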