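#' Fused/split detection configuration
#'
#' Thresholds for intron gain/loss (exon fission/fusion) candidate
#' screening and sequence verification: the summed split-exon length must
#' be within `len_delta_max` (5%) of the fused exon length; the summed
#' aligned fraction of the split exons against the fused exon must lie in
#' `[aligned_frac_min, aligned_frac_max]` (0.75-1.1, allowing overlap of
#' aligned spans to exceed 1); and the verification alignment of the
#' rejoined split sequence against the fused exon must cross the first and
#' last joint point and cover at least `verify_coverage_min` (70%) of the
#' fused exon.
#'
#' @param len_delta_max Relative length-difference bound (default 0.05).
#' @param aligned_frac_min,aligned_frac_max Aligned-fraction window
#'   (defaults 0.75 and 1.1).
#' @param verify_coverage_min Minimum fused-exon coverage of the
#'   verification alignment (default 0.70).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(len_delta_max = 0.05, aligned_frac_min = 0.75,
                          aligned_frac_max = 1.1,
                          verify_coverage_min = 0.70) {
  stopifnot(len_delta_max > 0, aligned_frac_min > 0,
            aligned_frac_max > aligned_frac_min, verify_coverage_min > 0)
  structure(list(len_delta_max = len_delta_max,
                 aligned_frac_min = aligned_frac_min,
                 aligned_frac_max = aligned_frac_max,
                 verify_coverage_min = verify_coverage_min),
            class = "fusion_config")
}

.empty_events <- function() {
  data.frame(fused_species = character(), fused_uexon = character(),
             split_uexons = character(), k = integer(),
             len_delta_frac = numeric(), aligned_frac = numeric(),
             verify_coverage = numeric(), joints_crossed = logical(),
             stringsAsFactors = FALSE)
}

# Candidates with the fused exon on the "from" side of oriented links.
.fusion_candidates_side <- function(links, ue_f, ue_s, exclude_f, exclude_s,
                                    species_f, cfg) {
  if (nrow(links) == 0) return(list())
  rank_s <- stats::setNames(ue_s$uexons$rank, ue_s$uexons$uexon_id)
  len_s <- stats::setNames(ue_s$uexons$length, ue_s$uexons$uexon_id)
  len_f <- stats::setNames(ue_f$uexons$length, ue_f$uexons$uexon_id)
  cands <- list()
  for (f in setdiff(unique(links$from), exclude_f)) {
    h <- links[links$from == f & !(links$to %in% exclude_s), , drop = FALSE]
    if (nrow(h) < 2) next
    ord <- order(rank_s[h$to])
    h <- h[ord, , drop = FALSE]
    ranks <- rank_s[h$to]
    if (!all(diff(ranks) == 1)) next   # splits must be consecutive in rank
    L <- len_f[[f]]
    delta <- abs(sum(len_s[h$to]) - L) / L
    if (delta > cfg$len_delta_max) next
    af <- sum(h$aln_split) / L
    if (af < cfg$aligned_frac_min || af > cfg$aligned_frac_max) next
    cands[[length(cands) + 1L]] <- list(
      fused_species = species_f, fused_uexon = f, split_uexons = h$to,
      k = nrow(h), len_delta_frac = delta, aligned_frac = af)
  }
  cands
}

#' Find fused/split exon candidates
#'
#' A united exon hit by two or more distinct united exons of the partner
#' gene is a candidate fused exon when (1) the summed split lengths are
#' within 5% of its length, (2) the split exons are adjacent (consecutive
#' ranks, no other exon inserted between them) and (3) the summed aligned
#' fraction of the splits against the fused exon lies in 0.75-1.1.
#' Both orientations (fused in either species) are screened.  United exons
#' already confirmed by earlier stages are excluded.
#'
#' @param hits Directed hit table for the gene pair.
#' @param ue_a,ue_b `united_exons` of the two genes.
#' @param confirmed Link table of already-confirmed assignments.
#' @param cfg A [fusion_config()].
#' @return A list of candidate descriptors (fused species/united exon,
#'   ordered split united exons, metrics).
#' @export
find_fused_split_candidates <- function(hits, ue_a, ue_b,
                                        confirmed = .empty_links(),
                                        cfg = fusion_config()) {
  links <- .uexon_links(hits, ue_a, ue_b)
  if (nrow(links) == 0) return(list())
  fwd <- data.frame(from = links$uexon_a, to = links$uexon_b,
                    aln_split = links$aln_len_b, stringsAsFactors = FALSE)
  rev <- data.frame(from = links$uexon_b, to = links$uexon_a,
                    aln_split = links$aln_len_a, stringsAsFactors = FALSE)
  c(.fusion_candidates_side(fwd, ue_a, ue_b, unique(confirmed$uexon_a),
                            unique(confirmed$uexon_b), "A", cfg),
    .fusion_candidates_side(rev, ue_b, ue_a, unique(confirmed$uexon_b),
                            unique(confirmed$uexon_a), "B", cfg))
}

#' Verify a fused/split candidate by realignment
#'
#' The split exon sequences are joined in rank order into one long
#' sequence, whose single best local alignment against the fused exon must
#' cross the first and last joint point and cover at least 70% of the
#' fused exon.
#'
#' @param cand A candidate from [find_fused_split_candidates()].
#' @param fused_seq Fused united-exon sequence.
#' @param split_seqs Split united-exon sequences, in rank order.
#' @param scfg A [search_config()] for the verification aligner.
#' @param cfg A [fusion_config()].
#' @return A one-row event data.frame when verified, otherwise `NULL`.
#' @export
verify_fused_split <- function(cand, fused_seq, split_seqs,
                               scfg = search_config(),
                               cfg = fusion_config()) {
  joined <- paste(split_seqs, collapse = "")
  joints <- cumsum(nchar(split_seqs))
  joints <- joints[-length(joints)]
  a <- local_align_nt(joined, fused_seq, scfg)
  if (a$score <= 0) return(NULL)
  crossed <- a$q_start <= joints[1] && a$q_end >= joints[length(joints)] + 1L
  coverage <- (a$s_end - a$s_start + 1L) / nchar(fused_seq)
  if (!crossed || coverage < cfg$verify_coverage_min) return(NULL)
  data.frame(fused_species = cand$fused_species,
             fused_uexon = cand$fused_uexon,
             split_uexons = paste(cand$split_uexons, collapse = ","),
             k = cand$k, len_delta_frac = cand$len_delta_frac,
             aligned_frac = cand$aligned_frac, verify_coverage = coverage,
             joints_crossed = crossed, stringsAsFactors = FALSE)
}

#' Detect and verify fused/split events for one gene pair
#'
#' Runs candidate screening in both orientations and realignment
#' verification; emits events plus the fused-to-split links they imply
#' (provenance `fused_split`), which join the anchor set.
#'
#' @inheritParams find_fused_split_candidates
#' @param scfg A [search_config()] for the verification aligner.
#' @return A list with `events` (one row per verified event) and `links`
#'   (one row per fused-split united-exon pair, oriented A to B).
#' @export
detect_fused_split <- function(hits, ue_a, ue_b, confirmed = .empty_links(),
                               scfg = search_config(),
                               cfg = fusion_config()) {
  cands <- find_fused_split_candidates(hits, ue_a, ue_b, confirmed, cfg)
  if (length(cands) == 0)
    return(list(events = .empty_events(), links = .empty_links()))
  seq_of <- function(ue) stats::setNames(ue$uexons$seq, ue$uexons$uexon_id)
  sa <- seq_of(ue_a); sb <- seq_of(ue_b)
  events <- list(); link_rows <- list()
  for (cand in cands) {
    fused_seq <- if (cand$fused_species == "A") sa[[cand$fused_uexon]]
                 else sb[[cand$fused_uexon]]
    split_seqs <- if (cand$fused_species == "A")
      unname(sb[cand$split_uexons]) else unname(sa[cand$split_uexons])
    ev <- verify_fused_split(cand, fused_seq, split_seqs, scfg, cfg)
    if (is.null(ev)) next
    events[[length(events) + 1L]] <- ev
    link_rows[[length(link_rows) + 1L]] <- data.frame(
      uexon_a = if (cand$fused_species == "A") cand$fused_uexon
                else cand$split_uexons,
      uexon_b = if (cand$fused_species == "A") cand$split_uexons
                else cand$fused_uexon,
      evalue = NA_real_, method = "nt", provenance = "fused_split",
      out_of_order = FALSE, stringsAsFactors = FALSE)
  }
  if (length(events) == 0)
    return(list(events = .empty_events(), links = .empty_links()))
  links <- do.call(rbind, link_rows)
  links <- links[!duplicated(paste(links$uexon_a, links$uexon_b)), ,
                 drop = FALSE]
  list(events = do.call(rbind, events), links = links)
}
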