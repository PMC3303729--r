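#' Assignment configuration
#'
#' Rules used when converting homology hits into final assignments: the
#' out-of-order exception (accepted only when exon lengths differ by at
#' most `exception_len_diff_max` bases and the hit e-value is below
#' `exception_evalue_max`, then tagged) and the minimum number of anchors a
#' gene must have before anchor mapping is attempted.
#'
#' @param exception_len_diff_max Maximum length difference (bp, default 6)
#'   for an out-of-order hit to be eligible for the exception.
#' @param exception_evalue_max E-value must be strictly below this
#'   (default 1e-10) for the exception.
#' @param min_anchors_per_gene Genes with fewer anchors abandon their
#'   unresolved exons (default 2).
#' @return An object of class `assign_config`.
#' @export
assign_config <- function(exception_len_diff_max = 6,
                          exception_evalue_max = 1e-10,
                          min_anchors_per_gene = 2) {
  stopifnot(exception_len_diff_max > 0, exception_evalue_max > 0,
            min_anchors_per_gene > 0)
  structure(list(exception_len_diff_max = exception_len_diff_max,
                 exception_evalue_max = exception_evalue_max,
                 min_anchors_per_gene = min_anchors_per_gene),
            class = "assign_config")
}

# Orient a directed hit table into A->B space and lift to united exons.
# Returns one row per (uexon_a, uexon_b) with the best e-value and the
# maximal aligned lengths observed on each side.
.uexon_links <- function(hits, ue_a, ue_b) {
  if (nrow(hits) == 0)
    return(data.frame(uexon_a = character(), uexon_b = character(),
                      evalue = numeric(), score = numeric(),
                      aln_len_a = numeric(), aln_len_b = numeric(),
                      method = character(), stringsAsFactors = FALSE))
  ab <- hits$direction == "ab"
  ua <- ub <- character(nrow(hits))
  ua[ab] <- uexon_of(ue_a, hits$query_exon[ab])
  ua[!ab] <- uexon_of(ue_a, hits$subject_exon[!ab])
  ub[ab] <- uexon_of(ue_b, hits$subject_exon[ab])
  ub[!ab] <- uexon_of(ue_b, hits$query_exon[!ab])
  la <- ifelse(ab, hits$q_end - hits$q_start + 1L,
               hits$s_end - hits$s_start + 1L)
  lb <- ifelse(ab, hits$s_end - hits$s_start + 1L,
               hits$q_end - hits$q_start + 1L)
  key <- paste(ua, ub, sep = "\r")
  agg <- lapply(split(seq_along(key), key), function(idx) {
    b <- idx[which.min(hits$evalue[idx])]
    data.frame(uexon_a = ua[b], uexon_b = ub[b],
               evalue = hits$evalue[b], score = max(hits$score[idx]),
               aln_len_a = max(la[idx]), aln_len_b = max(lb[idx]),
               method = hits$method[b], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

.empty_links <- function() {
  data.frame(uexon_a = character(), uexon_b = character(),
             evalue = numeric(), method = character(),
             provenance = character(), out_of_order = logical(),
             stringsAsFactors = FALSE)
}

#' Best-reciprocal-hit exon pairs
#'
#' Exons with exactly one hit each (as query), whose single hits point at
#' each other, become one-to-one ortholog pairs, lifted to their united
#' exons.
#'
#' @param hits A directed hit table from [two_step_search()] for one gene
#'   pair.
#' @param ue_a,ue_b `united_exons` of the two genes.
#' @return A link table: `uexon_a`, `uexon_b`, `evalue`, `method`,
#'   `provenance` (`"brh"`), `out_of_order` (FALSE).
#' @export
find_brh_pairs <- function(hits, ue_a, ue_b) {
  if (nrow(hits) == 0) return(.empty_links())
  ab <- hits[hits$direction == "ab", , drop = FALSE]
  ba <- hits[hits$direction == "ba", , drop = FALSE]
  single_a <- names(which(table(ab$query_exon) == 1))
  single_b <- names(which(table(ba$query_exon) == 1))
  cand <- ab[ab$query_exon %in% single_a &
             ab$subject_exon %in% single_b, , drop = FALSE]
  if (nrow(cand) == 0) return(.empty_links())
  back <- ba$subject_exon[match(cand$subject_exon, ba$query_exon)]
  cand <- cand[!is.na(back) & back == cand$query_exon, , drop = FALSE]
  if (nrow(cand) == 0) return(.empty_links())
  out <- data.frame(uexon_a = uexon_of(ue_a, cand$query_exon),
                    uexon_b = uexon_of(ue_b, cand$subject_exon),
                    evalue = cand$evalue, method = cand$method,
                    provenance = "brh", out_of_order = FALSE,
                    stringsAsFactors = FALSE)
  out[!duplicated(paste(out$uexon_a, out$uexon_b)), , drop = FALSE]
}

#' Collapse multi-hit exons whose hits share one united exon
#'
#' An exon with two or more hits is assigned one-to-one at the united-exon
#' level when all its hit exons are members of a single united exon of the
#' partner gene and at least one of those exons links back to the original
#' exon in the reverse search; otherwise it is left unresolved.
#'
#' @inheritParams find_brh_pairs
#' @return A link table (provenance `"multi_collapse"`).
#' @export
collapse_multi_hits <- function(hits, ue_a, ue_b) {
  if (nrow(hits) == 0) return(.empty_links())
  one_side <- function(fwd, rev, ue_q, ue_s, orient_a_first) {
    multi <- names(which(table(fwd$query_exon) >= 2))
    rows <- lapply(multi, function(x) {
      h <- fwd[fwd$query_exon == x, , drop = FALSE]
      us <- unique(uexon_of(ue_s, h$subject_exon))
      if (length(us) != 1) return(NULL)
      back_ok <- any(rev$query_exon %in% h$subject_exon &
                     rev$subject_exon == x)
      if (!back_ok) return(NULL)
      b <- which.min(h$evalue)
      uq <- uexon_of(ue_q, x)
      data.frame(uexon_a = if (orient_a_first) uq else us,
                 uexon_b = if (orient_a_first) us else uq,
                 evalue = h$evalue[b], method = h$method[b],
                 provenance = "multi_collapse", out_of_order = FALSE,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0) .empty_links() else do.call(rbind, rows)
  }
  ab <- hits[hits$direction == "ab", , drop = FALSE]
  ba <- hits[hits$direction == "ba", , drop = FALSE]
  out <- rbind(one_side(ab, ba, ue_a, ue_b, TRUE),
               one_side(ba, ab, ue_b, ue_a, FALSE))
  out[!duplicated(paste(out$uexon_a, out$uexon_b)), , drop = FALSE]
}

#' Build the anchor set from confirmed assignments
#'
#' All united exons confirmed by best-reciprocal hits, multi-hit collapse
#' or fused/split verification become anchors, ordered by rank in both
#' genes.  A fused exon anchors against the rank span of its split
#' partners, so each side's view stores a partner-rank interval.
#'
#' @param links Confirmed link table (provenances `brh`, `multi_collapse`,
#'   `fused_split`).
#' @param ue_a,ue_b `united_exons` of the two genes.
#' @return An `anchor_set`: `links` plus per-side views `a` (`uexon_id`,
#'   `rank`, `partner_lo`, `partner_hi`, sorted by rank) and `b`.
#' @export
build_anchor_set <- function(links, ue_a, ue_b) {
  rank_a <- ue_a$uexons$rank[match(links$uexon_a, ue_a$uexons$uexon_id)]
  rank_b <- ue_b$uexons$rank[match(links$uexon_b, ue_b$uexons$uexon_id)]
  side_view <- function(own, partner) {
    if (length(own) == 0)
      return(data.frame(uexon_id = character(), rank = integer(),
                        partner_lo = integer(), partner_hi = integer()))
    sp <- split(partner, own)
    v <- data.frame(uexon_id = vapply(split(names(sp), names(sp)), `[`, "", 1),
                    partner_lo = vapply(sp, min, 0),
                    partner_hi = vapply(sp, max, 0),
                    stringsAsFactors = FALSE)
    v
  }
  va <- side_view(links$uexon_a, rank_b)
  va$rank <- ue_a$uexons$rank[match(va$uexon_id, ue_a$uexons$uexon_id)]
  va <- va[order(va$rank), , drop = FALSE]
  vb <- side_view(links$uexon_b, rank_a)
  vb$rank <- ue_b$uexons$rank[match(vb$uexon_id, ue_b$uexons$uexon_id)]
  vb <- vb[order(vb$rank), , drop = FALSE]
  structure(list(links = links, a = va, b = vb), class = "anchor_set")
}

# In-order/exception acceptance for one side. unresolved: uexon ids on the
# 'from' side; cand: candidate links oriented (from, to); view: the anchor
# view of the from side; to_rank/len lookups.
.anchor_side <- function(unresolved, cand, view, from_rank, to_rank,
                         from_len, to_len, cfg) {
  acc <- list()
  abandoned <- character()
  lack <- nrow(view) < cfg$min_anchors_per_gene
  for (u in unresolved) {
    r <- from_rank[[u]]
    if (lack) {
      abandoned <- c(abandoned, u)
      next
    }
    up <- view[view$rank < r, , drop = FALSE]
    dn <- view[view$rank > r, , drop = FALSE]
    lo <- if (nrow(up) > 0) up$partner_hi[which.max(up$rank)] else -Inf
    hi <- if (nrow(dn) > 0) dn$partner_lo[which.min(dn$rank)] else Inf
    h <- cand[cand$from == u, , drop = FALSE]
    for (k in seq_len(nrow(h))) {
      pr <- to_rank[[h$to[k]]]
      in_order <- pr > lo && pr < hi
      if (in_order) {
        acc[[length(acc) + 1L]] <- data.frame(
          from = u, to = h$to[k], evalue = h$evalue[k],
          method = h$method[k], provenance = "anchor_in_order",
          out_of_order = FALSE, stringsAsFactors = FALSE)
      } else {
        ldiff <- abs(from_len[[u]] - to_len[[h$to[k]]])
        if (ldiff <= cfg$exception_len_diff_max &&
            h$evalue[k] < cfg$exception_evalue_max) {
          acc[[length(acc) + 1L]] <- data.frame(
            from = u, to = h$to[k], evalue = h$evalue[k],
            method = h$method[k], provenance = "anchor_exception",
            out_of_order = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(accepted = if (length(acc) > 0) do.call(rbind, acc) else NULL,
       lack_of_anchors = abandoned)
}

#' Assign remaining united exons by anchor order
#'
#' For each unresolved united exon the nearest flanking anchors (by rank,
#' skipping non-anchor exons) are located; a hit is in order when the
#' partner united exon's rank lies strictly between the flanking anchors'
#' partner ranks (one-sided when the exon lies before the first or after
#' the last anchor).  All in-order hits are accepted — one partner gives
#' one-to-one, several give one-to-multi.  An out-of-order hit is accepted
#' only under the exception rule (length difference at most
#' `cfg$exception_len_diff_max` bp and e-value below
#' `cfg$exception_evalue_max`) and is then tagged `out_of_order`.  Genes
#' with fewer than `cfg$min_anchors_per_gene` anchors abandon their
#' unresolved exons (reported as lack of anchors).  Both sides are
#' processed and accepted links deduplicated.
#'
#' @param hits Directed hit table for the gene pair.
#' @param confirmed Confirmed link table (anchors' provenance).
#' @param anchors An `anchor_set` from [build_anchor_set()].
#' @param ue_a,ue_b `united_exons` of the two genes.
#' @param cfg An [assign_config()].
#' @return A list: `accepted` link table (provenances `anchor_in_order` /
#'   `anchor_exception`), and `lack_of_anchors`, the united exons abandoned
#'   because their gene had too few anchors.
#' @export
anchor_map_assign <- function(hits, confirmed, anchors, ue_a, ue_b,
                              cfg = assign_config()) {
  all_links <- .uexon_links(hits, ue_a, ue_b)
  resolved_a <- unique(confirmed$uexon_a)
  resolved_b <- unique(confirmed$uexon_b)
  with_hits_a <- unique(all_links$uexon_a)
  with_hits_b <- unique(all_links$uexon_b)
  unresolved_a <- setdiff(with_hits_a, resolved_a)
  unresolved_b <- setdiff(with_hits_b, resolved_b)
  rank_a <- stats::setNames(ue_a$uexons$rank, ue_a$uexons$uexon_id)
  rank_b <- stats::setNames(ue_b$uexons$rank, ue_b$uexons$uexon_id)
  len_a <- stats::setNames(ue_a$uexons$length, ue_a$uexons$uexon_id)
  len_b <- stats::setNames(ue_b$uexons$length, ue_b$uexons$uexon_id)
  cand_a <- data.frame(from = all_links$uexon_a, to = all_links$uexon_b,
                       evalue = all_links$evalue, method = all_links$method,
                       stringsAsFactors = FALSE)
  cand_b <- data.frame(from = all_links$uexon_b, to = all_links$uexon_a,
                       evalue = all_links$evalue, method = all_links$method,
                       stringsAsFactors = FALSE)
  ra <- .anchor_side(unresolved_a, cand_a, anchors$a, rank_a, rank_b,
                     len_a, len_b, cfg)
  rb <- .anchor_side(unresolved_b, cand_b, anchors$b, rank_b, rank_a,
                     len_b, len_a, cfg)
  acc <- .empty_links()
  if (!is.null(ra$accepted)) {
    acc <- rbind(acc, data.frame(
      uexon_a = ra$accepted$from, uexon_b = ra$accepted$to,
      evalue = ra$accepted$evalue, method = ra$accepted$method,
      provenance = ra$accepted$provenance,
      out_of_order = ra$accepted$out_of_order, stringsAsFactors = FALSE))
  }
  if (!is.null(rb$accepted)) {
    acc <- rbind(acc, data.frame(
      uexon_a = rb$accepted$to, uexon_b = rb$accepted$from,
      evalue = rb$accepted$evalue, method = rb$accepted$method,
      provenance = rb$accepted$provenance,
      out_of_order = rb$accepted$out_of_order, stringsAsFactors = FALSE))
  }
  acc <- acc[!duplicated(paste(acc$uexon_a, acc$uexon_b)), , drop = FALSE]
  list(accepted = acc,
       lack_of_anchors = unique(c(ra$lack_of_anchors, rb$lack_of_anchors)))
}

#' Finalize assignments into a complete status partition
#'
#' Every united exon (and every exon) of the gene pair receives exactly one
#' status: `one_to_one` (one accepted partner), `one_to_multi` (several),
#' `no_hit` (no homology hit in either search step) or `ignored` (had hits
#' but none was accepted).  A fused exon thus reports as one-to-multi with
#' its split counterparts as partners, and each split exon as one-to-one.
#' Exon-level status is `no_hit` for exons without their own hits and the
#' united exon's status otherwise.
#'
#' @param pair_id The gene pair identifier.
#' @param hits Directed hit table for the pair.
#' @param links All accepted/confirmed links for the pair.
#' @param lack_of_anchors United exons abandoned for lack of anchors.
#' @param ue_a,ue_b `united_exons` of the two genes (regions classified).
#' @param gene_a,gene_b Gene identifiers.
#' @return A list: `uexon_status` (one row per united exon of either
#'   species), `exon_status`, and `links` (with `pair_id` stamped).
#' @export
finalize_assignments <- function(pair_id, hits, links, lack_of_anchors,
                                 ue_a, ue_b, gene_a, gene_b) {
  ua <- ue_a$uexons[ue_a$uexons$gene_id == gene_a, , drop = FALSE]
  ub <- ue_b$uexons[ue_b$uexons$gene_id == gene_b, , drop = FALSE]
  hit_exons <- unique(c(hits$query_exon, hits$subject_exon))
  hit_u <- unique(c(
    if (nrow(hits) > 0) uexon_of(ue_a, intersect(hit_exons,
        ue_a$members$exon_id)) else character(),
    if (nrow(hits) > 0) uexon_of(ue_b, intersect(hit_exons,
        ue_b$members$exon_id)) else character()))
  side_status <- function(u, own_col, other_col) {
    part <- split(links[[other_col]], links[[own_col]])
    prov <- split(links$provenance, links[[own_col]])
    ooo <- split(links$out_of_order, links[[own_col]])
    n <- vapply(u$uexon_id, function(id)
      length(unique(part[[id]])), 0L)
    status <- ifelse(n >= 2, "one_to_multi",
              ifelse(n == 1, "one_to_one",
              ifelse(u$uexon_id %in% hit_u, "ignored", "no_hit")))
    reason <- ifelse(status == "ignored" &
                     u$uexon_id %in% lack_of_anchors, "lack_of_anchors",
              ifelse(status == "ignored", "no_accepted_hit", ""))
    data.frame(pair_id = pair_id,
               species = if (own_col == "uexon_a") "A" else "B",
               gene_id = u$gene_id, uexon_id = u$uexon_id, rank = u$rank,
               length = u$length,
               region = if ("region" %in% names(u))
                 as.character(u$region) else NA_character_,
               status = status, n_partners = n,
               partners = vapply(u$uexon_id, function(id)
                 paste(unique(part[[id]]), collapse = ","), ""),
               provenance = vapply(u$uexon_id, function(id)
                 paste(unique(prov[[id]]), collapse = ","), ""),
               out_of_order = vapply(u$uexon_id, function(id)
                 isTRUE(any(ooo[[id]])), TRUE),
               reason = reason, stringsAsFactors = FALSE)
  }
  us <- rbind(side_status(ua, "uexon_a", "uexon_b"),
              side_status(ub, "uexon_b", "uexon_a"))
  rownames(us) <- NULL
  bad <- is.na(us$status)
  if (any(bad)) stop("internal: unstatused united exon(s): ",
                     paste(us$uexon_id[bad], collapse = ", "))
  exon_side <- function(ue, gene, species) {
    mem <- ue$members[ue$members$uexon_id %in%
                        us$uexon_id[us$species == species], , drop = FALSE]
    st <- us$status[match(mem$uexon_id, us$uexon_id)]
    own_hit <- mem$exon_id %in% hit_exons
    data.frame(pair_id = pair_id, species = species,
               exon_id = mem$exon_id, uexon_id = mem$uexon_id,
               status = ifelse(own_hit, st, "no_hit"),
               stringsAsFactors = FALSE)
  }
  es <- rbind(exon_side(ue_a, gene_a, "A"), exon_side(ue_b, gene_b, "B"))
  rownames(es) <- NULL
  lk <- links
  if (nrow(lk) > 0) lk$pair_id <- pair_id else lk$pair_id <- character()
  list(uexon_status = us, exon_status = es, links = lk)
}
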