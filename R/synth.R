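#' Synthetic dataset configuration
#'
#' Parameters of the synthetic ortholog-pair generator.  Species A genes
#' are built from random sequence; species B genes are derived from them
#' by substitutions, indels and structural events, then re-laid-out on
#' fresh chromosomes with resampled introns so only sequence and exon
#' order — not genomic coordinates — carry across, as in real data.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_genes Number of orthologous gene pairs.
#' @param exons_per_gene Range (min, max) of exon regions per gene.
#' @param exon_len,intron_len Ranges (bp) for region and intron lengths.
#' @param utr5_exons,utr3_exons Number of pure-UTR regions at each end.
#' @param n_isoforms Range of transcripts per gene.
#' @param p_alt_boundary Per extra isoform, probability of replacing one
#'   internal exon with a 5'-shifted boundary variant (creates overlapping
#'   exon variants that merge into one united exon).
#' @param alt_shift Range (bp) of the boundary shift.
#' @param p_skip_exon Per extra isoform, probability of skipping one
#'   internal exon.
#' @param substitution_rate Per-base substitution probability in species B.
#' @param indel_rate Per-base probability that an indel event starts.
#' @param indel_len Range (bp) of indel lengths.
#' @param cds_indel_mod3 Restrict indel lengths in pure-CDS regions to
#'   multiples of three (frame-preserving), emulating the reading-frame
#'   conservation seen between real orthologous coding exons.
#' @param n_fission Exact number of exon fission events (one exon in A,
#'   several adjacent exons in B) planted across the dataset.
#' @param fission_k Possible piece counts for fission events.
#' @param fission_k_prob Sampling weights over `fission_k`.
#' @param n_decoy Exact number of fission decoys: the region is cut as for
#'   a fission, but every piece after the first is replaced by unrelated
#'   random sequence, so no fused/split event should be detected.
#' @param p_exon_duplication Per eligible CDS region, probability of a
#'   tandem duplication in species B (a one-to-multi case).
#' @param p_species_specific Per gene, probability of inserting a novel
#'   species-B-specific exon, and independently of deleting one region
#'   from B (leaving a species-A-specific exon).
#' @param utr_bias Probability that a species-specific event falls in a
#'   UTR region rather than anywhere eligible.
#' @param p_noncoding Per gene, probability of being non-coding (no CDS).
#' @param p_gene_duplication Per gene, probability of an extra species-B
#'   gene copy, giving a one-to-multi gene pair (two rows in the pair
#'   table sharing the A gene).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_genes = 50,
                         exons_per_gene = c(4, 9),
                         exon_len = c(60, 300), intron_len = c(80, 400),
                         utr5_exons = 1, utr3_exons = 1,
                         n_isoforms = c(1, 3), p_alt_boundary = 0.6,
                         alt_shift = c(9, 30), p_skip_exon = 0.3,
                         substitution_rate = 0.05, indel_rate = 0,
                         indel_len = c(1, 9), cds_indel_mod3 = TRUE,
                         n_fission = 0, fission_k = c(2, 3),
                         fission_k_prob = c(0.5, 0.5), n_decoy = 0,
                         p_exon_duplication = 0, p_species_specific = 0,
                         utr_bias = 0.7, p_noncoding = 0,
                         p_gene_duplication = 0) {
  stopifnot(length(exons_per_gene) == 2, exons_per_gene[1] >= 3,
            exons_per_gene[1] <= exons_per_gene[2],
            exon_len[1] >= 30, intron_len[1] >= 20,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            all(fission_k >= 2), length(fission_k_prob) == length(fission_k),
            n_fission >= 0, n_decoy >= 0,
            p_exon_duplication >= 0, p_exon_duplication <= 1,
            p_species_specific >= 0, p_species_specific <= 1,
            p_noncoding >= 0, p_noncoding <= 1,
            p_gene_duplication >= 0, p_gene_duplication <= 1)
  if (exons_per_gene[1] < utr5_exons + utr3_exons + 2)
    stop("exons_per_gene too small for the requested UTR exon counts")
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence with substitutions and indels
#'
#' Substitutions occur per base at `cfg$substitution_rate` (always to a
#' different base).  Indel events start per base at `cfg$indel_rate`;
#' lengths are drawn from `cfg$indel_len`, restricted to multiples of
#' three when `in_cds` and `cfg$cds_indel_mod3` are set.  Events are
#' spaced so deletions never overlap, keeping the net length change equal
#' to the sum of the drawn signed lengths.
#'
#' @param seq Input sequence (character scalar).
#' @param cfg A [synth_config()].
#' @param in_cds Is this a pure coding region?
#' @return A list: `seq` (mutated), `map` (integer vector mapping 0-based
#'   boundary offsets `0..nchar(seq)` into the mutated sequence, as
#'   `map[x + 1]`), `delta` (net length change).
#' @export
mutate_sequence <- function(seq, cfg, in_cds = FALSE) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sub_at <- which(stats::runif(n) < cfg$substitution_rate)
  for (p in sub_at) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  del <- logical(n)
  ins <- character(n)
  if (cfg$indel_rate > 0) {
    starts <- which(stats::runif(n) < cfg$indel_rate)
    maxlen <- cfg$indel_len[2]
    kept <- integer(0)
    last <- -Inf
    for (p in starts) {         # space events so deletions cannot overlap
      if (p - last > maxlen) { kept <- c(kept, p); last <- p }
    }
    for (p in kept) {
      L <- sample(seq(cfg$indel_len[1], cfg$indel_len[2]), 1)
      if (in_cds && cfg$cds_indel_mod3) {
        L <- 3L * sample(seq_len(max(1L, cfg$indel_len[2] %/% 3L)), 1)
      }
      if (stats::runif(1) < 0.5) {            # deletion
        p2 <- min(p, n - L + 1L)
        if (p2 >= 1) del[p2:(p2 + L - 1L)] <- TRUE
      } else {
        ins[p] <- .rand_dna(L)
      }
    }
  }
  emitted <- as.integer(!del) + nchar(ins)
  cum <- c(0L, cumsum(emitted))
  pieces <- ifelse(del, "", ch)
  out <- paste0(paste0(pieces, ins), collapse = "")
  list(seq = out, map = cum, delta = nchar(out) - n)
}

#' Plant an exon fission event
#'
#' Cuts a sequence into `k` pieces at `k - 1` random interior points; the
#' total exonic sequence is conserved, so the 5% length criterion of
#' fused/split detection holds by construction.  Each cut leaves at least
#' 30 bp per piece.
#'
#' @param seq The exon sequence (length at least `k * 30`).
#' @param k Number of pieces.
#' @return Character vector of the `k` piece sequences, in order.
#' @export
plant_fission <- function(seq, k) {
  n <- nchar(seq)
  if (n < k * 30) stop("exon too short to split into ", k, " pieces")
  cuts <- sort(sample(seq(30, n - 30), k - 1))
  while (k > 2 && any(diff(cuts) < 30)) {
    cuts <- sort(sample(seq(30, n - 30), k - 1))
  }
  bounds <- c(0, cuts, n)
  vapply(seq_len(k), function(i)
    substr(seq, bounds[i] + 1, bounds[i + 1]), "")
}

# Lay out regions on a fresh chromosome with random introns and flanks.
# Regions are given in transcript orientation; returns the chromosome
# sequence and per-region 0-based forward-strand genomic intervals.
.layout_gene <- function(region_seqs, strand, intron_len) {
  n <- length(region_seqs)
  flank5 <- .rand_dna(sample(seq(intron_len[1], intron_len[2]), 1))
  introns <- vapply(seq_len(max(0, n - 1)), function(i)
    .rand_dna(sample(seq(intron_len[1], intron_len[2]), 1)), "")
  parts <- character(0)
  starts <- integer(n); ends <- integer(n)
  pos <- nchar(flank5)
  parts <- flank5
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + nchar(region_seqs[i])
    ends[i] <- pos
    parts <- c(parts, region_seqs[i])
    if (i < n) { parts <- c(parts, introns[i]); pos <- pos + nchar(introns[i]) }
  }
  flank3 <- .rand_dna(sample(seq(intron_len[1], intron_len[2]), 1))
  parts <- c(parts, flank3)
  chrom_seq <- paste(parts, collapse = "")
  L <- nchar(chrom_seq)
  if (strand == "-") {
    chrom_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chrom_seq)))
    tmp <- starts
    starts <- L - ends
    ends <- L - tmp
  }
  list(chrom_seq = chrom_seq, starts = starts, ends = ends, L = L)
}

# Genomic interval of an exon given its region's forward layout interval
# and 0-based offsets within the region (transcript orientation).
.exon_interval <- function(rstart, rend, strand, off_a, off_b) {
  if (strand == "-") c(rend - off_b, rend - off_a)
  else c(rstart + off_a, rstart + off_b)
}

#' Generate a synthetic two-species ortholog dataset with planted truth
#'
#' Builds `cfg$n_genes` species-A genes from random sequence, derives the
#' orthologous species-B genes by applying the configured mutations and
#' structural events, and writes all standard pipeline inputs to
#' `out_dir`: refFlat annotation and genome FASTA for each species, the
#' gene-pair TSV, and the planted truth as JSON.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return A list of class `synth_dataset`: `files` (named paths),
#'   `truth` (data.frame: `pair_id`, `gene_a`, `gene_b`, `rank_a`,
#'   `rank_b`, `label` — one of conserved, duplicated, fused, split,
#'   species_specific, diverged — `event`, `delta_len`, `region_type`),
#'   and `cfg`.
#' @export
generate_dataset <- function(cfg, out_dir = tempfile("synthdata")) {
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_struct_eligible_needed <- cfg$n_fission + cfg$n_decoy
  genes <- vector("list", cfg$n_genes)
  # --- species A structures -------------------------------------------------
  for (g in seq_len(cfg$n_genes)) {
    gid_a <- sprintf("GA%04d", g)
    gid_b <- sprintf("GB%04d", g)
    n_r <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
    lens <- sample(seq(cfg$exon_len[1], cfg$exon_len[2]), n_r,
                   replace = TRUE)
    seqs <- vapply(lens, .rand_dna, "")
    noncoding <- stats::runif(1) < cfg$p_noncoding
    ics <- cfg$utr5_exons + 1L
    ice <- n_r - cfg$utr3_exons
    type <- rep("CDS", n_r)
    type[seq_len(cfg$utr5_exons)] <- "UTR5"
    if (cfg$utr3_exons > 0)
      type[seq(n_r - cfg$utr3_exons + 1L, n_r)] <- "UTR3"
    type[ics] <- "UTR5_CDS"
    type[ice] <- "CDS_UTR3"
    if (noncoding) type <- rep("no_CDS", n_r)
    o5 <- sample(seq(10, lens[ics] - 10), 1)
    o3 <- sample(seq(10, lens[ice] - 10), 1)
    cds_len <- (lens[ics] - o5) + sum(lens[seq_len(n_r) > ics &
                                            seq_len(n_r) < ice]) + o3
    o3 <- o3 - cds_len %% 3L           # keep the CDS a whole codon count
    while (o3 < 12) o3 <- o3 + 3L      # keep the stop well inside its exon
    # isoforms: list of exon tables (region index, 0-based offsets)
    full_tx <- data.frame(region = seq_len(n_r), off_a = 0L, off_b = lens)
    txs <- list(full_tx)
    n_iso <- sample(seq(cfg$n_isoforms[1], cfg$n_isoforms[2]), 1)
    internal <- setdiff(seq_len(n_r), c(1, n_r, ics, ice))
    variant_regions <- integer(0)
    for (k in seq_len(max(0, n_iso - 1))) {
      tx <- full_tx
      if (length(internal) > 0 && stats::runif(1) < cfg$p_alt_boundary) {
        ri <- internal[sample.int(length(internal), 1)]
        d <- sample(seq(cfg$alt_shift[1], cfg$alt_shift[2]), 1)
        if (lens[ri] - d >= 30) {
          tx$off_a[ri] <- d
          variant_regions <- c(variant_regions, ri)
        }
      }
      if (length(internal) > 1 && stats::runif(1) < cfg$p_skip_exon) {
        ri <- internal[sample.int(length(internal), 1)]
        tx <- tx[tx$region != ri, , drop = FALSE]
      }
      txs[[length(txs) + 1L]] <- tx
    }
    genes[[g]] <- list(gid_a = gid_a, gid_b = gid_b, n_r = n_r,
                       lens = lens, seqs = seqs, type = type,
                       ics = ics, ice = ice, o5 = o5, o3 = o3,
                       noncoding = noncoding, txs = txs,
                       variant_regions = unique(variant_regions))
  }
  # --- choose structural event targets across the dataset -------------------
  eligible <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(g) {
    gn <- genes[[g]]
    ri <- which(gn$type == "CDS" &
                !(seq_len(gn$n_r) %in% gn$variant_regions) &
                gn$lens >= max(cfg$fission_k) * 45)
    if (length(ri) == 0) return(NULL)
    data.frame(g = g, region = ri)
  }))
  n_el <- if (is.null(eligible)) 0L else nrow(eligible)
  if (n_el < n_struct_eligible_needed)
    stop("not enough eligible CDS regions for the requested fission/decoy ",
         "events (", n_el, " < ", n_struct_eligible_needed, ")")
  ev_rows <- if (n_struct_eligible_needed > 0)
    eligible[sample.int(n_el, n_struct_eligible_needed), , drop = FALSE]
  else NULL
  fission_tab <- if (cfg$n_fission > 0)
    ev_rows[seq_len(cfg$n_fission), , drop = FALSE] else NULL
  decoy_tab <- if (cfg$n_decoy > 0)
    ev_rows[cfg$n_fission + seq_len(cfg$n_decoy), , drop = FALSE] else NULL
  # --- derive species B, lay out both species, emit files -------------------
  refflat_a <- character(0); refflat_b <- character(0)
  genome_a <- list(); genome_b <- list()
  pair_rows <- list(); truth_rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    gn <- genes[[g]]
    strand_a <- sample(c("+", "-"), 1)
    lay_a <- .layout_gene(gn$seqs, strand_a, cfg$intron_len)
    chrom_a <- sprintf("chrA_%04d", g)
    genome_a[[chrom_a]] <- lay_a$chrom_seq
    refflat_a <- c(refflat_a,
                   .emit_refflat(gn, gn$gid_a, chrom_a, strand_a, lay_a,
                                 b_side = NULL))
    pid <- sprintf("pair%04d", g)
    n_copies <- 1L + (stats::runif(1) < cfg$p_gene_duplication)
    for (copy in seq_len(n_copies)) {
      gid_b <- if (copy == 1) gn$gid_b else paste0(gn$gid_b, "d")
      this_pid <- if (copy == 1) pid else paste0(pid, "d")
      fiss <- if (copy == 1 && !is.null(fission_tab))
        fission_tab$region[fission_tab$g == g] else integer(0)
      deco <- if (copy == 1 && !is.null(decoy_tab))
        decoy_tab$region[decoy_tab$g == g] else integer(0)
      b <- .derive_b(gn, cfg, fiss, deco)
      strand_b <- sample(c("+", "-"), 1)
      lay_b <- .layout_gene(b$seqs, strand_b, cfg$intron_len)
      chrom_b <- sprintf("chrB_%04d%s", g, if (copy == 1) "" else "d")
      genome_b[[chrom_b]] <- lay_b$chrom_seq
      refflat_b <- c(refflat_b,
                     .emit_refflat(gn, gid_b, chrom_b, strand_b, lay_b,
                                   b_side = b))
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(pair_id = this_pid, gene_a = gn$gid_a, gene_b = gid_b,
                   stringsAsFactors = FALSE)
      tr <- b$truth
      tr$pair_id <- this_pid
      tr$gene_a <- gn$gid_a
      tr$gene_b <- gid_b
      truth_rows[[length(truth_rows) + 1L]] <- tr
    }
  }
  truth <- do.call(rbind, truth_rows)
  truth <- truth[, c("pair_id", "gene_a", "gene_b", "rank_a", "rank_b",
                     "label", "event", "delta_len", "region_type")]
  rownames(truth) <- NULL
  pairs <- do.call(rbind, pair_rows)
  files <- list(
    pairs = file.path(out_dir, "pairs.tsv"),
    ann_a = file.path(out_dir, "species_a.refFlat"),
    ann_b = file.path(out_dir, "species_b.refFlat"),
    genome_a = file.path(out_dir, "species_a.fa"),
    genome_b = file.path(out_dir, "species_b.fa"),
    truth = file.path(out_dir, "truth.json"))
  utils::write.table(pairs[, c("gene_a", "gene_b", "pair_id")], files$pairs,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(refflat_a, files$ann_a)
  writeLines(refflat_b, files$ann_b)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome_a)), files$genome_a, width = 80)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome_b)), files$genome_b, width = 80)
  jsonlite::write_json(truth, files$truth, digits = NA)
  structure(list(files = files, truth = truth, pairs = pairs, cfg = cfg),
            class = "synth_dataset")
}

# Derive the species-B region list from a species-A gene structure.
# Returns one descriptor per B region (parallel to the region/sequence
# list), the deleted A regions, and planted-truth rows.  Descriptor kinds:
# conserved, dup (tandem copy), fission_piece, novel.
.derive_b <- function(gn, cfg, fission_regions, decoy_regions) {
  n_r <- gn$n_r
  # per-gene species-specific events
  ins_new <- stats::runif(1) < cfg$p_species_specific
  del_region <- NA_integer_
  if (stats::runif(1) < cfg$p_species_specific) {
    pure_utr <- which(gn$type %in% c("UTR5", "UTR3"))
    pure_cds <- setdiff(which(gn$type == "CDS"),
                        c(fission_regions, decoy_regions,
                          gn$variant_regions))
    pool <- if (length(pure_utr) > 0 && stats::runif(1) < cfg$utr_bias)
      pure_utr else c(pure_utr, pure_cds)
    if (length(pool) > 0) del_region <- pool[sample.int(length(pool), 1)]
  }
  dup_regions <- integer(0)
  if (cfg$p_exon_duplication > 0) {
    pool <- setdiff(which(gn$type == "CDS"),
                    c(fission_regions, decoy_regions, gn$variant_regions,
                      del_region))
    dup_regions <- pool[stats::runif(length(pool)) < cfg$p_exon_duplication]
  }
  b_seqs <- character(0)
  b_src <- list()     # one descriptor per B region, parallel to b_seqs
  deleted <- integer(0)
  for (i in seq_len(n_r)) {
    if (!is.na(del_region) && i == del_region) {
      deleted <- c(deleted, i)
      next
    }
    if (i %in% fission_regions || i %in% decoy_regions) {
      is_decoy <- i %in% decoy_regions
      k <- sample(cfg$fission_k, 1, prob = cfg$fission_k_prob)
      pieces <- plant_fission(gn$seqs[i], k)
      # substitutions only: indels would break the total-length
      # conservation that fission events guarantee by construction
      sub_cfg <- cfg
      sub_cfg$indel_rate <- 0
      pieces <- vapply(pieces, function(p)
        mutate_sequence(p, sub_cfg, in_cds = FALSE)$seq, "")
      if (is_decoy && k >= 2) {
        for (j in seq(2, k)) pieces[j] <- .rand_dna(nchar(pieces[j]))
      }
      for (p in seq_len(k)) {
        b_seqs <- c(b_seqs, pieces[p])
        b_src[[length(b_src) + 1L]] <-
          list(a_region = i, kind = "fission_piece", piece = p, k = k,
               decoy = is_decoy)
      }
      next
    }
    n_copies <- if (i %in% dup_regions) 2L else 1L
    for (copy in seq_len(n_copies)) {
      m <- mutate_sequence(gn$seqs[i], cfg, in_cds = gn$type[i] == "CDS")
      b_seqs <- c(b_seqs, m$seq)
      b_src[[length(b_src) + 1L]] <-
        list(a_region = i, kind = if (n_copies == 2) "dup" else "conserved",
             map = m$map, delta = m$delta)
    }
  }
  if (ins_new) {
    # novel species-specific exon, placement biased toward UTR-side slots
    newlen <- sample(seq(cfg$exon_len[1], cfg$exon_len[2]), 1)
    slot <- if (stats::runif(1) < cfg$utr_bias) {
      if (stats::runif(1) < 0.5) 0L else length(b_seqs)
    } else sample(0:length(b_seqs), 1)
    b_seqs <- append(b_seqs, .rand_dna(newlen), after = slot)
    b_src <- append(b_src,
                    list(list(a_region = NA_integer_, kind = "novel")),
                    after = slot)
  }
  truth <- list()
  for (j in seq_along(b_src)) {
    s <- b_src[[j]]
    truth[[length(truth) + 1L]] <- switch(s$kind,
      conserved = data.frame(rank_a = s$a_region, rank_b = j,
        label = "conserved", event = "none", delta_len = s$delta,
        region_type = gn$type[s$a_region], stringsAsFactors = FALSE),
      dup = data.frame(rank_a = s$a_region, rank_b = j,
        label = "duplicated", event = "duplication", delta_len = s$delta,
        region_type = gn$type[s$a_region], stringsAsFactors = FALSE),
      fission_piece = data.frame(rank_a = s$a_region, rank_b = j,
        label = if (s$decoy) "diverged" else "split",
        event = if (s$decoy) "decoy" else "fission",
        delta_len = NA_real_, region_type = gn$type[s$a_region],
        stringsAsFactors = FALSE),
      novel = data.frame(rank_a = NA_integer_, rank_b = j,
        label = "species_specific", event = "gain", delta_len = NA_real_,
        region_type = NA_character_, stringsAsFactors = FALSE))
  }
  for (i in deleted) {
    truth[[length(truth) + 1L]] <- data.frame(
      rank_a = i, rank_b = NA_integer_, label = "species_specific",
      event = "loss", delta_len = NA_real_, region_type = gn$type[i],
      stringsAsFactors = FALSE)
  }
  list(seqs = b_seqs, src = b_src, deleted = deleted,
       truth = do.call(rbind, truth))
}

# refFlat lines for one gene. For species A (b_side NULL) exon offsets come
# straight from the isoform tables; for species B each A exon is mapped
# through the derivation descriptors (deleted regions dropped, fission
# regions expanded to their pieces, offsets passed through the indel map).
.emit_refflat <- function(gn, gid, chrom, strand, lay, b_side = NULL) {
  region_of_b <- list()
  if (!is.null(b_side)) {
    for (j in seq_along(b_side$src)) {
      s <- b_side$src[[j]]
      if (is.na(s$a_region)) next
      key <- as.character(s$a_region)
      region_of_b[[key]] <- c(region_of_b[[key]], j)
    }
  }
  lines <- character(0)
  for (t in seq_along(gn$txs)) {
    tx <- gn$txs[[t]]
    iv <- list()
    for (r in seq_len(nrow(tx))) {
      i <- tx$region[r]; a <- tx$off_a[r]; b2 <- tx$off_b[r]
      if (is.null(b_side)) {
        iv[[length(iv) + 1L]] <-
          .exon_interval(lay$starts[i], lay$ends[i], strand, a, b2)
      } else {
        for (j in region_of_b[[as.character(i)]]) {
          s <- b_side$src[[j]]
          if (s$kind == "fission_piece") {
            # fission targets have only full-span exons; emit the piece
            iv[[length(iv) + 1L]] <- c(lay$starts[j], lay$ends[j])
          } else {
            a2 <- s$map[a + 1L]; b3 <- s$map[b2 + 1L]
            if (b3 <= a2) next
            iv[[length(iv) + 1L]] <-
              .exon_interval(lay$starts[j], lay$ends[j], strand, a2, b3)
          }
        }
      }
    }
    # species-B novel exon: attach to the first transcript
    if (!is.null(b_side) && t == 1) {
      for (j in seq_along(b_side$src)) {
        if (b_side$src[[j]]$kind == "novel")
          iv[[length(iv) + 1L]] <- c(lay$starts[j], lay$ends[j])
      }
    }
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    m <- m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
    cds <- .tx_cds(gn, strand, lay, b_side)
    lines <- c(lines, paste(
      gid, sprintf("%s_T%02d", gid, t), chrom, strand,
      min(m[, 1]), max(m[, 2]), cds[1], cds[2], nrow(m),
      paste0(paste(m[, 1], collapse = ","), ","),
      paste0(paste(m[, 2], collapse = ","), ","), sep = "\t"))
  }
  lines
}

# Genomic CDS interval (refFlat convention: start == end for non-coding).
.tx_cds <- function(gn, strand, lay, b_side) {
  if (gn$noncoding) {
    z <- min(lay$starts)
    return(c(z, z))
  }
  ics <- gn$ics; ice <- gn$ice
  o5 <- gn$o5; o3 <- gn$o3
  if (is.null(b_side)) {
    i5 <- ics; i3 <- ice
  } else {
    i5 <- NA_integer_; i3 <- NA_integer_
    for (j in seq_along(b_side$src)) {
      s <- b_side$src[[j]]
      if (is.na(s$a_region)) next
      if (s$a_region == ics && s$kind %in% c("conserved", "dup") &&
          is.na(i5)) { i5 <- j; o5 <- s$map[gn$o5 + 1L] }
      if (s$a_region == ice && s$kind %in% c("conserved", "dup") &&
          is.na(i3)) { i3 <- j; o3 <- s$map[gn$o3 + 1L] }
    }
    if (is.na(i5) || is.na(i3))
      stop("internal: CDS boundary region lost in species-B derivation")
  }
  p5 <- .exon_interval(lay$starts[i5], lay$ends[i5], strand, o5, o5 + 1L)
  p3 <- .exon_interval(lay$starts[i3], lay$ends[i3], strand, o3 - 1L, o3)
  c(min(p5[1], p3[1]), max(p5[2], p3[2]))
}
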