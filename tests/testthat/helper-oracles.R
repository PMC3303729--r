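# Independent reference implementations used to cross-check the package.
# These are deliberately naive (full matrices, explicit loops) and share
# only the documented determinism contract with the production code.

# Full-matrix Gotoh local alignment in plain R. Returns score and 1-based
# spans under the same deterministic rule as the production aligner: the
# endpoint is the first maximal cell in row-major order; ties while filling
# prefer diagonal, then gap-in-subject (up), then gap-in-query (left); gap
# states prefer opening over extending on ties.
oracle_sw <- function(q, s, score_fun, gap_open, gap_extend) {
  n <- length(q); m <- length(s)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in query (left)
  F <- matrix(NEG, n + 1, m + 1)   # gap in subject (up)
  pH <- matrix(0L, n + 1, m + 1)   # 0 stop, 1 diag, 2 from F, 3 from E
  pE <- matrix(0L, n + 1, m + 1)   # 0 open, 1 extend
  pF <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      fo <- H[i - 1, j] - gap_open - gap_extend
      fe <- F[i - 1, j] - gap_extend
      if (fo >= fe) { F[i, j] <- fo; pF[i, j] <- 0L }
      else          { F[i, j] <- fe; pF[i, j] <- 1L }
      eo <- H[i, j - 1] - gap_open - gap_extend
      ee <- E[i, j - 1] - gap_extend
      if (eo >= ee) { E[i, j] <- eo; pE[i, j] <- 0L }
      else          { E[i, j] <- ee; pE[i, j] <- 1L }
      d <- H[i - 1, j - 1] + score_fun(q[i - 1], s[j - 1])
      h <- d; p <- 1L
      if (F[i, j] > h) { h <- F[i, j]; p <- 2L }
      if (E[i, j] > h) { h <- E[i, j]; p <- 3L }
      if (h <= 0) { h <- 0; p <- 0L }
      H[i, j] <- h; pH[i, j] <- p
      if (h > best + 1e-9) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0)
    return(list(score = 0, q_start = NA, q_end = NA, s_start = NA,
                s_end = NA))
  i <- bi; j <- bj; state <- 0L
  repeat {
    if (state == 0L) {
      p <- pH[i, j]
      if (p == 0L) break
      if (p == 1L) { i <- i - 1; j <- j - 1 }
      else if (p == 2L) state <- 1L
      else state <- 2L
    } else if (state == 1L) {
      p <- pF[i, j]; i <- i - 1
      if (p == 0L) state <- 0L
    } else {
      p <- pE[i, j]; j <- j - 1
      if (p == 0L) state <- 0L
    }
  }
  list(score = best, q_start = i, q_end = bi - 1, s_start = j,
       s_end = bj - 1)
}

oracle_sw_nt <- function(qs, ss, match = 1, mismatch = -2, gap_open = 2,
                         gap_extend = 2) {
  q <- strsplit(qs, "")[[1]]
  s <- strsplit(ss, "")[[1]]
  oracle_sw(q, s, function(a, b) {
    if (a %in% c("N") || b %in% c("N") || a != b) mismatch else match
  }, gap_open, gap_extend)
}

# Exhaustive best-reciprocal-hit enumeration over a directed hit table:
# for every (x, y) pair check out-degree-1 and mutual single hits.
oracle_brh <- function(hits) {
  ab <- hits[hits$direction == "ab", , drop = FALSE]
  ba <- hits[hits$direction == "ba", , drop = FALSE]
  out <- list()
  for (x in unique(ab$query_exon)) {
    hx <- ab[ab$query_exon == x, , drop = FALSE]
    if (nrow(hx) != 1) next
    y <- hx$subject_exon
    hy <- ba[ba$query_exon == y, , drop = FALSE]
    if (nrow(hy) == 1 && hy$subject_exon == x)
      out[[length(out) + 1L]] <- c(x, y)
  }
  if (length(out) == 0)
    return(data.frame(a = character(), b = character()))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

# Union-find labelling of overlap components of a set of intervals
# (0-based half-open). Abutting intervals do not overlap.
oracle_components <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && start[i] < end[j] && start[j] < end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Build a minimal united_exons object directly (one exon per united exon)
# for constructing assignment-stage fixtures without running the merger.
make_ue <- function(gene, lens, strand = "+") {
  n <- length(lens)
  u <- data.frame(uexon_id = sprintf("%s:U%02d", gene, seq_len(n)),
                  gene_id = gene, chrom = paste0("chr_", gene),
                  strand = strand, start = cumsum(c(0, head(lens, -1) + 100)),
                  rank = seq_len(n), n_members = 1L,
                  stringsAsFactors = FALSE)
  u$end <- u$start + lens
  u$length <- lens
  m <- data.frame(uexon_id = u$uexon_id,
                  exon_id = sprintf("%s:E%03d", gene, seq_len(n)),
                  stringsAsFactors = FALSE)
  structure(list(uexons = u, members = m), class = "united_exons")
}

# Directed hit rows for fixtures (scores/spans filled with plausible
# values; the assignment stages only consult evalue, identity and spans).
make_hit <- function(pair_id, qe, se, direction, evalue = 1e-20,
                     q_len = 100, s_len = 100, method = "nt") {
  data.frame(pair_id = pair_id, query_exon = qe, subject_exon = se,
             direction = direction, method = method, score = 50,
             evalue = evalue, q_start = 1L, q_end = as.integer(q_len),
             s_start = 1L, s_end = as.integer(s_len), identity = 0.95,
             stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Random coding sequence built from fourfold-degenerate codons, plus a
# copy diverged only at third codon positions (peptide conserved).
fourfold_pair <- function(n_codons) {
  stems <- c("GC", "GG", "GT", "CC", "CT", "CG", "TC", "AC")
  st <- sample(stems, n_codons, replace = TRUE)
  third <- sample(c("A", "C", "G", "T"), n_codons, replace = TRUE)
  third2 <- vapply(third, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  list(q = paste0(paste0(st, third), collapse = ""),
       s = paste0(paste0(st, third2), collapse = ""))
}
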