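#' Merge overlapping exon variants into united exons
#'
#' Exons of one gene that share at least one base are merged transitively;
#' the merged span is the interval union (minimum start, maximum end) of
#' the overlap component, so alternative acceptor/donor variants collapse
#' to the longest common region.  Exons that merely abut (one's end equals
#' the other's start) are not merged.  United exons are ranked 5' to 3'
#' and carry IDs `<gene>:U<rank>`.
#'
#' @param ann An `exon_annotation` (see [read_annotation()]).
#' @return A list of class `united_exons` with data.frames `uexons`
#'   (`uexon_id`, `gene_id`, `chrom`, `strand`, `start`, `end`, `rank`,
#'   `n_members`, `length`) and `members` (`uexon_id`, `exon_id`).
#' @export
build_united_exons <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0) {
    return(structure(list(
      uexons = data.frame(uexon_id = character(), gene_id = character(),
                          chrom = character(), strand = character(),
                          start = numeric(), end = numeric(),
                          rank = integer(), n_members = integer(),
                          length = numeric()),
      members = data.frame(uexon_id = character(), exon_id = character())),
      class = "united_exons"))
  }
  per_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  res <- lapply(per_gene, function(idx) {
    e <- ex[idx, , drop = FALSE]
    ir <- IRanges::IRanges(start = e$start + 1L, end = e$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE, min.gapwidth = 0L)
    revmap <- S4Vectors::mcols(red)$revmap
    n <- length(red)
    r <- seq_len(n)
    if (e$strand[1] == "-") r <- rev(r)
    u <- data.frame(uexon_id = sprintf("%s:U%02d", e$gene_id[1], r),
                    gene_id = e$gene_id[1], chrom = e$chrom[1],
                    strand = e$strand[1],
                    start = BiocGenerics::start(red) - 1L,
                    end = BiocGenerics::end(red),
                    rank = r,
                    n_members = lengths(revmap),
                    stringsAsFactors = FALSE)
    m <- data.frame(uexon_id = rep(u$uexon_id, lengths(revmap)),
                    exon_id = e$exon_id[unlist(revmap)],
                    stringsAsFactors = FALSE)
    list(u = u, m = m)
  })
  uexons <- do.call(rbind, lapply(res, `[[`, "u"))
  members <- do.call(rbind, lapply(res, `[[`, "m"))
  rownames(uexons) <- rownames(members) <- NULL
  uexons$length <- uexons$end - uexons$start
  structure(list(uexons = uexons, members = members), class = "united_exons")
}

#' @export
print.united_exons <- function(x, ...) {
  cat(sprintf("united_exons: %d united exons over %d genes (%d members)\n",
              nrow(x$uexons), length(unique(x$uexons$gene_id)),
              nrow(x$members)))
  invisible(x)
}

#' Map an exon to its united exon
#'
#' @param ue A `united_exons` object.
#' @param exon_id Exon ID(s).
#' @return The united-exon ID(s); unknown exons are an error.
#' @export
uexon_of <- function(ue, exon_id) {
  i <- match(exon_id, ue$members$exon_id)
  if (anyNA(i))
    stop("unknown exon(s): ", paste(exon_id[is.na(i)], collapse = ", "))
  ue$members$uexon_id[i]
}

.region_levels <- c("UTR5", "UTR5_CDS", "CDS", "CDS_UTR3", "UTR3", "SLR",
                    "no_CDS")

#' Classify united exons into gene-region categories
#'
#' Uses the union CDS span of the gene (minimum `cds_start`, maximum
#' `cds_end` over its coding transcripts).  Six categories for coding
#' genes: `UTR5` (entirely 5' of the CDS span), `UTR5_CDS` (contains the
#' CDS 5' boundary only), `CDS` (inside the span), `CDS_UTR3`, `UTR3`
#' (symmetric on the 3' side) and `SLR` (single long region, containing
#' both CDS boundaries, i.e. running from 5' UTR through the coding region
#' into the 3' UTR).  Orientation is strand-aware.  Genes with no coding
#' transcript get the sentinel `no_CDS`.
#'
#' @param ue A `united_exons` object.
#' @param ann The matching `exon_annotation`.
#' @return `ue` with a `region` column added to `uexons`.
#' @export
classify_regions <- function(ue, ann) {
  tx <- ann$transcripts
  coding <- tx[!is.na(tx$cds_start), , drop = FALSE]
  span <- if (nrow(coding) > 0) {
    do.call(rbind, lapply(split(coding, coding$gene_id), function(g)
      data.frame(gene_id = g$gene_id[1], cs = min(g$cds_start),
                 ce = max(g$cds_end), stringsAsFactors = FALSE)))
  } else data.frame(gene_id = character(), cs = numeric(), ce = numeric())
  u <- ue$uexons
  m <- match(u$gene_id, span$gene_id)
  cs <- span$cs[m]; ce <- span$ce[m]
  has5 <- u$start < cs & u$end > cs   # contains genomic CDS start boundary
  has3 <- u$start < ce & u$end > ce
  region <- rep(NA_character_, nrow(u))
  region[is.na(cs)] <- "no_CDS"
  ok <- !is.na(cs)
  region[ok & has5 & has3] <- "SLR"
  left_only <- ok & has5 & !has3
  right_only <- ok & !has5 & has3
  inside <- ok & !has5 & !has3 & u$start >= cs & u$end <= ce
  before <- ok & u$end <= cs
  after <- ok & u$start >= ce
  pos <- u$strand != "-"
  region[left_only] <- ifelse(pos[left_only], "UTR5_CDS", "CDS_UTR3")
  region[right_only] <- ifelse(pos[right_only], "CDS_UTR3", "UTR5_CDS")
  region[inside] <- "CDS"
  region[before] <- ifelse(pos[before], "UTR5", "UTR3")
  region[after] <- ifelse(pos[after], "UTR3", "UTR5")
  ue$uexons$region <- factor(region, levels = .region_levels)
  ue
}

#' Extract united-exon sequences (transcript orientation)
#'
#' @param ue A `united_exons` object.
#' @param fasta FASTA path or `DNAStringSet` for the species' genome.
#' @return `ue` with `uexons$seq` populated.
#' @export
united_exon_sequences <- function(ue, fasta) {
  genome <- .load_genome(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  u <- ue$uexons
  miss <- setdiff(unique(u$chrom), names(genome))
  if (length(miss) > 0)
    stop("chromosomes missing from FASTA: ", paste(miss, collapse = ", "))
  v <- Biostrings::DNAStringSet(genome[u$chrom],
                                start = u$start + 1L, end = u$end)
  neg <- u$strand == "-"
  if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
  ue$uexons$seq <- as.character(v)
  ue
}

#' Export united exons as BED6
#'
#' Name is the united-exon ID, score the member count.
#'
#' @param ue A `united_exons` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
uexons_to_bed6 <- function(ue, path) {
  u <- ue$uexons
  utils::write.table(
    data.frame(u$chrom, u$start, u$end, u$uexon_id, u$n_members, u$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export united exons as TSV (rank, region, members)
#'
#' @param ue A `united_exons` object (regions classified if available).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
uexons_to_tsv <- function(ue, path) {
  u <- ue$uexons
  mem <- vapply(split(ue$members$exon_id, ue$members$uexon_id)[u$uexon_id],
                paste, "", collapse = ",")
  out <- data.frame(uexon_id = u$uexon_id, gene_id = u$gene_id,
                    chrom = u$chrom, strand = u$strand, start = u$start,
                    end = u$end, rank = u$rank,
                    region = if ("region" %in% names(u))
                      as.character(u$region) else NA_character_,
                    members = mem, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
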