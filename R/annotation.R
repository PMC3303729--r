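#' Read a gene-ortholog pair table
#'
#' A tab-separated table with two gene-ID columns (`gene_a`, `gene_b`; a
#' header row is detected and optional) and an optional `pair_id` column.
#' One-to-multi gene orthology is represented as several rows, i.e. a gene
#' ID may recur on either side; each row becomes one strictly one-to-one
#' pair.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `pair_id`, `gene_a`, `gene_b`.
#' @export
read_gene_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty gene-pair file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(tolower(fields[[1]][1:2]), c("gene_a", "gene_b"))
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) stop("gene-pair file has a header but no rows: ", path)
  rows <- lapply(seq(start, length(fields)), function(i) {
    f <- fields[[i]]
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]))
      stop("malformed gene-pair row at line ", i, " of ", path)
    f
  })
  ga <- vapply(rows, `[`, "", 1L)
  gb <- vapply(rows, `[`, "", 2L)
  pid <- vapply(rows, function(f) if (length(f) >= 3) f[3] else "", "")
  if (any(!nzchar(pid)))
    pid <- ifelse(nzchar(pid), pid, sprintf("pair%05d", seq_along(ga)))
  data.frame(pair_id = pid, gene_a = ga, gene_b = gb,
             stringsAsFactors = FALSE)
}

#' @rdname read_annotation
#' @format NULL
#' @name exon_annotation
NULL

.new_annotation <- function(transcripts, exons, tx_exon) {
  structure(list(transcripts = transcripts, exons = exons, tx_exon = tx_exon),
            class = "exon_annotation")
}

#' @export
print.exon_annotation <- function(x, ...) {
  cat(sprintf("exon_annotation: %d genes, %d transcripts, %d distinct exons\n",
              length(unique(x$exons$gene_id)), nrow(x$transcripts),
              nrow(x$exons)))
  invisible(x)
}

# Deduplicate exons on (gene_id, interval), assign 5'->3' ranks and stable
# IDs of the form <gene>:E<rank>.  Raw per-transcript exon table in, model out.
.build_model <- function(tx, raw) {
  key <- paste(raw$gene_id, raw$start, raw$end, sep = "\r")
  first <- !duplicated(key)
  ex <- raw[first, c("gene_id", "chrom", "strand", "start", "end")]
  ex <- ex[order(ex$gene_id, ex$start, ex$end), , drop = FALSE]
  # rows are sorted by gene_id, so split() groups align with row order
  ex$rank <- unlist(lapply(split(ex$strand == "-", ex$gene_id), function(neg) {
    n <- length(neg)
    if (neg[1]) rev(seq_len(n)) else seq_len(n)
  }), use.names = FALSE)
  ex$exon_id <- sprintf("%s:E%03d", ex$gene_id, ex$rank)
  rownames(ex) <- NULL
  lk <- match(paste(raw$gene_id, raw$start, raw$end, sep = "\r"),
              paste(ex$gene_id, ex$start, ex$end, sep = "\r"))
  tx_exon <- data.frame(transcript_id = raw$transcript_id,
                        exon_id = ex$exon_id[lk],
                        stringsAsFactors = FALSE)
  .validate_model(tx, ex, tx_exon)
  .new_annotation(tx, ex[, c("exon_id", "gene_id", "chrom", "strand",
                             "start", "end", "rank")], tx_exon)
}

.validate_model <- function(tx, ex, tx_exon) {
  for (i in seq_len(nrow(tx))) {
    if (is.na(tx$cds_start[i])) next
    eids <- tx_exon$exon_id[tx_exon$transcript_id == tx$transcript_id[i]]
    e <- ex[ex$exon_id %in% eids, , drop = FALSE]
    cov_start <- any(e$start <= tx$cds_start[i] & tx$cds_start[i] < e$end)
    cov_end <- any(e$start < tx$cds_end[i] & tx$cds_end[i] <= e$end)
    if (!cov_start || !cov_end)
      stop("CDS outside exons for transcript ", tx$transcript_id[i])
  }
  invisible(TRUE)
}

.parse_refflat <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) < 11) stop("refFlat file must have 11 columns: ", path)
  names(d)[1:11] <- c("gene_id", "transcript_id", "chrom", "strand",
                      "tx_start", "tx_end", "cds_start", "cds_end",
                      "exon_count", "exon_starts", "exon_ends")
  tx <- data.frame(transcript_id = d$transcript_id, gene_id = d$gene_id,
                   chrom = d$chrom, strand = d$strand,
                   cds_start = as.numeric(d$cds_start),
                   cds_end = as.numeric(d$cds_end),
                   stringsAsFactors = FALSE)
  noncoding <- tx$cds_start == tx$cds_end
  tx$cds_start[noncoding] <- NA_real_
  tx$cds_end[noncoding] <- NA_real_
  raw <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    st <- as.numeric(strsplit(d$exon_starts[i], ",", fixed = TRUE)[[1]])
    en <- as.numeric(strsplit(d$exon_ends[i], ",", fixed = TRUE)[[1]])
    if (length(st) != length(en) || any(is.na(st)) || any(is.na(en)))
      stop("malformed exon list at refFlat line ", i)
    data.frame(transcript_id = d$transcript_id[i], gene_id = d$gene_id[i],
               chrom = d$chrom[i], strand = d$strand[i],
               start = st, end = en, stringsAsFactors = FALSE)
  }))
  list(tx = tx, raw = raw)
}

.parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0) stop("no exon records in GTF: ", path)
  exm <- S4Vectors::mcols(ex)
  raw <- data.frame(transcript_id = as.character(exm$transcript_id),
                    gene_id = as.character(exm$gene_id),
                    chrom = as.character(GenomeInfoDb::seqnames(ex)),
                    strand = as.character(BiocGenerics::strand(ex)),
                    start = BiocGenerics::start(ex) - 1L,
                    end = BiocGenerics::end(ex),
                    stringsAsFactors = FALSE)
  cds <- gr[md$type == "CDS"]
  tx_ids <- unique(raw$transcript_id)
  cds_tab <- if (length(cds) > 0) {
    ci <- data.frame(tid = as.character(S4Vectors::mcols(cds)$transcript_id),
                     start = BiocGenerics::start(cds) - 1L,
                     end = BiocGenerics::end(cds))
    do.call(rbind, lapply(split(ci, ci$tid), function(g)
      data.frame(tid = g$tid[1], cds_start = min(g$start),
                 cds_end = max(g$end))))
  } else data.frame(tid = character(), cds_start = numeric(),
                    cds_end = numeric())
  m <- match(tx_ids, cds_tab$tid)
  first <- match(tx_ids, raw$transcript_id)
  tx <- data.frame(transcript_id = tx_ids, gene_id = raw$gene_id[first],
                   chrom = raw$chrom[first], strand = raw$strand[first],
                   cds_start = cds_tab$cds_start[m],
                   cds_end = cds_tab$cds_end[m], stringsAsFactors = FALSE)
  list(tx = tx, raw = raw)
}

.parse_bed12 <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) < 12) stop("BED12 file must have 12+ columns: ", path)
  gene <- if (ncol(d) >= 13) d[[13]] else sub("\\..*$", "", d[[4]])
  tx <- data.frame(transcript_id = d[[4]], gene_id = gene,
                   chrom = d[[1]], strand = d[[6]],
                   cds_start = as.numeric(d[[7]]),
                   cds_end = as.numeric(d[[8]]), stringsAsFactors = FALSE)
  noncoding <- tx$cds_start == tx$cds_end
  tx$cds_start[noncoding] <- NA_real_
  tx$cds_end[noncoding] <- NA_real_
  raw <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    n <- as.integer(d[[10]][i])
    sizes <- as.numeric(strsplit(d[[11]][i], ",", fixed = TRUE)[[1]])[1:n]
    offs <- as.numeric(strsplit(d[[12]][i], ",", fixed = TRUE)[[1]])[1:n]
    if (any(is.na(sizes)) || any(is.na(offs)))
      stop("malformed block list at BED12 line ", i)
    st <- as.numeric(d[[2]][i]) + offs
    data.frame(transcript_id = d[[4]][i], gene_id = gene[i],
               chrom = d[[1]][i], strand = d[[6]][i],
               start = st, end = st + sizes, stringsAsFactors = FALSE)
  }))
  list(tx = tx, raw = raw)
}

#' Read transcript annotation into the internal gene/exon model
#'
#' Supported dialects: UCSC refFlat (11 columns), GTF2.2 and BED12 (with an
#' optional 13th gene-ID column; otherwise the name field, stripped of a
#' trailing `.suffix`, is used as the gene ID).  All coordinates are
#' normalised to 0-based half-open internally (GTF is converted on read).
#' Exons identical in `(gene, interval)` across isoforms are deduplicated
#' into a single record with a stable ID `<gene>:E<rank>`, where ranks run
#' 5' to 3' along the gene (reversed genomic order on the minus strand).
#' Transcripts with `cds_start == cds_end` (refFlat/BED12 convention) or no
#' CDS features (GTF) are treated as non-coding.
#'
#' @param path Annotation file path.
#' @param format One of `"refFlat"`, `"gtf"`, `"bed12"`.
#' @return An `exon_annotation` object: a list with data.frames
#'   `transcripts` (`transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `cds_start`, `cds_end` — NA for non-coding), `exons` (`exon_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `rank`) and `tx_exon`
#'   (`transcript_id`, `exon_id`).
#' @export
read_annotation <- function(path, format = c("refFlat", "gtf", "bed12")) {
  format <- match.arg(format)
  p <- switch(format,
              refFlat = .parse_refflat(path),
              gtf = .parse_gtf(path),
              bed12 = .parse_bed12(path))
  if (any(p$raw$start >= p$raw$end))
    stop("exon with non-positive length in ", path)
  .build_model(p$tx, p$raw)
}

#' Write annotation back out in a supported dialect
#'
#' Inverse of [read_annotation()] up to exon coordinate sets: per-transcript
#' exon coordinates, strand and CDS round-trip exactly in every dialect.
#'
#' @param ann An `exon_annotation`.
#' @param path Output file path.
#' @param format One of `"refFlat"`, `"gtf"`, `"bed12"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("refFlat", "gtf", "bed12")) {
  format <- match.arg(format)
  tx <- ann$transcripts
  ex_of <- split(ann$tx_exon$exon_id, ann$tx_exon$transcript_id)
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    e <- ann$exons[match(ex_of[[tx$transcript_id[i]]], ann$exons$exon_id), ]
    e <- e[order(e$start), , drop = FALSE]
    cs <- if (is.na(tx$cds_start[i])) min(e$start) else tx$cds_start[i]
    ce <- if (is.na(tx$cds_end[i])) min(e$start) else tx$cds_end[i]
    switch(format,
      refFlat = paste(tx$gene_id[i], tx$transcript_id[i], tx$chrom[i],
                      tx$strand[i], min(e$start), max(e$end), cs, ce,
                      nrow(e), paste0(paste(e$start, collapse = ","), ","),
                      paste0(paste(e$end, collapse = ","), ","), sep = "\t"),
      bed12 = paste(tx$chrom[i], min(e$start), max(e$end),
                    tx$transcript_id[i], 0, tx$strand[i], cs, ce, "0,0,0",
                    nrow(e),
                    paste0(paste(e$end - e$start, collapse = ","), ","),
                    paste0(paste(e$start - min(e$start), collapse = ","), ","),
                    tx$gene_id[i], sep = "\t"),
      gtf = {
        feat <- sprintf(
          "%s\torthoexon\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          tx$chrom[i], e$start + 1L, e$end, tx$strand[i],
          tx$gene_id[i], tx$transcript_id[i])
        if (!is.na(tx$cds_start[i])) {
          cde <- e[e$end > tx$cds_start[i] & e$start < tx$cds_end[i], ,
                   drop = FALSE]
          cde$start <- pmax(cde$start, tx$cds_start[i])
          cde$end <- pmin(cde$end, tx$cds_end[i])
          feat <- c(feat, sprintf(
            "%s\torthoexon\tCDS\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            tx$chrom[i], cde$start + 1L, cde$end, tx$strand[i],
            tx$gene_id[i], tx$transcript_id[i]))
        }
        paste(feat, collapse = "\n")
      })
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.load_genome <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(fasta)
  Biostrings::readDNAStringSet(fasta)
}

#' Extract exon sequences from a genome FASTA
#'
#' Fills the `seq` column of the exon table: the genomic slice for each
#' exon interval, reverse-complemented on the minus strand so sequences are
#' in transcript orientation.
#'
#' @param ann An `exon_annotation`.
#' @param fasta Path to a FASTA file, or a `DNAStringSet`.
#' @return `ann` with `exons$seq` populated.
#' @export
extract_exon_sequences <- function(ann, fasta) {
  genome <- .load_genome(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ex <- ann$exons
  miss <- setdiff(unique(ex$chrom), names(genome))
  if (length(miss) > 0)
    stop("chromosomes missing from FASTA: ", paste(miss, collapse = ", "))
  too_far <- ex$end > Biostrings::width(genome)[match(ex$chrom, names(genome))]
  if (any(too_far))
    stop("exon interval beyond sequence end: ",
         paste(ex$exon_id[too_far][1:min(3, sum(too_far))], collapse = ", "))
  v <- Biostrings::DNAStringSet(genome[ex$chrom],
                                start = ex$start + 1L, end = ex$end)
  neg <- ex$strand == "-"
  if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
  ann$exons$seq <- as.character(v)
  ann
}
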