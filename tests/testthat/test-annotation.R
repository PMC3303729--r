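write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("gene-pair tables read one pair per row, duplicates allowed", {
  f <- write_tsv_lines(c("g1\tm1"))
  p <- read_gene_pairs(f)
  expect_equal(nrow(p), 1)
  expect_equal(p$gene_a, "g1")

  f2 <- write_tsv_lines(c("gene_a\tgene_b", "g1\tm1", "g1\tm2"))
  p2 <- read_gene_pairs(f2)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$gene_a, c("g1", "g1"))
  expect_equal(anyDuplicated(p2$pair_id), 0)
})

test_that("duplicated left IDs flatten to several one-to-one pairs", {
  set.seed(21)
  left <- sprintf("gl%03d", 1:93)
  left <- c(left, sample(left, 7))          # 7 recurring left IDs
  right <- sprintf("gr%03d", 1:100)
  f <- write_tsv_lines(paste(sample(left), right, sep = "\t"))
  p <- read_gene_pairs(f)
  expect_equal(nrow(p), 100)
  expect_equal(length(unique(p$gene_a)), 93)
})

test_that("malformed and empty pair files are errors naming the line", {
  expect_error(read_gene_pairs(write_tsv_lines(c("a\tb", "only_one_field"))),
               "line 2")
  f <- tempfile(); file.create(f)
  expect_error(read_gene_pairs(f), "empty")
})

refflat_fixture <- function(strand = "+", cds = c(120, 380)) {
  write_tsv_lines(paste("g1", "t1", "chr1", strand, 100, 400, cds[1],
                        cds[2], 2, "100,300,", "200,400,", sep = "\t"))
}

test_that("refFlat exons parse with strand-aware 5'->3' ranks", {
  ann <- read_annotation(refflat_fixture("+"), "refFlat")
  expect_equal(nrow(ann$exons), 2)
  expect_equal(ann$exons$start, c(100, 300))
  expect_equal(ann$exons$end, c(200, 400))
  expect_equal(ann$exons$rank, c(1, 2))

  annm <- read_annotation(refflat_fixture("-"), "refFlat")
  expect_equal(annm$exons$rank[annm$exons$start == 300], 1)
  expect_equal(annm$exons$rank[annm$exons$start == 100], 2)
})

test_that("GTF coordinates convert to 0-based half-open", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "CDS", 151, 350, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), f)
  ann <- read_annotation(f, "gtf")
  expect_equal(ann$exons$start, c(100, 300))
  expect_equal(ann$exons$end, c(200, 400))
  expect_equal(ann$transcripts$cds_start, 150)
  expect_equal(ann$transcripts$cds_end, 350)
})

test_that("BED12 blocks parse and non-coding transcripts get NA CDS", {
  f <- write_tsv_lines(paste("chr1", 100, 400, "t1", 0, "+", 100, 100,
                             "0,0,0", 2, "100,100,", "0,200,", "g1",
                             sep = "\t"))
  ann <- read_annotation(f, "bed12")
  expect_equal(ann$exons$start, c(100, 300))
  expect_true(is.na(ann$transcripts$cds_start))
  expect_equal(ann$transcripts$gene_id, "g1")
})

test_that("shared exons across isoforms deduplicate into one record", {
  f <- write_tsv_lines(c(
    paste("g1", "t1", "chr1", "+", 100, 400, 120, 380, 2,
          "100,300,", "200,400,", sep = "\t"),
    paste("g1", "t2", "chr1", "+", 100, 400, 120, 380, 2,
          "100,300,", "200,400,", sep = "\t")))
  ann <- read_annotation(f, "refFlat")
  expect_equal(nrow(ann$exons), 2)          # deduplicated
  expect_equal(nrow(ann$tx_exon), 4)        # but both isoforms reference them
})

test_that("a CDS outside the transcript's exons is a validation error", {
  f <- write_tsv_lines(paste("g1", "tbad", "chr1", "+", 100, 400, 250,
                             260, 2, "100,300,", "200,400,", sep = "\t"))
  expect_error(read_annotation(f, "refFlat"), "tbad")
})

test_that("annotation round-trips through every supported dialect", {
  set.seed(31)
  cfg <- synth_config(seed = 31, n_genes = 4)
  ds <- generate_dataset(cfg)
  ann <- read_annotation(ds$files$ann_a, "refFlat")
  for (fmt in c("refFlat", "gtf", "bed12")) {
    f <- tempfile()
    write_annotation(ann, f, fmt)
    back <- read_annotation(f, fmt)
    key <- function(a) sort(paste(a$exons$gene_id, a$exons$start,
                                  a$exons$end))
    expect_equal(key(back), key(ann), info = fmt)
    expect_equal(sort(back$transcripts$transcript_id),
                 sort(ann$transcripts$transcript_id), info = fmt)
  }
})

test_that("exon ranks are a strand-consistent permutation", {
  cfg <- synth_config(seed = 33, n_genes = 6)
  ds <- generate_dataset(cfg)
  for (side in c("ann_a", "ann_b")) {
    ann <- read_annotation(ds$files[[side]], "refFlat")
    for (g in unique(ann$exons$gene_id)) {
      e <- ann$exons[ann$exons$gene_id == g, ]
      expect_setequal(e$rank, seq_len(nrow(e)))
      ord <- order(e$start)
      if (e$strand[1] == "+") expect_true(all(diff(e$rank[ord]) > 0))
      else expect_true(all(diff(e$rank[ord]) < 0))
    }
  }
})

test_that("exon sequences match an independent slice/revcomp oracle", {
  set.seed(41)
  chrom <- rand_dna(10000)
  n <- 50
  starts <- sample(0:9900, n)
  ends <- starts + sample(30:100, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  lines <- vapply(seq_len(n), function(i)
    paste(sprintf("g%02d", i), sprintf("t%02d", i), "chrX", strand[i],
          starts[i], ends[i], starts[i], starts[i], 1,
          paste0(starts[i], ","), paste0(ends[i], ","), sep = "\t"), "")
  ann <- read_annotation(write_tsv_lines(lines), "refFlat")
  genome <- Biostrings::DNAStringSet(c(chrX = chrom))
  ann <- extract_exon_sequences(ann, genome)
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  for (i in seq_len(nrow(ann$exons))) {
    e <- ann$exons[i, ]
    expected <- substr(chrom, e$start + 1, e$end)
    if (e$strand == "-") expected <- revcomp(expected)
    expect_identical(e$seq, expected)
    expect_equal(nchar(e$seq), e$end - e$start)
  }
})

test_that("sequence extraction errors on missing or short chromosomes", {
  f <- refflat_fixture("+")
  ann <- read_annotation(f, "refFlat")
  expect_error(extract_exon_sequences(
    ann, Biostrings::DNAStringSet(c(chrZ = "ACGT"))), "missing")
  expect_error(extract_exon_sequences(
    ann, Biostrings::DNAStringSet(c(chr1 = rand_dna(300)))), "beyond")
})
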