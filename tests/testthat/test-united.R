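# Coding genes get one transcript holding all (disjoint) exons; without a
# CDS each exon variant rides its own transcript, as isoform variants do.
ann_from_exons <- function(gene, starts, ends, strand = "+", cds = NULL) {
  n <- length(starts)
  lines <- if (is.null(cds)) {
    paste(gene, paste0(gene, "_t", seq_len(n)), "chr1", strand,
          starts, ends, starts, starts, 1,
          paste0(starts, ","), paste0(ends, ","), sep = "\t")
  } else {
    o <- order(starts)
    paste(gene, paste0(gene, "_t1"), "chr1", strand,
          min(starts), max(ends), cds[1], cds[2], n,
          paste0(paste(starts[o], collapse = ","), ","),
          paste0(paste(ends[o], collapse = ","), ","), sep = "\t")
  }
  f <- tempfile()
  writeLines(lines, f)
  read_annotation(f, "refFlat")
}

test_that("overlapping exons merge into the interval union", {
  ann <- ann_from_exons("g1", c(100, 150), c(200, 250))
  ue <- build_united_exons(ann)
  expect_equal(nrow(ue$uexons), 1)
  expect_equal(ue$uexons$start, 100)
  expect_equal(ue$uexons$end, 250)
  expect_equal(ue$uexons$n_members, 2)
})

test_that("disjoint exons stay separate, ranked 5' to 3'", {
  ann <- ann_from_exons("g1", c(100, 300), c(200, 400))
  ue <- build_united_exons(ann)
  expect_equal(nrow(ue$uexons), 2)
  expect_equal(ue$uexons$rank, c(1, 2))
  annm <- ann_from_exons("g1", c(100, 300), c(200, 400), strand = "-")
  uem <- build_united_exons(annm)
  expect_equal(uem$uexons$rank[uem$uexons$start == 300], 1)
})

test_that("alternative-acceptor variants sharing the 3' end merge", {
  # two exon variants 20 bp apart at the 5' end
  ann <- ann_from_exons("g1", c(100, 120), c(300, 300))
  ue <- build_united_exons(ann)
  expect_equal(nrow(ue$uexons), 1)
  expect_equal(ue$uexons$start, 100)    # the longer 5' end wins
  expect_equal(ue$uexons$end, 300)
})

test_that("abutting exons are not merged", {
  ann <- ann_from_exons("g1", c(100, 200), c(200, 300))
  ue <- build_united_exons(ann)
  expect_equal(nrow(ue$uexons), 2)
})

test_that("united exons are idempotent under re-merging", {
  set.seed(51)
  starts <- sample(0:2000, 12)
  ends <- starts + sample(50:300, 12, replace = TRUE)
  ann <- ann_from_exons("g1", starts, ends)
  ue <- build_united_exons(ann)
  ann2 <- ann_from_exons("g1", ue$uexons$start, ue$uexons$end)
  ue2 <- build_united_exons(ann2)
  expect_equal(ue2$uexons$start, ue$uexons$start)
  expect_equal(ue2$uexons$end, ue$uexons$end)
})

test_that("uexon_of is total over the gene's exons and errors otherwise", {
  ann <- ann_from_exons("g1", c(100, 150, 500), c(200, 250, 600))
  ue <- build_united_exons(ann)
  for (e in ann$exons$exon_id)
    expect_true(uexon_of(ue, e) %in% ue$uexons$uexon_id)
  merged <- ue$uexons$uexon_id[ue$uexons$n_members == 2]
  mem <- ue$members$exon_id[ue$members$uexon_id == merged]
  expect_equal(unique(uexon_of(ue, mem)), merged)
  expect_error(uexon_of(ue, "nope"), "unknown")
})

test_that("random multi-exon genes match the union-find oracle", {
  set.seed(52)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    starts <- sample(0:3000, n)
    ends <- starts + sample(20:400, n, replace = TRUE)
    ann <- ann_from_exons("g1", starts, ends)
    ue <- build_united_exons(ann)
    # partition: disjoint, membership total
    u <- ue$uexons[order(ue$uexons$start), ]
    if (nrow(u) > 1)
      expect_true(all(u$start[-1] >= u$end[-nrow(u)]))
    expect_setequal(ue$members$exon_id, ann$exons$exon_id)
    expect_equal(anyDuplicated(ue$members$exon_id), 0)
    # oracle comparison on component labels
    e <- ann$exons
    lab <- oracle_components(e$start, e$end)
    got <- uexon_of(ue, e$exon_id)
    expect_equal(length(unique(got)), length(unique(lab)))
    expect_true(all(tapply(got, lab, function(x) length(unique(x))) == 1))
    expect_true(all(tapply(lab, got, function(x) length(unique(x))) == 1))
  }
})

test_that("region classification covers the six coding categories", {
  ann <- ann_from_exons("g1",
                        c(100, 400, 600, 850, 1000),
                        c(300, 550, 700, 950, 1100),
                        cds = c(500, 900))
  ue <- classify_regions(build_united_exons(ann), ann)
  r <- as.character(ue$uexons$region[order(ue$uexons$rank)])
  expect_equal(r, c("UTR5", "UTR5_CDS", "CDS", "CDS_UTR3", "UTR3"))
  # SLR: one exon containing the whole CDS span
  ann2 <- ann_from_exons("g2", 450, 950, cds = c(500, 900))
  ue2 <- classify_regions(build_united_exons(ann2), ann2)
  expect_equal(as.character(ue2$uexons$region), "SLR")
})

test_that("region classification is strand-aware", {
  ann <- ann_from_exons("g1", c(100, 450, 1000), c(300, 950, 1100),
                        strand = "-", cds = c(500, 900))
  ue <- classify_regions(build_united_exons(ann), ann)
  u <- ue$uexons
  # on the minus strand the genomically-left exon is 3'
  expect_equal(as.character(u$region[u$start == 100]), "UTR3")
  expect_equal(as.character(u$region[u$start == 450]), "SLR")
  expect_equal(as.character(u$region[u$start == 1000]), "UTR5")
})

test_that("genes without any coding transcript classify as no_CDS", {
  ann <- ann_from_exons("g1", c(100, 400), c(300, 550))
  ue <- classify_regions(build_united_exons(ann), ann)
  expect_true(all(ue$uexons$region == "no_CDS"))
})

test_that("united-exon exports write BED6 and TSV", {
  ann <- ann_from_exons("g1", c(100, 150), c(200, 250))
  ue <- build_united_exons(ann)
  b <- tempfile(); uexons_to_bed6(ue, b)
  bed <- read.delim(b, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(bed$V5, 2)   # member count as score
  t <- tempfile(); uexons_to_tsv(ue, t)
  tsv <- read.delim(t)
  expect_equal(tsv$members, "g1:E001,g1:E002")
})
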