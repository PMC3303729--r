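test_that("length criterion arithmetic accepts 195 and rejects 180", {
  set.seed(81)
  # fused exon in A; two split exons in B
  s1 <- rand_dna(100); s2 <- rand_dna(100)
  build <- function(fused_len) {
    fused <- substr(paste0(s1, s2), 1, fused_len)
    ue_a <- make_ue("gA", fused_len)
    ue_a$uexons$seq <- fused
    ue_b <- make_ue("gB", c(100, 100))
    ue_b$uexons$seq <- c(s1, s2)
    hits <- rbind(
      make_hit("p", "gB:E001", "gA:E001", "ba", q_len = 100, s_len = 100),
      make_hit("p", "gB:E002", "gA:E001", "ba", q_len = 95, s_len = 95))
    find_fused_split_candidates(hits, ue_a, ue_b)
  }
  ok <- build(195)
  expect_equal(length(ok), 1)
  expect_equal(ok[[1]]$fused_species, "A")
  expect_lt(abs(ok[[1]]$len_delta_frac - 5 / 195), 1e-12)
  expect_equal(length(build(180)), 0)   # 0.111 > 0.05
})

test_that("non-adjacent split exons are rejected", {
  ue_a <- make_ue("gA", 200)
  ue_b <- make_ue("gB", rep(100, 5))
  hits <- rbind(
    make_hit("p", "gB:E003", "gA:E001", "ba", q_len = 100),
    make_hit("p", "gB:E005", "gA:E001", "ba", q_len = 100))
  expect_equal(length(find_fused_split_candidates(hits, ue_a, ue_b)), 0)
})

test_that("aligned-fraction window excludes sparse hit coverage", {
  ue_a <- make_ue("gA", 200)
  ue_b <- make_ue("gB", c(100, 100))
  hits <- rbind(   # only 40+40 of 200 aligned: fraction 0.4 < 0.75
    make_hit("p", "gB:E001", "gA:E001", "ba", q_len = 40),
    make_hit("p", "gB:E002", "gA:E001", "ba", q_len = 40))
  expect_equal(length(find_fused_split_candidates(hits, ue_a, ue_b)), 0)
})

test_that("verification accepts an exact concatenation", {
  set.seed(82)
  s1 <- rand_dna(120); s2 <- rand_dna(90)
  cand <- list(fused_species = "A", fused_uexon = "gA:U01",
               split_uexons = c("gB:U01", "gB:U02"), k = 2,
               len_delta_frac = 0, aligned_frac = 1)
  ev <- verify_fused_split(cand, paste0(s1, s2), c(s1, s2))
  expect_false(is.null(ev))
  expect_equal(ev$verify_coverage, 1.0)
  expect_true(ev$joints_crossed)
})

test_that("verification rejects when the last joint is not crossed", {
  set.seed(83)
  s1 <- rand_dna(120)
  cand <- list(fused_species = "A", fused_uexon = "gA:U01",
               split_uexons = c("gB:U01", "gB:U02"), k = 2,
               len_delta_frac = 0, aligned_frac = 1)
  # fused exon matches only the first split; second split is unrelated
  ev <- verify_fused_split(cand, paste0(s1, rand_dna(90)),
                           c(s1, rand_dna(90)))
  expect_null(ev)
})

test_that("planted fissions are detected end-to-end and decoys rejected", {
  cfg <- synth_config(seed = 84, n_genes = 30, exons_per_gene = c(6, 8),
                      exon_len = c(90, 300), substitution_rate = 0.05,
                      n_fission = 10, n_decoy = 8, n_isoforms = c(1, 1))
  ds <- generate_dataset(cfg)
  res <- run_pipeline(pipeline_config(ds$files$pairs, ds$files$ann_a,
                                      ds$files$ann_b, ds$files$genome_a,
                                      ds$files$genome_b))
  fiss <- unique(ds$truth[ds$truth$event == "fission",
                          c("pair_id", "gene_a", "rank_a")])
  expect_equal(nrow(res$events), nrow(fiss))
  expect_setequal(res$events$fused_uexon,
                  sprintf("%s:U%02d", fiss$gene_a, fiss$rank_a))
  expect_true(all(res$events$fused_species == "A"))
  # every emitted event satisfies the stated bounds
  expect_true(all(res$events$len_delta_frac <= 0.05))
  expect_true(all(res$events$aligned_frac >= 0.75 &
                  res$events$aligned_frac <= 1.1))
  expect_true(all(res$events$verify_coverage >= 0.70))
  expect_true(all(res$events$joints_crossed))
  # split counts match the planted k, per fused exon
  tr_f <- ds$truth[ds$truth$event == "fission", ]
  k_planted <- table(sprintf("%s:U%02d", tr_f$gene_a, tr_f$rank_a))
  k_got <- setNames(res$events$k, res$events$fused_uexon)
  expect_equal(as.integer(k_got[names(k_planted)]),
               as.integer(k_planted))
  # decoy regions never yield events
  dec <- unique(ds$truth$gene_a[ds$truth$event == "decoy"])
  expect_false(any(sub(":.*", "", res$events$fused_uexon) %in%
                   setdiff(dec, fiss$gene_a)))
})

test_that("fused exons report one-to-multi, split exons one-to-one", {
  cfg <- synth_config(seed = 85, n_genes = 8, exons_per_gene = c(6, 8),
                      exon_len = c(90, 300), substitution_rate = 0.02,
                      n_fission = 3, n_isoforms = c(1, 1))
  ds <- generate_dataset(cfg)
  res <- run_pipeline(pipeline_config(ds$files$pairs, ds$files$ann_a,
                                      ds$files$ann_b, ds$files$genome_a,
                                      ds$files$genome_b))
  st <- res$uexon_status
  for (i in seq_len(nrow(res$events))) {
    f <- res$events$fused_uexon[i]
    sp <- strsplit(res$events$split_uexons[i], ",")[[1]]
    expect_equal(st$status[st$uexon_id == f], "one_to_multi")
    expect_true(all(st$status[st$uexon_id %in% sp] == "one_to_one"))
    expect_setequal(strsplit(st$partners[st$uexon_id == f], ",")[[1]], sp)
  }
})
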