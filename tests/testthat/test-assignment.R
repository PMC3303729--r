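# Two-gene fixture: single-member united exons with controllable lengths.
fixture_pair <- function(lens_a = rep(100, 5), lens_b = rep(100, 5)) {
  list(ue_a = make_ue("gA", lens_a), ue_b = make_ue("gB", lens_b))
}
eid <- function(g, i) sprintf("%s:E%03d", g, i)
uid <- function(g, i) sprintf("%s:U%02d", g, i)

test_that("sole mutual hits become best-reciprocal pairs", {
  fx <- fixture_pair()
  hits <- rbind(make_hit("p", eid("gA", 1), eid("gB", 1), "ab"),
                make_hit("p", eid("gB", 1), eid("gA", 1), "ba"))
  brh <- find_brh_pairs(hits, fx$ue_a, fx$ue_b)
  expect_equal(nrow(brh), 1)
  expect_equal(brh$uexon_a, uid("gA", 1))
  expect_equal(brh$uexon_b, uid("gB", 1))
  expect_equal(brh$provenance, "brh")
})

test_that("asymmetric sole hits are not reciprocal", {
  fx <- fixture_pair()
  hits <- rbind(make_hit("p", eid("gA", 1), eid("gB", 1), "ab"),
                make_hit("p", eid("gB", 1), eid("gA", 2), "ba"))
  expect_equal(nrow(find_brh_pairs(hits, fx$ue_a, fx$ue_b)), 0)
})

test_that("random bipartite hit graphs match the enumeration oracle", {
  set.seed(71)
  for (rep in 1:40) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    fx <- fixture_pair(rep(100, na), rep(100, nb))
    n_edges <- sample(1:(na * nb), 1)
    idx <- sample(na * nb, n_edges)
    qa <- ((idx - 1) %% na) + 1
    sb <- ((idx - 1) %/% na) + 1
    hits <- do.call(rbind, c(
      lapply(seq_len(n_edges), function(k)
        make_hit("p", eid("gA", qa[k]), eid("gB", sb[k]), "ab")),
      lapply(seq_len(n_edges), function(k)
        if (runif(1) < 0.8)
          make_hit("p", eid("gB", sb[k]), eid("gA", qa[k]), "ba")
        else NULL)))
    got <- find_brh_pairs(hits, fx$ue_a, fx$ue_b)
    ref <- oracle_brh(hits)
    got_keys <- sort(paste(got$uexon_a, got$uexon_b))
    ref_keys <- sort(paste(uid("gA", as.integer(sub(".*E", "", ref$a))),
                           uid("gB", as.integer(sub(".*E", "", ref$b)))))
    expect_equal(got_keys, ref_keys)
  }
})

# A gene whose united exon 1 has two member exon variants.
variant_ue <- function(gene) {
  u <- data.frame(uexon_id = uid(gene, 1:2), gene_id = gene,
                  chrom = "c", strand = "+", start = c(0, 500),
                  end = c(200, 600), rank = 1:2, n_members = c(2L, 1L),
                  length = c(200, 100), stringsAsFactors = FALSE)
  m <- data.frame(uexon_id = uid(gene, c(1, 1, 2)),
                  exon_id = eid(gene, 1:3), stringsAsFactors = FALSE)
  structure(list(uexons = u, members = m), class = "united_exons")
}

test_that("multi-hits into one united exon collapse with a backward link", {
  ue_a <- make_ue("gA", c(200, 100))
  ue_b <- variant_ue("gB")
  hits <- rbind(
    make_hit("p", eid("gA", 1), eid("gB", 1), "ab"),
    make_hit("p", eid("gA", 1), eid("gB", 2), "ab"),
    make_hit("p", eid("gB", 1), eid("gA", 1), "ba"),
    make_hit("p", eid("gB", 2), eid("gA", 1), "ba"))
  mc <- collapse_multi_hits(hits, ue_a, ue_b)
  expect_true(nrow(mc) >= 1)
  expect_equal(unique(mc$uexon_a), uid("gA", 1))
  expect_equal(unique(mc$uexon_b), uid("gB", 1))
  expect_true(all(mc$provenance == "multi_collapse"))
})

test_that("multi-hits across distinct united exons stay unresolved", {
  ue_a <- make_ue("gA", c(200, 100))
  ue_b <- variant_ue("gB")
  hits <- rbind(
    make_hit("p", eid("gA", 1), eid("gB", 1), "ab"),
    make_hit("p", eid("gA", 1), eid("gB", 3), "ab"),  # different uexon
    make_hit("p", eid("gB", 1), eid("gA", 1), "ba"))
  expect_equal(nrow(collapse_multi_hits(hits, ue_a, ue_b)), 0)
})

test_that("a missing backward relationship blocks the collapse", {
  ue_a <- make_ue("gA", rep(100, 9))
  ue_b <- variant_ue("gB")
  hits <- rbind(
    make_hit("p", eid("gA", 1), eid("gB", 1), "ab"),
    make_hit("p", eid("gA", 1), eid("gB", 2), "ab"),
    make_hit("p", eid("gB", 2), eid("gA", 9), "ba"))  # points elsewhere
  expect_equal(nrow(collapse_multi_hits(hits, ue_a, ue_b)), 0)
})

confirmed_links <- function(pairs_a, pairs_b, prov = "brh") {
  data.frame(uexon_a = if (length(pairs_a)) uid("gA", pairs_a) else character(),
             uexon_b = if (length(pairs_b)) uid("gB", pairs_b) else character(),
             evalue = numeric(length(pairs_a)) + 1e-30,
             method = rep("nt", length(pairs_a)),
             provenance = rep(prov, length(pairs_a)),
             out_of_order = logical(length(pairs_a)),
             stringsAsFactors = FALSE)
}

test_that("anchor sets order confirmed pairs by rank on both sides", {
  fx <- fixture_pair(rep(100, 5), rep(100, 6))
  links <- confirmed_links(c(4, 2), c(5, 2))
  an <- build_anchor_set(links, fx$ue_a, fx$ue_b)
  expect_equal(an$a$rank, c(2, 4))
  expect_equal(an$a$partner_lo, c(2, 5))
  expect_equal(an$b$rank, c(2, 5))
  an0 <- build_anchor_set(confirmed_links(integer(0), integer(0)),
                          fx$ue_a, fx$ue_b)
  expect_equal(nrow(an0$a), 0)
})

test_that("in-order hits between flanking anchors are accepted", {
  fx <- fixture_pair(rep(100, 5), rep(100, 7))
  links <- confirmed_links(c(2, 4), c(2, 5))
  an <- build_anchor_set(links, fx$ue_a, fx$ue_b)
  hits <- rbind(make_hit("p", eid("gA", 3), eid("gB", 3), "ab",
                         evalue = 1e-6))
  am <- anchor_map_assign(hits, links, an, fx$ue_a, fx$ue_b)
  expect_equal(nrow(am$accepted), 1)
  expect_equal(am$accepted$uexon_b, uid("gB", 3))
  expect_equal(am$accepted$provenance, "anchor_in_order")
  expect_false(am$accepted$out_of_order)
})

test_that("out-of-order hits are rejected unless short and near-identical", {
  fx <- fixture_pair(rep(100, 5), c(rep(100, 6), 140))
  links <- confirmed_links(c(2, 4), c(2, 5))
  an <- build_anchor_set(links, fx$ue_a, fx$ue_b)
  # length differs by 40 bp: ignored even at a strong e-value
  h1 <- make_hit("p", eid("gA", 3), eid("gB", 7), "ab", evalue = 1e-15)
  am1 <- anchor_map_assign(h1, links, an, fx$ue_a, fx$ue_b)
  expect_equal(nrow(am1$accepted), 0)
  # equal lengths + e-value 1e-15: accepted and tagged
  fx2 <- fixture_pair(rep(100, 5), rep(100, 7))
  an2 <- build_anchor_set(links, fx2$ue_a, fx2$ue_b)
  h2 <- make_hit("p", eid("gA", 3), eid("gB", 7), "ab", evalue = 1e-15)
  am2 <- anchor_map_assign(h2, links, an2, fx2$ue_a, fx2$ue_b)
  expect_equal(nrow(am2$accepted), 1)
  expect_true(am2$accepted$out_of_order)
  expect_equal(am2$accepted$provenance, "anchor_exception")
  # same but weak e-value: rejected
  h3 <- make_hit("p", eid("gA", 3), eid("gB", 7), "ab", evalue = 1e-8)
  am3 <- anchor_map_assign(h3, links, an2, fx2$ue_a, fx2$ue_b)
  expect_equal(nrow(am3$accepted), 0)
})

test_that("one-sided flanks apply at gene ends", {
  fx <- fixture_pair(rep(100, 5), rep(100, 7))
  links <- confirmed_links(c(2, 4), c(3, 5))
  an <- build_anchor_set(links, fx$ue_a, fx$ue_b)
  # A1 precedes the first anchor: any partner rank < 3 is in order
  h <- make_hit("p", eid("gA", 1), eid("gB", 1), "ab", evalue = 1e-6)
  am <- anchor_map_assign(h, links, an, fx$ue_a, fx$ue_b)
  expect_equal(nrow(am$accepted), 1)
  # but partner rank beyond the first anchor's partner is out of order
  h2 <- make_hit("p", eid("gA", 1), eid("gB", 4), "ab", evalue = 1e-6)
  am2 <- anchor_map_assign(h2, links, an, fx$ue_a, fx$ue_b)
  expect_equal(nrow(am2$accepted), 0)
})

test_that("genes with fewer than two anchors abandon unresolved exons", {
  fx <- fixture_pair()
  links <- confirmed_links(2, 2)
  an <- build_anchor_set(links, fx$ue_a, fx$ue_b)
  h <- make_hit("p", eid("gA", 3), eid("gB", 3), "ab", evalue = 1e-30)
  am <- anchor_map_assign(h, links, an, fx$ue_a, fx$ue_b)
  expect_equal(nrow(am$accepted), 0)
  expect_true(uid("gA", 3) %in% am$lack_of_anchors)
})

test_that("several in-order hits give a one-to-multi assignment", {
  fx <- fixture_pair(rep(100, 5), rep(100, 8))
  links <- confirmed_links(c(2, 4), c(2, 6))
  an <- build_anchor_set(links, fx$ue_a, fx$ue_b)
  hits <- rbind(
    make_hit("p", eid("gA", 3), eid("gB", 3), "ab", evalue = 1e-6),
    make_hit("p", eid("gA", 3), eid("gB", 4), "ab", evalue = 1e-7))
  am <- anchor_map_assign(hits, links, an, fx$ue_a, fx$ue_b)
  expect_equal(nrow(am$accepted), 2)
  fin <- finalize_assignments("p", hits, rbind(links, am$accepted),
                              character(), fx$ue_a, fx$ue_b, "gA", "gB")
  st <- fin$uexon_status
  expect_equal(st$status[st$uexon_id == uid("gA", 3)], "one_to_multi")
  expect_equal(st$n_partners[st$uexon_id == uid("gA", 3)], 2)
})

test_that("finalize partitions every united exon into one status", {
  fx <- fixture_pair(rep(100, 4), rep(100, 4))
  hits <- rbind(make_hit("p", eid("gA", 1), eid("gB", 1), "ab"),
                make_hit("p", eid("gB", 1), eid("gA", 1), "ba"),
                make_hit("p", eid("gA", 2), eid("gB", 2), "ab"))
  links <- confirmed_links(1, 1)
  fin <- finalize_assignments("p", hits, links, character(),
                              fx$ue_a, fx$ue_b, "gA", "gB")
  st <- fin$uexon_status
  expect_equal(nrow(st), 8)
  expect_true(all(st$status %in% c("no_hit", "ignored", "one_to_one",
                                   "one_to_multi")))
  expect_equal(st$status[st$uexon_id == uid("gA", 1)], "one_to_one")
  expect_equal(st$status[st$uexon_id == uid("gA", 2)], "ignored")
  expect_equal(st$status[st$uexon_id == uid("gA", 3)], "no_hit")
  # BRH symmetry: assigned from both sides
  expect_equal(st$status[st$uexon_id == uid("gB", 1)], "one_to_one")
  expect_equal(st$partners[st$uexon_id == uid("gB", 1)], uid("gA", 1))
})
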