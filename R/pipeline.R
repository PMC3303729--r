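#' Pipeline configuration
#'
#' Bundles input locations and the stage configurations.  Inputs may be
#' file paths or pre-built objects (`exon_annotation`, data.frame of
#' pairs, `DNAStringSet` genomes).
#'
#' @param pairs Gene-pair table path or data.frame (`pair_id`, `gene_a`,
#'   `gene_b`).
#' @param ann_a,ann_b Annotation paths or `exon_annotation` objects.
#' @param genome_a,genome_b FASTA paths or `DNAStringSet`s.
#' @param format Annotation dialect when paths are given.
#' @param search A [search_config()].
#' @param assign An [assign_config()].
#' @param fusion A [fusion_config()].
#' @param out_dir Optional output directory; when set, every stage's table
#'   is written as TSV and the effective configuration as JSON.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pairs, ann_a, ann_b, genome_a, genome_b,
                            format = "refFlat",
                            search = search_config(),
                            assign = assign_config(),
                            fusion = fusion_config(),
                            out_dir = NULL) {
  structure(list(pairs = pairs, ann_a = ann_a, ann_b = ann_b,
                 genome_a = genome_a, genome_b = genome_b, format = format,
                 search = search, assign = assign, fusion = fusion,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.load_inputs <- function(config) {
  pairs <- if (is.data.frame(config$pairs)) config$pairs
           else read_gene_pairs(config$pairs)
  load_ann <- function(x) {
    if (inherits(x, "exon_annotation")) x
    else read_annotation(x, config$format)
  }
  list(pairs = pairs,
       ann_a = load_ann(config$ann_a), ann_b = load_ann(config$ann_b),
       genome_a = .load_genome(config$genome_a),
       genome_b = .load_genome(config$genome_b))
}

#' Validate pipeline inputs
#'
#' Checks that every gene named in the pair table exists in its species'
#' annotation, that every annotated chromosome is present in the genome
#' FASTA and long enough for its exons, and that CDS intervals are sane.
#' Fatal problems and warnings are distinguished; nothing is raised
#' silently.
#'
#' @param config A [pipeline_config()].
#' @return A data.frame report: `level` (`fatal`/`warning`), `message`.
#'   Zero rows means all checks passed.
#' @export
validate_inputs <- function(config) {
  rows <- list()
  note <- function(level, msg)
    rows[[length(rows) + 1L]] <<- data.frame(level = level, message = msg,
                                             stringsAsFactors = FALSE)
  inp <- tryCatch(.load_inputs(config), error = function(e) e)
  if (inherits(inp, "error")) {
    note("fatal", conditionMessage(inp))
    return(do.call(rbind, rows))
  }
  for (side in c("a", "b")) {
    ann <- inp[[paste0("ann_", side)]]
    genome <- inp[[paste0("genome_", side)]]
    names(genome) <- sub("\\s.*$", "", names(genome))
    genes <- unique(ann$exons$gene_id)
    want <- unique(inp$pairs[[paste0("gene_", side)]])
    missing_genes <- setdiff(want, genes)
    if (length(missing_genes) > 0)
      note("fatal", paste0("pair table names unknown species-",
                           toupper(side), " gene(s): ",
                           paste(missing_genes, collapse = ", ")))
    miss_chr <- setdiff(unique(ann$exons$chrom), names(genome))
    if (length(miss_chr) > 0)
      note("fatal", paste0("chromosome(s) absent from species-",
                           toupper(side), " FASTA: ",
                           paste(miss_chr, collapse = ", ")))
    ok_chr <- ann$exons$chrom %in% names(genome)
    if (any(ok_chr)) {
      w <- Biostrings::width(genome)[match(ann$exons$chrom[ok_chr],
                                           names(genome))]
      beyond <- ann$exons$end[ok_chr] > w
      if (any(beyond))
        note("fatal", paste0("exon(s) beyond chromosome end in species ",
                             toupper(side), ": ",
                             paste(utils::head(
                               ann$exons$exon_id[ok_chr][beyond], 3),
                               collapse = ", ")))
    }
    tx <- ann$transcripts
    bad_cds <- !is.na(tx$cds_start) & tx$cds_start >= tx$cds_end
    if (any(bad_cds))
      note("fatal", paste0("empty/inverted CDS for transcript(s): ",
                           paste(tx$transcript_id[bad_cds], collapse = ", ")))
    unpaired <- setdiff(genes, want)
    if (length(unpaired) > 0)
      note("warning", paste0(length(unpaired), " annotated species-",
                             toupper(side), " gene(s) not in pair table"))
  }
  if (length(rows) == 0)
    return(data.frame(level = character(), message = character()))
  do.call(rbind, rows)
}

# Full assignment for one gene pair; returns finalize() output plus events.
.run_pair <- function(pair_id, gene_a, gene_b, ann_a, ann_b, ue_a, ue_b,
                      config) {
  ex_a <- ann_a$exons[ann_a$exons$gene_id == gene_a, , drop = FALSE]
  ex_b <- ann_b$exons[ann_b$exons$gene_id == gene_b, , drop = FALSE]
  if (nrow(ex_a) == 0 || nrow(ex_b) == 0)
    stop("pair ", pair_id, " references unknown gene(s)")
  sub_ue <- function(ue, gene) {
    keep <- ue$uexons$gene_id == gene
    structure(list(uexons = ue$uexons[keep, , drop = FALSE],
                   members = ue$members[ue$members$uexon_id %in%
                                          ue$uexons$uexon_id[keep], ,
                                        drop = FALSE]),
              class = "united_exons")
  }
  ua <- sub_ue(ue_a, gene_a)
  ub <- sub_ue(ue_b, gene_b)
  hits <- two_step_search(pair_id, ex_a, ex_b, config$search)
  brh <- find_brh_pairs(hits, ua, ub)
  mc <- collapse_multi_hits(hits, ua, ub)
  confirmed <- rbind(brh, mc)
  confirmed <- confirmed[!duplicated(paste(confirmed$uexon_a,
                                           confirmed$uexon_b)), ,
                         drop = FALSE]
  fs <- detect_fused_split(hits, ua, ub, confirmed, config$search,
                           config$fusion)
  confirmed <- rbind(confirmed, fs$links)
  anchors <- build_anchor_set(confirmed, ua, ub)
  am <- anchor_map_assign(hits, confirmed, anchors, ua, ub, config$assign)
  links <- rbind(confirmed, am$accepted)
  links <- links[!duplicated(paste(links$uexon_a, links$uexon_b)), ,
                 drop = FALSE]
  fin <- finalize_assignments(pair_id, hits, links, am$lack_of_anchors,
                              ua, ub, gene_a, gene_b)
  ev <- fs$events
  if (nrow(ev) > 0) ev$pair_id <- pair_id else ev$pair_id <- character()
  fin$events <- ev
  fin$hits <- hits
  fin
}

#' Run the exon-orthology pipeline end to end
#'
#' Stage order: read inputs, merge overlapping exons into united exons and
#' classify gene regions, two-step homology search per gene pair,
#' best-reciprocal-hit assignment, multi-hit collapse, fused/split
#' detection, anchor construction, order-constrained anchor mapping,
#' finalization, downstream summaries.  The pipeline is deterministic:
#' identical inputs and configuration give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `orthoexon_result`: `uexon_status`,
#'   `exon_status`, `links`, `events`, `hits`, `summary_uexon`,
#'   `summary_exon`, `uexons_a`, `uexons_b` and the `config`.
#' @export
run_pipeline <- function(config) {
  report <- validate_inputs(config)
  if (any(report$level == "fatal"))
    stop("input validation failed:\n  ",
         paste(report$message[report$level == "fatal"], collapse = "\n  "))
  inp <- .load_inputs(config)
  ann_a <- extract_exon_sequences(inp$ann_a, inp$genome_a)
  ann_b <- extract_exon_sequences(inp$ann_b, inp$genome_b)
  ue_a <- classify_regions(build_united_exons(ann_a), ann_a)
  ue_b <- classify_regions(build_united_exons(ann_b), ann_b)
  ue_a <- united_exon_sequences(ue_a, inp$genome_a)
  ue_b <- united_exon_sequences(ue_b, inp$genome_b)
  pieces <- lapply(seq_len(nrow(inp$pairs)), function(i) {
    .run_pair(inp$pairs$pair_id[i], inp$pairs$gene_a[i],
              inp$pairs$gene_b[i], ann_a, ann_b, ue_a, ue_b, config)
  })
  bindp <- function(field) {
    out <- do.call(rbind, lapply(pieces, `[[`, field))
    rownames(out) <- NULL
    out
  }
  res <- structure(list(
    uexon_status = bindp("uexon_status"),
    exon_status = bindp("exon_status"),
    links = bindp("links"),
    events = bindp("events"),
    hits = bindp("hits"),
    uexons_a = ue_a, uexons_b = ue_b,
    config = config), class = "orthoexon_result")
  res$summary_uexon <- summarize_assignments(res, "united_exon")
  res$summary_exon <- summarize_assignments(res, "exon")
  if (!is.null(config$out_dir)) .write_result(res, config$out_dir)
  res
}

#' @export
print.orthoexon_result <- function(x, ...) {
  cat("orthoexon_result\n")
  cat(sprintf("  gene pairs: %d\n", length(unique(x$uexon_status$pair_id))))
  cat(sprintf("  united exons: %d   exons: %d   accepted links: %d\n",
              nrow(x$uexon_status), nrow(x$exon_status), nrow(x$links)))
  cat(sprintf("  fused/split events: %d\n", nrow(x$events)))
  cat("  united-exon status summary:\n")
  s <- x$summary_uexon
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-13s %6d  (%6.2f%%)\n", s$status[i], s$count[i],
                s$pct[i]))
  invisible(x)
}

.write_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(res$uexon_status, "assignments.tsv")
  wt(res$exon_status, "exon_status.tsv")
  wt(res$links, "links.tsv")
  wt(res$events, "events.tsv")
  wt(res$summary_uexon, "summary_united_exon.tsv")
  wt(res$summary_exon, "summary_exon.tsv")
  cfg <- res$config
  ser <- list(format = cfg$format, search = unclass(cfg$search),
              assign = unclass(cfg$assign), fusion = unclass(cfg$fusion))
  jsonlite::write_json(ser, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
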