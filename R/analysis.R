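.status_levels <- c("no_hit", "ignored", "one_to_one", "one_to_multi")

#' Summary table of assignment statuses
#'
#' Counts and percentages of `no_hit`, `ignored`, `one_to_one` and
#' `one_to_multi` at the exon or united-exon level, across both species.
#' Percentages are recomputed from the counts and reported to two
#' decimals.
#'
#' @param res An `orthoexon_result` from [run_pipeline()], or a list with
#'   `uexon_status` / `exon_status` data.frames.
#' @param level `"united_exon"` or `"exon"`.
#' @return A data.frame: `status`, `count`, `pct`, with a `total` row.
#' @export
summarize_assignments <- function(res, level = c("united_exon", "exon")) {
  level <- match.arg(level)
  st <- if (level == "united_exon") res$uexon_status$status
        else res$exon_status$status
  counts <- table(factor(st, levels = .status_levels))
  total <- sum(counts)
  out <- data.frame(status = c(names(counts), "total"),
                    count = c(as.integer(counts), total))
  out$pct <- round(100 * out$count / total, 2)
  out
}

#' Distribution of united exons with and without orthologs by gene region
#'
#' For each gene-region category, the fraction of united exons having an
#' orthologous partner (`one_to_one` or `one_to_multi`) versus not
#' (`no_hit` or `ignored`), normalised within the category.  Non-coding
#' genes (`no_CDS`) are excluded; categories with no united exons are
#' absent from the output.
#'
#' @param res An `orthoexon_result` (or list with `uexon_status`).
#' @return A data.frame: `region`, `n_with`, `n_without`, `frac_with`,
#'   `frac_without`.
#' @export
region_distribution <- function(res) {
  u <- res$uexon_status
  u <- u[!is.na(u$region) & u$region != "no_CDS", , drop = FALSE]
  if (nrow(u) == 0)
    return(data.frame(region = character(), n_with = integer(),
                      n_without = integer(), frac_with = numeric(),
                      frac_without = numeric()))
  has <- u$status %in% c("one_to_one", "one_to_multi")
  tab <- table(factor(u$region, levels = setdiff(.region_levels, "no_CDS")),
               factor(has, levels = c(TRUE, FALSE)))
  keep <- rowSums(tab) > 0
  tab <- tab[keep, , drop = FALSE]
  out <- data.frame(region = rownames(tab),
                    n_with = as.integer(tab[, 1]),
                    n_without = as.integer(tab[, 2]))
  out$frac_with <- out$n_with / (out$n_with + out$n_without)
  out$frac_without <- 1 - out$frac_with
  rownames(out) <- NULL
  out
}

# One-to-one united-exon pairs with lengths and the species-A region.
# Both regions are carried; `region` follows the A side, and
# `region_mismatch` flags pairs whose two sides classify differently.
.one_to_one_pairs <- function(res) {
  us <- res$uexon_status
  lk <- res$links
  if (nrow(lk) == 0)
    return(data.frame(pair_id = character(), uexon_a = character(),
                      uexon_b = character(), len_a = numeric(),
                      len_b = numeric(), diff = numeric(), mod3 = integer(),
                      region = character(), region_b = character(),
                      region_mismatch = logical()))
  akey <- paste(us$pair_id, us$uexon_id)
  ia <- match(paste(lk$pair_id, lk$uexon_a), akey)
  ib <- match(paste(lk$pair_id, lk$uexon_b), akey)
  keep <- us$status[ia] == "one_to_one" & us$status[ib] == "one_to_one"
  lk <- lk[keep, , drop = FALSE]; ia <- ia[keep]; ib <- ib[keep]
  out <- data.frame(pair_id = lk$pair_id, uexon_a = lk$uexon_a,
                    uexon_b = lk$uexon_b, len_a = us$length[ia],
                    len_b = us$length[ib], stringsAsFactors = FALSE)
  out$diff <- abs(out$len_a - out$len_b)
  out$mod3 <- as.integer(out$diff %% 3)
  out$region <- us$region[ia]
  out$region_b <- us$region[ib]
  out$region_mismatch <- !is.na(out$region) & !is.na(out$region_b) &
    out$region != out$region_b
  out
}

#' Exon length conservation among one-to-one ortholog pairs
#'
#' Only one-to-one united-exon pairs are analysed.  A pair is
#' length-conserved when the two united-exon lengths are identical.
#' Tabulated per gene-region category (the species-A side's category; see
#' the vignette for the choice).
#'
#' @param res An `orthoexon_result`.
#' @return A data.frame: `region`, `n_equal`, `n_unequal`, `frac_equal`.
#' @export
length_conservation <- function(res) {
  p <- .one_to_one_pairs(res)
  p <- p[!is.na(p$region) & p$region != "no_CDS", , drop = FALSE]
  tab <- table(factor(p$region, levels = setdiff(.region_levels, "no_CDS")),
               factor(p$diff == 0, levels = c(TRUE, FALSE)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  out <- data.frame(region = rownames(tab),
                    n_equal = as.integer(tab[, 1]),
                    n_unequal = as.integer(tab[, 2]))
  out$frac_equal <- out$n_equal / (out$n_equal + out$n_unequal)
  rownames(out) <- NULL
  out
}

#' Reading-frame (mod-3) distribution of length differences
#'
#' Among one-to-one pairs with unequal lengths, the remainder of the
#' absolute length difference divided by three, tabulated per region.
#' Remainder 0 means the downstream reading frame is preserved.
#'
#' @param res An `orthoexon_result`.
#' @return A data.frame: `region`, `n`, `n_mod0`, `n_mod1`, `n_mod2`,
#'   `frac_mod0`, `frac_mod1`, `frac_mod2`.
#' @export
mod3_distribution <- function(res) {
  p <- .one_to_one_pairs(res)
  p <- p[p$diff > 0 & !is.na(p$region) & p$region != "no_CDS", ,
         drop = FALSE]
  tab <- table(factor(p$region, levels = setdiff(.region_levels, "no_CDS")),
               factor(p$mod3, levels = 0:2))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  out <- data.frame(region = rownames(tab), n = as.integer(rowSums(tab)),
                    n_mod0 = as.integer(tab[, 1]),
                    n_mod1 = as.integer(tab[, 2]),
                    n_mod2 = as.integer(tab[, 3]))
  out$frac_mod0 <- out$n_mod0 / out$n
  out$frac_mod1 <- out$n_mod1 / out$n
  out$frac_mod2 <- out$n_mod2 / out$n
  rownames(out) <- NULL
  out
}

#' Histogram of small length differences
#'
#' One-to-one pairs with unequal lengths, restricted to differences of at
#' most `max_bp` (default 30), counted per difference and region.
#'
#' @param res An `orthoexon_result`.
#' @param max_bp Upper bound on the length difference (bp).
#' @return A data.frame: `region`, `diff`, `count`.
#' @export
small_diff_histogram <- function(res, max_bp = 30) {
  p <- .one_to_one_pairs(res)
  p <- p[p$diff >= 1 & p$diff <= max_bp & !is.na(p$region) &
           p$region != "no_CDS", , drop = FALSE]
  if (nrow(p) == 0)
    return(data.frame(region = character(), diff = integer(),
                      count = integer()))
  tab <- as.data.frame(table(region = p$region, diff = factor(p$diff,
    levels = 1:max_bp)), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(region = tab$region, diff = as.integer(tab$diff),
                    count = tab$Freq)
  out <- out[order(out$region, out$diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}
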