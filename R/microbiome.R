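#' Quality-control filtering of an ASV count table
#'
#' Drops ASVs present (count > 0) in fewer than `min_asv_prevalence` of the
#' stool samples, then drops samples with fewer than `min_reads` total reads
#' or, when absolute quantification is available, fewer than `min_copies`
#' 16S copies/mL. Prevalence is computed on the table as supplied, before any
#' sample removal.
#'
#' @param counts integer matrix, samples x ASVs.
#' @param min_asv_prevalence minimum fraction of samples an ASV must appear
#'   in (default 0.10).
#' @param min_reads minimum per-sample read depth (default 5000; a sample
#'   with exactly `min_reads` reads is retained).
#' @param copies optional named numeric vector of per-sample 16S copies/mL.
#' @param min_copies minimum copies/mL (default 1000); skipped with a warning
#'   when `copies` is `NULL`.
#' @return the filtered count matrix.
#' @export
filter_count_table <- function(counts, min_asv_prevalence = 0.10,
                               min_reads = 5000, copies = NULL,
                               min_copies = 1000) {
  stopifnot(is.matrix(counts), nrow(counts) > 0, ncol(counts) > 0)
  if (any(counts < 0) || any(counts != round(counts)))
    .nf_stop("counts must be non-negative integers")
  keep_asv <- colMeans(counts > 0) >= min_asv_prevalence
  out <- counts[, keep_asv, drop = FALSE]
  keep_s <- rowSums(counts) >= min_reads
  if (is.null(copies)) {
    if (min_copies > 0)
      warning("no 16S copy quantification supplied; copies/mL filter skipped")
  } else {
    cp <- copies[rownames(counts)]
    keep_s <- keep_s & !is.na(cp) & cp >= min_copies
  }
  if (!any(keep_s)) .nf_stop("all samples removed by the QC filter")
  out[keep_s, , drop = FALSE]
}

#' Aggregate ASV counts to genus level
#'
#' Sums counts of all ASVs assigned to the same genus. ASVs without a genus
#' assignment (`NA` or empty string in the map, or absent from it) are
#' dropped with a message.
#'
#' @param counts integer matrix, samples x ASVs.
#' @param genus_map named character vector mapping ASV id -> genus.
#' @return an integer matrix, samples x genera.
#' @export
aggregate_genera <- function(counts, genus_map) {
  stopifnot(is.matrix(counts))
  genus <- genus_map[colnames(counts)]
  unassigned <- is.na(genus) | genus == ""
  if (any(unassigned)) {
    message(sum(unassigned), " ASV(s) without genus assignment dropped")
    counts <- counts[, !unassigned, drop = FALSE]
    genus <- genus[!unassigned]
  }
  out <- t(rowsum(t(counts), group = genus))
  storage.mode(out) <- "integer"
  out
}

#' Depth normalization by scaling with ranked subsampling (SRS)
#'
#' Per sample, counts are scaled by `target_depth / depth` and split into
#' integer and fractional parts; the residual `target_depth - sum(integer
#' parts)` single counts are awarded to the taxa with the largest fractional
#' parts, ties broken in a seeded random order. Every normalized sample's
#' total equals `target_depth` exactly. When a sample's scaled counts are all
#' integral the result is deterministic and no random draw is consumed.
#'
#' @param counts integer matrix, samples x taxa.
#' @param target_depth common depth (default: the minimum sample depth).
#' @param seed integer seed for tie-breaking.
#' @return an integer matrix with all row sums equal to `target_depth`.
#' @export
srs_normalize <- function(counts, target_depth = min(rowSums(counts)),
                          seed = 1L) {
  stopifnot(is.matrix(counts))
  depths <- rowSums(counts)
  if (any(depths < target_depth))
    .nf_stop("target_depth exceeds the depth of sample(s): ",
             paste(head(rownames(counts)[depths < target_depth]),
                   collapse = ", "))
  set.seed(seed)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    scaled <- counts[i, ] * target_depth / depths[i]
    ip <- floor(scaled)
    rem <- as.integer(round(target_depth - sum(ip)))
    x <- as.integer(ip)
    if (rem > 0L) {
      frac <- scaled - ip
      ord <- order(-frac, sample.int(length(frac)))
      x[ord[seq_len(rem)]] <- x[ord[seq_len(rem)]] + 1L
    }
    out[i, ] <- x
  }
  storage.mode(out) <- "integer"
  out
}

#' Inverse Simpson alpha diversity with a rank-sum group comparison
#'
#' The inverse Simpson index `1 / sum(p_i^2)` of each sample's relative
#' abundances ([vegan::diversity()]), compared between two groups by a
#' two-sided Wilcoxon rank-sum test treating samples as independent.
#'
#' @param counts count matrix, samples x taxa (normalize depths first, e.g.
#'   with [srs_normalize()]).
#' @param groups optional two-level factor; when supplied the rank-sum test
#'   is run.
#' @return a list with `diversity` (per sample) and, when `groups` is given,
#'   `p` and the `wilcox.test` object `test`.
#' @export
alpha_diversity <- function(counts, groups = NULL) {
  stopifnot(is.matrix(counts))
  div <- vegan::diversity(counts, index = "invsimpson")
  if (is.null(groups)) return(list(diversity = div))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) .nf_stop("'groups' must have two levels")
  wt <- suppressWarnings(wilcox.test(div ~ groups))
  list(diversity = div, p = wt$p.value, test = wt)
}

#' Centered log-ratio transform of a count table
#'
#' Adds a pseudocount, closes each sample to proportions and applies
#' `clr(p) = log p - mean(log p)`; every row of the result sums to zero and
#' is invariant to the sample's sequencing depth.
#'
#' @param counts count matrix, samples x taxa.
#' @param pseudocount value added to every count before closure (default
#'   0.5).
#' @return a numeric matrix of CLR abundances.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  stopifnot(is.matrix(counts))
  lp <- log(counts + pseudocount)
  lp - rowMeans(lp)
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed samples, the standard
#' compositional beta-diversity metric. Use with [pca_ordination()] for
#' ordination and [permanova()] for group testing.
#'
#' @inheritParams clr_transform
#' @return a symmetric distance matrix.
#' @export
aitchison_distance <- function(counts, pseudocount = 0.5) {
  as.matrix(dist(clr_transform(counts, pseudocount), method = "euclidean"))
}
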