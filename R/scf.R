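## ---------------------------------------------------------------------------
## Site concordance factors: for each internal species-tree branch, sample
## quartets (one taxon from each of the branch's groups A,B,C,D), count
## decisive alignment columns — all four taxa unambiguous A/C/G/T and the
## column pattern supporting exactly one of the three quartet pairings
## (xxyy / xyxy / xyyx) — and average the fraction supporting the concordant
## pairing over quartets with at least one decisive site.
## ---------------------------------------------------------------------------

.aln_matrix <- function(aln) {
  if (is.matrix(aln) && is.character(aln)) {
    m <- toupper(aln)
  } else if (inherits(aln, "DNAbin")) {
    m <- toupper(as.character(as.matrix(aln)))
  } else stop("alignment must be a character matrix or DNAbin")
  if (is.null(rownames(m))) stop("alignment must have taxon row names")
  m
}

## per-quartet support counts over a list of alignment matrices;
## rows: concordant / alt1 / alt2 decisive-site counts
.quartet_site_counts <- function(alns, q) {
  counts <- c(0L, 0L, 0L)
  for (m in alns) {
    if (!all(q %in% rownames(m))) next
    s1 <- m[q[1L], ]; s2 <- m[q[2L], ]; s3 <- m[q[3L], ]; s4 <- m[q[4L], ]
    ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T") &
          s3 %in% c("A", "C", "G", "T") & s4 %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    s1 <- s1[ok]; s2 <- s2[ok]; s3 <- s3[ok]; s4 <- s4[ok]
    counts[1L] <- counts[1L] + sum(s1 == s2 & s3 == s4 & s1 != s3)
    counts[2L] <- counts[2L] + sum(s1 == s3 & s2 == s4 & s1 != s2)
    counts[3L] <- counts[3L] + sum(s1 == s4 & s2 == s3 & s1 != s2)
  }
  counts
}

#' Site concordance factors for every internal species-tree branch
#'
#' For each branch, `n_quartets` quartets are sampled (one taxon uniformly
#' from each of groups A, B, C, D, with replacement across quartets). For
#' each quartet, decisive sites are counted across all alignments carrying
#' the four taxa and the fraction supporting the concordant pairing AB|CD is
#' recorded; the branch sCF is 100 times the unweighted mean of these
#' fractions over quartets with at least one decisive site. Gaps and
#' ambiguity codes disqualify a site; only A/C/G/T count.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param alignments A list of alignments (character matrices with taxon row
#'   names, or `DNAbin`), one per locus; taxa may be missing from a locus.
#' @param n_quartets Quartets sampled per branch (default 300).
#' @param seed Integer seed making the quartet sampling reproducible.
#' @param ingroup Optional ingroup restriction passed to [branch_contexts()].
#' @return A data frame with columns `branch_id`, `sCF` (`NA` when no
#'   sampled quartet had a decisive site), `n_quartets_used` and
#'   `n_decisive_sites` (mean decisive sites per used quartet).
#' @export
site_concordance <- function(species_tree, alignments, n_quartets = 300,
                             seed = NULL, ingroup = NULL) {
  stopifnot(n_quartets >= 1)
  if (is.matrix(alignments) || inherits(alignments, "DNAbin"))
    alignments <- list(alignments)
  alns <- lapply(alignments, .aln_matrix)
  contexts <- branch_contexts(species_tree, ingroup = ingroup)
  rows <- with_seed(seed, lapply(contexts, function(ctx) {
    fracs <- rep(NA_real_, n_quartets)
    ndec <- numeric(n_quartets)
    for (r in seq_len(n_quartets)) {
      q <- c(sample(ctx$A, 1L), sample(ctx$B, 1L),
             sample(ctx$C, 1L), sample(ctx$D, 1L))
      cnt <- .quartet_site_counts(alns, q)
      tot <- sum(cnt)
      if (tot > 0L) { fracs[r] <- cnt[1L] / tot; ndec[r] <- tot }
    }
    used <- !is.na(fracs)
    data.frame(branch_id = ctx$branch_id,
               sCF = if (any(used)) 100 * mean(fracs[used]) else NA_real_,
               n_quartets_used = sum(used),
               n_decisive_sites = if (any(used)) mean(ndec[used]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
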