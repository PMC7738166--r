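## ---------------------------------------------------------------------------
## Gene-tree classification against species-tree branches, and gene
## concordance factors.
##
## For a branch with groups A,B,C,D a gene tree is DECISIVE when it carries at
## least one representative of each group.  A decisive tree is CONCORDANT when
## some split of the tree places all its members of A+B on one side and all of
## C+D on the other; ALT1 / ALT2 are the two alternative arrangements AC|BD
## and AD|BC (identities fixed by the group labels, never by frequency); a
## decisive tree matching none of the three is PARAPHYLETIC.
## ---------------------------------------------------------------------------

GENE_TREE_CLASSES <- c("CONCORDANT", "ALT1", "ALT2", "PARAPHYLETIC",
                       "NOT_DECISIVE")

## integer codes used internally: 1..5 in the order above
.classify_masks <- function(splits, leaf, cm) {
  if (mask_empty(mask_and(leaf, cm$A)) || mask_empty(mask_and(leaf, cm$B)) ||
      mask_empty(mask_and(leaf, cm$C)) || mask_empty(mask_and(leaf, cm$D)))
    return(5L)
  targets <- list(mask_and(mask_or(cm$A, cm$B), leaf),
                  mask_and(mask_or(cm$A, cm$C), leaf),
                  mask_and(mask_or(cm$A, cm$D), leaf))
  for (k in 1:3) {
    t <- targets[[k]]; tc <- mask_diff(leaf, t)
    for (s in splits)
      if (mask_eq(s, t) || mask_eq(s, tc)) return(k)
  }
  4L
}

## fast path: universe fits in one 31-bit word, splits given as integer vector
.classify_scalar <- function(splits, leaf, a, b, c, d) {
  if (bitwAnd(leaf, a) == 0L || bitwAnd(leaf, b) == 0L ||
      bitwAnd(leaf, c) == 0L || bitwAnd(leaf, d) == 0L)
    return(5L)
  for (k in 1:3) {
    t <- switch(k, bitwAnd(bitwOr(a, b), leaf), bitwAnd(bitwOr(a, c), leaf),
                bitwAnd(bitwOr(a, d), leaf))
    tc <- bitwAnd(leaf, bitwNot(t))
    if (length(splits) && any(splits == t | splits == tc)) return(k)
  }
  4L
}

#' Classify one gene tree against one species-tree branch
#'
#' @param gene_tree A `phylo`; its leaves must be a subset of the taxon
#'   universe covered by `context`.
#' @param context A `branch_context` (see [branch_contexts()]).
#' @return One of `"CONCORDANT"`, `"ALT1"`, `"ALT2"`, `"PARAPHYLETIC"`,
#'   `"NOT_DECISIVE"`. `ALT1` is the AC|BD arrangement and `ALT2` AD|BC;
#'   trees with fewer than 4 leaves, or missing a whole group, are
#'   `NOT_DECISIVE`.
#' @export
classify_gene_tree <- function(gene_tree, context) {
  stopifnot(inherits(context, "branch_context"))
  universe <- taxon_universe(c(context$A, context$B, context$C, context$D))
  extra <- setdiff(gene_tree$tip.label, universe)
  if (length(extra))
    stop("gene tree leaves outside the species taxon universe: ",
         paste(extra, collapse = ", "))
  sm <- tree_split_masks(gene_tree, universe)
  cm <- context_masks(context, universe)
  GENE_TREE_CLASSES[.classify_masks(sm$splits, sm$leaf, cm)]
}

## Classify all gene trees against all contexts: integer matrix
## (trees x contexts) of class codes.  The engine behind gene_concordance()
## and the bootstrap.
classify_matrix <- function(gene_trees, contexts, universe) {
  scalar <- length(universe) <= .BITS
  pre <- lapply(gene_trees, function(tr) {
    extra <- setdiff(tr$tip.label, universe)
    if (length(extra))
      stop("gene tree leaves outside the species taxon universe: ",
           paste(extra, collapse = ", "))
    sm <- tree_split_masks(tr, universe)
    if (scalar)
      list(leaf = sm$leaf[1L],
           splits = vapply(sm$splits, `[`, integer(1), 1L))
    else sm
  })
  cms <- lapply(contexts, context_masks, universe = universe)
  out <- matrix(0L, nrow = length(gene_trees), ncol = length(contexts))
  for (j in seq_along(contexts)) {
    cm <- cms[[j]]
    if (scalar) {
      a <- cm$A[1L]; b <- cm$B[1L]; c <- cm$C[1L]; d <- cm$D[1L]
      for (i in seq_along(pre))
        out[i, j] <- .classify_scalar(pre[[i]]$splits, pre[[i]]$leaf,
                                      a, b, c, d)
    } else {
      for (i in seq_along(pre))
        out[i, j] <- .classify_masks(pre[[i]]$splits, pre[[i]]$leaf, cm)
    }
  }
  colnames(out) <- vapply(contexts, `[[`, character(1), "branch_id")
  out
}

counts_from_codes <- function(codes) {
  tab <- tabulate(codes, nbins = 5L)
  c(n_concordant = tab[1L], n_alt1 = tab[2L], n_alt2 = tab[3L],
    n_paraphyletic = tab[4L], n_decisive = sum(tab[1:4]))
}

#' Gene concordance factors for every internal species-tree branch
#'
#' Classifies each gene tree against each internal branch of the species tree
#' and reports, per branch, the counts of concordant, alternative-1 (AC|BD),
#' alternative-2 (AD|BC) and paraphyletic decisive trees, together with the
#' derived percentages gCF, gDF1, gDF2 and gDFP (denominator: decisive
#' trees). Branches with no decisive tree get `NA` percentages.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param gene_trees `multiPhylo` or list of `phylo`; leaves may be any
#'   subset of the species-tree taxa (missing taxa allowed).
#' @param ingroup Optional ingroup restriction passed to [branch_contexts()].
#' @return An object of class `concordance`: a data frame with one row per
#'   branch and columns `branch_id`, `n_decisive`, `n_concordant`, `n_alt1`,
#'   `n_alt2`, `n_paraphyletic`, `gCF`, `gDF1`, `gDF2`, `gDFP`. Attributes
#'   carry the contexts and the per-tree class matrix used by the Delta
#'   bootstrap.
#' @examples
#' sp <- parse_newick("((a,b),(c,d));")
#' gt <- rep(c(sp), 3)
#' gene_concordance(sp, gt)
#' @export
gene_concordance <- function(species_tree, gene_trees, ingroup = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) stop("need at least one gene tree")
  contexts <- branch_contexts(species_tree, ingroup = ingroup)
  if (!length(contexts)) stop("species tree has no internal branches")
  universe <- taxon_universe(species_tree$tip.label)
  cls <- classify_matrix(gene_trees, contexts, universe)
  rows <- lapply(seq_along(contexts), function(j) {
    cnt <- counts_from_codes(cls[, j])
    nd <- cnt[["n_decisive"]]
    pct <- if (nd > 0L) 100 * cnt[1:4] / nd else rep(NA_real_, 4L)
    data.frame(branch_id = contexts[[j]]$branch_id,
               n_decisive = nd,
               n_concordant = cnt[["n_concordant"]],
               n_alt1 = cnt[["n_alt1"]], n_alt2 = cnt[["n_alt2"]],
               n_paraphyletic = cnt[["n_paraphyletic"]],
               gCF = pct[[1L]], gDF1 = pct[[2L]], gDF2 = pct[[3L]],
               gDFP = pct[[4L]], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, contexts = contexts, classes = cls,
            n_trees = length(gene_trees),
            species_tree = species_tree,
            class = c("concordance", "data.frame"))
}

#' @export
as.data.frame.concordance <- function(x, ...) {
  for (a in c("contexts", "classes", "species_tree", "n_trees"))
    attr(x, a) <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.concordance <- function(x, digits = 2, ...) {
  cat("Gene concordance factors:", attr(x, "n_trees"), "gene trees,",
      nrow(x), "internal branches\n\n")
  y <- as.data.frame(x)
  num <- c("gCF", "gDF1", "gDF2", "gDFP")
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, ...)
  invisible(x)
}

#' @export
summary.concordance <- function(object, ...) {
  cat("Branches:", nrow(object), "  gene trees:", attr(object, "n_trees"), "\n")
  cat("gCF range: [", round(min(object$gCF, na.rm = TRUE), 2), ", ",
      round(max(object$gCF, na.rm = TRUE), 2), "]  mean ",
      round(mean(object$gCF, na.rm = TRUE), 2), "\n", sep = "")
  invisible(object)
}

#' Chi-square polytomy test on the three resolutions of a branch
#'
#' Goodness-of-fit of the counts of the three possible resolutions around a
#' branch against equal thirds (the expectation under a hard polytomy), with
#' 2 degrees of freedom. Failure to reject is consistent with a polytomy.
#' This operates on whole-tree topology counts; it approximates (and need not
#' equal) quartet-frequency versions of the test.
#'
#' @param n1,n2,n3 Non-negative counts of the three resolutions.
#' @return An object of class `htest` with the chi-square statistic, df and
#'   p-value.
#' @examples
#' polytomy_chi2(442, 437, 413)
#' @export
polytomy_chi2 <- function(n1, n2, n3) {
  o <- c(n1, n2, n3)
  stopifnot(length(o) == 3L, all(o >= 0))
  n <- sum(o)
  if (n == 0) stop("all counts are zero")
  e <- n / 3
  stat <- sum((o - e)^2 / e)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = 2),
                 p.value = pchisq(stat, df = 2, lower.tail = FALSE),
                 method = "Chi-square polytomy test (equal-thirds null)",
                 data.name = paste(o, collapse = ", ")),
            class = "htest")
}
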