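## ---------------------------------------------------------------------------
## The Delta test: a gene-tree analogue of the site-based D (ABBA-BABA) test.
## Around a species-tree branch the two discordant topology classes are
## expected in equal numbers under incomplete lineage sorting alone; an excess
## of one class (Delta > 0) indicates introgression involving non-sister
## lineages.  Significance comes from a gene-tree bootstrap: resample the
## gene-tree list with replacement, recompute Delta with the DF1/DF2 class
## identities FIXED from the observed data (re-ranking per replicate would
## bias the null upward), and refer the observed Delta to the half-normal
## null implied by the bootstrap spread.
## ---------------------------------------------------------------------------

#' Screening and bootstrap configuration for the Delta test
#'
#' @param min_discordant_fraction Branches are tested only when the fraction
#'   of decisive-but-discordant gene trees exceeds this (default 0.05).
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of comparisons for the Dunn-Sidak correction; default
#'   `NULL` means "use the number of branches actually tested".
#' @param n_boot Bootstrap pseudo-replicates (default 2000; at least 100).
#' @param seed Integer seed driving all resampling.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_discordant_fraction = 0.05, alpha = 0.05,
                          m = NULL, n_boot = 2000, seed = NULL) {
  stopifnot(min_discordant_fraction >= 0, min_discordant_fraction < 1,
            alpha > 0, alpha < 1, n_boot >= 100,
            is.null(m) || m >= 1)
  structure(list(min_discordant_fraction = min_discordant_fraction,
                 alpha = alpha, m = m, n_boot = as.integer(n_boot),
                 seed = seed), class = "screen_config")
}

#' Normalized Delta statistic from the two discordant counts
#'
#' Delta = (DF1 - DF2) / (DF1 + DF2), where DF1 is the more frequent and DF2
#' the less frequent discordant topology class; the ranking is performed
#' here, so Delta is always in \[0, 1\]. Both counts zero gives `NA` (no
#' discordance to test).
#'
#' @param n_alt1,n_alt2 Non-negative counts of the two discordant classes
#'   (unranked).
#' @return Delta, a number in \[0, 1\], or `NA_real_`.
#' @examples
#' delta_statistic(437, 413)  # 24/850
#' @export
delta_statistic <- function(n_alt1, n_alt2) {
  stopifnot(n_alt1 >= 0, n_alt2 >= 0)
  s <- n_alt1 + n_alt2
  if (s == 0) return(NA_real_)
  abs(n_alt1 - n_alt2) / s
}

#' Dunn-Sidak per-comparison cutoff
#'
#' The per-test p-value cutoff 1 - (1 - alpha)^(1/m) that keeps the
#' family-wise error rate at `alpha` over `m` independent comparisons. It is
#' never smaller than the Bonferroni cutoff `alpha/m`.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return The per-comparison cutoff.
#' @examples
#' sidak_cutoff(0.05, 17)
#' @export
sidak_cutoff <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}

#' Select branches with enough discordance to test
#'
#' Keeps branches where the fraction of decisive gene trees that are
#' discordant, `(n_decisive - n_concordant) / n_decisive`, exceeds
#' `min_discordant_fraction`. Branches with no decisive tree are dropped.
#'
#' @param records A `concordance` object (or its data frame).
#' @param config A [screen_config()].
#' @return Character vector of branch ids.
#' @export
screen_branches <- function(records, config = screen_config()) {
  df <- as.data.frame(records)
  ok <- df$n_decisive > 0 &
    (df$n_decisive - df$n_concordant) / pmax(df$n_decisive, 1) >
      config$min_discordant_fraction
  df$branch_id[ok]
}

## seed scoping: run expr under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Core bootstrap on a per-tree class-code matrix (trees x branches).
## Joint index resampling so branch statistics co-vary across replicates.
## Returns a list of per-branch result rows.
.delta_boot_engine <- function(cls, branch_ids, n_boot, seed, alpha, cutoff) {
  n <- nrow(cls)
  B <- length(branch_ids)
  obs <- vector("list", B)
  for (j in seq_len(B)) {
    cnt <- counts_from_codes(cls[, j])
    df1_is_alt1 <- cnt[["n_alt1"]] >= cnt[["n_alt2"]]
    obs[[j]] <- list(cnt = cnt, df1_is_alt1 = df1_is_alt1,
                     delta = delta_statistic(cnt[["n_alt1"]], cnt[["n_alt2"]]))
  }
  boot <- matrix(NA_real_, nrow = n_boot, ncol = B)
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      for (j in seq_len(B)) {
        tab <- tabulate(cls[idx, j], nbins = 5L)
        a1 <- tab[2L]; a2 <- tab[3L]
        s <- a1 + a2
        if (s > 0)
          boot[r, j] <- if (obs[[j]]$df1_is_alt1) (a1 - a2) / s else (a2 - a1) / s
      }
    }
  })
  out <- vector("list", B)
  for (j in seq_len(B)) {
    o <- obs[[j]]
    cnt <- o$cnt
    n_df1 <- max(cnt[["n_alt1"]], cnt[["n_alt2"]])
    n_df2 <- min(cnt[["n_alt1"]], cnt[["n_alt2"]])
    bj <- boot[, j]
    n_ok <- sum(!is.na(bj))
    degenerate <- FALSE
    if (is.na(o$delta)) {               # no discordant trees at all
      bsd <- NA_real_; z <- NA_real_; p <- NA_real_
    } else {
      bsd <- sd(bj, na.rm = TRUE)
      if (length(unique(bj[!is.na(bj)])) < 4L)
        warning("branch ", branch_ids[j], ": fewer than 4 distinct bootstrap ",
                "Delta values")
      if (!is.finite(bsd) || bsd == 0) {
        if (o$delta == 0) { z <- 0; p <- 1 }
        else { z <- Inf; p <- NA_real_; degenerate <- TRUE }
        bsd <- if (is.finite(bsd)) bsd else NA_real_
      } else {
        z <- o$delta / bsd
        ## observed Delta is non-negative by ranking; under the null it is the
        ## absolute value of an (approximately) centred normal, so the upper
        ## tail of its null distribution is the folded-normal tail
        p <- 2 * pnorm(z, lower.tail = FALSE)
      }
    }
    out[[j]] <- data.frame(
      branch_id = branch_ids[j],
      n_decisive = cnt[["n_decisive"]], n_concordant = cnt[["n_concordant"]],
      n_df1 = n_df1, n_df2 = n_df2,
      df1_class = if (o$df1_is_alt1) "ALT1" else "ALT2",
      delta = o$delta, boot_sd = bsd, z_score = z, p_value = p,
      n_boot = n_boot, n_boot_defined = n_ok,
      significant_raw = !is.na(p) & p < alpha,
      significant_corrected = !is.na(p) & p < cutoff,
      degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out
}

#' Bootstrap Delta test for one species-tree branch
#'
#' Computes the observed Delta for the branch, then resamples the full
#' gene-tree list with replacement `n_boot` times, recomputing Delta per
#' pseudo-replicate with the DF1/DF2 class identities fixed from the observed
#' data. The Z-score is the observed Delta over the bootstrap standard
#' deviation and the p-value is the upper tail of the implied half-normal
#' null (Delta is non-negative by construction).
#'
#' @param gene_trees List of `phylo` gene trees.
#' @param species_tree Rooted binary `phylo` (supplies the taxon universe).
#' @param branch A `branch_context` for the tested branch.
#' @param config A [screen_config()]; `n_boot`, `seed`, `alpha` and `m` are
#'   used (`m` defaults to 1 here).
#' @return A one-row data frame of class `delta_result` with columns
#'   `branch_id`, `n_decisive`, `n_concordant`, `n_df1`, `n_df2`,
#'   `df1_class`, `delta`, `boot_sd`, `z_score`, `p_value`, `n_boot`,
#'   `significant_raw`, `significant_corrected`, `degenerate`.
#' @export
bootstrap_delta <- function(gene_trees, species_tree, branch,
                            config = screen_config()) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(inherits(branch, "branch_context"))
  universe <- taxon_universe(species_tree$tip.label)
  cls <- classify_matrix(gene_trees, list(branch), universe)
  m <- if (is.null(config$m)) 1L else config$m
  cutoff <- sidak_cutoff(config$alpha, m)
  res <- .delta_boot_engine(cls, branch$branch_id, config$n_boot,
                            config$seed, config$alpha, cutoff)[[1L]]
  res$seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  class(res) <- c("delta_result", "data.frame")
  res
}

#' Four-taxon follow-up Delta test
#'
#' Restricts the gene-tree set to four chosen taxa, one drawn from each of
#' the branch's groups A, B, C and D (so the tested branch is internal in
#' the restricted trees), drops trees missing any chosen taxon, and runs the
#' Delta bootstrap on the restricted set.
#'
#' @param gene_trees List of `phylo` gene trees.
#' @param species_tree Rooted binary `phylo`.
#' @param branch A `branch_context`.
#' @param chosen Character vector of exactly 4 taxa, one from each of
#'   `branch$A`, `branch$B`, `branch$C`, `branch$D` (any order).
#' @param config A [screen_config()].
#' @return A `delta_result` (see [bootstrap_delta()]) with an extra column
#'   `n_loci_used`, the number of gene trees carrying all four chosen taxa.
#' @export
quartet_followup <- function(gene_trees, species_tree, branch, chosen,
                             config = screen_config()) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(inherits(branch, "branch_context"))
  chosen <- as.character(chosen)
  if (length(chosen) != 4L || anyDuplicated(chosen))
    stop("'chosen' must be 4 distinct taxa")
  pick <- function(group) chosen[chosen %in% branch[[group]]]
  sel <- lapply(c("A", "B", "C", "D"), pick)
  if (any(lengths(sel) != 1L))
    stop("'chosen' must contain exactly one taxon from each of groups ",
         "A, B, C and D")
  keep <- vapply(gene_trees, function(tr) all(chosen %in% tr$tip.label),
                 logical(1))
  if (!any(keep)) stop("no gene tree carries all four chosen taxa")
  sub <- lapply(gene_trees[keep], restrict_tree, keep = chosen)
  qctx <- new_branch_context(sel[[1L]], sel[[2L]], sel[[3L]], sel[[4L]])
  qsp <- parse_newick(sprintf("((%s,%s),(%s,%s));", sel[[1L]], sel[[2L]],
                              sel[[3L]], sel[[4L]]))
  res <- bootstrap_delta(sub, qsp, qctx, config)
  res$n_loci_used <- sum(keep)
  res
}

#' Genome-scale Delta test across all qualifying branches
#'
#' The full per-branch pipeline: gene concordance factors, screening of
#' branches whose discordant fraction exceeds the threshold, a shared
#' gene-tree bootstrap (the same resampled datasets are used for every
#' branch, so branch statistics co-vary), Z-scores and p-values, and
#' Dunn-Sidak family-wise correction over the tested branches.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param gene_trees List of `phylo` gene trees (missing taxa allowed).
#' @param config A [screen_config()].
#' @param ingroup Optional ingroup restriction passed to [branch_contexts()].
#' @return An object of class `delta_test`: a list with components
#'   `results` (data frame, one row per tested branch, columns as in
#'   [bootstrap_delta()]), `concordance` (the `concordance` object),
#'   `config`, `m`, `cutoff` (the Dunn-Sidak per-test cutoff) and `n_trees`.
#' @examples
#' sp <- parse_newick("((a,b),(c,d));")
#' set.seed(1)
#' gt <- rep(c(sp, parse_newick("((a,c),(b,d));"),
#'             parse_newick("((a,d),(b,c));")), c(60, 25, 15))
#' delta_test(sp, gt, screen_config(n_boot = 200, seed = 1))
#' @export
delta_test <- function(species_tree, gene_trees, config = screen_config(),
                       ingroup = NULL) {
  stopifnot(inherits(config, "screen_config"))
  conc <- gene_concordance(species_tree, gene_trees, ingroup = ingroup)
  ids <- screen_branches(conc, config)
  m <- if (is.null(config$m)) max(length(ids), 1L) else config$m
  cutoff <- sidak_cutoff(config$alpha, m)
  results <- NULL
  if (length(ids)) {
    cls <- attr(conc, "classes")[, match(ids, conc$branch_id), drop = FALSE]
    rows <- .delta_boot_engine(cls, ids, config$n_boot, config$seed,
                               config$alpha, cutoff)
    results <- do.call(rbind, rows)
    rownames(results) <- NULL
  }
  structure(list(results = results, concordance = conc, config = config,
                 m = m, cutoff = cutoff, n_trees = attr(conc, "n_trees")),
            class = "delta_test")
}

#' @export
print.delta_test <- function(x, digits = 4, ...) {
  cat("Delta introgression test:", x$n_trees, "gene trees,",
      nrow(x$concordance), "internal branches\n")
  cat("Screened (discordant fraction > ",
      x$config$min_discordant_fraction, "): ",
      if (is.null(x$results)) 0L else nrow(x$results), " branches tested\n",
      sep = "")
  cat("Dunn-Sidak cutoff (alpha = ", x$config$alpha, ", m = ", x$m, "): ",
      signif(x$cutoff, 3), "\n\n", sep = "")
  if (is.null(x$results)) {
    cat("No branch passed screening.\n")
    return(invisible(x))
  }
  y <- x$results[c("branch_id", "n_decisive", "n_df1", "n_df2", "delta",
                   "boot_sd", "z_score", "p_value", "significant_raw",
                   "significant_corrected")]
  for (cn in c("delta", "boot_sd", "z_score", "p_value"))
    y[[cn]] <- signif(y[[cn]], digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.delta_test <- function(object, ...) {
  r <- object$results
  cat("Tested branches:       ", if (is.null(r)) 0L else nrow(r), "\n")
  if (!is.null(r)) {
    cat("Significant (raw):     ", sum(r$significant_raw, na.rm = TRUE), "\n")
    cat("Significant (Sidak):   ", sum(r$significant_corrected, na.rm = TRUE),
        "\n")
  }
  invisible(object)
}

#' @export
as.data.frame.delta_test <- function(x, ...) x$results
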