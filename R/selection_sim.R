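## ---------------------------------------------------------------------------
## Forward Wright-Fisher check that purifying selection does not distort
## gene-tree topology frequencies, on the 3-population species tree
## ((p2,p3),p1).  Haploid populations with multiplicative fitness (1+s)^k,
## deleterious-only irreversible mutation; one chromosome sampled per
## population per locus and the recorded genealogy classified into the three
## rooted triplet topologies.
## ---------------------------------------------------------------------------

#' Configuration for the Wright-Fisher selection simulation
#'
#' Defaults mirror the standard strong-purifying-selection check: a
#' population-scaled selection coefficient Ns = -7.5, a per-locus deleterious
#' mutation rate of 3e-7 per generation, an internal branch subtending p2 and
#' p3 of 0.01 N generations, tip branches of 8 N generations, and a p3
#' population 0.04 times the size of p1 and p2; 50 loci per replicate, 100
#' replicates.
#'
#' @param N Haploid population size of p1, p2 and the ancestral populations.
#' @param p3_ratio Size of p3 relative to N (default 0.04).
#' @param Ns Population-scaled selection coefficient (default -7.5); the raw
#'   per-mutation coefficient is `s = Ns / N`.
#' @param U Per-locus deleterious mutation rate per generation (default
#'   3e-7; the high-mutation condition uses 3e-5).
#' @param internal_gens Internal branch length in generations (default
#'   `0.01 * N`).
#' @param tip_gens Tip branch lengths in generations (default `8 * N`).
#' @param ancestral_gens Generations the ancestral population is run before
#'   the first split (default `2 * N`; long enough that the sampled triplet
#'   virtually always finds its first coalescence, loci that do not are
#'   reported as unresolved).
#' @param n_loci Non-recombining loci per replicate (default 50; loci are
#'   fully independent, i.e. freely recombining).
#' @param n_replicates Number of replicate simulations (default 100).
#' @param ploidy `"haploid"` (the simulation's native convention) or
#'   `"diploid"`, which only changes the coalescent-unit conversion used by
#'   [internal_branch_units()].
#' @param seed Integer seed.
#' @return A list of class `wf_config`.
#' @export
wf_config <- function(N = 500, p3_ratio = 0.04, Ns = -7.5, U = 3e-7,
                      internal_gens = round(0.01 * N),
                      tip_gens = round(8 * N),
                      ancestral_gens = round(2 * N),
                      n_loci = 50, n_replicates = 100,
                      ploidy = c("haploid", "diploid"), seed = NULL) {
  ploidy <- match.arg(ploidy)
  N <- as.integer(N)
  stopifnot(N >= 10, is.finite(Ns), U >= 0,
            internal_gens >= 1, tip_gens >= 1, ancestral_gens >= 1,
            n_loci >= 1, n_replicates >= 1,
            p3_ratio > 0, p3_ratio <= 1)
  structure(list(N = N, N3 = max(1L, as.integer(round(p3_ratio * N))),
                 p3_ratio = p3_ratio, Ns = Ns, s = Ns / N, U = U,
                 internal_gens = as.integer(internal_gens),
                 tip_gens = as.integer(tip_gens),
                 ancestral_gens = as.integer(ancestral_gens),
                 n_loci = as.integer(n_loci),
                 n_replicates = as.integer(n_replicates),
                 ploidy = ploidy, seed = seed),
            class = "wf_config")
}

#' Internal branch length in coalescent units
#'
#' @param config A [wf_config()].
#' @return `internal_gens / N` under the haploid convention, or
#'   `internal_gens / (2 N)` under the diploid one.
#' @export
internal_branch_units <- function(config) {
  stopifnot(inherits(config, "wf_config"))
  config$internal_gens / (ifelse(config$ploidy == "diploid", 2, 1) * config$N)
}

#' Simulate Wright-Fisher genealogies and count triplet topologies
#'
#' Runs `n_replicates` forward simulations of `n_loci` independent loci on
#' the species tree ((p2,p3),p1) and classifies each locus genealogy by which
#' pair of the three sampled chromosomes coalesces first.
#'
#' @param config A [wf_config()].
#' @return A data frame of class `wf_topology_counts` with one row per
#'   replicate and columns `replicate`, `n_concordant` ((p2,p3) first),
#'   `n_p1p2`, `n_p1p3`, `n_unresolved` (no coalescence within the simulated
#'   span; excluded from the resolved total).
#' @examples
#' cfg <- wf_config(N = 100, n_loci = 20, n_replicates = 2, seed = 1)
#' simulate_wf_genealogies(cfg)
#' @export
simulate_wf_genealogies <- function(config) {
  stopifnot(inherits(config, "wf_config"))
  rows <- with_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      codes <- .wf_triplet_sim(config$n_loci, config$N, config$N3,
                               config$ancestral_gens, config$internal_gens,
                               config$tip_gens, config$s, config$U)
      tab <- tabulate(codes + 1L, nbins = 4L)
      data.frame(replicate = r, n_concordant = tab[1L], n_p1p2 = tab[2L],
                 n_p1p3 = tab[3L], n_unresolved = tab[4L])
    })
  })
  res <- do.call(rbind, rows)
  if (any(res$n_unresolved > 0))
    message(sum(res$n_unresolved), " locus/loci left unresolved ",
            "(no coalescence within the simulated span)")
  structure(res, config = config,
            class = c("wf_topology_counts", "data.frame"))
}

#' @export
print.wf_topology_counts <- function(x, ...) {
  tot <- pool_topology_counts(x)
  n <- sum(tot)
  cat("Wright-Fisher triplet topologies over", nrow(x), "replicates\n")
  cat(sprintf("  (p2,p3): %d (%.1f%%)   (p1,p2): %d (%.1f%%)   (p1,p3): %d (%.1f%%)\n",
              tot[1], 100 * tot[1] / n, tot[2], 100 * tot[2] / n,
              tot[3], 100 * tot[3] / n))
  invisible(x)
}

#' Pool per-replicate topology counts
#'
#' @param counts A `wf_topology_counts` data frame (or any data frame with
#'   columns `n_concordant`, `n_p1p2`, `n_p1p3`), or a numeric vector of
#'   length 3.
#' @return Named integer vector of the three pooled topology counts.
#' @export
pool_topology_counts <- function(counts) {
  if (is.numeric(counts) && length(counts) == 3L)
    return(setNames(as.integer(counts), c("n_concordant", "n_p1p2", "n_p1p3")))
  c(n_concordant = sum(counts$n_concordant),
    n_p1p2 = sum(counts$n_p1p2),
    n_p1p3 = sum(counts$n_p1p3))
}

#' Test for a shift in topology frequencies between two conditions
#'
#' Compares the pooled triplet-topology distributions of two simulation
#' conditions (typically neutral vs selected) with a 3 x 2 contingency
#' chi-square; when any expected cell is below 5 Fisher's exact test is used
#' instead. Non-rejection replicates the finding that purifying selection
#' leaves the gene-tree topology distribution unchanged.
#'
#' @param neutral,selected `wf_topology_counts` objects or length-3 count
#'   vectors.
#' @return An object of class `htest`.
#' @export
topology_bias_test <- function(neutral, selected) {
  a <- pool_topology_counts(neutral)
  b <- pool_topology_counts(selected)
  if (sum(a) == 0 || sum(b) == 0) stop("empty topology pool")
  tab <- cbind(neutral = a, selected = b)
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cells < 5)) {
    ht <- fisher.test(tab)
    ht$method <- paste("Fisher's exact test (3x2 topology table;",
                       "expected cell < 5)")
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    ht$method <- "Chi-square test on the 3x2 topology table"
  }
  ht$data.name <- "pooled triplet topology counts, neutral vs selected"
  ht
}
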