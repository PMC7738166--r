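## ---------------------------------------------------------------------------
## Multispecies-coalescent gene-tree simulator with instantaneous
## introgression pulses.
##
## Time runs backward from the present in coalescent units (1 unit = 2N
## generations under the diploid convention); species-tree branch lengths are
## in these units.  Within a population holding k lineages, coalescence
## events occur at rate k(k-1)/2 per unit; unmerged lineages pass to the
## parent population.  A pulse (donor, recipient, time, gamma) reroutes each
## lineage present in the recipient population at that time into the donor
## population independently with probability gamma.
## ---------------------------------------------------------------------------

#' Introgression pulse specification
#'
#' @param donor,recipient Population labels: a tip label, an internal node
#'   label, or the comma-joined sorted taxa of an internal clade (e.g.
#'   `"a,b"`), or `"ROOT"` for the ancestral population above the root.
#' @param time Time before the present, in coalescent units; must fall within
#'   the existence interval of both populations.
#' @param gamma Probability that a recipient lineage traces its ancestry
#'   through the donor at that time, in \[0, 1\].
#' @return A list of class `introgression_pulse`.
#' @export
introgression_pulse <- function(donor, recipient, time, gamma) {
  stopifnot(is.character(donor), is.character(recipient),
            time >= 0, gamma >= 0, gamma <= 1)
  if (identical(donor, recipient)) stop("donor and recipient must differ")
  structure(list(donor = donor, recipient = recipient, time = time,
                 gamma = gamma), class = "introgression_pulse")
}

#' Simulation configuration for the coalescent gene-tree generator
#'
#' @param species_tree Rooted binary `phylo` with branch lengths in
#'   coalescent units (all positive). Set `units = "generations"` together
#'   with `N` to supply branch lengths in generations instead.
#' @param pulses List of [introgression_pulse()] objects (may be empty).
#' @param n_loci Number of independent loci (gene trees) to simulate.
#' @param samples_per_species Lineages sampled per species (default 1; labels
#'   gain a `_k` suffix when > 1).
#' @param missing_prob Per-locus probability that each taxon is independently
#'   missing (default 0); at least two taxa are always retained.
#' @param seed Master seed; per-locus substreams are derived from it so locus
#'   results do not depend on execution order.
#' @param units `"coalescent"` (default) or `"generations"`; in the latter
#'   case branch lengths and pulse times are divided by `ploidy * N`.
#' @param N,ploidy Population size and ploidy (1 or 2, default 2) used only
#'   for the generation-to-coalescent-unit conversion.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species_tree, pulses = list(), n_loci,
                       samples_per_species = 1, missing_prob = 0,
                       seed = NULL, units = c("coalescent", "generations"),
                       N = NULL, ploidy = 2) {
  units <- match.arg(units)
  validate_tree(species_tree)
  if (!ape::is.rooted(species_tree) || !ape::is.binary(species_tree))
    stop("species tree must be rooted and binary")
  if (is.null(species_tree$edge.length))
    stop("species tree must have branch lengths")
  if (any(species_tree$edge.length <= 0))
    stop("species-tree branch lengths must be positive")
  stopifnot(n_loci >= 1, samples_per_species >= 1,
            missing_prob >= 0, missing_prob < 1)
  if (inherits(pulses, "introgression_pulse")) pulses <- list(pulses)
  scale <- 1
  if (units == "generations") {
    if (is.null(N)) stop("units = 'generations' requires N")
    scale <- 1 / (ploidy * N)
    species_tree$edge.length <- species_tree$edge.length * scale
    pulses <- lapply(pulses, function(p) { p$time <- p$time * scale; p })
  }
  cfg <- structure(list(species_tree = species_tree, pulses = pulses,
                        n_loci = as.integer(n_loci),
                        samples_per_species = as.integer(samples_per_species),
                        missing_prob = missing_prob, seed = seed),
                   class = "sim_config")
  .msc_prep(cfg)        # validates pulses against population intervals
  cfg
}

## Precompute species-tree structure: node ages, children, population names
## and existence intervals, the sorted event table, and resolved pulses.
.msc_prep <- function(cfg) {
  sp <- cfg$species_tree
  ntip <- length(sp$tip.label)
  nnode <- ntip + sp$Nnode
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(sp)    # distance from root
  age <- max(depth[seq_len(ntip)]) - depth   # deepest tip has age 0
  age[abs(age) < 1e-12] <- 0
  parent <- integer(nnode)
  children <- vector("list", nnode)
  for (i in seq_len(nrow(sp$edge))) {
    p <- sp$edge[i, 1L]; ch <- sp$edge[i, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  ## clade label strings for population naming
  clade <- vector("list", nnode)
  for (i in seq_len(ntip)) clade[[i]] <- sp$tip.label[i]
  ord <- stats::reorder(sp, "postorder")$edge
  for (i in seq_len(nrow(ord)))
    clade[[ord[i, 1L]]] <- c(clade[[ord[i, 1L]]], clade[[ord[i, 2L]]])
  pop_names <- lapply(seq_len(nnode), function(v) {
    nm <- if (v <= ntip) sp$tip.label[v]
          else paste(sort(clade[[v]]), collapse = ",")
    lab <- if (v > ntip && !is.null(sp$node.label) &&
               nzchar(sp$node.label[v - ntip] %||% "")) sp$node.label[v - ntip]
    nms <- c(nm, lab)
    if (v == root) nms <- c(nms, "ROOT")
    nms
  })
  resolve_pop <- function(label) {
    hit <- which(vapply(pop_names, function(x) label %in% x, logical(1)))
    if (length(hit) != 1L) stop("unknown population label: ", label)
    hit
  }
  pop_start <- age
  pop_end <- rep(Inf, nnode)
  nonroot <- setdiff(seq_len(nnode), root)
  pop_end[nonroot] <- age[parent[nonroot]]
  pulses <- lapply(cfg$pulses, function(p) {
    d <- resolve_pop(p$donor); r <- resolve_pop(p$recipient)
    for (v in c(d, r))
      if (p$time < pop_start[v] - 1e-12 || p$time >= pop_end[v])
        stop("pulse time ", p$time, " outside the existence interval of ",
             "population '", pop_names[[v]][1], "' [", pop_start[v], ", ",
             format(pop_end[v]), ")")
    list(donor = d, recipient = r, time = p$time, gamma = p$gamma)
  })
  ## event table: pulses before node merges at equal times
  ev_time <- c(vapply(pulses, `[[`, numeric(1), "time"),
               age[(ntip + 1L):nnode])
  ev_type <- c(rep(1L, length(pulses)), rep(2L, nnode - ntip)) # 1 pulse 2 node
  ev_id <- c(seq_along(pulses), (ntip + 1L):nnode)
  o <- order(ev_time, ev_type)
  list(ntip = ntip, nnode = nnode, root = root, age = age, parent = parent,
       children = children, pulses = pulses,
       ev = list(time = ev_time[o], type = ev_type[o], id = ev_id[o]))
}

#' Expected gene-tree concordance under the multispecies coalescent
#'
#' For an internal species-tree branch of length `T` coalescent units, the
#' probability that a gene tree is concordant with the branch is
#' `1 - (2/3) exp(-T)`: the two lineages entering the branch either coalesce
#' within it (probability `1 - exp(-T)`) or all three orderings above it are
#' equally likely.
#'
#' @param T Branch length in coalescent units, >= 0 (vectorized).
#' @return Concordance probability in \[1/3, 1\].
#' @examples
#' expected_concordance(0)    # 1/3, a star tree
#' expected_concordance(0.1)
#' @export
expected_concordance <- function(T) {
  if (any(T < 0)) stop("T must be non-negative")
  1 - (2 / 3) * exp(-T)
}

## simulate one locus; everything already in coalescent units
.sim_locus <- function(prep, tips_kept, samples) {
  ## lineages: population (species node id) and gene node id; tip lineages
  ## activate at their species tip age (0 unless non-ultrametric)
  lin_pop <- rep(tips_kept, each = samples)
  L <- length(lin_pop)
  lin_node <- seq_len(L)
  g_age <- numeric(2L * L - 1L)
  g_age[seq_len(L)] <- prep$age[lin_pop]
  g_child <- matrix(0L, nrow = 2L * L - 1L, ncol = 2L)
  nxt <- L
  moved <- rep(FALSE, length(prep$pulses))
  ev <- prep$ev
  n_ev <- length(ev$time)
  t_cur <- 0
  for (e in seq_len(n_ev + 1L)) {
    t_next <- if (e <= n_ev) ev$time[e] else Inf
    ## coalesce within (t_cur, t_next] in every population holding >= 2
    ## lineages, at rate k(k-1)/2 per coalescent unit
    if (t_next > t_cur && length(lin_pop) > 1L) {
      for (p in unique(lin_pop)) {
        idx <- which(lin_pop == p)
        k <- length(idx)
        if (k < 2L) next
        t <- max(t_cur, prep$age[p])   # population may start later (aged tips)
        while (k >= 2L) {
          t <- t + rexp(1L, rate = k * (k - 1L) / 2)
          if (t > t_next) break
          pr <- sample.int(k, 2L)
          i1 <- idx[pr[1L]]; i2 <- idx[pr[2L]]
          nxt <- nxt + 1L
          g_child[nxt, ] <- c(lin_node[i1], lin_node[i2])
          g_age[nxt] <- t
          lin_node[i1] <- nxt
          lin_node <- lin_node[-i2]
          lin_pop <- lin_pop[-i2]
          idx <- which(lin_pop == p)
          k <- length(idx)
        }
      }
    }
    if (e > n_ev) break
    t_cur <- max(t_cur, t_next)
    if (ev$type[e] == 1L) {                      # pulse
      pl <- prep$pulses[[ev$id[e]]]
      if (pl$gamma > 0) {
        idx <- which(lin_pop == pl$recipient)
        if (length(idx)) {
          mv <- runif(length(idx)) < pl$gamma
          if (any(mv)) {
            lin_pop[idx[mv]] <- pl$donor
            moved[ev$id[e]] <- TRUE
          }
        }
      }
    } else {                                     # species node: merge pops
      v <- ev$id[e]
      lin_pop[lin_pop %in% prep$children[[v]]] <- v
    }
  }
  list(n_tips = L, n_nodes = nxt, age = g_age, child = g_child,
       tip_pop = rep(tips_kept, each = samples), moved = moved)
}

## convert the coalescence record to an ape phylo object
.locus_phylo <- function(rec, tip_labels) {
  L <- rec$n_tips
  n_int <- rec$n_nodes - L
  ## internal node created k-th (id L+k) -> phylo id 2L - k; root = L+1
  remap <- function(id) ifelse(id <= L, id, 2L * L - (id - L))
  edges <- matrix(0L, nrow = 2L * (n_int), ncol = 2L)
  elen <- numeric(2L * n_int)
  r <- 0L
  for (k in n_int:1) {
    v <- L + k
    for (ch in rec$child[v, ]) {
      r <- r + 1L
      edges[r, ] <- c(remap(v), remap(ch))
      elen[r] <- rec$age[v] - rec$age[ch]
    }
  }
  structure(list(edge = edges, edge.length = elen,
                 tip.label = tip_labels, Nnode = n_int),
            class = "phylo")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' @param config A [sim_config()].
#' @return A list with components `trees` (a `multiPhylo` of binary gene
#'   trees with branch lengths in coalescent units) and `truth`, the
#'   per-locus truth log: a data frame with the locus index, the gene-tree
#'   newick, one logical `moved_<k>` column per pulse (did pulse k reroute at
#'   least one lineage), and — when one lineage is sampled per species — one
#'   `class_<branch_id>` column per internal species-tree branch giving the
#'   gene tree's topology class for that branch.
#' @examples
#' sp <- parse_newick("((a:1,b:1):0.5,(c:1,d:1):0.5);")
#' sim <- simulate_gene_trees(sim_config(sp, n_loci = 10, seed = 1))
#' @export
simulate_gene_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prep <- .msc_prep(config)
  ntip <- prep$ntip
  sp <- config$species_tree
  samples <- config$samples_per_species
  n_loci <- config$n_loci
  locus_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max, n_loci))
  trees <- vector("list", n_loci)
  moved <- matrix(FALSE, nrow = n_loci, ncol = length(prep$pulses))
  for (i in seq_len(n_loci)) {
    rec <- with_seed(locus_seeds[i], {
      kept <- seq_len(ntip)
      if (config$missing_prob > 0) {
        drop <- runif(ntip) < config$missing_prob
        if (sum(!drop) >= 2L) kept <- which(!drop)
      }
      .sim_locus(prep, kept, samples)
    })
    labs <- sp$tip.label[rec$tip_pop]
    if (samples > 1L)
      labs <- paste0(labs, "_", rep(seq_len(samples), times = rec$n_tips / samples))
    trees[[i]] <- .locus_phylo(rec, labs)
    if (length(prep$pulses)) moved[i, ] <- rec$moved
  }
  class(trees) <- "multiPhylo"
  truth <- data.frame(locus = seq_len(n_loci),
                      newick = vapply(trees, write_newick, character(1),
                                      digits = 8),
                      stringsAsFactors = FALSE)
  if (length(prep$pulses))
    for (k in seq_len(ncol(moved)))
      truth[[paste0("moved_", k)]] <- moved[, k]
  if (samples == 1L && ntip >= 4L) {
    contexts <- branch_contexts(sp)
    cls <- classify_matrix(trees, contexts, taxon_universe(sp$tip.label))
    for (j in seq_along(contexts))
      truth[[paste0("class_", contexts[[j]]$branch_id)]] <-
        GENE_TREE_CLASSES[cls[, j]]
  }
  list(trees = trees, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Simulate a JC69 alignment along a gene tree
#'
#' Jukes-Cantor (equal rates, equal base frequencies) evolution from a
#' uniform root state, sites independent. Branch lengths are the gene tree's
#' lengths multiplied by `scale` (substitutions per site per coalescent
#' unit).
#'
#' @param gene_tree `phylo` with branch lengths.
#' @param length Alignment length in bp (>= 1).
#' @param scale Substitutions per site per unit of branch length; `0` yields
#'   identical sequences.
#' @param seed Optional integer seed.
#' @return A character matrix (rows = taxa, uppercase A/C/G/T) with the
#'   taxon labels as row names.
#' @export
simulate_alignment <- function(gene_tree, length, scale = 1, seed = NULL) {
  if (is.null(gene_tree$edge.length))
    stop("gene tree must have branch lengths")
  stopifnot(length >= 1, scale >= 0)
  tr <- gene_tree
  tr$edge.length <- tr$edge.length * scale
  dat <- with_seed(seed,
                   phangorn::simSeq(tr, l = as.integer(length), type = "DNA"))
  m <- toupper(as.character(dat))
  rownames(m) <- names(dat)
  m
}

#' Write an alignment to FASTA
#'
#' @param aln Character matrix (rows = taxa) as returned by
#'   [simulate_alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a nucleotide alignment from FASTA or relaxed PHYLIP
#'
#' Format is auto-detected: files starting with `>` are FASTA, otherwise a
#' relaxed sequential PHYLIP (`ntax nsites` header, then `name sequence`
#' records, possibly wrapped) is assumed.
#'
#' @param path Input file.
#' @return Character matrix (rows = taxa, uppercase).
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty alignment file: ", path)
  if (startsWith(trimws(lines[1]), ">")) {
    hdr <- grep("^>", lines)
    names <- sub("^>\\s*", "", lines[hdr])
    starts <- hdr + 1L
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[starts[i]:ends[i]], collapse = "")
    }, character(1))
  } else {
    dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    if (length(dims) < 2L || anyNA(dims))
      stop("bad PHYLIP header in ", path)
    body <- lines[-1L]
    names <- character(0); seqs <- character(0)
    for (ln in body) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(names) < dims[1L] &&
          (length(seqs) == 0L || nchar(seqs[length(seqs)]) >= dims[2L])) {
        names <- c(names, tok[1L])
        seqs <- c(seqs, paste(tok[-1L], collapse = ""))
      } else {
        seqs[length(seqs)] <- paste0(seqs[length(seqs)],
                                     paste(tok, collapse = ""))
      }
    }
    if (length(names) != dims[1L])
      stop("expected ", dims[1L], " sequences in ", path)
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("unequal sequence lengths in ", path)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names
  m
}
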