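# Shared fixtures and independent oracles used across the suite.

# random rooted binary tree with given labels
rand_tree <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels))
}

# split-set fingerprint of a tree via ape's clade enumeration (independent of
# the package's bitmask machinery): canonical sorted sides of non-trivial
# unrooted splits
split_keys <- function(tree) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- sort(labs[cl])
    other <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    keys <- c(keys, key)
  }
  sort(unique(keys))
}

# brute-force gene-tree classifier: restrict explicitly, enumerate every
# split of the restricted tree, and test the three arrangements by set
# comparison
oracle_classify <- function(gene_tree, ctx) {
  present <- lapply(ctx[c("A", "B", "C", "D")], intersect,
                    y = gene_tree$tip.label)
  if (any(lengths(present) == 0)) return("NOT_DECISIVE")
  labs <- gene_tree$tip.label
  pp <- ape::prop.part(gene_tree)
  sides <- list()
  for (cl in pp) {
    for (side in list(sort(labs[cl]), sort(setdiff(labs, labs[cl])))) {
      if (length(side) >= 2 && length(side) <= length(labs) - 2)
        sides <- c(sides, list(side))
    }
  }
  matches <- function(g1, g2) {
    s <- sort(c(present[[g1]], present[[g2]]))
    o <- sort(setdiff(labs, s))
    if (length(s) < 2 || length(o) < 2) return(FALSE)
    any(vapply(sides, function(x) identical(x, s) || identical(x, o),
               logical(1)))
  }
  if (matches("A", "B")) return("CONCORDANT")
  if (matches("A", "C")) return("ALT1")
  if (matches("A", "D")) return("ALT2")
  "PARAPHYLETIC"
}

# a 29-taxon rooted binary species tree with a 26-taxon ingroup and a
# 3-taxon outgroup clade, mimicking the shape of a genome-scale primate
# phylogeny fixture
species_tree_29 <- function() {
  ing <- paste0("sp", sprintf("%02d", 1:26))
  nest <- ing[1]
  for (k in 2:26) nest <- paste0("(", nest, ",", ing[k], ")")
  parse_newick(paste0("((og1,(og2,og3)),", nest, ");"))
}

ingroup_29 <- function() paste0("sp", sprintf("%02d", 1:26))
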