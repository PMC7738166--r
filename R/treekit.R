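#' @useDynLib phylodelta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq pnorm sd rexp rmultinom rbinom runif rpois setNames
#'   chisq.test fisher.test lm coef complete.cases
#' @importFrom utils write.table read.table packageVersion
"_PACKAGE"

## ---------------------------------------------------------------------------
## Newick I/O.  Parsing and writing stand on ape; this layer adds validation
## (duplicate labels, malformed input with a character position where we can
## find one) and keeps the package's contract independent of ape's interface.
## Taxon-name matching throughout the package is EXACT string equality: no
## case folding, no whitespace trimming, no underscore/space interconversion.
## ---------------------------------------------------------------------------

#' Parse a single newick string into a tree
#'
#' @param text A newick string, terminated by `;`.
#' @return An object of class `phylo` (see \pkg{ape}). Branch lengths and
#'   internal node labels are preserved when present; quoted labels are
#'   unquoted.
#' @details Leaf labels must be unique and non-empty. Taxon names are matched
#'   by exact string equality everywhere in this package.
#' @examples
#' tr <- parse_newick("((a,b),(c,d));")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("newick parse error: input does not end with ';'")
  .check_balanced(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)),
                 warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick parse error: input did not yield a tree")
  validate_tree(tr)
  tr
}

## bracket balance pre-check, reporting the 1-based character position of the
## first offending parenthesis
.check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at character ", i, ": unmatched ')'")
    }
  }
  if (depth != 0L)
    stop("newick parse error at character ", nchar(text),
         ": ", depth, " unclosed '('")
  invisible(TRUE)
}

#' Validate a tree object
#'
#' Checks the invariants assumed throughout the package: unique non-empty leaf
#' labels and non-negative branch lengths (when present).
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly; errors describe any violation.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch length")
  invisible(tree)
}

#' Read a set of trees from a newick file (one tree per line)
#'
#' @param path Path to a newick file; one tree per line (blank lines skipped).
#' @return A `multiPhylo` list of validated trees.
#' @export
read_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees in ", path)
  trees <- lapply(seq_along(lines), function(i) {
    tryCatch(parse_newick(lines[i]),
             error = function(e) stop("tree ", i, " in ", path, ": ",
                                      conditionMessage(e)))
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Write a tree to a newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths (default 15, so that a
#'   parse/write round trip preserves lengths).
#' @return A newick string ending in `;`.
#' @export
write_newick <- function(tree, digits = 15) {
  validate_tree(tree)
  ape::write.tree(tree, digits = digits)
}

#' Write a set of trees to a newick file, one per line
#'
#' @param trees A `multiPhylo` or list of `phylo` objects.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, digits = 15) {
  txt <- vapply(trees, write_newick, character(1), digits = digits)
  writeLines(txt, path)
  invisible(path)
}

#' Restrict a tree to a subset of taxa
#'
#' Induced subtree on `keep`: degree-2 nodes are suppressed and their branch
#' lengths summed (standard pruning semantics).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain; must be a subset of
#'   the tree's leaves with at least 2 members.
#' @return The induced `phylo` subtree.
#' @export
restrict_tree <- function(tree, keep) {
  keep <- as.character(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(unique(keep)) < 2L) stop("need at least 2 taxa to restrict to")
  ape::keep.tip(tree, keep)
}

## ---------------------------------------------------------------------------
## Bitmask split machinery.  A taxon universe (sorted character vector) maps
## each taxon to one bit; a set of taxa is a packed integer vector (31 bits
## per word).  All gene-tree classification runs on these masks.
## ---------------------------------------------------------------------------

.BITS <- 31L

taxon_universe <- function(labels) sort(unique(as.character(labels)))

mask_zero <- function(universe) integer(ceiling(length(universe) / .BITS))

mask_from_taxa <- function(taxa, universe) {
  idx <- match(taxa, universe)
  if (anyNA(idx))
    stop("taxa outside universe: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  m <- mask_zero(universe)
  if (length(idx)) {
    w <- (idx - 1L) %/% .BITS + 1L
    b <- (idx - 1L) %% .BITS
    for (i in seq_along(idx))
      m[w[i]] <- bitwOr(m[w[i]], bitwShiftL(1L, b[i]))
  }
  m
}

mask_taxa <- function(mask, universe) {
  idx <- integer(0)
  for (w in seq_along(mask)) {
    if (mask[w] == 0L) next
    bits <- which(bitwAnd(mask[w], bitwShiftL(1L, 0:(.BITS - 1L))) != 0L)
    idx <- c(idx, (w - 1L) * .BITS + bits)
  }
  universe[idx]
}

mask_and <- function(a, b) bitwAnd(a, b)
mask_or  <- function(a, b) bitwOr(a, b)
mask_diff <- function(a, b) bitwAnd(a, bitwNot(b))
mask_eq  <- function(a, b) all(a == b)
mask_empty <- function(a) all(a == 0L)
mask_popcount <- function(a) {
  n <- 0L
  for (w in a) {
    while (w != 0L) { n <- n + bitwAnd(w, 1L); w <- bitwShiftR(w, 1L) }
  }
  n
}

## Clade masks for every internal edge of `tree`, over `universe`.
## Returns list(leaf = leaf-set mask, splits = list of canonical one-side
## masks of the non-trivial splits, in the unrooted sense, deduplicated).
## Canonical form: the side NOT containing the lowest-index leaf present.
tree_split_masks <- function(tree, universe) {
  ntip <- length(tree$tip.label)
  tipmask <- lapply(tree$tip.label, mask_from_taxa, universe = universe)
  leaf <- Reduce(mask_or, tipmask, mask_zero(universe))
  if (ntip < 4L) return(list(leaf = leaf, splits = list()))
  tr <- stats::reorder(tree, "postorder")
  nnode <- ntip + tr$Nnode
  clade <- vector("list", nnode)
  clade[seq_len(ntip)] <- tipmask
  e <- tr$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    cm <- clade[[ch]]
    clade[[p]] <- if (is.null(clade[[p]])) cm else mask_or(clade[[p]], cm)
  }
  ## lowest-index leaf of the tree within the universe
  low <- which.min(match(tree$tip.label, universe))
  lowmask <- tipmask[[low]]
  out <- list(); seen <- character(0)
  for (i in seq_len(nrow(e))) {
    ch <- e[i, 2L]
    if (ch <= ntip) next                  # tip edge: trivial
    cm <- clade[[ch]]
    side <- if (mask_empty(mask_and(cm, lowmask))) cm else mask_diff(leaf, cm)
    k <- mask_popcount(side)
    if (k < 2L || k > ntip - 2L) next     # trivial in the unrooted sense
    key <- paste(side, collapse = ".")
    if (key %in% seen) next               # root edge duplicates
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- side
  }
  list(leaf = leaf, splits = out)
}

#' Non-trivial bipartitions (splits) of a tree
#'
#' @param tree A `phylo` object.
#' @return A list of objects of class `bipartition`, each with components
#'   `left` and `right` (character vectors; the side containing the
#'   lexicographically smallest label comes first). Trees with fewer than 4
#'   leaves yield an empty list. The two edges incident to the root of a
#'   rooted tree induce one split, not two.
#' @export
bipartitions <- function(tree) {
  validate_tree(tree)
  universe <- taxon_universe(tree$tip.label)
  sm <- tree_split_masks(tree, universe)
  lapply(sm$splits, function(side) {
    a <- mask_taxa(side, universe)
    b <- mask_taxa(mask_diff(sm$leaf, side), universe)
    new_bipartition(a, b)
  })
}

new_bipartition <- function(a, b) {
  a <- sort(a); b <- sort(b)
  if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
  structure(list(left = a, right = b), class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(paste(x$left, collapse = ","), "|", paste(x$right, collapse = ","), "\n")
  invisible(x)
}

#' @export
format.bipartition <- function(x, ...) {
  paste(paste(x$left, collapse = ","), paste(x$right, collapse = ","), sep = "|")
}

## ---------------------------------------------------------------------------
## Branch contexts: the four taxon groups around each internal branch of a
## rooted binary species tree.  A,B are the two child clades below the
## branch's distal node, C the sister clade, D everything else.  The two
## branches incident to the root induce the same unrooted split; one context
## is emitted for it (distal side = root child whose clade holds the
## lexicographically smallest taxon among the two).
## ---------------------------------------------------------------------------

#' Derive the four-group context around each internal species-tree branch
#'
#' For every internal branch of a rooted binary species tree, the four
#' disjoint taxon groups (A, B, C, D) that define the concordant gene-tree
#' arrangement AB|CD and its two alternatives AC|BD (ALT1) and AD|BC (ALT2):
#' A and B are the two child clades below the branch, C the sister clade and
#' D the remaining taxa. A rooted binary tree on n taxa yields n - 3 contexts.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param ingroup Optional character vector of ingroup taxa. When supplied,
#'   only contexts whose distal clade (A + B) is a proper subset of the
#'   ingroup are kept — the standard convention for excluding the outgroup
#'   attachment branches from per-branch testing.
#' @return A list of `branch_context` objects with components `branch_id`
#'   (canonical id: sorted taxa of the smaller split side, comma-joined),
#'   `A`, `B`, `C`, `D` (character vectors) and `split` (`bipartition`).
#' @export
branch_contexts <- function(species_tree, ingroup = NULL) {
  validate_tree(species_tree)
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (!ape::is.binary(species_tree))
    stop("species tree must be binary (no polytomies)")
  ntip <- length(species_tree$tip.label)
  if (ntip < 4L) return(list())
  tr <- stats::reorder(species_tree, "postorder")
  e <- tr$edge
  root <- ntip + 1L
  nnode <- ntip + tr$Nnode
  ## clade tip sets per node
  clade <- vector("list", nnode)
  for (i in seq_len(ntip)) clade[[i]] <- tr$tip.label[i]
  for (i in seq_len(nrow(e)))
    clade[[e[i, 1L]]] <- c(clade[[e[i, 1L]]], clade[[e[i, 2L]]])
  children <- split(e[, 2L], e[, 1L])
  parent <- integer(nnode); parent[e[, 2L]] <- e[, 1L]
  all_taxa <- sort(tr$tip.label)
  root_kids <- children[[as.character(root)]]
  ## pick which root child carries the merged root context
  root_carrier <- NA_integer_
  int_kids <- root_kids[root_kids > ntip]
  if (length(int_kids) == 2L) {
    mins <- vapply(int_kids, function(k) min(clade[[k]]), character(1))
    root_carrier <- int_kids[order(mins)[1L]]
  } else if (length(int_kids) == 1L) {
    ## other root child is a leaf: the root split is trivial, no context
    root_carrier <- NA_integer_
  }
  out <- list()
  for (v in (ntip + 2L):nnode) {          # internal nodes except the root
    kids <- children[[as.character(v)]]
    A <- sort(clade[[kids[1L]]]); B <- sort(clade[[kids[2L]]])
    p <- parent[v]
    if (p == root) {
      if (is.na(root_carrier) || v != root_carrier) next
      sib <- root_kids[root_kids != v]
      sk <- children[[as.character(sib)]]   # sibling is internal here
      C <- sort(clade[[sk[1L]]]); D <- sort(clade[[sk[2L]]])
    } else {
      pk <- children[[as.character(p)]]
      sib <- pk[pk != v]
      C <- sort(clade[[sib]])
      D <- sort(setdiff(all_taxa, c(A, B, C)))
      if (!length(D)) next
    }
    out[[length(out) + 1L]] <- new_branch_context(A, B, C, D)
  }
  if (!is.null(ingroup)) {
    out <- Filter(function(ctx) {
      ab <- c(ctx$A, ctx$B)
      all(ab %in% ingroup) && length(ab) < length(ingroup)
    }, out)
  }
  out
}

#' Construct a branch context
#'
#' @param A,B,C,D Disjoint non-empty character vectors of taxon labels; their
#'   union is the taxon universe of the species tree. A and B are the child
#'   clades below the branch, C the sister clade, D the remainder.
#' @return An object of class `branch_context`.
#' @export
new_branch_context <- function(A, B, C, D) {
  groups <- list(A = sort(A), B = sort(B), C = sort(C), D = sort(D))
  if (any(lengths(groups) == 0L)) stop("all four groups must be non-empty")
  allt <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(allt)) stop("groups A,B,C,D must be disjoint")
  ab <- sort(c(groups$A, groups$B)); cd <- sort(c(groups$C, groups$D))
  smaller <- if (length(ab) < length(cd)) ab
             else if (length(cd) < length(ab)) cd
             else if (paste(ab, collapse = ",") <= paste(cd, collapse = ",")) ab
             else cd
  structure(c(groups, list(
    branch_id = paste(smaller, collapse = ","),
    split = new_bipartition(ab, cd))), class = "branch_context")
}

#' @export
print.branch_context <- function(x, ...) {
  cat("branch", x$branch_id, "\n")
  for (g in c("A", "B", "C", "D"))
    cat(" ", g, "=", paste(x[[g]], collapse = ","), "\n")
  invisible(x)
}

## masks for a context over a universe (internal; memoised by callers)
context_masks <- function(ctx, universe) {
  list(A = mask_from_taxa(ctx$A, universe),
       B = mask_from_taxa(ctx$B, universe),
       C = mask_from_taxa(ctx$C, universe),
       D = mask_from_taxa(ctx$D, universe))
}
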