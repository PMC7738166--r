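test_that("newick parsing captures topology, lengths and labels", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))
  sp <- bipartitions(tr)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$left, c("a", "b"))
  expect_equal(sp[[1]]$right, c("c", "d"))

  tr2 <- parse_newick("((a:1,b:2):0.5,c:1);")
  len <- setNames(tr2$edge.length, tr2$tip.label[tr2$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 1))
  expect_true(0.5 %in% tr2$edge.length)

  tr3 <- parse_newick("((a,b)anc:0.5,c);")
  expect_true("anc" %in% tr3$node.label)
  expect_match(write_newick(tr3), "anc")
})

test_that("parsing rejects malformed and duplicated input", {
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  expect_error(parse_newick("((a,b),(c,d))"), "';'")
  expect_error(parse_newick("((a,b),(c,d)));"), "character 14")
  expect_error(parse_newick("(((a,b),(c,d);"), "unclosed")
})

test_that("write/parse round trip preserves splits and lengths", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:64, 1)
    tr <- rand_tree(paste0("t", seq_len(n)))
    back <- parse_newick(write_newick(tr))
    expect_setequal(back$tip.label, tr$tip.label)
    expect_identical(split_keys(back), split_keys(tr))
    # lengths preserved to >= 10 significant digits through the text form
    o <- setNames(tr$edge.length, tr$edge[, 2])
    b <- setNames(back$edge.length, back$edge[, 2])
    expect_equal(sort(unname(b)), sort(unname(o)), tolerance = 1e-10)
  }
})

test_that("restriction yields the induced subtree with summed lengths", {
  tr <- parse_newick("((a,b),(c,(d,e)));")
  sub <- restrict_tree(tr, c("a", "c", "d"))
  expect_setequal(sub$tip.label, c("a", "c", "d"))
  expect_identical(split_keys(sub), character(0))  # 3 leaves: no splits
  # pruning sums branch lengths through suppressed nodes
  tr2 <- parse_newick("((a:1,b:1):2,(c:1,(d:1,e:1):3):1);")
  sub2 <- restrict_tree(tr2, c("a", "d"))
  expect_equal(sum(sub2$edge.length), 1 + 2 + 1 + 3 + 1)
  # identity
  expect_identical(split_keys(restrict_tree(tr, tr$tip.label)),
                   split_keys(tr))
  expect_error(restrict_tree(tr, c("a", "zz")), "zz")
  expect_error(restrict_tree(tr, "a"), "at least 2")
})

test_that("nested restriction equals restriction to the intersection", {
  set.seed(7)
  for (rep in 1:25) {
    labs <- paste0("t", 1:10)
    tr <- rand_tree(labs)
    s1 <- sample(labs, 7)
    s2 <- c(sample(s1, 3), sample(setdiff(labs, s1), 2))
    both <- intersect(s1, s2)
    if (length(both) < 2) next
    a <- restrict_tree(restrict_tree(tr, s1), both)
    b <- restrict_tree(tr, both)
    expect_identical(split_keys(a), split_keys(b))
    expect_equal(sum(a$edge.length), sum(b$edge.length), tolerance = 1e-12)
  }
})

test_that("bipartition counts follow n - 3 and agree with an independent enumeration", {
  expect_length(bipartitions(parse_newick("(((a,b),c),(d,e));")), 2L)
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    tr <- rand_tree(paste0("t", seq_len(n)))
    bp <- bipartitions(tr)
    expect_length(bp, n - 3L)
    keys <- sort(vapply(bp, function(b) {
      l <- paste(b$left, collapse = ","); r <- paste(b$right, collapse = ",")
      if (l < r) l else r
    }, character(1)))
    expect_identical(keys, split_keys(tr))
  }
  # fewer than 4 leaves: empty, not an error
  expect_length(bipartitions(parse_newick("((a,b),c);")), 0L)
})

test_that("branch contexts partition the taxon set around each internal branch", {
  ctx <- branch_contexts(parse_newick("((a,b),(c,d));"))
  expect_length(ctx, 1L)
  expect_equal(ctx[[1]]$A, "a")
  expect_equal(ctx[[1]]$B, "b")
  expect_setequal(c(ctx[[1]]$C, ctx[[1]]$D), c("c", "d"))

  expect_length(branch_contexts(parse_newick("((((a,b),c),d),e);")), 2L)
  expect_error(branch_contexts(parse_newick("((a,b,c),(d,e));")), "binary")

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:24, 1)
    tr <- rand_tree(paste0("t", seq_len(n)))
    ctxs <- branch_contexts(tr)
    expect_length(ctxs, n - 3L)
    keys <- split_keys(tr)
    for (cx in ctxs) {
      expect_setequal(c(cx$A, cx$B, cx$C, cx$D), tr$tip.label)
      expect_equal(anyDuplicated(c(cx$A, cx$B, cx$C, cx$D)), 0L)
      ab <- sort(c(cx$A, cx$B)); cd <- sort(c(cx$C, cx$D))
      key <- if (paste(ab, collapse = ",") < paste(cd, collapse = ","))
        paste(ab, collapse = ",") else paste(cd, collapse = ",")
      expect_true(key %in% keys)   # concordant split is a tree split
    }
    # ids stable under re-parsing
    ctxs2 <- branch_contexts(parse_newick(write_newick(tr)))
    expect_setequal(vapply(ctxs, `[[`, "", "branch_id"),
                    vapply(ctxs2, `[[`, "", "branch_id"))
  }
})

test_that("a 29-taxon tree yields 26 contexts, 24 within the ingroup", {
  tr <- species_tree_29()
  expect_length(branch_contexts(tr), 26L)
  expect_length(branch_contexts(tr, ingroup = ingroup_29()), 24L)
})
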