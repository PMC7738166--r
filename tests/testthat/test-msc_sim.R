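test_that("expected concordance has the right endpoints and shape", {
  expect_equal(expected_concordance(0), 1 / 3)
  expect_equal(expected_concordance(50), 1, tolerance = 1e-12)
  tt <- seq(0, 5, by = 0.25)
  expect_true(all(diff(expected_concordance(tt)) > 0))
  expect_error(expected_concordance(-0.1), "non-negative")
})

test_that("simulated topology frequencies match the coalescent closed form", {
  for (T in c(0.1, 1)) {
    sp <- parse_newick(sprintf("((a:1,b:1):%f,c:%f);", T, 1 + T))
    sim <- simulate_gene_trees(sim_config(sp, n_loci = 4000, seed = 50 + round(100 * T)))
    conc <- vapply(sim$trees, function(tr)
      ape::is.monophyletic(tr, c("a", "b")), logical(1))
    p <- expected_concordance(T)
    se <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(mean(conc) - p), 3 * se)
    # the two discordant classes are exchangeable
    disc <- vapply(sim$trees[!conc], function(tr)
      ape::is.monophyletic(tr, c("a", "c")), logical(1))
    bt <- binom.test(sum(disc), length(disc))
    expect_gt(bt$p.value, 0.001)
  }
})

test_that("gene trees are binary, positive-length, and round-trip parseable", {
  sp <- parse_newick("((((A:1,B:1):0.5,C:1.5):0.5,D:2):0.5,E:2.5);")
  sim <- simulate_gene_trees(sim_config(sp, n_loci = 50, seed = 13,
                                        missing_prob = 0.2))
  for (tr in sim$trees) {
    expect_true(ape::is.binary(tr))
    expect_true(all(tr$edge.length >= 0))
    back <- parse_newick(write_newick(tr))
    expect_setequal(back$tip.label, tr$tip.label)
    if (length(tr$tip.label) >= 4)
      expect_identical(split_keys(back), split_keys(tr))
    expect_gte(length(tr$tip.label), 2L)
  }
  # with missing taxa, some loci drop tips
  sizes <- vapply(sim$trees, function(tr) length(tr$tip.label), integer(1))
  expect_true(any(sizes < 5))
})

test_that("simulation is reproducible and locus substreams are independent of order", {
  sp <- parse_newick("((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);")
  s1 <- simulate_gene_trees(sim_config(sp, n_loci = 20, seed = 77))
  s2 <- simulate_gene_trees(sim_config(sp, n_loci = 20, seed = 77))
  expect_identical(s1$truth$newick, s2$truth$newick)
  # the first loci of a longer run coincide with those of a shorter run
  s3 <- simulate_gene_trees(sim_config(sp, n_loci = 10, seed = 77))
  expect_identical(s3$truth$newick, s1$truth$newick[1:10])
})

test_that("a zero-strength pulse leaves the simulation untouched", {
  sp <- parse_newick("((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);")
  p0 <- introgression_pulse("c", "b", time = 0.2, gamma = 0)
  plain <- simulate_gene_trees(sim_config(sp, n_loci = 30, seed = 19))
  gated <- simulate_gene_trees(sim_config(sp, pulses = list(p0),
                                          n_loci = 30, seed = 19))
  expect_identical(plain$truth$newick, gated$truth$newick)
  expect_false(any(gated$truth$moved_1))
})

test_that("a gamma = 1 pulse reroutes the recipient into the donor lineage", {
  # long tip branches: a rerouted b lineage almost surely coalesces with c
  sp <- parse_newick("((a:2,b:2):0.5,(c:2.2,d:2.2):0.3);")
  p1 <- introgression_pulse("c", "b", time = 0, gamma = 1)
  sim <- simulate_gene_trees(sim_config(sp, pulses = list(p1),
                                        n_loci = 300, seed = 23))
  expect_true(all(sim$truth$moved_1))
  # b now behaves as if sampled from c: the b+c arrangement (ALT2) dominates
  cls <- sim$truth[["class_a,b"]]
  expect_gt(mean(cls == "ALT2"), 0.8)
})

test_that("pulses are validated against population existence intervals", {
  sp <- parse_newick("((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);")
  expect_error(sim_config(sp, list(introgression_pulse("zz", "b", 0.2, 0.5)),
                          n_loci = 5), "unknown population")
  # the 'a,b' ancestral population exists only over [1.0, 1.5)
  expect_error(sim_config(sp, list(introgression_pulse("c", "a,b", 0.2, 0.5)),
                          n_loci = 5), "existence interval")
  expect_silent(sim_config(sp, list(introgression_pulse("c,d", "a,b", 1.3, 0.5)),
                           n_loci = 5))
})

test_that("JC69 alignments reproduce the expected divergence", {
  two <- parse_newick("(x:0.15,y:0.15);")
  aln <- simulate_alignment(two, length = 10000, scale = 1, seed = 3)
  pdiff <- mean(aln["x", ] != aln["y", ])
  t <- 0.3
  expected <- 0.75 * (1 - exp(-4 * t / 3))
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(pdiff - expected), 3 * se)

  # determinism and the zero-rate limit
  aln2 <- simulate_alignment(two, length = 10000, scale = 1, seed = 3)
  expect_identical(aln, aln2)
  flat <- simulate_alignment(two, length = 100, scale = 0, seed = 4)
  expect_true(all(flat["x", ] == flat["y", ]))
  notree <- parse_newick("(x,y);")
  expect_error(simulate_alignment(notree, 10), "branch lengths")
})

test_that("fasta round trip preserves the alignment", {
  two <- parse_newick("(x:0.1,y:0.1);")
  aln <- simulate_alignment(two, length = 60, scale = 1, seed = 5)
  f <- tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  back <- read_alignment(f)
  expect_identical(back, aln)
})
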