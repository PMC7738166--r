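test_that("the Delta statistic ranks counts and normalizes", {
  expect_equal(delta_statistic(437, 413), 24 / 850)
  expect_equal(delta_statistic(413, 437), 24 / 850)  # ranking is internal
  expect_equal(delta_statistic(10, 10), 0)
  expect_equal(delta_statistic(5, 0), 1)
  expect_true(is.na(delta_statistic(0, 0)))
  set.seed(2)
  for (i in 1:50) {
    x <- sample(0:500, 2)
    if (sum(x) == 0) next
    d <- delta_statistic(x[1], x[2])
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, delta_statistic(x[2], x[1]))
  }
})

test_that("the Dunn-Sidak cutoff matches its closed form and dominates Bonferroni", {
  expect_equal(signif(sidak_cutoff(0.05, 17), 3), 0.00301)
  expect_equal(sidak_cutoff(0.05, 1), 0.05)
  expect_equal(sidak_cutoff(0.05, 2), 1 - sqrt(0.95))
  expect_equal(sidak_cutoff(0.05, 2), 0.02532, tolerance = 1e-3)
  for (a in c(0.01, 0.05, 0.1))
    for (m in c(1, 2, 5, 17, 100))
      expect_gte(sidak_cutoff(a, m), a / m - 1e-12)
  expect_error(sidak_cutoff(0, 5))
  expect_error(sidak_cutoff(0.05, 0))
})

test_that("branch screening applies the discordant-fraction threshold", {
  rec <- data.frame(branch_id = c("b1", "b2", "b3"),
                    n_decisive = c(100, 100, 0),
                    n_concordant = c(96, 45, 0))
  expect_equal(screen_branches(rec, screen_config()), "b2")
  expect_equal(screen_branches(rec,
                               screen_config(min_discordant_fraction = 0)),
               c("b1", "b2"))
  expect_error(screen_config(n_boot = 50), "n_boot")
})

test_that("the gene-tree bootstrap is seed-reproducible and internally consistent", {
  sp <- parse_newick("((a:1,b:1):0.3,(c:1,d:1):1);")
  sim <- simulate_gene_trees(sim_config(sp, n_loci = 300, seed = 11))
  ctx <- branch_contexts(sp)[[1]]
  cfg <- screen_config(n_boot = 200, seed = 99)
  r1 <- bootstrap_delta(sim$trees, sp, ctx, cfg)
  r2 <- bootstrap_delta(sim$trees, sp, ctx, cfg)
  expect_identical(r1, r2)                       # bit-identical under a seed
  expect_equal(r1$delta,
               (r1$n_df1 - r1$n_df2) / (r1$n_df1 + r1$n_df2))
  expect_gte(r1$n_df1, r1$n_df2)
  expect_gte(r1$delta, 0); expect_lte(r1$delta, 1)
  # p decreases as z increases (same construction, different z)
  zs <- seq(0, 5, by = 0.5)
  ps <- 2 * pnorm(zs, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  # no discordance at all: flagged undefined
  conc <- rep(c(parse_newick("((a,b),(c,d));")), 150)
  r3 <- bootstrap_delta(conc, sp, ctx, cfg)
  expect_true(is.na(r3$delta))
  expect_true(is.na(r3$p_value))
})

test_that("delta_test screens, corrects and co-varies branches", {
  sp5 <- parse_newick("((((A:1,B:1):0.5,C:1.5):0.5,D:2):0.5,E:2.5);")
  sim <- simulate_gene_trees(sim_config(sp5, n_loci = 400, seed = 21))
  dt <- delta_test(sp5, sim$trees, screen_config(n_boot = 200, seed = 5))
  expect_s3_class(dt, "delta_test")
  expect_equal(dt$m, nrow(dt$results))
  expect_equal(dt$cutoff, sidak_cutoff(0.05, dt$m))
  expect_true(all(dt$results$p_value >= 0 & dt$results$p_value <= 1,
                  na.rm = TRUE))
  # corrected significance implies raw significance
  expect_true(all(!dt$results$significant_corrected |
                    dt$results$significant_raw))
  out <- capture.output(print(dt))
  expect_true(any(grepl("Dunn-Sidak", out)))
})

test_that("the quartet follow-up restricts trees and validates the choice", {
  sp <- parse_newick("((a:1,b:1):0.3,(c:1,d:1):1);")
  sim <- simulate_gene_trees(sim_config(sp, n_loci = 200, seed = 31))
  ctx <- branch_contexts(sp)[[1]]
  cfg <- screen_config(n_boot = 150, seed = 8)
  full <- bootstrap_delta(sim$trees, sp, ctx, cfg)
  quart <- quartet_followup(sim$trees, sp, ctx,
                            c("a", "b", "c", "d"), cfg)
  # on a 4-taxon tree the restriction is the identity
  expect_equal(quart$n_loci_used, 200)
  for (cn in c("n_df1", "n_df2", "delta", "boot_sd", "z_score", "p_value"))
    expect_equal(quart[[cn]], full[[cn]])
  expect_error(quartet_followup(sim$trees, sp, ctx, c("a", "b", "c", "c")),
               "distinct")
  expect_error(quartet_followup(sim$trees, sp, ctx, c("c", "d", "a", "b")),
               NA)  # order does not matter
  sp6 <- parse_newick("(((a1:1,a2:1):1,b:2):1,(c:1,d:1):2);")
  ctx6 <- branch_contexts(sp6)
  ids6 <- vapply(ctx6, `[[`, "", "branch_id")
  cx <- ctx6[[match("c,d", ids6)]]   # groups: A={a1,a2}, B={b}, C={c}, D={d}
  expect_error(quartet_followup(sim$trees, sp6, cx, c("a1", "a2", "b", "c")),
               "exactly one")
})

test_that("a strong pulse between non-sister lineages is detected", {
  sp5 <- parse_newick("((((A:1,B:1):0.5,C:1.5):0.5,D:2):0.5,E:2.5);")
  pulse <- introgression_pulse("C", "A", time = 0.25, gamma = 0.4)
  sim <- simulate_gene_trees(sim_config(sp5, pulses = list(pulse),
                                        n_loci = 600, seed = 41))
  dt <- delta_test(sp5, sim$trees, screen_config(n_boot = 300, seed = 6))
  r <- dt$results[dt$results$branch_id == "A,B", ]
  expect_true(r$significant_corrected)
  expect_equal(r$df1_class, "ALT1")   # the A+C arrangement is inflated
})
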