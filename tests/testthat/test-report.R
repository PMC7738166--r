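fixture_files <- function(dir, n_loci = 40, seed = 91, with_aln = FALSE) {
  sp <- parse_newick("((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);")
  sim <- simulate_gene_trees(sim_config(sp, n_loci = n_loci, seed = seed))
  spf <- file.path(dir, "species.nwk")
  gtf <- file.path(dir, "genetrees.nwk")
  writeLines(write_newick(sp), spf)
  write_trees(sim$trees, gtf)
  out <- list(sp = spf, gt = gtf, tree = sp, sim = sim)
  if (with_aln) {
    ad <- file.path(dir, "aln")
    dir.create(ad)
    for (i in seq_along(sim$trees))
      write_fasta(simulate_alignment(sim$trees[[i]], 150, scale = 0.5,
                                     seed = seed + i),
                  file.path(ad, sprintf("locus%03d.fasta", i)))
    out$aln_dir <- ad
  }
  out
}

test_that("run_concord writes the per-branch table and annotated tree", {
  dir <- withr::local_tempdir()
  fx <- fixture_files(dir, with_aln = TRUE)
  res <- run_concord(fx$sp, fx$gt, file.path(dir, "out"),
                     aln_dir = fx$aln_dir, n_quartets = 20, seed = 1)
  tab <- read.table(file.path(dir, "out.cf.tsv"), sep = "\t", header = TRUE,
                    check.names = FALSE)
  expect_true(all(c("branch_id", "n_decisive", "gCF", "sCF") %in% names(tab)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_decisive, 40)
  ann <- readLines(file.path(dir, "out.cf.nwk"))
  expect_match(ann, "/")                       # gCF/sCF labels present
  expect_true(file.exists(file.path(dir, "out.cf.tsv.manifest.json")))
  # identical concordant input: gCF 100 everywhere
  gtf2 <- file.path(dir, "concordant.nwk")
  write_trees(rep(c(fx$tree), 3), gtf2)
  res2 <- run_concord(fx$sp, gtf2, file.path(dir, "out2"))
  expect_true(all(as.data.frame(res2$concordance)$gCF == 100))
})

test_that("run_concord rejects taxa absent from the species tree", {
  dir <- withr::local_tempdir()
  fx <- fixture_files(dir)
  bad <- file.path(dir, "bad.nwk")
  writeLines(c(write_newick(fx$tree), "((a,zz),(c,d));"), bad)
  expect_error(run_concord(fx$sp, bad, file.path(dir, "out")), "zz")
})

test_that("run_delta output is byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  fx <- fixture_files(dir, n_loci = 120)
  cfg <- screen_config(n_boot = 150, seed = 42)
  t1 <- file.path(dir, "d1.tsv"); t2 <- file.path(dir, "d2.tsv")
  run_delta(fx$sp, fx$gt, t1, config = cfg)
  run_delta(fx$sp, fx$gt, t2, config = cfg)
  expect_identical(readLines(t1), readLines(t2))
  tab <- read.table(t1, sep = "\t", header = TRUE)
  expect_true(all(c("branch_id", "delta", "boot_sd", "z_score", "p_value",
                    "significant_raw", "significant_corrected") %in%
                    names(tab)))
})

test_that("concordance-versus-age regression recovers exact relationships", {
  rec <- data.frame(branch_id = paste0("b", 1:6),
                    gCF = c(90, 80, 70, 60, 50, 40),
                    sCF = c(50, 52, 49, 51, 48, 50))
  ages <- data.frame(branch_id = paste0("b", 1:6), age = 1:6)
  rep <- report_cf_vs_age(rec, ages)
  s <- rep$summary
  expect_equal(s$r_squared[s$measure == "gCF"], 1, tolerance = 1e-12)
  expect_lt(s$r_squared[s$measure == "sCF"], 0.5)
  # degenerate ages: flagged, r^2 reported as 0
  flat <- report_cf_vs_age(rec, transform(ages, age = 2))
  expect_true(all(flat$summary$degenerate))
  expect_true(all(flat$summary$r_squared == 0))
  expect_error(report_cf_vs_age(rec[1:2, ], ages[1:2, ]), "fewer than 3")
})

test_that("noise with zero slope yields a small r^2 matching lm directly", {
  set.seed(77)
  n <- 30
  ages <- data.frame(branch_id = paste0("b", 1:n), age = runif(n, 1, 50))
  rec <- data.frame(branch_id = paste0("b", 1:n), gCF = rnorm(n, 60, 5))
  rep <- report_cf_vs_age(rec, ages)
  direct <- summary(lm(rec$gCF ~ ages$age))$r.squared
  expect_equal(rep$summary$r_squared, direct, tolerance = 1e-12)
  expect_lt(rep$summary$r_squared, 0.3)
})

test_that("simulation configs round-trip through YAML and JSON", {
  dir <- withr::local_tempdir()
  txt <- c("species_tree: '((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);'",
           "n_loci: 12",
           "seed: 5",
           "missing_prob: 0.1",
           "locus_length: 100",
           "subst_scale: 0.5",
           "pulses:",
           "  - donor: c",
           "    recipient: b",
           "    time: 0.1",
           "    gamma: 0.2")
  yf <- file.path(dir, "cfg.yaml")
  writeLines(txt, yf)
  scy <- read_sim_config(yf)
  expect_s3_class(scy$config, "sim_config")
  expect_equal(scy$config$n_loci, 12L)
  expect_length(scy$config$pulses, 1L)
  expect_equal(scy$locus_length, 100)
  jf <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(
    species_tree = "((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);",
    n_loci = 12, seed = 5,
    pulses = list(list(donor = "c", recipient = "b", time = 0.1,
                       gamma = 0.2))),
    jf, auto_unbox = TRUE)
  scj <- read_sim_config(jf)
  expect_equal(scj$config$n_loci, scy$config$n_loci)
  expect_equal(scj$config$pulses[[1]]$gamma, 0.2)
  # simulating from the parsed config works
  sim <- simulate_gene_trees(scy$config)
  expect_length(sim$trees, 12L)
})
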