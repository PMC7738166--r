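## ---------------------------------------------------------------------------
## File-level entry points used by the command-line script (inst/cli), plus
## report generation: concordance tables, annotated trees, and the
## concordance-versus-node-age summary.  TSV dialect: tab-separated, '.'
## decimal, header row, no quoting, '\n' newlines.
## ---------------------------------------------------------------------------

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              dec = ".", eol = "\n")
  invisible(path)
}

#' Write a reproducibility manifest next to an output file
#'
#' Records the command, package version, seed, configuration echo and input
#' file MD5 digests; a stochastic run is bit-identically reproducible from
#' its manifest.
#'
#' @param out_path Output file the manifest describes; the manifest is
#'   written to `<out_path>.manifest.json`.
#' @param command Character name of the command.
#' @param inputs Named character vector of input file paths.
#' @param config List echoed verbatim.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_path, command, inputs = character(0),
                           config = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    return(invisible(NULL))
  man <- list(command = command,
              tool = "phylodelta",
              version = as.character(packageVersion("phylodelta")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              inputs = as.list(tools::md5sum(inputs)),
              config = config)
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Annotate a species tree with concordance factors
#'
#' Sets internal node labels to `"gCF/sCF"` (or `"gCF"` when no site
#' concordance is supplied), matching each branch's distal node.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param records A `concordance` object for this tree.
#' @param scf Optional data frame from [site_concordance()].
#' @param digits Rounding for the labels.
#' @return The tree with `node.label` set.
#' @export
annotate_concordance <- function(species_tree, records, scf = NULL,
                                 digits = 1) {
  contexts <- attr(records, "contexts")
  ntip <- length(species_tree$tip.label)
  ## clade taxon key per internal node
  tr <- stats::reorder(species_tree, "postorder")
  nnode <- ntip + tr$Nnode
  clade <- vector("list", nnode)
  for (i in seq_len(ntip)) clade[[i]] <- tr$tip.label[i]
  for (i in seq_len(nrow(tr$edge)))
    clade[[tr$edge[i, 1L]]] <- c(clade[[tr$edge[i, 1L]]],
                                 clade[[tr$edge[i, 2L]]])
  keys <- vapply((ntip + 1L):nnode, function(v)
    paste(sort(clade[[v]]), collapse = ","), character(1))
  labels <- rep("", tr$Nnode)
  df <- as.data.frame(records)
  for (j in seq_along(contexts)) {
    ctx <- contexts[[j]]
    key <- paste(sort(c(ctx$A, ctx$B)), collapse = ",")
    node <- match(key, keys)
    if (is.na(node)) next
    g <- df$gCF[df$branch_id == ctx$branch_id][1L]
    lab <- if (is.na(g)) "NA" else format(round(g, digits), trim = TRUE)
    if (!is.null(scf)) {
      s <- scf$sCF[scf$branch_id == ctx$branch_id][1L]
      lab <- paste0(lab, "/", if (length(s) == 0 || is.na(s)) "NA"
                              else format(round(s, digits), trim = TRUE))
    }
    labels[node] <- lab
  }
  out <- tr
  out$node.label <- labels
  out
}

#' Run the concordance analysis on files
#'
#' Reads a species tree and a gene-tree set (and optionally a directory of
#' per-locus alignments for site concordance), computes gene (and site)
#' concordance factors, and writes a per-branch TSV plus an annotated newick
#' with internal labels `"gCF/sCF"`.
#'
#' @param species_tree_file Newick file with the rooted binary species tree.
#' @param gene_trees_file Newick file, one gene tree per line.
#' @param out_prefix Output prefix; writes `<prefix>.cf.tsv` and
#'   `<prefix>.cf.nwk`.
#' @param aln_dir Optional directory of FASTA/relaxed-PHYLIP alignments
#'   (extensions fa/fasta/fas/phy/phylip), one per locus.
#' @param n_quartets Quartets per branch for site concordance.
#' @param seed Seed for quartet sampling.
#' @param ingroup Optional character vector restricting tested branches.
#' @return Invisibly, a list with the `concordance` object, the sCF table
#'   (or `NULL`) and the output paths.
#' @export
run_concord <- function(species_tree_file, gene_trees_file, out_prefix,
                        aln_dir = NULL, n_quartets = 300, seed = NULL,
                        ingroup = NULL) {
  sp <- parse_newick(paste(readLines(species_tree_file, warn = FALSE),
                           collapse = ""))
  gt <- read_trees(gene_trees_file)
  extra <- setdiff(unique(unlist(lapply(gt, `[[`, "tip.label"))),
                   sp$tip.label)
  if (length(extra))
    stop("gene-tree taxa absent from the species tree: ",
         paste(extra, collapse = ", "))
  conc <- gene_concordance(sp, gt, ingroup = ingroup)
  scf <- NULL
  if (!is.null(aln_dir)) {
    files <- list.files(aln_dir, pattern = "\\.(fa|fasta|fas|phy|phylip)$",
                        full.names = TRUE)
    if (!length(files)) stop("no alignments found in ", aln_dir)
    alns <- lapply(files, read_alignment)
    scf <- site_concordance(sp, alns, n_quartets = n_quartets, seed = seed,
                            ingroup = ingroup)
  }
  df <- as.data.frame(conc)
  if (!is.null(scf)) df <- merge(df, scf, by = "branch_id", sort = FALSE)
  tsv <- paste0(out_prefix, ".cf.tsv")
  nwk <- paste0(out_prefix, ".cf.nwk")
  write_tsv(df, tsv)
  writeLines(write_newick(annotate_concordance(sp, conc, scf)), nwk)
  write_manifest(tsv, "concord",
                 c(species_tree = species_tree_file,
                   gene_trees = gene_trees_file),
                 list(n_quartets = n_quartets, seed = seed,
                      ingroup = ingroup))
  invisible(list(concordance = conc, scf = scf, tsv = tsv, tree = nwk))
}

#' Run the Delta introgression test on files
#'
#' Reads a species tree and a gene-tree set, screens branches by discordant
#' fraction, runs the gene-tree bootstrap Delta test, and writes the
#' per-branch TSV (raw and Dunn-Sidak-corrected significance) plus a
#' manifest.
#'
#' @param species_tree_file,gene_trees_file Newick inputs as in
#'   [run_concord()].
#' @param out_tsv Output TSV path.
#' @param config A [screen_config()].
#' @param ingroup Optional ingroup restriction.
#' @return Invisibly, the `delta_test` object.
#' @export
run_delta <- function(species_tree_file, gene_trees_file, out_tsv,
                      config = screen_config(), ingroup = NULL) {
  sp <- parse_newick(paste(readLines(species_tree_file, warn = FALSE),
                           collapse = ""))
  gt <- read_trees(gene_trees_file)
  dt <- delta_test(sp, gt, config = config, ingroup = ingroup)
  out <- dt$results
  if (is.null(out))
    out <- data.frame(branch_id = character(0))
  write_tsv(out, out_tsv)
  write_manifest(out_tsv, "delta",
                 c(species_tree = species_tree_file,
                   gene_trees = gene_trees_file),
                 config[setdiff(names(config), "")])
  invisible(dt)
}

#' Concordance factors versus node age
#'
#' Ordinary least-squares r-squared of gCF (and sCF when present) against
#' user-supplied node ages; dating itself is out of scope, ages come from
#' the caller.
#'
#' @param records A `concordance` object or per-branch data frame with
#'   `branch_id` and `gCF` (and optionally `sCF`) columns.
#' @param node_ages Data frame with columns `branch_id` and `age`.
#' @return A list of class `cf_age_report`: the merged table and a summary
#'   data frame with columns `measure`, `r_squared`, `slope`, `n`,
#'   `degenerate` (TRUE when the ages have zero variance, in which case
#'   r-squared is reported as 0).
#' @export
report_cf_vs_age <- function(records, node_ages) {
  stopifnot(all(c("branch_id", "age") %in% names(node_ages)))
  df <- merge(as.data.frame(records), node_ages, by = "branch_id")
  measures <- intersect(c("gCF", "sCF"), names(df))
  rows <- lapply(measures, function(mv) {
    sub <- df[complete.cases(df[c(mv, "age")]), ]
    if (nrow(sub) < 3L)
      stop("fewer than 3 branches with both ", mv, " and age")
    if (stats::var(sub$age) == 0)
      return(data.frame(measure = mv, r_squared = 0, slope = NA_real_,
                        n = nrow(sub), degenerate = TRUE))
    fit <- lm(sub[[mv]] ~ sub$age)
    data.frame(measure = mv, r_squared = summary(fit)$r.squared,
               slope = unname(coef(fit)[2L]), n = nrow(sub),
               degenerate = FALSE)
  })
  structure(list(table = df, summary = do.call(rbind, rows)),
            class = "cf_age_report")
}

#' @export
print.cf_age_report <- function(x, ...) {
  cat("Concordance factor vs node age (OLS)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: r^2 = %.4f over %d branches%s\n", s$measure[i],
                s$r_squared[i], s$n[i],
                if (s$degenerate[i]) " (degenerate: constant ages)" else ""))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file must contain `species_tree` (newick string), `n_loci`, and
#' optionally `pulses` (list of `donor`/`recipient`/`time`/`gamma` records),
#' `samples_per_species`, `missing_prob`, `seed`, `units`, `N`, `ploidy`,
#' and sequence parameters `locus_length` and `subst_scale`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A list: `config` (a [sim_config()]) plus `locus_length` and
#'   `subst_scale` (possibly `NULL`).
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$species_tree) || is.null(raw$n_loci))
    stop("config must provide 'species_tree' and 'n_loci'")
  pulses <- list()
  if (!is.null(raw$pulses)) {
    pl <- raw$pulses
    if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
    pulses <- lapply(pl, function(p)
      introgression_pulse(p$donor, p$recipient, p$time, p$gamma))
  }
  cfg <- sim_config(parse_newick(raw$species_tree), pulses = pulses,
                    n_loci = raw$n_loci,
                    samples_per_species = raw$samples_per_species %||% 1,
                    missing_prob = raw$missing_prob %||% 0,
                    seed = raw$seed,
                    units = raw$units %||% "coalescent",
                    N = raw$N, ploidy = raw$ploidy %||% 2)
  list(config = cfg, locus_length = raw$locus_length,
       subst_scale = raw$subst_scale)
}
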