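test_that("simulate_tree produces valid reproducible Yule trees", {
  tr <- simulate_tree(5, 1, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_identical(length(tr$tip.label), 5L)
  expect_setequal(tr$tip.label, sprintf("sp%04d", 1:5))
  expect_true(ape::is.rooted(tr))
  # valid Newick on write
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  expect_identical(length(read_newick(path)$tip.label), 5L)
  # determinism: same seed, byte-identical Newick
  expect_identical(ape::write.tree(simulate_tree(40, 2, seed = 7)),
                   ape::write.tree(simulate_tree(40, 2, seed = 7)))
  expect_false(identical(ape::write.tree(simulate_tree(40, 2, seed = 7)),
                         ape::write.tree(simulate_tree(40, 2, seed = 8))))
})

test_that("simulated trees are ultrametric with the Yule expected depth", {
  set.seed(601)
  n <- 16; lambda <- 1.5; nrep <- 500
  depths <- numeric(nrep)
  for (r in seq_len(nrep)) {
    tr <- simulate_tree(n, lambda)
    tip_depth <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(tip_depth)), 1e-8)     # ultrametric
    depths[r] <- tip_depth[1]
  }
  # E[depth] = sum_{k=2..n} 1/(lambda k); per-interval var = 1/(lambda k)^2
  expected <- sum(1 / (lambda * (2:n)))
  mc_se <- sqrt(sum(1 / (lambda * (2:n))^2) / nrep)
  expect_lt(abs(mean(depths) - expected), 3 * mc_se)
})

test_that("Brownian lifespans have the closed-form tip covariance", {
  # sigma2 = 0 collapses every tip to the root state
  tr <- simulate_tree(6, 1, seed = 2)
  ls0 <- simulate_lifespans(tr, 0, root_lifespan_log10 = 1.3)
  expect_equal(ls0$log10_lifespan, rep(1.3, 6))
  expect_equal(ls0$max_lifespan_years, rep(10^1.3, 6))

  # two-taxon difference variance = sigma2 * (sum of tip branch lengths)
  t2 <- ape::read.tree(text = "(A:0.7,B:1.8);")
  set.seed(602)
  diffs <- replicate(2000, {
    x <- simulate_lifespans(t2, 0.4, 0)$log10_lifespan
    x[1] - x[2]
  })
  v_expected <- 0.4 * (0.7 + 1.8)
  mc_se <- v_expected * sqrt(2 / 2000)
  expect_lt(abs(var(diffs) - v_expected), 3 * mc_se)

  # full tip covariance matches sigma2 * BrownianVCV entrywise
  tr8 <- simulate_tree(8, 1, seed = 3)
  C <- brownian_vcv(tr8)
  set.seed(603)
  sims <- replicate(3000, simulate_lifespans(tr8, 0.25, 0)$log10_lifespan)
  emp <- cov(t(sims))
  expect_lt(max(abs(emp - 0.25 * C)), 6 * 0.25 * max(diag(C)) / sqrt(3000) * 3)
})

test_that("sequence generator plants exactly the sites the scanner finds", {
  tr <- simulate_tree(30, 1, seed = 4)
  ls <- simulate_lifespans(tr, 0.12, 1.2, seed = 5)
  cfg <- sim_config()
  sq <- simulate_sequences(ls, cfg, seed = 6)
  seqs <- sq$records
  expect_identical(length(seqs), 30L)
  for (sp in names(seqs)) {
    sites <- scan_phosphosites(seqs[[sp]])
    planted_cterm <- sum(sites >= sq$boundary)
    expect_identical(planted_cterm, unname(sq$true_sites[sp]))
    # the only site before the boundary is the optional acceptor analog
    pre <- sites[sites < sq$boundary]
    if (sq$has_t294[sp]) expect_identical(pre, cfg$t294_position)
    else expect_identical(pre, integer(0))
  }
  # conserved core identical across species outside the acceptor position
  cores <- substr(unclass(seqs), 1, cfg$core_length)
  stripped <- vapply(cores, function(s) {
    substr(s, cfg$t294_position, cfg$t294_position) <- "?"
    s
  }, character(1))
  expect_identical(length(unique(stripped)), 1L)
})

test_that("zero effect and baseline give zero C-terminal sites everywhere", {
  tr <- simulate_tree(12, 1, seed = 7)
  ls <- simulate_lifespans(tr, 0.12, 1.2, seed = 8)
  sq <- simulate_sequences(ls, sim_config(site_effect = 0, baseline_sites = 0),
                           seed = 9)
  expect_true(all(sq$true_sites == 0L))
  for (sp in names(sq$records))
    expect_identical(sum(scan_phosphosites(sq$records[[sp]]) >= sq$boundary), 0L)
})

test_that("infeasible expected site counts are rejected", {
  ls <- data.frame(species_id = c("a", "b"), log10_lifespan = c(1, 30))
  expect_error(simulate_sequences(ls, sim_config()), "cterm_length/2")
  # a single extreme-lifespan species saturates at capacity instead of failing
  ls2 <- data.frame(species_id = c("a", "b", "c"),
                    log10_lifespan = c(1, 1.2, 8))
  sq <- simulate_sequences(ls2, sim_config(), seed = 1)
  expect_lte(unname(sq$true_sites["c"]), sim_config()$cterm_length %/% 2L)
})

test_that("noise-free MS tables recover the planted ratios exactly", {
  truth <- c(S10 = 0.04, T294 = 1.1, S303 = 11.7, S338 = 80)
  df <- simulate_ms_table(truth, sim_config(ms_noise_cv = 0, ms_missing_rate = 0),
                          seed = 10)
  tab <- relative_abundance_table(df, names(truth))
  expect_equal(setNames(tab$ratio, tab$site_label), truth, tolerance = 1e-12)
})

test_that("total missingness makes every site undefined", {
  truth <- c(S1 = 2, S2 = 5)
  df <- simulate_ms_table(truth, sim_config(ms_missing_rate = 1), seed = 11)
  tab <- relative_abundance_table(df, names(truth))
  expect_true(all(!tab$defined))
})

test_that("median recovered ratio over noisy replicates is within 5% of truth", {
  truth <- c(S303 = 11.7)
  cfg <- sim_config(ms_noise_cv = 0.2, ms_missing_rate = 0)
  set.seed(612)
  ratios <- replicate(500, {
    df <- simulate_ms_table(truth, cfg)
    relative_abundance(df, "S303")$ratio
  })
  expect_lt(abs(median(ratios) - truth) / truth, 0.05)
})

test_that("planted low-confidence decoys are caught by the filters", {
  truth <- c(S1 = 2, S2 = 5)
  cfg <- sim_config(ms_noise_cv = 0, ms_missing_rate = 0, ms_low_conf_frac = 1)
  df <- simulate_ms_table(truth, cfg, seed = 13)
  # unfiltered, the huge decoy intensities corrupt the ratios
  raw <- relative_abundance_table(df, names(truth))
  expect_false(isTRUE(all.equal(setNames(raw$ratio, raw$site_label), truth)))
  # filtered, the planted truth is recovered exactly
  tab <- relative_abundance_table(suppressMessages(filter_records(df)),
                                  names(truth))
  expect_equal(setNames(tab$ratio, tab$site_label), truth, tolerance = 1e-12)
})

test_that("a full study bundle is byte-identical under a fixed seed", {
  cfg <- sim_config(n_species = 10, seed = 99)
  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  files <- list.files(d1)
  expect_setequal(files, c("sequences.fasta", "alignment.fasta", "tree.nwk",
                           "lifespans.tsv", "quant.tsv", "truth.json"))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the bundle
  d3 <- file.path(tempfile(), "run3")
  simulate_study(sim_config(n_species = 10, seed = 100), out_dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "tree.nwk"))),
    unname(tools::md5sum(file.path(d3, "tree.nwk")))))
})

test_that("generated bundles round-trip through the real pipeline", {
  cfg <- sim_config(n_species = 48, seed = 17)
  out <- file.path(tempfile(), "bundle")
  st <- simulate_study(cfg, out_dir = out)
  res <- suppressMessages(run_comparative(run_config(
    alignment = st$paths$alignment, tree = st$paths$tree,
    lifespans = st$paths$lifespans, sequences = st$paths$fasta,
    quant = st$paths$quant,
    ref_boundary = st$sequences$boundary,
    acceptor_position = cfg$t294_position)))
  # per-species features agree with the generator's bookkeeping
  ft <- res$features
  expect_identical(setNames(ft$n_sites_cterm, ft$species_id)[names(st$sequences$true_sites)],
                   st$sequences$true_sites)
  expect_identical(setNames(ft$has_t294_equiv, ft$species_id)[names(st$sequences$has_t294)],
                   st$sequences$has_t294)
  # planted positive effect is recovered as a positive PGLS slope
  sd_row <- subset(res$regression, predictor == "site_density" & model == "PGLS")
  expect_gt(sd_row$beta, 0)
})
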