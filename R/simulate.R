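#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the synthetic data generator,
#' which emulates the statistical structure the comparative analysis assumes:
#' a Yule species phylogeny, Brownian-evolving log10 maximum lifespan, a
#' conserved protein core plus a variable C-terminal segment whose `[ST]P`
#' site count depends on lifespan, and noisy MS1 intensity tables.
#'
#' @param n_species Number of species (tree leaves).
#' @param birth_rate Yule speciation rate (events per lineage per unit time).
#' @param sigma2 Brownian rate of log10 lifespan (log10-years^2 per unit
#'   branch length).
#' @param root_lifespan_log10 Root state of log10 maximum lifespan
#'   (log10 years).
#' @param site_effect Expected additional C-terminal `[ST]P` sites per unit
#'   log10 lifespan.
#' @param baseline_sites Expected C-terminal sites at log10 lifespan 0.
#' @param cterm_length C-terminal segment length (residues).
#' @param core_length Conserved-core length (residues); the true C-terminal
#'   boundary is `core_length + 1`.
#' @param t294_position Position of the optional acceptor analog inside the
#'   core (the human protein's T294).
#' @param t294_logistic_intercept,t294_logistic_slope Logistic model (on
#'   log10 lifespan) for the probability that a species carries the acceptor
#'   analog.
#' @param ms_noise_cv Coefficient of variation of the multiplicative
#'   intensity noise.
#' @param ms_missing_rate Probability that any one intensity is missing
#'   (zeroed).
#' @param ms_low_conf_frac Fraction of sites that additionally receive
#'   decoy rows below the confidence thresholds, to exercise the filters.
#' @param seed Integer RNG seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @return A validated list of class `sim_config`.
#' @details Defaults describe a mammal-like panel with a clearly detectable
#'   planted signal. With `birth_rate = 1` a 128-leaf Yule tree has expected
#'   depth ~4.4, so `sigma2 = 0.12` gives tip standard deviations of ~0.7
#'   log10 years around a 16-year root — a spread from about a year to a few
#'   centuries, somewhat broader than a real mammal panel. `site_effect =
#'   12` over a 120-residue segment is a site-density slope of 0.1 per log10
#'   year, the same order as the observed contrast between short- and
#'   long-lived species; it is deliberately at the upper end of that range
#'   because Poisson counting noise in the planted sites plus phylogenetic
#'   correction otherwise leaves the signal undetectable at this panel size.
#'   The logistic parameters make the acceptor analog essentially a
#'   threshold trait appearing in species beyond ~40-year lifespans.
#' @export
sim_config <- function(n_species = 128L, birth_rate = 1, sigma2 = 0.12,
                       root_lifespan_log10 = 1.2, site_effect = 12,
                       baseline_sites = 0, cterm_length = 120L,
                       core_length = 298L, t294_position = 294L,
                       t294_logistic_intercept = -32, t294_logistic_slope = 20,
                       ms_noise_cv = 0.2, ms_missing_rate = 0.1,
                       ms_low_conf_frac = 0, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species), birth_rate = birth_rate,
              sigma2 = sigma2, root_lifespan_log10 = root_lifespan_log10,
              site_effect = site_effect, baseline_sites = baseline_sites,
              cterm_length = as.integer(cterm_length),
              core_length = as.integer(core_length),
              t294_position = as.integer(t294_position),
              t294_logistic_intercept = t294_logistic_intercept,
              t294_logistic_slope = t294_logistic_slope,
              ms_noise_cv = ms_noise_cv, ms_missing_rate = ms_missing_rate,
              ms_low_conf_frac = ms_low_conf_frac, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 2L, birth_rate > 0, sigma2 >= 0,
              site_effect >= 0, baseline_sites >= 0,
              cterm_length >= 2L, core_length > t294_position,
              ms_noise_cv >= 0, ms_missing_rate >= 0, ms_missing_rate <= 1,
              ms_low_conf_frac >= 0, ms_low_conf_frac <= 1)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Grows a tree under a constant-rate pure-birth process: with `k` extant
#' lineages the waiting time to the next speciation is exponential with rate
#' `birth_rate * k` and a uniformly chosen lineage splits. The root is the
#' first split (two lineages); after the `n`-th lineage appears one final
#' exponential interval at rate `birth_rate * n` elapses before the present,
#' so the expected root-to-tip depth is `sum_{k=2..n} 1/(birth_rate * k)`.
#' The tree is ultrametric. Leaves are labelled `sp0001`, `sp0002`, ...
#'
#' @param n_species Number of leaves (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_species)
  stopifnot(n >= 2L, birth_rate > 0)
  # node bookkeeping: birth time, split time (NA while active / for tips)
  birth <- c(0, 0)
  split <- c(NA_real_, NA_real_)
  kid1 <- c(NA_integer_, NA_integer_)
  kid2 <- c(NA_integer_, NA_integer_)
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = birth_rate * k)
    i <- active[sample.int(k, 1L)]
    split[i] <- t
    c1 <- length(birth) + 1L
    c2 <- length(birth) + 2L
    birth <- c(birth, t, t)
    split <- c(split, NA_real_, NA_real_)
    kid1 <- c(kid1, NA_integer_, NA_integer_)
    kid2 <- c(kid2, NA_integer_, NA_integer_)
    kid1[i] <- c1
    kid2[i] <- c2
    active <- c(setdiff(active, i), c1, c2)
  }
  t_end <- t + stats::rexp(1L, rate = birth_rate * n)
  labels <- sprintf("sp%04d", seq_len(n))
  tip_label <- rep(NA_character_, length(birth))
  tip_label[sort(active)] <- labels
  nwk_node <- function(i) {
    len <- (if (is.na(split[i])) t_end else split[i]) - birth[i]
    if (is.na(kid1[i])) {
      paste0(tip_label[i], ":", format(len, digits = 15))
    } else {
      paste0("(", nwk_node(kid1[i]), ",", nwk_node(kid2[i]), "):",
             format(len, digits = 15))
    }
  }
  nwk <- paste0("(", nwk_node(1L), ",", nwk_node(2L), ");")
  validate_phylogeny(ape::read.tree(text = nwk))
}

#' Simulate log10 maximum lifespans by Brownian motion on a tree
#'
#' Starting from the root state, every branch adds an independent
#' zero-mean normal increment with variance `sigma2 *` branch length; tip
#' values are returned on the log10-years scale, with the back-transformed
#' years alongside.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param sigma2 Brownian rate (log10-years^2 per unit branch length).
#' @param root_lifespan_log10 Root state.
#' @param seed Optional seed.
#' @return `data.frame` with `species_id`, `log10_lifespan`,
#'   `max_lifespan_years`, one row per tip in tree order.
#' @export
simulate_lifespans <- function(tree, sigma2 = 0.03, root_lifespan_log10 = 1.2,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_phylogeny(tree)
  n_tip <- length(tree$tip.label)
  val <- numeric(n_tip + tree$Nnode)
  val[n_tip + 1L] <- root_lifespan_log10
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    e <- tr$edge[k, ]
    val[e[2L]] <- val[e[1L]] +
      stats::rnorm(1L, 0, sqrt(sigma2 * tr$edge.length[k]))
  }
  data.frame(species_id = tree$tip.label,
             log10_lifespan = val[seq_len(n_tip)],
             max_lifespan_years = 10^val[seq_len(n_tip)])
}

#' Simulate protein sequences with lifespan-dependent phosphosite density
#'
#' Every species receives the same conserved core (no `[ST]P` motifs, except
#' an optional acceptor analog at `t294_position`, placed with probability
#' `plogis(intercept + slope * log10 lifespan)` and always followed by a
#' proline so that its presence is a motif), concatenated with a C-terminal
#' segment of `cterm_length` residues carrying `K ~ Poisson(baseline_sites +
#' site_effect * log10 lifespan)` non-overlapping `SP`/`TP` dimers at random
#' positions (the per-species expectation saturates at the segment's dimer
#' capacity of `cterm_length / 2`; a configuration infeasible on average is
#' an error). Remaining positions are drawn from an alphabet free of P, S and
#' T, so the planted dimers are exactly the motifs a scan recovers. Because
#' all sequences have equal length the true alignment is the gap-free
#' alignment of the sequences themselves; the true C-terminal boundary is
#' `core_length + 1`.
#'
#' @param lifespans `data.frame` from [simulate_lifespans()] (or any frame
#'   with `species_id` and `log10_lifespan`).
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return List with `records` (a `protein_set`), `alignment` (an `msa`),
#'   `boundary` (true `cterm_start`, identical for every species),
#'   `true_sites` (named integer, planted C-terminal motif count) and
#'   `has_t294` (named logical).
#' @export
simulate_sequences <- function(lifespans, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("species_id", "log10_lifespan") %in% names(lifespans)))
  ll <- lifespans$log10_lifespan
  sp <- as.character(lifespans$species_id)
  lam <- pmax(0, cfg$baseline_sites + cfg$site_effect * ll)
  n_slots <- cfg$cterm_length %/% 2L
  if (mean(lam) > n_slots)
    stop("expected site count (mean ", format(mean(lam), digits = 4),
         ") exceeds cterm_length/2 = ", n_slots,
         "; lengthen the C-terminal segment or reduce the effect")
  # individual extreme-lifespan species saturate at the slot capacity
  lam <- pmin(lam, n_slots)
  filler <- strsplit("ACDEFGHIKLMNQRVWY", "", fixed = TRUE)[[1]]
  core <- sample(filler, cfg$core_length, replace = TRUE)
  core[cfg$t294_position + 1L] <- "P"
  core[cfg$t294_position] <- "A"
  p_t294 <- stats::plogis(cfg$t294_logistic_intercept +
                            cfg$t294_logistic_slope * ll)
  has_t294 <- stats::runif(length(ll)) < p_t294
  slots <- seq(1L, by = 2L, length.out = n_slots)
  seqs <- character(length(ll))
  true_k <- integer(length(ll))
  for (i in seq_along(ll)) {
    k <- min(stats::rpois(1L, lam[i]), n_slots)
    tail_v <- sample(filler, cfg$cterm_length, replace = TRUE)
    if (k > 0L) {
      at <- slots[sample.int(n_slots, k)]
      tail_v[at] <- sample(c("S", "T"), k, replace = TRUE)
      tail_v[at + 1L] <- "P"
    }
    core_i <- core
    if (has_t294[i]) core_i[cfg$t294_position] <- "T"
    seqs[i] <- paste0(paste(core_i, collapse = ""),
                      paste(tail_v, collapse = ""))
    true_k[i] <- k
  }
  names(seqs) <- sp
  list(records = as_protein_set(seqs),
       alignment = as_msa(seqs),
       boundary = cfg$core_length + 1L,
       true_sites = stats::setNames(true_k, sp),
       has_t294 = stats::setNames(has_t294, sp))
}

#' Simulate a modified-peptide quantification table
#'
#' For each site the unmodified intensity is drawn log-normally around a base
#' level; the modified intensity is the true occupancy ratio times the
#' unmodified intensity times multiplicative log-normal noise with
#' coefficient of variation `ms_noise_cv` (mean 1). Each intensity is then
#' independently zeroed with probability `ms_missing_rate`. A fraction
#' `ms_low_conf_frac` of sites also receives decoy rows planted below the
#' confidence thresholds so that downstream filters are exercised. The table
#' uses the generic dialect of [read_quant_table()].
#'
#' @param true_ratios Named nonnegative numeric vector: true modified /
#'   unmodified intensity ratio per site label.
#' @param cfg A [sim_config()] (only the `ms_*` fields are used).
#' @param base_intensity Median unmodified MS1 intensity (arbitrary units).
#' @param protein_id Protein identifier written to every row.
#' @param path Optional TSV output path.
#' @param seed Optional seed.
#' @return The quant `data.frame` (invisibly if `path` is given).
#' @export
simulate_ms_table <- function(true_ratios, cfg = sim_config(),
                              base_intensity = 1e8, protein_id = "SIRT6",
                              path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(names(true_ratios)), all(true_ratios >= 0))
  sdlog <- sqrt(log(1 + cfg$ms_noise_cv^2))
  rows <- list()
  digits_to_aa <- function(s) chartr("0123456789", "ACDEFGHIKL", s)
  n_low <- round(cfg$ms_low_conf_frac * length(true_ratios))
  low_sites <- if (n_low > 0) names(true_ratios)[seq_len(n_low)] else character(0)
  for (site in names(true_ratios)) {
    pep <- paste0("GLV", digits_to_aa(gsub("[A-Z]", "", site)), "VK")
    unmod <- stats::rlnorm(1L, log(base_intensity), 0.5)
    noise <- if (cfg$ms_noise_cv > 0)
      stats::rlnorm(1L, -sdlog^2 / 2, sdlog) else 1
    mod <- true_ratios[[site]] * unmod * noise
    if (stats::runif(1L) < cfg$ms_missing_rate) mod <- 0
    if (stats::runif(1L) < cfg$ms_missing_rate) unmod <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = pep, protein_id = protein_id,
      site_label = c(site, ""), is_modified = c(TRUE, FALSE),
      localization_prob = c(0.99, NA), intensity = c(mod, unmod),
      protein_prob = 0.99, fixed_mods = "", stringsAsFactors = FALSE)
    if (site %in% low_sites) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, protein_id = protein_id,
        site_label = site, is_modified = TRUE,
        localization_prob = c(0.50, 0.99), intensity = 100 * base_intensity,
        protein_prob = c(0.99, 0.90), fixed_mods = "",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Generate a complete synthetic study bundle
#'
#' Runs all generators under one seed: a Yule tree, Brownian lifespans,
#' lifespan-dependent sequences, and a noisy MS quantification table for a
#' small panel of sites. With `out_dir` set, everything is written to disk
#' (FASTA, aligned FASTA, Newick, lifespan TSV, quant TSV) together with a
#' `truth.json` sidecar holding the generator parameters and per-species
#' ground truth. A fixed seed yields byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param ms_sites Named true ratios for the MS table; the default is a
#'   seven-site panel with ratios spread from ~0.04 to ~80.
#' @return List with `tree`, `lifespans`, `sequences` (see
#'   [simulate_sequences()]), `quant`, `config`, and `paths` (when written).
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL,
                           ms_sites = c(S10 = 0.04, T294 = 1.1, S303 = 11.7,
                                        S330 = 1.5, T337 = 40, S338 = 80,
                                        S326 = 0)) {
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_species, cfg$birth_rate)
  lifespans <- simulate_lifespans(tree, cfg$sigma2, cfg$root_lifespan_log10)
  seqs <- simulate_sequences(lifespans, cfg)
  quant <- simulate_ms_table(ms_sites, cfg)
  out <- list(tree = tree, lifespans = lifespans, sequences = seqs,
              quant = quant, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "sequences.fasta"),
      alignment = file.path(out_dir, "alignment.fasta"),
      tree = file.path(out_dir, "tree.nwk"),
      lifespans = file.path(out_dir, "lifespans.tsv"),
      quant = file.path(out_dir, "quant.tsv"),
      truth = file.path(out_dir, "truth.json"))
    write_fasta(seqs$records, paths$fasta)
    write_fasta(unclass(seqs$alignment), paths$alignment)
    ape::write.tree(tree, paths$tree)
    utils::write.table(lifespans, paths$lifespans, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(quant, paths$quant, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg),
           boundary = seqs$boundary,
           true_sites = as.list(seqs$true_sites),
           has_t294 = as.list(seqs$has_t294),
           ms_true_ratios = as.list(ms_sites)),
      paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
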