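#' Build a run configuration for the comparative pipeline
#'
#' @param alignment Path to the species alignment (aligned FASTA or Clustal).
#' @param tree Path to the species phylogeny (Newick).
#' @param lifespans Path to the species lifespan TSV (`species_id`,
#'   `max_lifespan_years`).
#' @param sequences Optional path to the unaligned FASTA; when given, each
#'   ungapped alignment row is checked against it.
#' @param quant Optional modified-peptide quantification TSV.
#' @param quant_dialect Dialect of `quant`, see [read_quant_table()].
#' @param reference_id Reference species for coordinates (default: first
#'   alignment row).
#' @param ref_boundary Reference residue starting the C-terminal domain.
#' @param acceptor_position Reference position of the acceptor flag (T294).
#' @param predictors Feature columns screened against lifespan.
#' @param log10_response Log10-transform lifespan before regression.
#' @param out_dir Output directory (`NULL` = return results only).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(alignment, tree, lifespans, sequences = NULL,
                       quant = NULL, quant_dialect = "generic",
                       reference_id = NULL, ref_boundary = 290L,
                       acceptor_position = 294L,
                       predictors = c("site_density", "has_t294_equiv",
                                      "net_charge", "frac_charged",
                                      "frac_proline"),
                       log10_response = TRUE, out_dir = NULL, seed = 1L) {
  cfg <- list(alignment = alignment, tree = tree, lifespans = lifespans,
              sequences = sequences, quant = quant,
              quant_dialect = quant_dialect, reference_id = reference_id,
              ref_boundary = as.integer(ref_boundary),
              acceptor_position = as.integer(acceptor_position),
              predictors = predictors, log10_response = isTRUE(log10_response),
              out_dir = out_dir, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (key in c("alignment", "tree", "lifespans", "sequences", "quant"))
    y[[key]] <- resolve(y[[key]])
  do.call(run_config, y)
}

#' Read a species lifespan table
#'
#' @param path TSV with columns `species_id` and `max_lifespan_years`.
#' @return `data.frame` with those columns.
#' @export
read_lifespan_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("species_id", "max_lifespan_years"), names(df))
  if (length(missing))
    stop("lifespan table missing columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(df$max_lifespan_years) | df$max_lifespan_years <= 0))
    stop("maximum lifespans must be positive and finite")
  df
}

#' Run the end-to-end comparative analysis
#'
#' Executes the full pipeline: read the alignment and phylogeny, map
#' reference coordinates and project the C-terminal boundary, compute
#' per-species sequence features, reconcile species names with the tree and
#' lifespan table, and regress (log10) maximum lifespan on each feature
#' separately under both PGLS and OLS. If a quantification table is
#' configured, site-level relative phosphopeptide abundances are computed as
#' well. With `out_dir` set, all result tables and a machine-readable run
#' manifest (input hashes, parameters, versions) are written; a rerun with
#' the same configuration and inputs reproduces the bundle byte for byte.
#'
#' @param cfg A [run_config()] list, or the path to a YAML file for
#'   [read_run_config()].
#' @return List with `features`, `conservation`, `boundary`, `regression`,
#'   `scatter`, `site_ratios` (or `NULL`), `dropped`, `manifest`.
#' @export
run_comparative <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))

  aln <- read_alignment(cfg$alignment)
  reference_id <- if (is.null(cfg$reference_id)) names(aln)[1] else cfg$reference_id
  if (!is.null(cfg$sequences)) {
    seqs <- read_fasta(cfg$sequences)
    shared <- intersect(names(seqs), names(aln))
    if (!length(shared))
      stop("stage sequences: no species shared between FASTA and alignment")
    ungapped <- ungap_alignment(aln)
    bad <- shared[unclass(ungapped[shared]) != unclass(seqs[shared])]
    if (length(bad))
      stop("stage sequences: alignment rows disagree with FASTA for: ",
           paste(bad, collapse = ", "))
  }

  colmap <- build_column_map(aln, reference_id)
  conservation <- conservation_profile(aln)
  boundary <- project_cterm_boundary(aln, colmap, cfg$ref_boundary)
  features <- feature_table(aln, reference_id = reference_id,
                            ref_boundary = cfg$ref_boundary,
                            acceptor_position = cfg$acceptor_position)
  if (any(features$degenerate))
    message("run_comparative: excluding ", sum(features$degenerate),
            " species with zero-length C-terminal domains: ",
            paste(features$species_id[features$degenerate], collapse = ", "))
  usable <- features[!features$degenerate, , drop = FALSE]

  lifespans <- read_lifespan_table(cfg$lifespans)
  tree <- read_newick(cfg$tree)
  traits <- merge(usable, lifespans, by = "species_id")
  if (!nrow(traits))
    stop("stage match: no species shared between features and lifespan table")
  matched <- prune_and_match(tree, traits)

  regression <- lifespan_screen(matched$traits, matched$tree,
                                predictors = cfg$predictors,
                                log10_response = cfg$log10_response)
  scatter <- data.frame(
    species_id = matched$traits$species_id,
    max_lifespan_years = matched$traits$max_lifespan_years,
    log10_lifespan = log10(matched$traits$max_lifespan_years),
    site_density = matched$traits$site_density)

  site_ratios <- NULL
  if (!is.null(cfg$quant)) {
    q <- read_quant_table(cfg$quant, dialect = cfg$quant_dialect)
    site_ratios <- relative_abundance_table(filter_records(q))
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("alignment", "tree", "lifespans", "sequences", "quant")])
  manifest <- list(
    package = "phosevol",
    version = as.character(utils::packageVersion("phosevol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = list(
      reference_id = reference_id, ref_boundary = cfg$ref_boundary,
      acceptor_position = cfg$acceptor_position,
      predictors = cfg$predictors, log10_response = cfg$log10_response,
      quant_dialect = cfg$quant_dialect, seed = cfg$seed,
      protein_prob_min = 0.95, localization_min = 0.80),
    n_species_analyzed = nrow(matched$traits),
    dropped = list(from_tree = matched$dropped_from_tree,
                   from_traits = matched$dropped_from_traits,
                   degenerate = features$species_id[features$degenerate]))

  out <- list(features = features, conservation = conservation,
              boundary = boundary, regression = regression,
              scatter = scatter, site_ratios = site_ratios,
              dropped = manifest$dropped, manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(cfg$out_dir, "feature_table.tsv"))
    write_conservation(conservation, file.path(cfg$out_dir, "conservation.tsv"))
    utils::write.table(
      data.frame(species_id = names(boundary), cterm_start = boundary),
      file.path(cfg$out_dir, "boundary_map.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_regression_results(regression,
                             file.path(cfg$out_dir, "regression_results.tsv"))
    utils::write.table(scatter, file.path(cfg$out_dir, "scatter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(site_ratios))
      write_site_table(site_ratios, file.path(cfg$out_dir, "site_ratios.tsv"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
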