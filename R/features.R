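#' Scan a protein sequence for [ST]P phosphosite motifs
#'
#' Returns every position at which a serine or threonine is immediately
#' followed by a proline — the minimal recognition pattern of proline-directed
#' (CMGC-family) kinases, used here to predict phosphorylation sites.
#'
#' @param sequence A single amino-acid string (case-insensitive).
#' @param minus1_proline If `TRUE`, additionally report S/T positions preceded
#'   by a proline (the looser "proline at -1 or +1" reading). Off by default:
#'   the counting motif is strictly `[ST]P`.
#' @return Integer vector of 1-based positions of the S/T residue of each
#'   motif, strictly increasing. An empty or length-1 sequence yields
#'   `integer(0)`; a terminal S/T can never match the default motif.
#' @examples
#' scan_phosphosites("SPAGTPQS")  # 1, 5
#' @export
scan_phosphosites <- function(sequence, minus1_proline = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < 2L && !minus1_proline) return(integer(0))
  if (n == 0L) return(integer(0))
  st <- v %in% c("S", "T")
  hit <- st & c(v[-1L] == "P", FALSE)
  if (minus1_proline) hit <- hit | (st & c(FALSE, v[-n] == "P"))
  which(hit)
}

#' Per-species sequence features over a C-terminal domain
#'
#' Computes the feature set used in the lifespan comparison for one sequence:
#' predicted `[ST]P` site counts (whole sequence and C-terminal domain),
#' site density normalized to domain length, net charge, charged-residue
#' fraction and proline fraction.
#'
#' @param sequence Amino-acid string for one species.
#' @param cterm_start 1-based index of the first residue of the C-terminal
#'   domain in *this* sequence (project a reference boundary with
#'   [project_cterm_boundary()] when sequences are aligned).
#' @param region Region over which charge and composition fractions are
#'   computed: the C-terminal domain (default, the region of interest) or the
#'   full sequence.
#' @param minus1_proline Passed to [scan_phosphosites()].
#' @return A one-row `data.frame` with columns `n_sites_total`,
#'   `n_sites_cterm`, `cterm_start`, `cterm_length`, `site_density`,
#'   `net_charge`, `frac_charged`, `frac_proline`.
#' @details Net charge uses the simplest standard convention: K, R count +1;
#'   D, E count -1; histidine and the termini are ignored. `X` residues count
#'   toward lengths but never toward any tally. A degenerate domain
#'   (`cterm_start = length + 1`, length 0) is allowed and yields zero counts
#'   with `site_density` and fractions of `NaN`; such species are flagged and
#'   dropped by the pipeline.
#' @examples
#' compute_features("DEKRSPAA", cterm_start = 5)
#' @export
compute_features <- function(sequence, cterm_start,
                             region = c("cterm", "full"),
                             minus1_proline = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  region <- match.arg(region)
  len <- nchar(sequence)
  cterm_start <- as.integer(cterm_start)
  if (cterm_start < 1L || cterm_start > len + 1L)
    stop("cterm_start ", cterm_start, " out of range for sequence of length ", len)
  sites <- scan_phosphosites(sequence, minus1_proline = minus1_proline)
  cterm_length <- len - cterm_start + 1L
  n_cterm <- sum(sites >= cterm_start)
  scored <- if (region == "cterm") {
    if (cterm_length > 0L) substr(sequence, cterm_start, len) else ""
  } else sequence
  tab <- .aa_counts(scored)
  reg_len <- nchar(scored)
  data.frame(
    n_sites_total = length(sites),
    n_sites_cterm = n_cterm,
    cterm_start   = cterm_start,
    cterm_length  = cterm_length,
    site_density  = n_cterm / cterm_length,
    net_charge    = (tab["K"] + tab["R"]) - (tab["D"] + tab["E"]),
    frac_charged  = (tab["D"] + tab["E"] + tab["K"] + tab["R"]) / reg_len,
    frac_proline  = tab["P"] / reg_len,
    row.names = NULL
  )
}

.aa_counts <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  letters20 <- strsplit(.aa_alphabet, "", fixed = TRUE)[[1]]
  tab <- table(factor(v, levels = letters20))
  stats::setNames(as.integer(tab), letters20)
}

#' Does a species carry a phosphoacceptor at a reference position?
#'
#' Maps a reference residue position (e.g. human T294) through the alignment
#' and reports whether the species' residue in that column is a
#' phosphoacceptor.
#'
#' @param aln An alignment from [read_alignment()].
#' @param colmap A [build_column_map()] result for the reference species.
#' @param species_id Species to interrogate.
#' @param ref_position 1-based residue position in the reference sequence.
#' @param accept Residues accepted as phosphoacceptors at the position.
#'   Default `c("S", "T")` since the counted motif is `[ST]P`; set to `"T"`
#'   for a strict threonine-only reading.
#' @return `TRUE` or `FALSE`; a gap at the mapped column is `FALSE`.
#' @export
has_phosphoacceptor_at_ref <- function(aln, colmap, species_id, ref_position,
                                       accept = c("S", "T")) {
  stopifnot(inherits(colmap, "column_map"))
  if (!species_id %in% names(aln))
    stop("species absent from alignment: ", species_id)
  col <- res_to_col(colmap, ref_position)
  ch <- substr(aln[[species_id]], col, col)
  ch %in% toupper(accept)
}

#' Feature table for a set of aligned species
#'
#' Runs the full per-species feature computation for every row of an
#' alignment: the reference C-terminal boundary is projected onto each
#' species, `[ST]P` sites are counted, and the reference-position
#' phosphoacceptor flag (T294 in the human protein's coordinates) is added.
#'
#' @param aln Alignment from [read_alignment()].
#' @param reference_id Species whose coordinates define the boundary and the
#'   acceptor position (default the first row; the pipeline default is the
#'   human sequence).
#' @param ref_boundary 1-based reference residue starting the C-terminal
#'   domain. Default 290, so the domain includes the acceptor position 294
#'   while the well-conserved region (up to ~298) ends shortly after.
#' @param acceptor_position Reference position tested by
#'   [has_phosphoacceptor_at_ref()] (default 294).
#' @param accept Acceptor residues, see [has_phosphoacceptor_at_ref()].
#' @param region,minus1_proline Passed to [compute_features()].
#' @return A `data.frame` with one row per species and columns `species_id`,
#'   `n_sites_total`, `n_sites_cterm`, `cterm_start`, `cterm_length`,
#'   `site_density`, `has_t294_equiv`, `net_charge`, `frac_charged`,
#'   `frac_proline`, plus a logical `degenerate` flag for species whose
#'   projected domain has zero length.
#' @export
feature_table <- function(aln, reference_id = names(aln)[1], ref_boundary = 290L,
                          acceptor_position = 294L, accept = c("S", "T"),
                          region = c("cterm", "full"), minus1_proline = FALSE) {
  region <- match.arg(region)
  cm <- build_column_map(aln, reference_id)
  bounds <- project_cterm_boundary(aln, cm, ref_boundary)
  seqs <- ungap_alignment(aln)
  rows <- lapply(names(aln), function(sp) {
    fv <- compute_features(seqs[[sp]], bounds[[sp]],
                           region = region, minus1_proline = minus1_proline)
    cbind(data.frame(species_id = sp),
          fv[, c("n_sites_total", "n_sites_cterm", "cterm_start",
                 "cterm_length", "site_density")],
          data.frame(has_t294_equiv = has_phosphoacceptor_at_ref(
            aln, cm, sp, acceptor_position, accept = accept)),
          fv[, c("net_charge", "frac_charged", "frac_proline")])
  })
  out <- do.call(rbind, rows)
  out$degenerate <- out$cterm_length == 0L
  rownames(out) <- NULL
  out
}

#' Write a feature table as TSV
#'
#' @param features Result of [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("species_id", "n_sites_total", "n_sites_cterm", "cterm_start",
            "cterm_length", "site_density", "has_t294_equiv", "net_charge",
            "frac_charged", "frac_proline")
  utils::write.table(features[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
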