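#' Read a modified-peptide quantification table
#'
#' Parses a search-engine peptide quantification TSV into the canonical
#' record layout used by [filter_records()] and [relative_abundance()].
#'
#' Two dialects are supported. `"generic"` expects the canonical columns
#' verbatim: `peptide`, `protein_id`, `site_label`, `is_modified`,
#' `localization_prob`, `intensity`, `protein_prob` (optional `fixed_mods`).
#' `"fragpipe"` accepts the documented subset of a FragPipe-style
#' `combined_modified_peptide.tsv`: `Peptide Sequence`, `Protein ID`,
#' `Protein Probability`, `Protein Start`, `Assigned Modifications`,
#' `Localization`, `Intensity`. Phosphorylations are recognized in
#' `Assigned Modifications` by the 79.966 Da mass tag, converted to
#' protein-coordinate site labels (e.g. `T294`) via `Protein Start`; other
#' (fixed) modifications are kept in `fixed_mods` so that modified/unmodified
#' pairing can require them to match.
#'
#' @param path TSV file with a header row.
#' @param dialect `"generic"` or `"fragpipe"`.
#' @return `data.frame` with the canonical columns above; multi-phospho
#'   peptides carry a `;`-separated `site_label`. Missing intensity cells are
#'   set to 0 (a per-file count is reported via [message()]).
#' @export
read_quant_table <- function(path, dialect = c("generic", "fragpipe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("quantification table not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- switch(dialect,
               generic = .quant_from_generic(raw),
               fragpipe = .quant_from_fragpipe(raw))
  n_missing <- sum(is.na(df$intensity))
  if (n_missing > 0) {
    message("read_quant_table: ", n_missing,
            " missing intensity cells set to 0 in ", basename(path))
    df$intensity[is.na(df$intensity)] <- 0
  }
  .validate_quant(df)
}

.quant_from_generic <- function(raw) {
  mandatory <- c("peptide", "protein_id", "site_label", "is_modified",
                 "localization_prob", "intensity", "protein_prob")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("quant table missing mandatory columns: ",
         paste(missing, collapse = ", "))
  df <- raw[mandatory]
  df$fixed_mods <- if ("fixed_mods" %in% names(raw)) as.character(raw$fixed_mods)
                   else ""
  df$is_modified <- as.logical(df$is_modified)
  df$site_label <- as.character(df$site_label)
  df$site_label[is.na(df$site_label)] <- ""
  df$fixed_mods[is.na(df$fixed_mods)] <- ""
  df
}

.quant_from_fragpipe <- function(raw) {
  mandatory <- c("Peptide Sequence", "Protein ID", "Protein Probability",
                 "Protein Start", "Assigned Modifications", "Localization",
                 "Intensity")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("quant table missing mandatory columns: ",
         paste(missing, collapse = ", "))
  mods <- as.character(raw[["Assigned Modifications"]])
  mods[is.na(mods)] <- ""
  start <- as.integer(raw[["Protein Start"]])
  parse_one <- function(mod_string, prot_start) {
    if (!nzchar(mod_string)) return(list(sites = "", fixed = ""))
    parts <- trimws(strsplit(mod_string, ",")[[1]])
    is_phos <- grepl("79\\.96", parts)
    sites <- vapply(parts[is_phos], function(p) {
      m <- regmatches(p, regexec("^([0-9]+)([A-Z])", p))[[1]]
      if (length(m) < 3L) stop("unparseable modification entry: ", p)
      paste0(m[3], prot_start + as.integer(m[2]) - 1L)
    }, character(1))
    list(sites = paste(sites, collapse = ";"),
         fixed = paste(parts[!is_phos], collapse = ","))
  }
  parsed <- Map(parse_one, mods, start)
  data.frame(
    peptide = as.character(raw[["Peptide Sequence"]]),
    protein_id = as.character(raw[["Protein ID"]]),
    site_label = vapply(parsed, `[[`, character(1), "sites"),
    is_modified = grepl("79\\.96", mods),
    localization_prob = as.numeric(raw[["Localization"]]),
    intensity = as.numeric(raw[["Intensity"]]),
    protein_prob = as.numeric(raw[["Protein Probability"]]),
    fixed_mods = vapply(parsed, `[[`, character(1), "fixed"),
    stringsAsFactors = FALSE)
}

.validate_quant <- function(df) {
  if (any(df$intensity < 0, na.rm = TRUE)) stop("negative intensities")
  for (col in c("localization_prob", "protein_prob")) {
    v <- df[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop(col, " outside [0, 1]")
  }
  if (any(df$is_modified & !nzchar(df$site_label)))
    stop("modified records without a site label")
  rownames(df) <- NULL
  df
}

#' Apply identification-confidence filters to quantification records
#'
#' Keeps records whose protein probability is strictly above
#' `protein_prob_min` (so a record at exactly the threshold is removed);
#' modified records must additionally have a site-localization probability of
#' at least `localization_min` (inclusive). Row order is preserved and the
#' removal counts per rule are reported. Filtering is idempotent.
#'
#' @param records Canonical quant `data.frame` from [read_quant_table()].
#' @param protein_prob_min Strict lower bound on protein probability
#'   (default 0.95).
#' @param localization_min Inclusive lower bound on localization probability
#'   for modified records (default 0.80).
#' @return Filtered `data.frame`.
#' @export
filter_records <- function(records, protein_prob_min = 0.95,
                           localization_min = 0.80) {
  keep_prot <- !is.na(records$protein_prob) &
    records$protein_prob > protein_prob_min
  loc_ok <- !records$is_modified |
    (!is.na(records$localization_prob) &
       records$localization_prob >= localization_min)
  message("filter_records: removed ", sum(!keep_prot),
          " records at protein probability <= ", protein_prob_min, " and ",
          sum(keep_prot & !loc_ok), " modified records below localization ",
          localization_min)
  out <- records[keep_prot & loc_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative phosphopeptide abundance at one site
#'
#' Computes the standard relative-occupancy statistic: the MS1 intensity of the
#' phosphopeptide divided by the intensity of the *same* peptide without the
#' phosphorylation. "Same" means identical sequence and identical fixed
#' modifications; intensities are summed across rows (charge states) of the
#' same peptide before division. When the unmodified peptide was not
#' detected (summed intensity 0) the ratio is undefined and flagged rather
#' than infinite.
#'
#' @param records Filtered quant `data.frame` (apply [filter_records()]
#'   first).
#' @param site_label Site of interest, e.g. `"S303"`.
#' @param include_multi Include peptides carrying additional phosphosites in
#'   the modified intensity of each constituent site (default `FALSE`:
#'   single-site phosphopeptides only).
#' @return One-row `data.frame` with `site_label`, `ratio` (`NA` when
#'   undefined), `defined`, `modified_intensity`, `unmodified_intensity`.
#' @examples
#' \dontrun{
#' q <- filter_records(read_quant_table("combined_modified_peptide.tsv",
#'                                      dialect = "fragpipe"))
#' relative_abundance(q, "S303")
#' }
#' @export
relative_abundance <- function(records, site_label, include_multi = FALSE) {
  labels <- strsplit(records$site_label, ";", fixed = TRUE)
  n_sites <- lengths(labels)
  has_site <- vapply(labels, function(l) site_label %in% l, logical(1))
  mod_sel <- records$is_modified & has_site &
    (include_multi | n_sites == 1L)
  if (!any(records$is_modified & has_site))
    stop("no modified record for site ", site_label)
  if (!any(mod_sel))
    stop("site ", site_label, " is only observed on multi-phosphorylated ",
         "peptides; rerun with include_multi = TRUE")
  key <- paste(records$peptide, records$fixed_mods, sep = "\r")
  mod_keys <- unique(key[mod_sel])
  unmod_sel <- !records$is_modified & key %in% mod_keys
  mod_int <- sum(records$intensity[mod_sel])
  unmod_int <- sum(records$intensity[unmod_sel])
  defined <- unmod_int > 0
  data.frame(site_label = site_label,
             ratio = if (defined) mod_int / unmod_int else NA_real_,
             defined = defined,
             modified_intensity = mod_int,
             unmodified_intensity = unmod_int,
             stringsAsFactors = FALSE)
}

#' Relative abundance for every observed site
#'
#' @param records Filtered quant `data.frame`.
#' @param sites Site labels to quantify; default every site observed on a
#'   modified record (single-site peptides unless `include_multi`).
#' @param include_multi See [relative_abundance()].
#' @return `data.frame`, one row per site, as in [relative_abundance()].
#' @export
relative_abundance_table <- function(records, sites = NULL,
                                     include_multi = FALSE) {
  if (is.null(sites)) {
    labels <- strsplit(records$site_label[records$is_modified], ";",
                       fixed = TRUE)
    if (!include_multi) labels <- labels[lengths(labels) == 1L]
    sites <- unique(unlist(labels))
    sites <- sites[order(as.integer(gsub("[A-Z]", "", sites)))]
  }
  out <- do.call(rbind, lapply(sites, relative_abundance,
                               records = records,
                               include_multi = include_multi))
  rownames(out) <- NULL
  out
}

#' Write a site-level relative-abundance table as TSV
#'
#' Undefined ratios (undetectable unmodified peptide) are written as the
#' string `UNDEF`.
#'
#' @param site_table Result of [relative_abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(site_table, path) {
  out <- data.frame(
    site_label = site_table$site_label,
    ratio = ifelse(site_table$defined,
                   format(site_table$ratio, digits = 10, trim = TRUE),
                   "UNDEF"),
    modified_intensity = site_table$modified_intensity,
    unmodified_intensity = site_table$unmodified_intensity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
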