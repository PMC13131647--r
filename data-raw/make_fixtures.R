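# Builds the synthetic fixture files under inst/extdata/.
#
# The ortholog set is a synthetic stand-in for a real SIRT6 ortholog panel:
# a shared conserved core (no [ST]P motifs except an optional acceptor at
# position 294 followed by proline, plus the near-invariant S10-P11 site),
# and species-specific C-terminal tails carrying planted [ST]P motifs. The
# human analog carries the documented site architecture (S10; T294; C-term
# motifs at 303, 305, 326, 330, 338; a T at 337 followed by S338, i.e. an
# acceptor the strict [ST]P scan does not count), so the default boundary
# (reference residue 290) yields 6 C-terminal motif sites for human, 2 for
# the guinea-pig analog and 6 for the bowhead analog.
#
# Run from the package root: Rscript data-raw/make_fixtures.R

library(phosevol)
set.seed(20260930)

filler <- strsplit("ACDEFGHIKLMNQRVWY", "")[[1]]  # no P, S, T
core_len <- 298L

core <- sample(filler, core_len, replace = TRUE)
core[10L] <- "S"; core[11L] <- "P"          # near-invariant N-terminal site
core[294L] <- "A"; core[295L] <- "P"        # acceptor slot + obligatory +1 P

make_tail <- function(total_len, st_sites, extra_t = integer(0)) {
  # st_sites / extra_t are absolute positions in the full (core + tail) seq
  v <- sample(filler, total_len - core_len, replace = TRUE)
  off <- function(p) p - core_len
  for (p in st_sites) {
    v[off(p)] <- sample(c("S", "T"), 1L)
    v[off(p) + 1L] <- "P"
  }
  for (p in extra_t) v[off(p)] <- "T"
  v
}

species <- list(
  Homo_sapiens = list(
    len = 355L, t294 = TRUE,
    sites = c(303L, 305L, 326L, 330L, 338L), extra_t = 337L),
  Pan_troglodytes = list(
    len = 355L, t294 = TRUE,
    sites = c(303L, 305L, 326L, 330L, 338L), extra_t = 337L),
  Balaena_mysticetus = list(
    len = 352L, t294 = TRUE,
    sites = c(303L, 310L, 320L, 335L, 344L)),
  Tursiops_truncatus = list(
    len = 350L, t294 = TRUE,
    sites = c(305L, 318L, 333L, 342L)),
  Cavia_porcellus = list(
    len = 345L, t294 = FALSE, sites = c(315L, 336L)),
  Heterocephalus_glaber = list(
    len = 348L, t294 = FALSE, sites = c(306L, 322L, 338L), insert = TRUE),
  Mus_musculus = list(
    len = 334L, t294 = FALSE, sites = 308L),
  Bos_taurus = list(
    len = 340L, t294 = FALSE, sites = c(312L, 328L))
)

# fixed sites the per-species substitutions must avoid
protected <- c(9:12, 293:296)
insert_block <- sample(filler, 4L, replace = TRUE)  # H. glaber core insertion

seqs <- character(0)
rows <- character(0)
max_tail <- max(vapply(species, function(s) s$len, integer(1))) - core_len

for (nm in names(species)) {
  s <- species[[nm]]
  core_i <- core
  if (s$t294) core_i[294L] <- "T"
  if (nm != "Homo_sapiens") {            # a few neutral substitutions
    at <- sample(setdiff(seq_len(core_len), protected), 6L)
    core_i[at] <- sample(filler, 6L, replace = TRUE)
  }
  # force human sites to be T294/S303/T305/S326/S330/T337/S338 spellings
  tail_i <- make_tail(s$len, s$sites, if (is.null(s$extra_t)) integer(0) else s$extra_t)
  if (nm %in% c("Homo_sapiens", "Pan_troglodytes")) {
    off <- function(p) p - core_len
    tail_i[off(303L)] <- "S"; tail_i[off(305L)] <- "T"
    tail_i[off(326L)] <- "S"; tail_i[off(330L)] <- "S"
    tail_i[off(338L)] <- "S"
  }
  seqs[nm] <- paste0(paste(core_i, collapse = ""), paste(tail_i, collapse = ""))
  # aligned row: core cols 1..200 | 4 insertion cols | core cols 201..298 |
  #              tail left-justified, end-padded to the widest tail
  ins <- if (isTRUE(s$insert)) paste(insert_block, collapse = "") else "----"
  core_str <- paste(core_i, collapse = "")
  tail_str <- paste(tail_i, collapse = "")
  rows[nm] <- paste0(substr(core_str, 1, 200), ins,
                     substr(core_str, 201, core_len), tail_str,
                     strrep("-", max_tail - nchar(tail_str)))
}
# H. glaber's stated length excludes the insertion; add it to its sequence
seqs["Heterocephalus_glaber"] <- gsub("-", "",
  rows[["Heterocephalus_glaber"]])

aln <- as_msa(rows)
stopifnot(identical(unclass(ungap_alignment(aln)), seqs[names(aln)]))

# verify the planted architecture with the package's own scanner
cm <- build_column_map(aln, "Homo_sapiens")
bounds <- project_cterm_boundary(aln, cm, 290L)
counts <- vapply(names(seqs), function(nm)
  sum(scan_phosphosites(seqs[[nm]]) >= bounds[[nm]]), integer(1))
print(counts)
stopifnot(counts[["Homo_sapiens"]] == 6L,
          counts[["Cavia_porcellus"]] == 2L,
          counts[["Balaena_mysticetus"]] == 6L,
          bounds[["Heterocephalus_glaber"]] == 294L)  # 290 + 4-residue insertion

out <- file.path("inst", "extdata")
write_fasta(as_protein_set(seqs), file.path(out, "synthetic_sirt6_orthologs.fasta"))
write_fasta(unclass(aln), file.path(out, "synthetic_sirt6_orthologs_aln.fasta"))

# ultrametric tree (depth 96, roughly Myr-scaled divergences)
writeLines(paste0(
  "(((Homo_sapiens:7,Pan_troglodytes:7):82,((Cavia_porcellus:41,",
  "Heterocephalus_glaber:41):30,Mus_musculus:71):18):7,",
  "((Balaena_mysticetus:34,Tursiops_truncatus:34):22,Bos_taurus:56):40);"),
  file.path(out, "synthetic_mammal_tree.nwk"))

write.table(
  data.frame(
    species_id = c("Homo_sapiens", "Pan_troglodytes", "Balaena_mysticetus",
                   "Tursiops_truncatus", "Cavia_porcellus",
                   "Heterocephalus_glaber", "Mus_musculus", "Bos_taurus"),
    max_lifespan_years = c(122.5, 59.4, 211, 51.6, 12, 31, 4, 20)),
  file.path(out, "synthetic_lifespans.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# Recombinant-protein quantification example (generic dialect): the MS1
# intensities are the published example-run values; peptides sharing an
# unmodified backbone (S326/S330 and T337/S338) share one unmodified row.
quant <- data.frame(
  peptide = c("ALSPGYK", "ALSPGYK",
              "VLETPAWDGK", "VLETPAWDGK",
              "LNSPELK", "LNSPELK",
              "EQSPAGHSPVR", "EQSPAGHSPVR", "EQSPAGHSPVR",
              "AVTSPGLK", "AVTSPGLK", "AVTSPGLK"),
  protein_id = "SIRT6",
  site_label = c("S10", "", "T294", "", "S303", "",
                 "S326", "S330", "", "T337", "S338", ""),
  is_modified = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
  localization_prob = c(0.97, NA, 0.99, NA, 0.96, NA,
                        0.95, 0.98, NA, 0.92, 0.99, NA),
  intensity = c(4.28e7, 1.42e9, 1.60e10, 1.81e10, 6.47e8, 5.55e7,
                0, 1.73e9, 1.13e9, 8.47e9, 8.59e9, 1.03e8),
  protein_prob = 0.99,
  fixed_mods = "")
write.table(quant, file.path(out, "sirt6_recombinant_quant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixtures written\n")
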