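# shared test helpers: random sequence generation and tiny fixture builders

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force sliding-window oracle for the [ST]P motif
scan_oracle <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  hits <- integer(0)
  if (length(v) >= 2) {
    for (i in seq_len(length(v) - 1)) {
      if (v[i] %in% c("S", "T") && v[i + 1] == "P") hits <- c(hits, i)
    }
  }
  hits
}

# independent per-letter tally via gsub
count_letter <- function(s, letter) {
  nchar(s) - nchar(gsub(letter, "", s, fixed = TRUE))
}

write_tmp_fasta <- function(seqs, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fasta.gz" else ".fasta")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  close(con)
  path
}

extdata <- function(f) system.file("extdata", f, package = "phosevol")

# canonical generic-dialect quant frame used across ms_quant tests
make_quant_df <- function() {
  data.frame(
    peptide = c("AVLSPK", "AVLSPK", "GHTPLR", "GHTPLR"),
    protein_id = "P1",
    site_label = c("S100", "", "T200", ""),
    is_modified = c(TRUE, FALSE, TRUE, FALSE),
    localization_prob = c(0.95, NA, 0.85, NA),
    intensity = c(2e8, 1e8, 5e7, 2e8),
    protein_prob = 0.99,
    fixed_mods = "",
    stringsAsFactors = FALSE)
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
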