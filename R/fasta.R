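#' Read protein sequences from a FASTA file
#'
#' Reads a (plain or gzipped) FASTA file of protein sequences into a named
#' character vector, one element per record. The header token before the first
#' whitespace becomes the species identifier; sequences are upper-cased and
#' validated against the 20 standard amino-acid letters plus `X`.
#'
#' @param path Path to a FASTA file (may be gzip-compressed).
#' @return A named character vector of class `protein_set`: names are species
#'   identifiers, values are upper-case amino-acid sequences.
#' @details Gap characters (`-` or `.`) are rejected: aligned FASTA belongs in
#'   [read_alignment()]. Duplicate identifiers and empty files are errors.
#' @examples
#' fa <- system.file("extdata", "synthetic_sirt6_orthologs.fasta",
#'                   package = "phosevol")
#' seqs <- read_fasta(fa)
#' names(seqs)
#' @seealso [read_alignment()], [scan_phosphosites()], [compute_features()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw bytes: the AA reader silently drops invalid letters, which
  # would defeat validation
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  as_protein_set(seqs)
}

#' Construct a validated protein sequence set
#'
#' @param seqs Named character vector: names are species ids (no whitespace),
#'   values amino-acid sequences. Lower-case letters are accepted and
#'   upper-cased.
#' @return The validated, upper-cased named character vector with class
#'   `protein_set`.
#' @export
as_protein_set <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence needs a species identifier")
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate species identifiers: ", paste(dup, collapse = ", "))
  }
  if (any(grepl("\\s", names(seqs))))
    stop("species identifiers must not contain whitespace")
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  gap <- grepl("[-.]", seqs)
  if (any(gap)) {
    stop("gap characters in unaligned sequences for: ",
         paste(names(seqs)[gap], collapse = ", "),
         " (use read_alignment() for aligned input)")
  }
  bad <- grepl(sprintf("[^%s]", .aa_alphabet), seqs)
  if (any(bad)) {
    stop("non amino-acid characters in: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  structure(seqs, class = "protein_set")
}

# 20 standard residues plus X (unknown); X counts toward lengths only.
.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYX"

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set:", length(x), "sequences,",
      min(nchar(x)), "-", max(nchar(x)), "residues\n")
  invisible(x)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (e.g. a `protein_set`).
#' @param path Output file path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
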