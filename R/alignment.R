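#' Read a multiple sequence alignment
#'
#' Reads an aligned-FASTA or Clustal file into a named character vector of
#' equal-length gapped rows (class `msa`), in file order.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`. Default guesses
#'   from the first non-blank line (`>` means FASTA).
#' @return Named character vector of class `msa`; all elements have identical
#'   width, gaps are `-`. `attr(x, "width")` holds the column count.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 25L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(first[1], ">")) "fasta" else "clustal"
  }
  rows <- if (format == "fasta") {
    # raw read so that ragged rows reach the validator (which names them)
    as.character(Biostrings::readBStringSet(path))
  } else {
    as.character(Biostrings::readAAMultipleAlignment(path, format = "clustal"))
  }
  names(rows) <- sub("\\s.*$", "", names(rows))
  rows <- gsub(".", "-", toupper(rows), fixed = TRUE)
  as_msa(rows)
}

#' Construct a validated alignment object
#'
#' @param rows Named character vector of gapped rows ('-' gaps), all equal
#'   length.
#' @return The rows with class `msa` and a `width` attribute.
#' @export
as_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("every alignment row needs a species identifier")
  if (anyDuplicated(names(rows)))
    stop("duplicate species identifiers in alignment: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    short <- names(rows)[w != max(w)]
    stop("ragged alignment rows (length != ", max(w), "): ",
         paste(short, collapse = ", "))
  }
  rows <- toupper(rows)
  structure(rows, width = unname(w[1]), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x), "rows x", attr(x, "width"), "columns\n")
  invisible(x)
}

#' Remove gaps from every alignment row
#'
#' @param aln An `msa` object.
#' @return A `protein_set` of ungapped sequences in alignment order.
#' @export
ungap_alignment <- function(aln) {
  s <- gsub("-", "", unclass(aln), fixed = TRUE)
  attributes(s) <- list(names = names(aln))
  as_protein_set(s)
}

#' Map reference residue positions to alignment columns
#'
#' Builds the bidirectional mapping between 1-based residue positions of a
#' reference row and 1-based alignment columns: the k-th non-gap character of
#' the reference row sits in column `res_to_col[k]`.
#'
#' @param aln An `msa` object.
#' @param reference_id Row to use as coordinate reference.
#' @return An object of class `column_map` with fields `reference_id`,
#'   `res_to_col` (integer vector over reference residues) and `col_to_res`
#'   (integer vector over columns, `NA` at reference-gap columns).
#' @export
build_column_map <- function(aln, reference_id) {
  stopifnot(inherits(aln, "msa"))
  if (!reference_id %in% names(aln))
    stop("reference species absent from alignment: ", reference_id)
  v <- strsplit(aln[[reference_id]], "", fixed = TRUE)[[1]]
  nongap <- v != "-"
  res_to_col <- which(nongap)
  col_to_res <- rep(NA_integer_, length(v))
  col_to_res[res_to_col] <- seq_along(res_to_col)
  structure(list(reference_id = reference_id,
                 res_to_col = res_to_col,
                 col_to_res = col_to_res),
            class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("column_map: reference", x$reference_id, "-",
      length(x$res_to_col), "residues over", length(x$col_to_res), "columns\n")
  invisible(x)
}

#' Look up the alignment column of a reference residue
#'
#' @param colmap A `column_map`.
#' @param ref_position 1-based residue position(s) in the reference sequence.
#' @return Integer column index/indices.
#' @export
res_to_col <- function(colmap, ref_position) {
  stopifnot(inherits(colmap, "column_map"))
  if (any(ref_position < 1L | ref_position > length(colmap$res_to_col)))
    stop("reference position out of range (reference has ",
         length(colmap$res_to_col), " residues)")
  colmap$res_to_col[ref_position]
}

#' Strict-identity conservation profile
#'
#' Per-column conservation as the fraction of rows carrying the modal non-gap
#' residue: absolute identity only, chemically similar residues get no
#' credit, and gaps never count toward the modal residue (they still count in
#' the denominator, so gap-heavy columns score low).
#'
#' @param aln An `msa` object.
#' @return Numeric vector of length `width`, each entry in `[0, 1]` (an
#'   all-gap column scores 0).
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "msa"), length(aln) > 0L)
  mat <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  n <- nrow(mat)
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(tabulate(factor(col))) / n
  })
}

#' Project a reference C-terminal boundary onto every species
#'
#' Given the reference-coordinate start of the C-terminal domain, returns for
#' each species the 1-based position, in its own ungapped sequence, of the
#' first residue at or after the boundary column.
#'
#' @param aln An `msa` object.
#' @param colmap `column_map` for the reference species.
#' @param ref_boundary 1-based reference residue index starting the domain.
#' @return Named integer vector: for each species,
#'   `cterm_start = 1 +` (number of its residues strictly before the boundary
#'   column). A species fully gapped from the boundary column onward gets
#'   `length + 1` (a zero-length, degenerate domain).
#' @export
project_cterm_boundary <- function(aln, colmap, ref_boundary) {
  stopifnot(inherits(aln, "msa"))
  bcol <- res_to_col(colmap, ref_boundary)
  out <- vapply(names(aln), function(sp) {
    v <- strsplit(aln[[sp]], "", fixed = TRUE)[[1]]
    before <- if (bcol > 1L) sum(v[seq_len(bcol - 1L)] != "-") else 0L
    1L + as.integer(before)
  }, integer(1))
  out
}

#' Write a conservation profile as two-column TSV
#'
#' @param profile Numeric vector from [conservation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(profile, path) {
  utils::write.table(
    data.frame(column = seq_along(profile), score = profile),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a conservation profile
#'
#' Simple diagnostic line plot of per-column conservation.
#'
#' @param profile Numeric vector from [conservation_profile()].
#' @param boundary_col Optional alignment column of the C-terminal boundary,
#'   drawn as a dashed vertical line.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_conservation <- function(profile, boundary_col = NULL, ...) {
  graphics::plot(seq_along(profile), profile, type = "l",
                 xlab = "alignment column", ylab = "conservation",
                 ylim = c(0, 1), ...)
  if (!is.null(boundary_col))
    graphics::abline(v = boundary_col, lty = 2, col = "grey40")
  invisible(NULL)
}
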