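#' Protein sequences, alignments and region extraction
#'
#' Sequences are plain named character vectors (names are the sequence ids,
#' values the ungapped residue strings over the 20 amino acids plus `X`).
#' Alignments are `protein_msa` objects: a character matrix with one row per
#' sequence and one column per alignment column, `"-"` marking gaps.
#'
#' @name sequences
NULL

VALID_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

validate_protein_seqs <- function(seqs, what = "sequence") {
  if (length(seqs) == 0) return(invisible(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every ", what, " must be named by a non-empty id")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty ", what, ": ", paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    any(!ch %in% VALID_RESIDUES)
  }, logical(1))
  if (any(bad))
    stop("invalid residue characters in: ",
         paste(names(seqs)[bad], collapse = ", "),
         " (allowed: ", paste(VALID_RESIDUES, collapse = ""), ", uppercase, no gaps)")
  invisible(seqs)
}

#' Read and write protein FASTA files
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return `read_fasta` returns a named character vector of ungapped,
#'   uppercase residue strings, in file order; an empty file yields an empty
#'   vector. `write_fasta` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' write_fasta(c(a = "MKV", b = "MAL"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- setNames(toupper(as.character(set)), ids)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty record(s) in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of residue strings (gapped rows are
#'   permitted so alignments can be written with the same function).
#' @param width Line-wrap width for the residue lines.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
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

#' Specify a 1-based inclusive sequence region with optional residue anchors
#'
#' Regions follow the coordinate convention used for the channel N-terminal
#' stretches (e.g. K103_K516): 1-based and inclusive on both ends. Optional
#' expected residues at the two ends guard against extracting from a wrong
#' isoform or a stale annotation.
#'
#' @param start_pos,end_pos 1-based residue positions, `start_pos <= end_pos`.
#' @param start_aa,end_aa Optional single expected residue letters.
#' @return A `region_spec` object.
#' @examples
#' region_spec(103, 516, "K", "K")
#' @export
region_spec <- function(start_pos, end_pos, start_aa = NULL, end_aa = NULL) {
  start_pos <- as.integer(start_pos); end_pos <- as.integer(end_pos)
  if (is.na(start_pos) || is.na(end_pos) || start_pos < 1L || start_pos > end_pos)
    stop("need 1 <= start_pos <= end_pos")
  structure(list(start_pos = start_pos, end_pos = end_pos,
                 start_aa = start_aa, end_aa = end_aa),
            class = "region_spec")
}

#' Extract a coordinate-checked region from a protein sequence
#'
#' @param seq A single residue string (optionally named).
#' @param region A [region_spec()].
#' @return The extracted residues as a character string; the name, when
#'   present, is suffixed with `"-<start>_<end>"`.
#' @examples
#' extract_region(c(p = "MKTAYIAK"), region_spec(4, 6, "A", "I"))
#' @export
extract_region <- function(seq, region) {
  stopifnot(inherits(region, "region_spec"), length(seq) == 1L)
  n <- nchar(seq)
  if (region$end_pos > n)
    stop("region ", region$start_pos, "..", region$end_pos,
         " out of bounds for sequence of length ", n)
  out <- substr(seq, region$start_pos, region$end_pos)
  if (!is.null(region$start_aa)) {
    got <- substr(out, 1L, 1L)
    if (got != region$start_aa)
      stop("expected residue ", region$start_aa, " at position ",
           region$start_pos, " but found ", got,
           " (wrong isoform or annotation?)")
  }
  if (!is.null(region$end_aa)) {
    got <- substr(out, nchar(out), nchar(out))
    if (got != region$end_aa)
      stop("expected residue ", region$end_aa, " at position ",
           region$end_pos, " but found ", got,
           " (wrong isoform or annotation?)")
  }
  if (!is.null(names(seq)))
    names(out) <- paste0(names(seq), "-", region$start_pos, "_", region$end_pos)
  out
}

#' Multiple protein alignment container
#'
#' @param rows Named character vector of gapped rows of identical length;
#'   alternatively a character matrix of single residues with row names.
#' @return A `protein_msa`: character matrix (sequences x columns), gaps `"-"`.
#' @examples
#' aln <- protein_msa(c(s1 = "MK-V", s2 = "MKAV"))
#' ncol(aln)
#' ungap(aln)
#' @export
protein_msa <- function(rows) {
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    if (length(rows) == 0) stop("alignment needs at least one row")
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L)
      stop("alignment rows differ in length: ",
           paste(range(lens), collapse = " vs "))
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    rownames(mat) <- names(rows)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("alignment rows must carry unique ids")
  bad <- !(mat %in% c(VALID_RESIDUES, GAP))
  if (any(bad)) stop("invalid characters in alignment")
  validate_protein_seqs(apply(mat, 1L, function(r) paste(r[r != GAP], collapse = "")),
                        what = "ungapped alignment row")
  structure(mat, class = c("protein_msa", class(mat)))
}

#' @rdname protein_msa
#' @param path FASTA file of gapped rows.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  rows <- setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
  protein_msa(rows)
}

#' @rdname protein_msa
#' @param aln A `protein_msa`.
#' @export
msa_rows <- function(aln) {
  stopifnot(inherits(aln, "protein_msa"))
  setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' @rdname protein_msa
#' @export
ungap <- function(aln) {
  stopifnot(inherits(aln, "protein_msa"))
  m <- unclass(aln)
  setNames(apply(m, 1L, function(r) paste(r[r != GAP], collapse = "")),
           rownames(m))
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein_msa:", nrow(x), "sequences x", ncol(x), "columns\n")
  invisible(x)
}

#' Read a gene-to-species mapping table
#'
#' @param path TSV with columns `gene_id` and `species_id` (header optional
#'   when exactly two columns are present).
#' @return Named character vector: species id per gene id.
#' @export
read_species_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "species_id") %in% names(df))) {
    df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("species map needs columns gene_id, species_id")
    names(df)[1:2] <- c("gene_id", "species_id")
  }
  setNames(as.character(df$species_id), as.character(df$gene_id))
}
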