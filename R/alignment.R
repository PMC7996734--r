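# Alignment container, readers and coordinate maps.

#' Construct an RNA alignment
#'
#' Rows are gapped sequences over `{A, C, G, U, -}`. Input is normalized:
#' case-folded to upper case, `T` mapped to `U`, and the gap characters
#' `.` and `~` mapped to `-`. IUPAC ambiguity codes are rejected because the
#' covariance score is defined on concrete bases only.
#'
#' @param rows Character vector of gapped sequences (equal length).
#' @param ids Row identifiers; duplicates get numeric suffixes.
#' @return An object of class `rna_alignment` with elements `ids`, `rows`,
#'   `M` (number of rows), `L` (number of columns) and `mat`
#'   (M x L character matrix).
#' @export
rna_alignment <- function(rows, ids = NULL) {
  if (!length(rows)) stop("empty alignment: no sequences")
  rows <- toupper(as.character(rows))
  rows <- gsub("T", "U", rows, fixed = TRUE)
  rows <- gsub("[.~]", "-", rows)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  L <- nchar(rows[1])
  if (L < 1L) stop("empty alignment: zero-length rows")
  ragged <- which(nchar(rows) != L)
  if (length(ragged))
    stop("ragged alignment: row '", ids[ragged[1]], "' has length ",
         nchar(rows[ragged[1]]), ", expected ", L)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "U", "-"))
  if (length(bad))
    stop("alphabet error: character(s) ", paste(bad, collapse = " "),
         " not in {A,C,G,U,-} (IUPAC ambiguity codes are rejected)")
  structure(list(ids = ids, rows = rows, M = length(rows), L = L, mat = mat),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("RNA alignment: ", x$M, " row(s) x ", x$L, " column(s)\n", sep = "")
  show <- utils::head(seq_len(x$M), 6L)
  for (k in show) cat(sprintf("  %-12s %s\n", x$ids[k], x$rows[k]))
  if (x$M > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a multiple RNA alignment
#'
#' Reads aligned FASTA or Clustal files (a one-row file is the degenerate
#' single-sequence mode). Sequences are normalized as in [rna_alignment()].
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An [rna_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.size(path)) stop("empty input file: ", path)
  if (format == "clustal") return(read_clustal(path))
  aln <- tryCatch(
    seqinr::read.alignment(path, format = format, forceToLower = FALSE),
    error = function(e) stop("could not parse ", path, " as ", format,
                             ": ", conditionMessage(e)))
  if (!length(aln$seq)) stop("empty input: no sequences in ", path)
  rna_alignment(unlist(aln$seq), ids = aln$nam)
}

# Tolerant Clustal block parser: blocks are separated by blank lines; within a
# block each line is "<id> <chunk>"; conservation lines (leading whitespace or
# only [*:. ] symbols) and the CLUSTAL header are skipped; chunks concatenate
# positionally across blocks.
read_clustal <- function(path) {
  lines <- readLines(path)
  if (length(lines) && grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  is_cons <- grepl("^\\s", lines) | grepl("^[*:. ]*$", lines)
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(blank)
  keep <- !blank & !is_cons
  if (!any(keep)) stop("empty input: no sequences in ", path)
  ids <- character(0)
  chunks <- list()
  for (bl in unique(block_id[keep])) {
    rows <- lines[keep & block_id == bl]
    f <- regmatches(rows, regexpr("^\\S+", rows))
    s <- gsub("\\s+|[0-9]+$", "", sub("^\\S+", "", rows))
    if (!length(ids)) {
      ids <- f
      chunks <- as.list(s)
    } else {
      if (length(f) != length(ids))
        stop("could not parse ", path, " as clustal: block with ",
             length(f), " rows, expected ", length(ids))
      chunks <- Map(paste0, chunks, s)
    }
  }
  rna_alignment(unlist(chunks), ids = ids)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An [rna_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "rna_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(aln$M)) {
    writeLines(c(paste0(">", aln$ids[k]), aln$rows[k]), con)
  }
  invisible(path)
}

#' Column/position coordinate map for one alignment row
#'
#' Alignment gaps shift helix indices between alignment and sequence
#' coordinates; this map converts between the two. Non-gap columns map to
#' `1..n` (the ungapped length) in order; gap columns have no image.
#'
#' @param aln An [rna_alignment()].
#' @param row Row index, `1 <= row <= M`.
#' @return A list of class `coordinate_map` with `row`, `col_to_pos` (integer
#'   vector of length `L`, `NA` at gap columns), `pos_to_col` (integer vector
#'   of length `n`), and `seq` (the ungapped row).
#' @export
coordinate_map <- function(aln, row) {
  stopifnot(inherits(aln, "rna_alignment"))
  row <- as.integer(row)
  if (is.na(row) || row < 1L || row > aln$M)
    stop("row out of range: ", row, " (alignment has ", aln$M, " rows)")
  chars <- aln$mat[row, ]
  nongap <- chars != "-"
  col_to_pos <- rep(NA_integer_, aln$L)
  col_to_pos[nongap] <- seq_len(sum(nongap))
  pos_to_col <- which(nongap)
  structure(list(row = row, col_to_pos = col_to_pos, pos_to_col = pos_to_col,
                 seq = paste(chars[nongap], collapse = "")),
            class = "coordinate_map")
}
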