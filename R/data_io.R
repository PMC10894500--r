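#' Normalize an abiotic-stress term
#'
#' Lower-cases, trims, and collapses internal whitespace. Hyphens are kept,
#' so "UV-B" and "uv-b" normalize to the same term while "cold  stress"
#' and "cold stress" collapse together.
#'
#' @param term character vector of stress terms.
#' @return character vector of normalized terms.
#' @export
normalize_stress_term <- function(term) {
  out <- tolower(trimws(as.character(term)))
  gsub("[[:space:]]+", " ", out)
}

#' Read a miRNA-abiotic-stress association table
#'
#' Reads a delimited text export (one association per row) such as a
#' processed PncStress-style table. Column names are configurable; the
#' sequence column is optional (sequences may instead come from FASTA).
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param columns named list mapping the roles `mirna`, `stress` and
#'   (optionally) `sequence` to column names in the file.
#' @param sep field separator, default tab.
#' @return data.frame with columns `mirna`, `stress` (normalized) and
#'   `sequence` (NA where absent), in file row order.
#' @export
read_association_table <- function(path,
                                   columns = list(mirna = "mirna",
                                                  stress = "stress",
                                                  sequence = "sequence"),
                                   sep = "\t") {
  if (!file.exists(path)) {
    stop("association table not found: ", path)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  for (role in c("mirna", "stress")) {
    col <- columns[[role]]
    if (is.null(col) || !col %in% names(df)) {
      stop("required column '", if (is.null(col)) role else col,
           "' (role: ", role, ") missing from ", path)
    }
  }
  seq_col <- columns[["sequence"]]
  has_seq <- !is.null(seq_col) && seq_col %in% names(df)
  data.frame(
    mirna = as.character(df[[columns$mirna]]),
    stress = normalize_stress_term(df[[columns$stress]]),
    sequence = if (has_seq) toupper(as.character(df[[seq_col]])) else
      rep(NA_character_, nrow(df)),
    stringsAsFactors = FALSE
  )
}

#' Read miRNA sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readBStringSet()]. Sequences are
#' upper-cased; both U and T are accepted and preserved as read.
#'
#' @param path FASTA file path.
#' @return named character vector, id -> sequence.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">")) {
    stop("malformed FASTA (line 1): expected a '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Assemble an association dataset
#'
#' Deduplicates (miRNA, stress) pairs, drops records whose miRNA has no
#' sequence (neither inline nor in `sequences`), and builds the binary
#' adjacency matrix `A` (miRNAs x stresses, lexicographic order on both
#' axes). `A[i, j] = 1` iff miRNA i is associated with stress j.
#'
#' @param records data.frame as returned by [read_association_table()],
#'   or any data.frame with columns `mirna`, `stress` and optionally
#'   `sequence`.
#' @param sequences optional named character vector (id -> sequence), e.g.
#'   from [read_fasta_sequences()]; inline sequences take precedence.
#' @return an object of class `association_dataset` with fields
#'   `mirna_ids`, `stress_terms`, `sequences`, `pairs` (data.frame),
#'   `A`, and a `dropped` list with counts of removed records.
#' @export
build_association_dataset <- function(records, sequences = NULL) {
  stopifnot(is.data.frame(records), all(c("mirna", "stress") %in% names(records)))
  if (nrow(records) == 0L) stop("no association records supplied")
  rec <- data.frame(
    mirna = as.character(records$mirna),
    stress = normalize_stress_term(records$stress),
    sequence = if ("sequence" %in% names(records))
      toupper(as.character(records$sequence)) else rep(NA_character_, nrow(records)),
    stringsAsFactors = FALSE
  )

  # resolve one sequence per miRNA id: inline first, then the FASTA map
  seq_map <- list()
  for (i in seq_len(nrow(rec))) {
    s <- rec$sequence[i]
    id <- rec$mirna[i]
    if (!is.na(s) && nzchar(s) && is.null(seq_map[[id]])) seq_map[[id]] <- s
  }
  if (!is.null(sequences)) {
    for (id in names(sequences)) {
      if (is.null(seq_map[[id]]) && nzchar(sequences[[id]])) {
        seq_map[[id]] <- toupper(sequences[[id]])
      }
    }
  }

  key <- paste(rec$mirna, rec$stress, sep = "\r")
  dup_n <- sum(duplicated(key))
  rec <- rec[!duplicated(key), , drop = FALSE]

  has_seq <- vapply(rec$mirna, function(id) !is.null(seq_map[[id]]), logical(1))
  noseq_n <- sum(!has_seq)
  if (noseq_n > 0L) {
    warning(noseq_n, " association(s) dropped: miRNA without sequence (",
            paste(unique(rec$mirna[!has_seq]), collapse = ", "), ")")
  }
  rec <- rec[has_seq, , drop = FALSE]
  if (nrow(rec) == 0L) stop("all records dropped; empty dataset")

  mirna_ids <- sort(unique(rec$mirna))
  stress_terms <- sort(unique(rec$stress))
  A <- matrix(0L, length(mirna_ids), length(stress_terms),
              dimnames = list(mirna_ids, stress_terms))
  A[cbind(match(rec$mirna, mirna_ids), match(rec$stress, stress_terms))] <- 1L

  structure(list(
    mirna_ids = mirna_ids,
    stress_terms = stress_terms,
    sequences = vapply(mirna_ids, function(id) seq_map[[id]], character(1)),
    pairs = rec[order(rec$mirna, rec$stress), c("mirna", "stress"), drop = FALSE],
    A = A,
    dropped = list(duplicates = dup_n, missing_sequence = noseq_n)
  ), class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat("association_dataset:", length(x$mirna_ids), "miRNAs x",
      length(x$stress_terms), "stresses,", sum(x$A), "associations\n")
  invisible(x)
}

#' Write / read a labeled numeric matrix as TSV
#'
#' The file has one header row of column labels and a leading label
#' column; values are written with 15 significant digits so a round-trip
#' is lossless well past 12 significant digits.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the labeled matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  if (length(m) > 0L && any(!is.finite(m))) {
    stop("refusing to write non-finite matrix entries")
  }
  rn <- rownames(m); cn <- colnames(m)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  if (is.null(cn)) cn <- as.character(seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", cn), collapse = "\t"), con)
  if (nrow(m) > 0L) {
    body <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = "\t"))
    writeLines(paste(rn, body, sep = if (ncol(m) > 0L) "\t" else ""), con)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  cn <- header[-1L]
  if (length(lines) == 1L) {
    return(matrix(numeric(0), 0L, length(cn), dimnames = list(NULL, cn)))
  }
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != length(cn) + 1L)) {
    stop("ragged row(s) at line(s): ",
         paste(which(widths != length(cn) + 1L) + 1L, collapse = ", "))
  }
  rn <- vapply(cells, `[[`, character(1), 1L)
  vals <- t(vapply(cells, function(x) as.numeric(x[-1L]), numeric(length(cn))))
  if (length(cn) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(rn, cn)
  vals
}
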