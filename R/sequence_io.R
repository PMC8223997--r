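# Reading, validation and cleaning of protein sequences and labeled pair files.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues, in the fixed column order used throughout the
#' package (property tables, class maps).
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a protein record
#'
#' @param id Non-empty identifier string.
#' @param sequence Amino-acid sequence; uppercased on construction.
#' @return A `protein_record` (list with `id`, `sequence`).
#' @export
protein_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("protein id must be a non-empty string", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string (protein '", id, "')",
         call. = FALSE)
  structure(list(id = id, sequence = toupper(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa)\n  ", seq,
      "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. The identifier is
#' the header token up to the first whitespace; sequences are uppercased but
#' not cleaned (see [clean_sequence()]).
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects (names are the ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(structure(list(), names = character()))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: sequence data before first header at line ", first,
         call. = FALSE)
  headers <- which(startsWith(lines, ">"))
  # empty records (header immediately followed by header or EOF)
  ends <- c(headers[-1L] - 1L, length(lines))
  for (i in seq_along(headers)) {
    body <- lines[seq2(headers[i] + 1L, ends[i])]
    if (!any(nzchar(trimws(body))))
      stop("malformed FASTA: empty record at line ", headers[i], call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("malformed FASTA: empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  recs <- lapply(seq_along(set), function(i)
    protein_record(ids[i], toupper(as.character(set[[i]]))))
  names(recs) <- ids
  recs
}

# base::seq that yields integer(0) when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1),
                                        "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Remove non-standard residues from a sequence
#'
#' Keeps only the 20 standard amino acids; selenocysteine (U), pyrrolysine (O)
#' and the ambiguity codes (B, J, X, Z) are removed along with anything else
#' outside the standard alphabet. Order is preserved and case is normalized.
#'
#' @param seq A non-empty sequence string.
#' @return The cleaned, uppercased sequence.
#' @export
clean_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  out <- gsub(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), "",
              toupper(seq))
  if (!nzchar(out))
    stop("sequence has no standard residues after cleaning", call. = FALSE)
  out
}

#' Construct a labeled pair example
#'
#' @param id_a,id_b Protein identifiers (file order defines the orientation of
#'   the concatenated pair features).
#' @param label `"positive"`, `"negative"` or `"unknown"`.
#' @return A `pair_example` list.
#' @export
pair_example <- function(id_a, id_b, label = c("unknown", "positive",
                                               "negative")) {
  label <- match.arg(label)
  structure(list(id_a = id_a, id_b = id_b, label = label),
            class = "pair_example")
}

#' Build a labeled pair set
#'
#' Bundles the interacting class C+ and the non-interacting class C-. Pairs
#' are ordered; the same ordered pair may not appear in both classes.
#'
#' @param positives,negatives Data frames with columns `id_a`, `id_b`.
#' @return A `labeled_pair_set` with data-frame components `positives` and
#'   `negatives`.
#' @export
labeled_pair_set <- function(positives, negatives) {
  positives <- as.data.frame(positives)[, c("id_a", "id_b")]
  negatives <- as.data.frame(negatives)[, c("id_a", "id_b")]
  keyp <- paste(positives$id_a, positives$id_b, sep = "\r")
  keyn <- paste(negatives$id_a, negatives$id_b, sep = "\r")
  both <- intersect(keyp, keyn)
  if (length(both) > 0L)
    stop("ordered pair(s) present in both classes: ",
         paste(gsub("\r", "/", utils::head(both, 5)), collapse = ", "),
         call. = FALSE)
  structure(list(positives = positives, negatives = negatives),
            class = "labeled_pair_set")
}

#' @export
print.labeled_pair_set <- function(x, ...) {
  cat("<labeled_pair_set> ", nrow(x$positives), " positive / ",
      nrow(x$negatives), " negative pairs\n", sep = "")
  invisible(x)
}

#' Read a labeled protein-pair file
#'
#' Tab-separated `idA<TAB>idB<TAB>label` with labels in `{1, 0}` or `{+, -}`.
#' A header row is auto-detected by a non-label token ("label" or similar) in
#' the third column. All ids must resolve against `proteins`. Duplicate lines
#' are retained with a warning.
#'
#' @param path Path to the TSV file.
#' @param proteins Named list of protein records (as from [read_fasta()]).
#' @return A [labeled_pair_set()].
#' @export
read_pairs <- function(path, proteins) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  empty <- data.frame(id_a = character(), id_b = character())
  if (!any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(labeled_pair_set(empty, empty))
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("id_a", "id_b", "label"),
                          blank.lines.skip = TRUE)
  valid <- c("1", "0", "+", "-")
  if (tolower(df$label[1L]) == "label") df <- df[-1L, , drop = FALSE]
  bad <- setdiff(unique(df$label), valid)
  if (length(bad) > 0L)
    stop("unknown label token(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(unique(c(df$id_a, df$id_b)), names(proteins))
  if (length(missing) > 0L)
    stop("pair file references unknown protein id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  key <- paste(df$id_a, df$id_b, df$label, sep = "\r")
  if (anyDuplicated(key))
    warning("duplicate pair line(s) retained: ",
            sum(duplicated(key)), " duplicate(s) in ", path, call. = FALSE)
  pos <- df$label %in% c("1", "+")
  labeled_pair_set(df[pos, 1:2, drop = FALSE], df[!pos, 1:2, drop = FALSE])
}

#' Write a labeled pair set as TSV
#'
#' @param pairs A [labeled_pair_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  df <- rbind(cbind(pairs$positives, label = "1"),
              cbind(pairs$negatives, label = "0"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
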