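#' Read sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file and normalizes the
#' residues: letters are uppercased and, for DNA, U is mapped to T so that T/U
#' count as one letter. Characters outside the declared alphabet (IUPAC
#' ambiguity codes, gaps, ...) are retained in the residue string so that
#' positional indices stay faithful to the original sequence; they match no
#' letter in downstream vectorization but still contribute to the sequence
#' length n. The number of such characters is reported per record.
#'
#' @param path path to a FASTA file.
#' @param alphabet_kind one of `"dna"`, `"protein"`, `"custom"`; controls
#'   normalization (U to T for DNA) and which characters count as
#'   non-alphabet.
#' @param alphabet for `alphabet_kind = "custom"`, the ordered letters.
#' @return A data frame of class `nv_sequences` with columns `id`,
#'   `residues`, `non_alphabet` (count of retained non-alphabet characters),
#'   and attribute `alphabet_kind`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acggtagtcc"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, alphabet_kind = c("dna", "protein", "custom"),
                       alphabet = NULL) {
  alphabet_kind <- match.arg(alphabet_kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  res <- as.character(set)
  nv_sequences(ids, res, alphabet_kind = alphabet_kind, alphabet = alphabet)
}

#' Construct a normalized sequence set
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of residue strings (any case; U allowed
#'   for DNA).
#' @inheritParams read_fasta
#' @return see [read_fasta()].
#' @export
nv_sequences <- function(id, residues,
                         alphabet_kind = c("dna", "protein", "custom"),
                         alphabet = NULL) {
  alphabet_kind <- match.arg(alphabet_kind)
  id <- as.character(id)
  residues <- as.character(residues)
  stopifnot(length(id) == length(residues))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(residues)
  if (any(empty)) {
    stop("record(s) with empty residues: ", paste(id[empty], collapse = ", "),
         call. = FALSE)
  }
  residues <- normalize_residues(residues, alphabet_kind)
  ab <- alphabet_for(alphabet_kind, alphabet)
  non_ab <- count_non_alphabet(residues, ab)
  out <- data.frame(id = id, residues = residues, non_alphabet = non_ab,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet_kind") <- alphabet_kind
  attr(out, "alphabet") <- ab
  class(out) <- c("nv_sequences", "data.frame")
  out
}

# Uppercase; for DNA map U -> T (T and U are one letter). Idempotent.
normalize_residues <- function(residues, alphabet_kind = "dna") {
  residues <- toupper(residues)
  if (alphabet_kind == "dna") residues <- gsub("U", "T", residues, fixed = TRUE)
  residues
}

alphabet_for <- function(alphabet_kind, alphabet = NULL) {
  if (!is.null(alphabet)) return(check_alphabet(toupper(alphabet)))
  switch(alphabet_kind,
         dna = dna_alphabet(),
         protein = protein_alphabet(),
         stop("alphabet_kind = \"custom\" requires an explicit alphabet",
              call. = FALSE))
}

count_non_alphabet <- function(residues, alphabet) {
  vapply(strsplit(residues, "", fixed = TRUE),
         function(ch) sum(!(ch %in% alphabet)), integer(1))
}

#' Write sequences to a FASTA file
#'
#' @param seqs an `nv_sequences` data frame (or any data frame with `id` and
#'   `residues` columns).
#' @param path output file.
#' @param width line-wrap width; `Inf` for unwrapped.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = if (is.finite(width)) width else 20001L)
  invisible(path)
}

#' Read a sequence-id to group label table
#'
#' Accepts comma- or tab-delimited text with at least two columns
#' (id, group); the delimiter is auto-detected from the first line and an
#' optional header row is recognized by a first field equal to "id"
#' (case-insensitive). Exact duplicate rows are tolerated; the same id mapped
#' to two different groups is an error.
#'
#' @param path delimited text file.
#' @return data frame with columns `id`, `group`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty label table: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    stop("label table row(s) with fewer than 2 columns: line ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  unquote <- function(x) gsub('^"|"$', "", trimws(x))
  tab <- data.frame(id = unquote(vapply(parts, `[[`, "", 1)),
                    group = unquote(vapply(parts, `[[`, "", 2)),
                    stringsAsFactors = FALSE)
  if (tolower(tab$id[[1]]) == "id") tab <- tab[-1, , drop = FALSE]
  tab <- unique(tab)
  dup <- duplicated(tab$id)
  if (any(dup)) {
    stop("conflicting group labels for id(s): ",
         paste(unique(tab$id[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' @export
print.nv_sequences <- function(x, ...) {
  cat("<nv_sequences> ", nrow(x), " sequence(s), alphabet_kind = ",
      attr(x, "alphabet_kind"), "\n", sep = "")
  lens <- nchar(x$residues)
  show <- utils::head(data.frame(id = x$id, length = lens,
                                 non_alphabet = x$non_alphabet), 10)
  print(show, row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}
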