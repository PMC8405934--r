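# Amino-acid alphabet accepted throughout: the 20 standard residues plus X
# (unknown). X is tolerated because curated UniProt entries may contain it;
# downstream scorers treat it as neutral.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Create a protein record
#'
#' A `protein_record` holds one amino-acid sequence with an identifier and
#' optional description. Sequences are uppercased and validated against the
#' 20-letter alphabet plus `X`.
#'
#' @param id Record identifier (nonempty string).
#' @param sequence Amino-acid sequence (string; whitespace and gap characters
#'   are stripped, case is ignored).
#' @param description Optional free-text description.
#' @return An object of class `protein_record` with elements `id`,
#'   `description` and `sequence`.
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[\\s*.-]", "", sequence, perl = TRUE))
  if (!nzchar(sequence)) {
    stop("protein_record: sequence must be nonempty", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf(
      "protein_record: illegal residue character '%s' at position %d in '%s'",
      chars[bad[1L]], bad[1L], id), call. = FALSE)
  }
  structure(list(id = id, description = description, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Sequence length of a protein record
#' @param record A `protein_record`.
#' @return Integer number of residues.
#' @export
record_length <- function(record) nchar(record$sequence)

#' Split a record's sequence into a character vector of residues
#' @param record A `protein_record`.
#' @return Character vector, one element per residue.
#' @export
residues <- function(record) strsplit(record$sequence, "", fixed = TRUE)[[1L]]

#' Create a 1-based inclusive residue region
#'
#' Coordinates follow the residue-numbering convention used in the
#' truncation-construct literature: 1-based, both endpoints included, so
#' region 1964--2564 of a 2564-residue protein has length 601.
#'
#' @param start First residue (1-based, inclusive).
#' @param end Last residue (1-based, inclusive); must satisfy `end >= start`.
#' @return An object of class `region` with elements `start` and `end`.
#' @export
region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L,
            !is.na(start), !is.na(end))
  if (start < 1L || end < start) {
    stop(sprintf("region: require 1 <= start <= end, got [%d, %d]",
                 start, end), call. = FALSE)
  }
  structure(list(start = start, end = end), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %d-%d (%d aa)\n", x$start, x$end, region_length(x)))
  invisible(x)
}

#' Length of a region in residues
#' @param r A `region`.
#' @return `end - start + 1`.
#' @export
region_length <- function(r) r$end - r$start + 1L

#' Validate a region against a parent record
#' @param r A `region`.
#' @param record A `protein_record` (or an integer parent length).
#' @return Invisibly `TRUE`; errors if the region exceeds the sequence.
#' @export
validate_region <- function(r, record) {
  len <- if (inherits(record, "protein_record")) record_length(record)
         else as.integer(record)
  if (r$end > len) {
    stop(sprintf("region %d-%d out of bounds for sequence of length %d",
                 r$start, r$end, len), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a protein FASTA file
#'
#' Parses a (possibly multi-record, line-wrapped) amino-acid FASTA file into
#' a list of [protein_record()]s, preserving entry order. Sequences are
#' uppercased and whitespace is stripped before validation.
#'
#' @param path Path to a FASTA file.
#' @return List of `protein_record` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("read_fasta: not FASTA-formatted: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    stop("read_fasta: empty file (no FASTA records): ", path, call. = FALSE)
  }
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    protein_record(id, as.character(set[[i]]), desc)
  })
}

#' Write protein records to a FASTA file
#'
#' @param records A `protein_record` or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    seq <- r$sequence
    starts <- seq(1L, nchar(seq), by = width)
    c(paste0(">", header), substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Extract a subsequence as a new record
#'
#' Realizes a truncation construct: the returned record carries the parent
#' id annotated with the region, e.g. `"SETD2/1964-2564"`.
#'
#' @param record A `protein_record`.
#' @param r A `region`, validated against the record.
#' @return A `protein_record` of length `region_length(r)`.
#' @export
subsequence <- function(record, r) {
  validate_region(r, record)
  protein_record(sprintf("%s/%d-%d", record$id, r$start, r$end),
                 substr(record$sequence, r$start, r$end),
                 record$description)
}

#' Built-in catalog of SETD2/Set2 truncation constructs
#'
#' Returns the named residue intervals of the human SETD2 (2564 aa)
#' truncation constructs used in affinity-purification and expression
#' experiments: the six MudPIT constructs (1-1692, 1-503, 504-1403,
#' 1404-2564, 1404-1963, 1964-2564) plus FL (1-2564), the N/C split
#' (SETD2-N 1-1403, SETD2-C 1404-2564) and 967-1403. The 504-1403 fragment
#' is also referred to as 505-1403 in some listings; the catalog stores
#' 504-1403 and records the variant as an alias.
#'
#' @return A `construct_catalog`: a data.frame with columns `name`,
#'   `parent_id`, `start`, `end`, `alias`, carrying attribute
#'   `parent_lengths` (named integer vector).
#' @export
builtin_catalog <- function() {
  entries <- data.frame(
    name = c("FL", "SETD2-N", "SETD2-C", "N1", "C4", "504-1403",
             "1404-1963", "N4", "967-1403"),
    parent_id = "SETD2",
    start = c(1L, 1L, 1404L, 1L, 1L, 504L, 1404L, 1964L, 967L),
    end = c(2564L, 1403L, 2564L, 1692L, 503L, 1403L, 1963L, 2564L, 1403L),
    alias = c("", "N", "N3", "1-1692", "1-503", "505-1403", "", "1964-2564", ""),
    stringsAsFactors = FALSE
  )
  structure(entries,
            parent_lengths = c(SETD2 = 2564L),
            class = c("construct_catalog", "data.frame"))
}

#' Look up a construct region by name (or alias)
#'
#' @param catalog A `construct_catalog`.
#' @param name Construct name or alias.
#' @return A `region`.
#' @export
catalog_region <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) i <- match(name, catalog$alias)
  if (is.na(i)) stop("catalog_region: unknown construct: ", name, call. = FALSE)
  region(catalog$start[i], catalog$end[i])
}

#' Write a construct catalog to TSV
#' @param catalog A `construct_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog)[, c("name", "parent_id", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a construct catalog from TSV
#' @param path TSV with columns name, parent_id, start, end.
#' @return A `construct_catalog` (without parent-length validation metadata).
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "parent_id", "start", "end") %in% names(df)))
  if (anyDuplicated(df$name)) stop("catalog names must be unique", call. = FALSE)
  df$alias <- if ("alias" %in% names(df)) df$alias else ""
  structure(df[, c("name", "parent_id", "start", "end", "alias")],
            class = c("construct_catalog", "data.frame"))
}
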