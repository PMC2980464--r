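#' Construct a set of sequence records
#'
#' A `seq_set` is the package's lightweight container for identified
#' sequences: a data frame with columns `id`, `description`, `residues`
#' and `alphabet` (one of `"nucleotide"`, `"protein"`).  Residues are
#' normalized to uppercase; for nucleotide records any IUPAC ambiguity
#' code other than N is converted to N (with a warning) so that alignment
#' scoring stays well-defined.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences.
#' @param description optional free-text descriptions (default `""`).
#' @param alphabet `"nucleotide"` or `"protein"`, recycled to all records.
#' @return A data frame of class `seq_set`.
#' @examples
#' seq_set(c("a", "b"), c("acgt", "TTGA"))
#' @export
seq_set <- function(id, residues, description = "", alphabet = "nucleotide") {
  id <- as.character(id)
  residues <- toupper(gsub("[[:space:]]", "", as.character(residues)))
  if (length(id) != length(residues))
    stop("`id` and `residues` must have the same length")
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "))
  }
  alphabet <- match.arg(alphabet, c("nucleotide", "protein"))
  if (alphabet == "nucleotide") {
    bad <- grepl("[^ACGTN]", residues)
    if (any(bad)) {
      residues[bad] <- gsub("[^ACGTN]", "N", residues[bad])
      warning(sum(bad), " record(s) contained non-ACGTN characters; ",
              "normalized to N")
    }
  }
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    residues = residues,
                    alphabet = rep_len(alphabet, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", nrow(x), "record(s) [",
      paste(unique(x$alphabet), collapse = "/"), "]\n")
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    r <- x$residues[i]
    cat(sprintf("  %-20s %5d %s%s\n", x$id[i], nchar(r),
                substr(r, 1, 40), if (nchar(r) > 40) "..." else ""))
  }
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Read a FASTA file into a seq_set
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; record order is
#' preserved, residues are uppercased and whitespace-stripped, and the
#' header is split into id (first word) and description (remainder).
#'
#' @param path path to an existing FASTA file.
#' @param alphabet alphabet of the records (`"nucleotide"` or `"protein"`).
#' @return A `seq_set`.
#' @export
read_fasta <- function(path, alphabet = "nucleotide") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(ids, as.character(set), desc, alphabet)
}

#' Write a seq_set to a FASTA file
#'
#' @param records a non-empty `seq_set`.
#' @param path output path.
#' @param line_width residues per sequence line (default 60).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  if (!inherits(records, "seq_set")) records <- as_seq_set(records)
  if (nrow(records) == 0) stop("cannot write an empty record set")
  if (anyDuplicated(records$id)) stop("duplicate sequence ids")
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Coerce to a seq_set
#'
#' Accepts a `seq_set`, a named character vector of sequences, or a data
#' frame with at least `id` and `residues` columns.
#'
#' @param x object to coerce.
#' @param alphabet alphabet used when `x` carries none.
#' @return A `seq_set`.
#' @export
as_seq_set <- function(x, alphabet = "nucleotide") {
  if (inherits(x, "seq_set")) return(x)
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(seq_set(ids, unname(x), alphabet = alphabet))
  }
  if (is.data.frame(x)) {
    return(seq_set(x$id, x$residues,
                   if ("description" %in% names(x)) x$description else "",
                   if ("alphabet" %in% names(x)) x$alphabet[1] else alphabet))
  }
  stop("cannot coerce object of class ", class(x)[1], " to seq_set")
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq a nucleotide string (A, C, G, T, N), a named/unnamed
#'   character vector, or a 1-row nucleotide `seq_set`.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ACGT")
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "seq_set")) {
    if (any(seq$alphabet != "nucleotide"))
      stop("reverse_complement is defined for nucleotide records only")
    seq <- seq$residues
  }
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq)))
    stop("reverse_complement: input is not a plain A/C/G/T/N sequence")
  vapply(chartr("ACGTN", "TGCAN", seq), .revstr, character(1),
         USE.NAMES = FALSE)
}

# frame offsets: frames +1..+3 read the forward strand starting at offsets
# 0..2; -1..-3 read the reverse complement at offsets 0..2.
.frame_labels <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames with the
#' standard genetic code.  Stop codons are rendered `*` and kept in the
#' peptide (translate-through), and any codon containing N becomes `X`.
#' Frames too short to contain a codon yield an empty peptide.
#'
#' @param seq a nucleotide string or a 1-row nucleotide `seq_set`.
#' @return A data frame with columns `frame` (+1..+3, -1..-3) and
#'   `peptide`.
#' @examples
#' six_frame_translate("ATGAAA")
#' @export
six_frame_translate <- function(seq) {
  if (inherits(seq, "seq_set")) {
    if (nrow(seq) != 1) stop("six_frame_translate expects a single record")
    if (seq$alphabet != "nucleotide") stop("nucleotide record required")
    seq <- seq$residues
  }
  seq <- toupper(seq)
  rc <- if (nchar(seq) > 0) reverse_complement(seq) else ""
  peps <- character(6)
  for (k in 1:3) {
    peps[k]     <- .translate_frame(seq, k - 1L)
    peps[k + 3] <- .translate_frame(rc, k - 1L)
  }
  data.frame(frame = .frame_labels, peptide = peps, stringsAsFactors = FALSE)
}

.translate_frame <- function(nt, offset) {
  n <- nchar(nt) - offset
  if (n < 3) return("")
  starts <- seq.int(offset + 1L, by = 3L, length.out = n %/% 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])   # standard code; '*' stops
  aa[is.na(aa)] <- "X"                             # codons containing N
  paste(aa, collapse = "")
}
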