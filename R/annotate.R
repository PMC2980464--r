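#' Build an annotated reference collection
#'
#' Couples nucleotide reference records with a function label and a
#' position in a functional hierarchy (a stand-in for an annotated
#' nucleotide collection plus an orthology table).  Records whose
#' function is unknown carry the label `"hypothetical"`.
#'
#' @param seqs a nucleotide `seq_set`.
#' @param function_label character vector, one label per record.
#' @param category_path `/`-joined hierarchy path per record (e.g.
#'   `"metabolism/lipid metabolism"`); when `NULL`, paths are looked up
#'   from `hierarchy` by function label.
#' @param hierarchy optional hierarchy table from [read_hierarchy()].
#' @return A data frame of class `ref_db` (a `seq_set` with
#'   `function_label` and `category_path` columns).
#' @export
reference_db <- function(seqs, function_label, category_path = NULL,
                         hierarchy = NULL) {
  seqs <- as_seq_set(seqs)
  function_label <- rep_len(as.character(function_label), nrow(seqs))
  if (is.null(category_path)) {
    if (is.null(hierarchy)) stop("supply category_path or a hierarchy table")
    category_path <- hierarchy$path[match(function_label, hierarchy$leaf)]
    category_path[is.na(category_path)] <- function_label[is.na(category_path)]
  }
  category_path <- rep_len(as.character(category_path), nrow(seqs))
  if (any(!nzchar(category_path))) stop("category_path entries must be non-empty")
  out <- cbind(seqs, data.frame(function_label = function_label,
                                category_path = category_path,
                                stringsAsFactors = FALSE))
  class(out) <- c("ref_db", "seq_set", "data.frame")
  out
}

#' Read / write a two-column function hierarchy
#'
#' The hierarchy is a TSV with columns `leaf` (function label) and `path`
#' (`/`-joined category path), kept as a flat file so annotation runs
#' offline.
#'
#' @param path file path.
#' @return A data frame with columns `leaf` and `path`.
#' @export
read_hierarchy <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("leaf", "path") %in% names(h)))
    stop("hierarchy file needs 'leaf' and 'path' columns")
  h
}

#' @rdname read_hierarchy
#' @param hierarchy the hierarchy data frame to write.
#' @export
write_hierarchy <- function(hierarchy, path) {
  utils::write.table(hierarchy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.assignment_columns <- function() {
  data.frame(est_id = character(), subject_id = character(),
             function_label = character(), category_path = character(),
             score = integer(), evalue = numeric(), method = character(),
             stringsAsFactors = FALSE)
}

#' Transfer annotations to ESTs by translated best hit
#'
#' Each EST is compared against the annotated reference collection with
#' a 6x6-frame translated search; the single highest-scoring reference
#' with E-value at or below the threshold donates its function label
#' (method `"besthit"`).  Ties are broken by (score desc, evalue asc,
#' subject_id asc).  All non-best qualifying hits are retained in the
#' `"discarded"` attribute for audit, and ESTs with no qualifying hit
#' are listed in the `"unassigned"` attribute.
#'
#' @param ests nucleotide `seq_set` of (consensus) ESTs.
#' @param ref_db a [reference_db()].
#' @param scheme protein-mode [scoring_scheme()].
#' @param e_threshold significance cut-off (default 1e-2).
#' @return Assignment data frame: `est_id`, `subject_id`,
#'   `function_label`, `category_path`, `score`, `evalue`, `method`.
#' @export
transfer_annotations <- function(ests, ref_db, scheme = protein_scheme(),
                                 e_threshold = 1e-2) {
  ests <- as_seq_set(ests)
  if (is.null(ref_db) || nrow(ref_db) == 0) {
    out <- .assignment_columns()
    attr(out, "unassigned") <- ests$id
    attr(out, "discarded") <- .assignment_columns()
    return(out)
  }
  hits <- translated_search_db(ests, as_seq_set(ref_db), scheme, e_threshold)
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]  # sorted per query
  rest <- hits[duplicated(hits$query_id), , drop = FALSE]
  mk <- function(h) {
    i <- match(h$subject_id, ref_db$id)
    data.frame(est_id = h$query_id, subject_id = h$subject_id,
               function_label = ref_db$function_label[i],
               category_path = ref_db$category_path[i],
               score = h$score, evalue = h$evalue, method = "besthit",
               stringsAsFactors = FALSE)
  }
  out <- if (nrow(best)) mk(best) else .assignment_columns()
  attr(out, "unassigned") <- setdiff(ests$id, out$est_id)
  attr(out, "discarded") <- if (nrow(rest)) mk(rest) else .assignment_columns()
  out
}

#' Direct assignment by near-exact nucleotide match
#'
#' Emulates exact-match orthology assignment: an EST is assigned a
#' function only when a reference aligns at `identity_min` percent
#' nucleotide identity or better over at least `coverage_min` percent of
#' the EST length (method `"exact"`).  Literal exactness is untenable on
#' noisy single-pass reads, so both thresholds are configurable.
#'
#' @param ests nucleotide `seq_set`.
#' @param ko_table a [reference_db()] standing in for the orthology
#'   collection.
#' @param identity_min minimum percent identity (default 95).
#' @param coverage_min minimum percent of the EST covered (default 80).
#' @param scheme nucleotide [scoring_scheme()].
#' @return Assignment data frame as in [transfer_annotations()], one row
#'   per directly assigned EST.
#' @export
exact_match_assign <- function(ests, ko_table, identity_min = 95,
                               coverage_min = 80,
                               scheme = nucleotide_scheme()) {
  stopifnot(identity_min > 0, identity_min <= 100,
            coverage_min > 0, coverage_min <= 100)
  ests <- as_seq_set(ests)
  rows <- list()
  if (!is.null(ko_table) && nrow(ko_table)) {
    lut <- .scheme_lut(scheme)
    for (qi in seq_len(nrow(ests))) {
      q <- ests$residues[qi]
      # a qualifying alignment spans >= coverage_min% of the EST at >=
      # identity_min% identity, which bounds its score from below; skip
      # references whose optimal score cannot reach that bound
      min_cols <- (coverage_min / 100) * nchar(q)
      floor_score <- min_cols *
        ((identity_min / 100) * scheme$match -
           (1 - identity_min / 100) * max(abs(scheme$mismatch),
                                          scheme$gap_open))
      pre <- sw_score_vec_cpp(q, ko_table$residues, lut,
                              scheme$gap_open, scheme$gap_extend)
      cand <- list()
      for (si in which(pre >= floor_score)) {
        al <- sw_align_cpp(q, ko_table$residues[si], lut,
                           scheme$gap_open, scheme$gap_extend)
        if (al$score <= 0) next
        ident <- 100 * al$n_ident / al$n_cols
        cover <- 100 * (al$q_end - al$q_start + 1) / nchar(q)
        if (ident >= identity_min && cover >= coverage_min)
          cand[[length(cand) + 1L]] <-
            data.frame(est_id = ests$id[qi], subject_id = ko_table$id[si],
                       function_label = ko_table$function_label[si],
                       category_path = ko_table$category_path[si],
                       score = al$score, evalue = NA_real_, method = "exact",
                       stringsAsFactors = FALSE)
      }
      if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(-cand$score, cand$subject_id), , drop = FALSE]
        rows[[length(rows) + 1L]] <- cand[1, , drop = FALSE]
      }
    }
  }
  out <- do.call(rbind, c(rows, list(.assignment_columns())))
  rownames(out) <- NULL
  out
}

#' Roll assignments up into a category profile
#'
#' Groups assignments by their category path truncated to
#' `hierarchy_level` components; assignments labelled `"hypothetical"`
#' form their own category regardless of path.  Fractions are counts
#' over the total and sum to one.
#'
#' @param assignments non-empty assignment data frame.
#' @param hierarchy_level number of leading path components to keep.
#' @return A list of class `category_profile`: `counts`, `fractions`
#'   (named numerics), `n_total`.
#' @export
rollup <- function(assignments, hierarchy_level = 1) {
  if (is.null(assignments) || nrow(assignments) == 0)
    stop("cannot roll up an empty assignment set")
  cat_of <- function(path, label) {
    if (identical(tolower(label), "hypothetical")) return("hypothetical")
    parts <- strsplit(path, "/", fixed = TRUE)[[1]]
    paste(parts[seq_len(min(hierarchy_level, length(parts)))], collapse = "/")
  }
  cats <- mapply(cat_of, assignments$category_path,
                 assignments$function_label, USE.NAMES = FALSE)
  counts <- table(cats)
  counts <- counts[order(-as.integer(counts), names(counts))]
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, fractions = counts / sum(counts),
                 n_total = sum(counts)),
            class = "category_profile")
}

#' @export
print.category_profile <- function(x, ...) {
  cat("category profile over", x$n_total, "assignments:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-35s %4d (%5.1f%%)\n", nm, x$counts[[nm]],
                100 * x$fractions[[nm]]))
  invisible(x)
}
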