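#' Run one search pass of the clone library against an EST set
#'
#' Pass 1 searches the raw EST database; pass 2 is run, after
#' contamination cleaning, against the validated versions of the ESTs
#' that matched in pass 1.  Both passes use the same E-value threshold.
#' `mode = "nucleotide"` aligns the sequences directly (the default, most
#' robust to frameshift sequencing errors); `mode = "translated"` runs a
#' 6x6-frame translated comparison instead.
#'
#' @param clones nucleotide `seq_set` of cDNA clones.
#' @param est_db nucleotide `seq_set` of ESTs.
#' @param scheme [scoring_scheme()] matching the mode.
#' @param e_threshold significance cut-off (default 1e-2).
#' @param pass_id 1 or 2.
#' @param mode `"nucleotide"` or `"translated"`.
#' @return A list of class `pass_result`: `pass_id`, `hits` (alignment
#'   data frame with `query_id` = clone, `subject_id` = EST),
#'   `e_threshold`, `mode`.
#' @export
run_pass <- function(clones, est_db, scheme = nucleotide_scheme(),
                     e_threshold = 1e-2, pass_id = 1,
                     mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  clones <- as_seq_set(clones)
  if (nrow(clones) == 0) stop("clone library is empty")
  hits <- if (mode == "nucleotide")
    search_db(clones, est_db, scheme, e_threshold)
  else
    translated_search_db(clones, est_db, scheme, e_threshold)
  structure(list(pass_id = as.integer(pass_id), hits = hits,
                 e_threshold = e_threshold, mode = mode),
            class = "pass_result")
}

.pass_pairs <- function(p) {
  if (nrow(p$hits) == 0) return(character(0))
  unique(paste(p$hits$query_id, p$hits$subject_id, sep = "\r"))
}

#' Consensus between the two search passes
#'
#' Only ESTs that matched the same cDNA clones in both passes are kept.
#' In `"pair"` mode (the stricter default) a (clone, EST) pair must be
#' present in both passes; in `"clone"` mode every pass-2 pair whose
#' clone also matched something in pass 1 is kept.
#'
#' @param p1,p2 `pass_result`s with `pass_id` 1 and 2.
#' @param mode `"pair"` or `"clone"`.
#' @return A list of class `consensus_set`: `pairs` (data frame
#'   `clone_id`, `est_id`), `clones`, `ests`.
#' @export
consensus <- function(p1, p2, mode = c("pair", "clone")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p1, "pass_result"), inherits(p2, "pass_result"))
  if (p1$pass_id != 1L || p2$pass_id != 2L)
    stop("consensus expects pass 1 and pass 2 results, in that order")
  keys2 <- .pass_pairs(p2)
  kept <- if (mode == "pair") {
    intersect(.pass_pairs(p1), keys2)
  } else {
    clones1 <- unique(p1$hits$query_id)
    keys2[sub("\r.*$", "", keys2) %in% clones1]
  }
  pairs <- if (length(kept)) {
    parts <- strsplit(kept, "\r", fixed = TRUE)
    data.frame(clone_id = vapply(parts, `[`, "", 1),
               est_id = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(clone_id = character(), est_id = character(),
               stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$clone_id, pairs$est_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, clones = unique(pairs$clone_id),
                 ests = unique(pairs$est_id), mode = mode),
            class = "consensus_set")
}

#' Stage-by-stage funnel report
#'
#' Collects the counts of the annotation funnel (clones in, clones and
#' ESTs matched in pass 1, ESTs surviving cleaning, consensus clones and
#' ESTs, annotated ESTs, direct assignments) and checks their internal
#' consistency.
#'
#' @param clones the input clone `seq_set`.
#' @param p1 pass-1 `pass_result`.
#' @param clean_report `clean_report` from cleaning the matched ESTs.
#' @param p2 pass-2 `pass_result`.
#' @param cset `consensus_set`.
#' @param assignments best-hit assignment data frame from
#'   [transfer_annotations()] (may be `NULL` before annotation).
#' @param direct direct-assignment data frame from [exact_match_assign()]
#'   (may be `NULL`).
#' @return A list of class `funnel_report` with the eight counts.
#' @export
build_funnel <- function(clones, p1, clean_report, p2, cset,
                         assignments = NULL, direct = NULL) {
  stopifnot(inherits(p1, "pass_result"), inherits(p2, "pass_result"),
            inherits(cset, "consensus_set"))
  ests_p1 <- unique(p1$hits$subject_id)
  if (inherits(clean_report, "clean_report") &&
      clean_report$n_input != length(ests_p1))
    stop("clean report does not cover the pass-1 matched ESTs ",
         "(inconsistent stage provenance)")
  f <- list(
    n_clones = nrow(as_seq_set(clones)),
    n_clones_matched_p1 = length(unique(p1$hits$query_id)),
    n_ests_matched_p1 = length(ests_p1),
    n_ests_validated = if (inherits(clean_report, "clean_report"))
      clean_report$n_kept else length(ests_p1),
    n_clones_consensus = length(cset$clones),
    n_ests_consensus = length(cset$ests),
    n_ests_annotated = if (is.null(assignments)) NA_integer_ else
      length(unique(assignments$est_id[assignments$method == "besthit"])),
    n_direct_assignments = if (is.null(direct)) NA_integer_ else nrow(direct))
  with(f, {
    if (n_clones_consensus > n_clones_matched_p1 ||
        n_clones_matched_p1 > n_clones)
      stop("funnel invariant violated: clone counts must shrink downstream")
    if (n_ests_validated > n_ests_matched_p1)
      stop("funnel invariant violated: validated ESTs exceed matched ESTs")
    if (n_ests_consensus > n_ests_validated)
      stop("funnel invariant violated: consensus ESTs exceed validated ESTs")
  })
  structure(f, class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("annotation funnel:\n")
  cat(sprintf("  clones in library        %6d\n", x$n_clones))
  cat(sprintf("  clones matched (pass 1)  %6d\n", x$n_clones_matched_p1))
  cat(sprintf("  ESTs matched (pass 1)    %6d\n", x$n_ests_matched_p1))
  cat(sprintf("  ESTs validated           %6d\n", x$n_ests_validated))
  cat(sprintf("  clones in consensus      %6d\n", x$n_clones_consensus))
  cat(sprintf("  ESTs in consensus        %6d\n", x$n_ests_consensus))
  if (!is.na(x$n_ests_annotated))
    cat(sprintf("  ESTs annotated           %6d\n", x$n_ests_annotated))
  if (!is.na(x$n_direct_assignments))
    cat(sprintf("  direct assignments       %6d\n", x$n_direct_assignments))
  invisible(x)
}
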