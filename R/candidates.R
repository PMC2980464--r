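#' Build a keyword-annotated protein collection
#'
#' Protein records carrying a function label and a set of free-text
#' keywords describing their activity (a flat, offline stand-in for
#' keyword retrieval from a curated protein database).
#'
#' @param seqs a protein `seq_set`.
#' @param function_label one label per record (e.g. the enzyme family).
#' @param keywords list of character vectors, or a single
#'   semicolon-joined string per record.
#' @return Data frame of class `protein_db` with columns `id`,
#'   `residues`, `function_label`, `keywords` (list column).
#' @export
protein_db <- function(seqs, function_label, keywords) {
  seqs <- as_seq_set(seqs, "protein")
  if (is.character(keywords))
    keywords <- strsplit(keywords, ";", fixed = TRUE)
  keywords <- lapply(keywords, function(k) trimws(tolower(k)))
  stopifnot(length(keywords) == nrow(seqs))
  out <- seqs
  out$function_label <- rep_len(as.character(function_label), nrow(seqs))
  out$keywords <- I(keywords)
  class(out) <- c("protein_db", "seq_set", "data.frame")
  out
}

#' Extract proteins by functional keyword
#'
#' Case-insensitive whole-word matching of query keywords against each
#' record's keyword set.  `mode = "any"` (union semantics, the default)
#' keeps records matching at least one keyword; `mode = "all"` requires
#' every keyword.
#'
#' @param db a [protein_db()].
#' @param keywords non-empty character vector of keywords.
#' @param mode `"any"` or `"all"`.
#' @return The matching subset of `db` (possibly zero rows).
#' @export
extract_by_keyword <- function(db, keywords, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (length(keywords) == 0 || any(!nzchar(keywords)))
    stop("keywords must be non-empty")
  keywords <- tolower(trimws(keywords))
  hit <- vapply(db$keywords, function(recs) {
    found <- vapply(keywords, function(k)
      any(grepl(paste0("\\b", k, "\\b"), recs)), logical(1))
    if (mode == "any") any(found) else all(found)
  }, logical(1))
  out <- db[hit, , drop = FALSE]
  class(out) <- class(db)
  out
}

#' Match functional proteins against a clone library
#'
#' Screens every extracted protein against the (translated) clones and
#' emits one candidate per qualifying (protein, clone) pair, carrying the
#' protein region covered by the alignment — the region later used for
#' reciprocal verification.
#'
#' @param proteins a [protein_db()] (e.g. from [extract_by_keyword()]);
#'   the `target_activity` of each candidate is the protein's
#'   `function_label`.
#' @param clones nucleotide `seq_set`.
#' @param scheme protein-mode [scoring_scheme()].
#' @param e_threshold significance cut-off.
#' @return Data frame of class `candidate_matches`: `clone_id`,
#'   `protein_id`, `target_activity`, alignment columns and
#'   `matched_region_aa`.
#' @export
match_candidates <- function(proteins, clones, scheme = protein_scheme(),
                             e_threshold = 1e-2) {
  clones <- as_seq_set(clones)
  pep_db <- lapply(clones$residues, .frame_peptides)
  rows <- list()
  for (pi in seq_len(nrow(proteins))) {
    prot <- seq_set(proteins$id[pi], proteins$residues[pi],
                    alphabet = "protein")
    hits <- .pvt_search(prot, clones, pep_db, scheme, e_threshold)
    if (nrow(hits) == 0) next
    region <- substr(rep(proteins$residues[pi], nrow(hits)),
                     hits$q_start, hits$q_end)
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = hits$subject_id, protein_id = hits$query_id,
      target_activity = proteins$function_label[pi],
      q_start = hits$q_start, q_end = hits$q_end,
      s_frame = hits$s_frame, score = hits$score, evalue = hits$evalue,
      identity_pct = hits$identity_pct,
      matched_region_aa = region, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(clone_id = character(), protein_id = character(),
                      target_activity = character(), q_start = integer(),
                      q_end = integer(), s_frame = integer(),
                      score = integer(), evalue = numeric(),
                      identity_pct = numeric(),
                      matched_region_aa = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$clone_id, out$target_activity, -out$score), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_matches", "data.frame")
  out
}

#' Reciprocal functional-consistency verification of a candidate region
#'
#' The protein region covered by a candidate alignment is searched back
#' against the full protein collection; the top hits are classified by
#' function label.  The verdict is `supported` when at least
#' `consistency_min` of the hits share the candidate's target activity or
#' are unlabelled, `undetermined` when there are no hits (or the region
#' is shorter than 20 aa), and `contradicted` otherwise.
#'
#' @param match one row of [match_candidates()] output.
#' @param proteins the full [protein_db()] to verify against.
#' @param top_n number of top hits to classify (default 50).
#' @param e_threshold significance cut-off for the verification search.
#' @param consistency_min fraction of consistent hits required for
#'   `supported` (default 0.9, tolerating a few hits of unidentified
#'   function).
#' @param scheme protein-mode [scoring_scheme()].
#' @return A list of class `consistency_report`: the candidate, `n_hits`,
#'   `n_consistent`, `consistency_fraction`, `verdict`.
#' @export
reciprocal_verify <- function(match, proteins, top_n = 50,
                              e_threshold = 1e-2, consistency_min = 0.9,
                              scheme = protein_scheme()) {
  stopifnot(nrow(match) == 1)
  region <- match$matched_region_aa
  if (nchar(region) < 20) {
    warning("candidate region shorter than 20 aa; verdict undetermined")
    return(structure(list(candidate = match, n_hits = 0L, n_consistent = 0L,
                          consistency_fraction = NA_real_,
                          verdict = "undetermined"),
                     class = "consistency_report"))
  }
  lut <- .scheme_lut(scheme)
  n_eff <- sum(nchar(proteins$residues))
  scores <- sw_score_vec_cpp(region, proteins$residues, lut,
                             scheme$gap_open, scheme$gap_extend)
  ok <- which(scores > 0)
  ok <- ok[evalue(scores[ok], nchar(region), n_eff, scheme) <= e_threshold]
  # the region trivially hits its own source; verification is about the rest
  ok <- ok[proteins$id[ok] != match$protein_id]
  ord <- ok[order(-scores[ok], proteins$id[ok])]
  top <- utils::head(ord, top_n)
  n_hits <- length(top)
  if (n_hits == 0)
    return(structure(list(candidate = match, n_hits = 0L, n_consistent = 0L,
                          consistency_fraction = NA_real_,
                          verdict = "undetermined"),
                     class = "consistency_report"))
  labels <- proteins$function_label[top]
  consistent <- labels == match$target_activity | !nzchar(labels) |
    tolower(labels) %in% c("unknown", "unidentified", "hypothetical")
  frac <- sum(consistent) / n_hits
  structure(list(candidate = match, n_hits = n_hits,
                 n_consistent = sum(consistent),
                 consistency_fraction = frac,
                 verdict = if (frac >= consistency_min) "supported"
                           else "contradicted"),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("candidate %s ~ %s (%s): %d/%d consistent hits -> %s\n",
              x$candidate$clone_id, x$candidate$protein_id,
              x$candidate$target_activity, x$n_consistent, x$n_hits,
              x$verdict))
  invisible(x)
}

#' Define a PCR primer pair
#'
#' Primer strings are stripped of whitespace and any non-base decoration
#' (printed primers often carry typeset spaces and 5'/3' labels) before
#' use.
#'
#' @param name primer pair name.
#' @param forward,reverse primer sequences, 5'->3'.
#' @param max_mismatch mismatches tolerated outside the 3' clamp
#'   (default 0: stringent annealing).
#' @param three_prime_exact number of 3'-terminal bases that must match
#'   exactly (default 5).
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, max_mismatch = 0,
                        three_prime_exact = 5) {
  clean <- function(p) {
    p <- toupper(gsub("[^ACGTNacgtn]", "", p))
    if (nchar(p) < 15) stop("primer shorter than 15 nt after cleaning: ", p)
    p
  }
  structure(list(name = name, forward = clean(forward),
                 reverse = clean(reverse),
                 max_mismatch = as.integer(max_mismatch),
                 three_prime_exact = as.integer(three_prime_exact)),
            class = "primer_pair")
}

#' Predict PCR products on a template (in-silico PCR)
#'
#' Finds sites where the forward primer anneals (at most `max_mismatch`
#' mismatches, exact 3' clamp) and, downstream on the same strand, the
#' reverse complement of the reverse primer.  Each site combination
#' yields one amplicon spanning from the forward primer's 5' end through
#' the reverse primer's 5' end; both template strands are scanned, so
#' predicted lengths are invariant under reverse complementation of the
#' template.
#'
#' @param template a single nucleotide record.
#' @param pair a [primer_pair()].
#' @return Data frame of amplicons: `template_id`, `start`, `end`
#'   (1-based inclusive on the given template), `length`, `strand`,
#'   sorted by position; zero rows when no site pair exists.
#' @export
insilico_pcr <- function(template, pair) {
  template <- as_seq_set(template)
  stopifnot(nrow(template) == 1, inherits(pair, "primer_pair"))
  tmpl <- template$residues
  L <- nchar(tmpl)
  amps_on <- function(strand_seq, strand) {
    f_sites <- primer_sites_cpp(strand_seq, pair$forward,
                                pair$max_mismatch, pair$three_prime_exact)
    rc_rev <- reverse_complement(pair$reverse)
    # the reverse primer anneals to this strand as its reverse complement;
    # its 3' clamp sits at the 5' end of the rc string
    r_sites <- rev_primer_sites(strand_seq, rc_rev, pair)
    out <- list()
    for (f in f_sites) for (r in r_sites) {
      start <- f + 1L                      # 1-based 5' end of forward site
      end <- r + nchar(rc_rev)             # 1-based 3' end of rc(reverse)
      len <- end - start + 1L
      if (r >= f && len >= nchar(pair$forward) + nchar(pair$reverse))
        out[[length(out) + 1L]] <-
          data.frame(template_id = template$id,
                     start = if (strand == "+") start else L - end + 1L,
                     end = if (strand == "+") end else L - start + 1L,
                     length = len, strand = strand, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  res <- rbind(amps_on(tmpl, "+"), amps_on(reverse_complement(tmpl), "-"))
  if (is.null(res))
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# sites of the reverse-complemented reverse primer: mismatch budget and 3'
# clamp apply to the primer's own 3' end, which is the first base of the
# rc string -- so match the reversed problem.
rev_primer_sites <- function(strand_seq, rc_rev, pair) {
  rts <- .revstr(strand_seq)
  sites <- primer_sites_cpp(rts, .revstr(rc_rev),
                            pair$max_mismatch, pair$three_prime_exact)
  # map 0-based offsets on the reversed template back
  nchar(strand_seq) - sites - nchar(rc_rev)
}

.revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
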