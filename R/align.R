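#' Scoring schemes for local alignment
#'
#' A scoring scheme bundles the substitution scores, affine gap costs and
#' Karlin-Altschul statistical parameters used by every search stage.  A
#' gap of length k costs `gap_open + (k - 1) * gap_extend`, i.e. the first
#' gapped position is charged `gap_open`.
#'
#' The statistical parameters lambda and K were estimated once per named
#' default scheme by fitting an extreme-value distribution to optimal
#' local-alignment scores of random sequence pairs (gapped lambda/K have
#' no closed form); [calibrate_scheme()] re-runs that procedure.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch substitution scores (nucleotide mode).
#' @param matrix_name substitution matrix (protein mode); `"BLOSUM62"`.
#' @param gap_open,gap_extend non-negative gap costs, `gap_extend <=
#'   gap_open`.
#' @param karlin_lambda,karlin_K positive Gumbel parameters for
#'   [evalue()].
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 2, mismatch = -3,
                           matrix_name = "BLOSUM62",
                           gap_open = 5, gap_extend = 2,
                           karlin_lambda = 1.1, karlin_K = 0.33) {
  mode <- match.arg(mode)
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (karlin_lambda <= 0 || karlin_K <= 0)
    stop("karlin_lambda and karlin_K must be positive")
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 matrix_name = matrix_name,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @details `nucleotide_scheme()` defaults to match +2 / mismatch -3 with
#'   gap open 5 / extend 2 (BLAST-compatible conventions);
#'   `protein_scheme()` to BLOSUM62 with gap open 11 / extend 1.
#' @export
nucleotide_scheme <- function(match = 2, mismatch = -3,
                              gap_open = 5, gap_extend = 2) {
  default <- match == 2 && mismatch == -3 && gap_open == 5 && gap_extend == 2
  scoring_scheme("nucleotide", match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = if (default) .karlin_table$nt["lambda"] else 1.1,
                 karlin_K = if (default) .karlin_table$nt["K"] else 0.33)
}

#' @rdname scoring_scheme
#' @export
protein_scheme <- function(matrix_name = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  default <- matrix_name == "BLOSUM62" && gap_open == 11 && gap_extend == 1
  scoring_scheme("protein", matrix_name = matrix_name,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = if (default) .karlin_table$prot["lambda"] else 0.25,
                 karlin_K = if (default) .karlin_table$prot["K"] else 0.04)
}

# Empirically calibrated Gumbel parameters for the named default schemes
# (random-pair simulation, see calibrate_scheme); frozen here so searches
# are deterministic.
.karlin_table <- list(
  nt   = c(lambda = 0.572, K = 0.150),
  prot = c(lambda = 0.210, K = 0.020)
)

# 128x128 integer score lookup indexed by ASCII code.
.scheme_lut <- function(scheme) {
  lut <- matrix(0L, 128, 128)
  if (scheme$mode == "nucleotide") {
    lut[] <- as.integer(scheme$mismatch)  # N and unknowns score as mismatch
    for (b in c("A", "C", "G", "T")) {
      i <- utf8ToInt(b) + 1L
      lut[i, i] <- as.integer(scheme$match)
    }
  } else {
    mat <- .protein_matrix(scheme$matrix_name)
    aas <- rownames(mat)
    xcol <- mat[, "X"]
    lut[] <- as.integer(min(mat))          # never hit in practice
    idx <- utf8ToInt(paste(aas, collapse = "")) + 1L
    for (a in seq_along(aas)) {
      lut[idx[a], ] <- as.integer(xcol[a])  # unknown char scores like X
      for (b in seq_along(aas))
        lut[idx[a], idx[b]] <- as.integer(mat[a, b])
    }
  }
  lut
}

.protein_env <- new.env(parent = emptyenv())

# Substitution matrix with the translate-through extension: '*' vs '*'
# scores +1 and '*' vs residue -4, so alignments may cross stop codons at
# a penalty.
.protein_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (!is.null(.protein_env[[key]])) return(.protein_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  mat <- e[[name]]
  if (!"*" %in% rownames(mat)) {
    mat <- rbind(cbind(mat, `*` = -4L), `*` = c(rep(-4L, ncol(mat)), 1L))
  }
  mat["*", ] <- -4L; mat[, "*"] <- -4L; mat["*", "*"] <- 1L
  .protein_env[[key]] <- mat
  mat
}

.check_alphabet <- function(rec, scheme) {
  if (any(rec$alphabet != scheme$mode))
    stop("record alphabet (", paste(unique(rec$alphabet), collapse = ","),
         ") does not match scheme mode (", scheme$mode, ")")
}

.alignment_columns <- c("query_id", "subject_id", "q_start", "q_end",
                        "s_start", "s_end", "q_frame", "s_frame", "score",
                        "evalue", "identity_pct", "aligned_query",
                        "aligned_subject")

.empty_alignment <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    q_start = integer(), q_end = integer(),
                    s_start = integer(), s_end = integer(),
                    q_frame = integer(), s_frame = integer(),
                    score = integer(), evalue = numeric(),
                    identity_pct = numeric(), aligned_query = character(),
                    aligned_subject = character(), stringsAsFactors = FALSE)
  out
}

.alignment_row <- function(query_id, subject_id, al, q_frame = 0L,
                           s_frame = 0L, evalue = NA_real_) {
  data.frame(query_id = query_id, subject_id = subject_id,
             q_start = al$q_start, q_end = al$q_end,
             s_start = al$s_start, s_end = al$s_end,
             q_frame = as.integer(q_frame), s_frame = as.integer(s_frame),
             score = al$score, evalue = evalue,
             identity_pct = 100 * al$n_ident / al$n_cols,
             aligned_query = al$aligned_query,
             aligned_subject = al$aligned_subject,
             stringsAsFactors = FALSE)
}

#' Optimal local alignment of two sequences
#'
#' Exact affine-gap Smith-Waterman (Gotoh recurrences) with one optimal
#' traceback; ties in the dynamic program are broken diagonal > up > left
#' for reproducibility.  A best score of 0 means no local alignment
#' exists and a zero-row data frame is returned.
#'
#' @param a,b single records (1-row `seq_set`, or a plain string) in the
#'   scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @return A 1-row alignment data frame (columns `query_id`, `subject_id`,
#'   1-based inclusive coordinates, `score`, `identity_pct`, gapped
#'   aligned strings), or zero rows for no alignment.
#' @examples
#' smith_waterman("ACGTACGT", "ACGTACGT", nucleotide_scheme())
#' @export
smith_waterman <- function(a, b, scheme = nucleotide_scheme()) {
  a <- as_seq_set(a, scheme$mode); b <- as_seq_set(b, scheme$mode)
  if (nrow(a) != 1 || nrow(b) != 1)
    stop("smith_waterman aligns exactly two single records")
  .check_alphabet(a, scheme); .check_alphabet(b, scheme)
  lut <- .scheme_lut(scheme)
  al <- sw_align_cpp(a$residues, b$residues, lut,
                     scheme$gap_open, scheme$gap_extend)
  if (al$score <= 0) return(.empty_alignment())
  .alignment_row(a$id, b$id, al)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `score` in
#' a search of a query of length `m` against a database of effective
#' length `n`: `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score positive alignment score.
#' @param m query length.
#' @param n effective database length (sum of subject lengths).
#' @param scheme a [scoring_scheme()] supplying lambda and K.
#' @return The E-value (positive numeric).
#' @examples
#' evalue(30, 400, 1e5, nucleotide_scheme())
#' @export
evalue <- function(score, m, n, scheme) {
  if (any(score <= 0)) stop("score must be positive")
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * score)
}

# order hits by (score desc, evalue asc, subject asc) within query
.sort_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$query_id, -hits$score, hits$evalue,
                     hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Search a sequence database
#'
#' Aligns every query against every database entry with
#' [smith_waterman()] and reports, per query, all subjects whose best
#' alignment reaches `e_threshold`.  The effective database length used
#' for E-values is the summed length of all database sequences.  Hits are
#' sorted by (score desc, evalue asc, subject_id asc) within each query.
#'
#' @param queries,db `seq_set`s in the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @param e_threshold report hits with E-value at or below this (default
#'   1e-2, the pipeline-wide significance cut-off).
#' @return An alignment data frame, one row per (query, subject) hit;
#'   queries without hits contribute no rows.
#' @export
search_db <- function(queries, db, scheme = nucleotide_scheme(),
                   e_threshold = 1e-2) {
  queries <- as_seq_set(queries, scheme$mode)
  if (is.null(db) || (is.data.frame(db) && nrow(db) == 0) ||
      (!is.data.frame(db) && length(db) == 0))
    return(.empty_alignment())
  db <- as_seq_set(db, scheme$mode)
  .check_alphabet(queries, scheme); .check_alphabet(db, scheme)
  if (e_threshold <= 0) stop("e_threshold must be positive")
  lut <- .scheme_lut(scheme)
  n_eff <- sum(nchar(db$residues))
  rows <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries$residues[qi]
    scores <- sw_score_vec_cpp(q, db$residues, lut,
                               scheme$gap_open, scheme$gap_extend)
    pos <- which(scores > 0)
    if (length(pos) == 0) next
    ev <- evalue(scores[pos], nchar(q), n_eff, scheme)
    keep <- pos[ev <= e_threshold]
    if (length(keep) == 0) next
    sub <- lapply(keep, function(si) {
      al <- sw_align_cpp(q, db$residues[si], lut,
                         scheme$gap_open, scheme$gap_extend)
      .alignment_row(queries$id[qi], db$id[si], al,
                     evalue = evalue(al$score, nchar(q), n_eff, scheme))
    })
    rows[[qi]] <- do.call(rbind, sub)
  }
  .sort_hits(do.call(rbind, c(rows, list(.empty_alignment()))))
}

# peptide set for the translated modes, in frame order +1,+2,+3,-1,-2,-3
.frame_peptides <- function(nt) six_frame_translate(nt)$peptide

#' Translated-vs-translated comparison of two nucleotide sequences
#'
#' Compares all 36 (query frame, subject frame) peptide pairs of two
#' nucleotide sequences (tBLASTx-style) and reports the best local
#' alignment with the frames recorded.  Coordinates are amino-acid
#' positions on the respective frame translations.
#'
#' @param query,subject single nucleotide records.
#' @param scheme a protein-mode [scoring_scheme()].
#' @return A 1-row alignment data frame (or zero rows if no frame pair
#'   aligns).
#' @export
translated_search <- function(query, subject, scheme = protein_scheme()) {
  query <- as_seq_set(query); subject <- as_seq_set(subject)
  if (scheme$mode != "protein") stop("translated_search needs a protein scheme")
  lut <- .scheme_lut(scheme)
  pq <- .frame_peptides(query$residues)
  ps <- .frame_peptides(subject$residues)
  if (all(!nzchar(pq)) || all(!nzchar(ps))) return(.empty_alignment())
  sc <- sw_score_cross_cpp(pq, ps, lut, scheme$gap_open, scheme$gap_extend)
  if (max(sc) <= 0) return(.empty_alignment())
  bi <- which(sc == max(sc), arr.ind = TRUE)[1, ]   # first index = tie-break
  al <- sw_align_cpp(pq[bi[1]], ps[bi[2]], lut,
                     scheme$gap_open, scheme$gap_extend)
  .alignment_row(query$id, subject$id, al,
                 q_frame = .frame_labels[bi[1]], s_frame = .frame_labels[bi[2]])
}

# effective translated length of a nucleotide db (in residues)
.aa_db_length <- function(db) sum(nchar(db$residues) %/% 3L)

#' Translated search of nucleotide queries against a nucleotide database
#'
#' Runs [translated_search()] for every (query, subject) pair, attaching
#' E-values computed from the query's longest frame translation and the
#' translated effective database length.
#'
#' @inheritParams search_db
#' @return An alignment data frame with `q_frame`/`s_frame` filled in.
#' @export
translated_search_db <- function(queries, db, scheme = protein_scheme(),
                                 e_threshold = 1e-2) {
  queries <- as_seq_set(queries)
  if (is.null(db) || (is.data.frame(db) && nrow(db) == 0))
    return(.empty_alignment())
  db <- as_seq_set(db)
  lut <- .scheme_lut(scheme)
  n_eff <- .aa_db_length(db)
  if (n_eff == 0) return(.empty_alignment())
  pep_db <- lapply(db$residues, .frame_peptides)
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    pq <- .frame_peptides(queries$residues[qi])
    m <- max(nchar(pq))
    if (m == 0) next
    for (si in seq_along(pep_db)) {
      sc <- sw_score_cross_cpp(pq, pep_db[[si]], lut,
                               scheme$gap_open, scheme$gap_extend)
      if (max(sc) <= 0) next
      ev <- evalue(max(sc), m, n_eff, scheme)
      if (ev > e_threshold) next
      bi <- which(sc == max(sc), arr.ind = TRUE)[1, ]
      al <- sw_align_cpp(pq[bi[1]], pep_db[[si]][bi[2]], lut,
                         scheme$gap_open, scheme$gap_extend)
      rows[[length(rows) + 1L]] <-
        .alignment_row(queries$id[qi], db$id[si], al,
                       q_frame = .frame_labels[bi[1]],
                       s_frame = .frame_labels[bi[2]], evalue = ev)
    }
  }
  .sort_hits(do.call(rbind, c(rows, list(.empty_alignment()))))
}

#' Search a protein query against translated nucleotide sequences
#'
#' For each database entry the protein is aligned to all six frame
#' translations (tBLASTn-style) and the best frame is reported, with the
#' same sorting and E-value thresholding as [search_db()].
#'
#' @param protein a single protein record.
#' @param nt_db a nucleotide `seq_set`.
#' @inheritParams search_db
#' @return An alignment data frame; `s_frame` records the subject frame.
#' @export
protein_vs_translated_search <- function(protein, nt_db,
                                         scheme = protein_scheme(),
                                         e_threshold = 1e-2) {
  protein <- as_seq_set(protein, "protein")
  if (nrow(protein) != 1) stop("one protein query at a time")
  if (is.null(nt_db) || (is.data.frame(nt_db) && nrow(nt_db) == 0))
    return(.empty_alignment())
  nt_db <- as_seq_set(nt_db)
  .pvt_search(protein, nt_db, lapply(nt_db$residues, .frame_peptides),
              scheme, e_threshold)
}

# workhorse behind protein_vs_translated_search, taking pre-translated
# subject peptides so callers screening many proteins against one clone
# set translate the clones only once
.pvt_search <- function(protein, nt_db, pep_db, scheme, e_threshold) {
  lut <- .scheme_lut(scheme)
  n_eff <- .aa_db_length(nt_db)
  m <- nchar(protein$residues)
  rows <- list()
  for (si in seq_len(nrow(nt_db))) {
    ps <- pep_db[[si]]
    if (all(!nzchar(ps))) next
    sc <- sw_score_vec_cpp(protein$residues, ps, lut,
                           scheme$gap_open, scheme$gap_extend)
    if (max(sc) <= 0) next
    ev <- evalue(max(sc), m, n_eff, scheme)
    if (ev > e_threshold) next
    bf <- which.max(sc)
    al <- sw_align_cpp(protein$residues, ps[bf], lut,
                       scheme$gap_open, scheme$gap_extend)
    rows[[length(rows) + 1L]] <-
      .alignment_row(protein$id, nt_db$id[si], al,
                     s_frame = .frame_labels[bf], evalue = ev)
  }
  .sort_hits(do.call(rbind, c(rows, list(.empty_alignment()))))
}

#' Estimate Gumbel parameters for a scoring scheme empirically
#'
#' Gapped Karlin-Altschul lambda/K have no closed form; this fits an
#' extreme-value distribution to optimal local-alignment scores of random
#' sequence pairs (method of moments refined by maximum likelihood) and
#' returns the implied `lambda` and `K`.  Used once to freeze the
#' built-in table for the named default schemes.
#'
#' @param scheme a [scoring_scheme()].
#' @param n_pairs number of random pairs to score.
#' @param m,n lengths of the two random sequences in each pair.
#' @param seed RNG seed.
#' @return Named numeric vector `c(lambda, K)`.
#' @export
calibrate_scheme <- function(scheme, n_pairs = 2000, m = 150, n = 300,
                             seed = 1) {
  alph <- if (scheme$mode == "nucleotide") c("A", "C", "G", "T")
          else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lut <- .scheme_lut(scheme)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  rand <- function(len) paste(sample(alph, len, replace = TRUE), collapse = "")
  scores <- vapply(seq_len(n_pairs), function(i)
    sw_score_cpp(rand(m), rand(n), lut, scheme$gap_open, scheme$gap_extend),
    integer(1))
  s <- as.numeric(scores)
  beta0 <- stats::sd(s) * sqrt(6) / pi
  mu0 <- mean(s) - 0.57722 * beta0
  nll <- function(p) {
    mu <- p[1]; beta <- exp(p[2])
    z <- (s - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  mu <- fit$par[1]; beta <- exp(fit$par[2])
  lambda <- 1 / beta
  K <- exp(mu / beta) / (m * n)
  c(lambda = lambda, K = K)
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
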