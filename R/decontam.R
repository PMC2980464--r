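#' Screening thresholds for contamination detection
#'
#' VecScreen-inspired defaults: a stringent match +1 / mismatch -5
#' screening scheme, score threshold 16 for matches whose footprint
#' reaches into a 25 nt terminal window and 24 for internal matches.
#'
#' @param terminal_score minimum score for a terminal-window match.
#' @param internal_score minimum score for an internal match.
#' @param terminal_window width (nt) of the terminal windows.
#' @param scheme the nucleotide [scoring_scheme()] used for screening.
#' @return A list of class `decontam_thresholds`.
#' @export
decontam_thresholds <- function(terminal_score = 16, internal_score = 24,
                                terminal_window = 25,
                                scheme = nucleotide_scheme(
                                  match = 1, mismatch = -5,
                                  gap_open = 3, gap_extend = 3)) {
  stopifnot(terminal_score > 0, internal_score >= terminal_score,
            terminal_window > 0)
  structure(list(terminal_score = terminal_score,
                 internal_score = internal_score,
                 terminal_window = terminal_window, scheme = scheme),
            class = "decontam_thresholds")
}

#' Locate vector/primer contamination in a sequence
#'
#' Each contaminant-library record is aligned repeatedly against the
#' sequence (masking previous matches) until no alignment reaches the
#' reporting thresholds.  A match is reported when its score reaches the
#' internal threshold anywhere, or the (lower) terminal threshold if its
#' footprint overlaps a terminal window.  Overlapping regions from
#' different contaminants are merged.
#'
#' @param seq a single nucleotide record.
#' @param lib a non-empty nucleotide `seq_set` of vector/primer sequences.
#' @param thresholds a [decontam_thresholds()].
#' @return Data frame of masked regions: `seq_id`, `start`, `end`
#'   (1-based inclusive), `source_id`, `score`, `terminal`.
#' @export
screen_contaminants <- function(seq, lib,
                                thresholds = decontam_thresholds()) {
  seq <- as_seq_set(seq)
  if (nrow(seq) != 1) stop("screen one sequence at a time")
  lib <- as_seq_set(lib)
  if (nrow(lib) == 0) stop("contaminant library is empty")
  th <- thresholds
  lut <- .scheme_lut(th$scheme)
  L <- nchar(seq$residues)
  regions <- list()
  for (vi in seq_len(nrow(lib))) {
    work <- seq$residues
    repeat {
      al <- sw_align_cpp(work, lib$residues[vi], lut,
                         th$scheme$gap_open, th$scheme$gap_extend)
      if (al$score < th$terminal_score) break
      in_term <- al$q_start <= th$terminal_window ||
        al$q_end > L - th$terminal_window
      if (al$score >= th$internal_score || in_term)
        regions[[length(regions) + 1L]] <-
          data.frame(seq_id = seq$id, start = al$q_start, end = al$q_end,
                     source_id = lib$id[vi], score = al$score,
                     terminal = in_term, stringsAsFactors = FALSE)
      # mask the matched stretch ('!' scores like a mismatch, and a run of
      # it cannot seed a new alignment) and look for further matches
      substr(work, al$q_start, al$q_end) <-
        strrep("!", al$q_end - al$q_start + 1L)
      if (al$score < th$internal_score && !in_term) break
    }
  }
  out <- do.call(rbind, regions)
  if (is.null(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), source_id = character(),
                      score = integer(), terminal = logical(),
                      stringsAsFactors = FALSE))
  # merge overlapping/adjacent calls, keeping the best score among merged
  ir <- IRanges::IRanges(out$start, out$end)
  red <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, red)
  grp <- S4Vectors::subjectHits(ov)
  merged <- do.call(rbind, lapply(seq_along(red), function(g) {
    members <- which(grp == g)
    best <- members[which.max(out$score[members])]
    data.frame(seq_id = seq$id,
               start = IRanges::start(red)[g], end = IRanges::end(red)[g],
               source_id = out$source_id[best], score = max(out$score[members]),
               terminal = IRanges::start(red)[g] <= th$terminal_window |
                 IRanges::end(red)[g] > L - th$terminal_window,
               stringsAsFactors = FALSE)
  }))
  merged[order(merged$start), , drop = FALSE]
}

#' Trim masked contamination from a sequence
#'
#' Removes terminal masks; if an internal mask splits the sequence the
#' longest clean fragment is kept.  A result shorter than `min_len` is a
#' rejection (local-alignment statistics are unreliable on very short
#' sequences) and `NULL` is returned.
#'
#' @param seq a single nucleotide record.
#' @param regions masked regions from [screen_contaminants()].
#' @param min_len minimum kept length (default 100 nt).
#' @return A trimmed 1-row `seq_set` with attribute `kept_range`
#'   (1-based, on the input), or `NULL` on rejection.
#' @export
trim_sequence <- function(seq, regions, min_len = 100) {
  seq <- as_seq_set(seq)
  L <- nchar(seq$residues)
  if (nrow(regions) == 0) {
    if (L < min_len) return(NULL)
    out <- seq; attr(out, "kept_range") <- c(1L, L)
    return(out)
  }
  if (any(regions$start < 1 | regions$end > L | regions$start > regions$end))
    stop("masked regions fall outside the sequence")
  clean <- IRanges::gaps(
    IRanges::reduce(IRanges::IRanges(regions$start, regions$end)),
    start = 1L, end = L)
  if (length(clean) == 0) return(NULL)
  w <- IRanges::width(clean)
  best <- which.max(w)           # ties: first (5'-most) fragment
  if (w[best] < min_len) return(NULL)
  s <- IRanges::start(clean)[best]; e <- IRanges::end(clean)[best]
  out <- seq_set(seq$id, substr(seq$residues, s, e), seq$description)
  attr(out, "kept_range") <- c(s, e)
  out
}

#' Screen and trim a whole sequence database
#'
#' Applies [screen_contaminants()] and [trim_sequence()] to every record
#' and reports per-sequence dispositions (`kept`, `trimmed`, `rejected`).
#' Fully contaminated (or over-trimmed) records are rejected rather than
#' masked, so `n_input = n_kept + n_rejected` always holds.
#'
#' @param db a nucleotide `seq_set`.
#' @param lib contaminant library (`seq_set`).
#' @param thresholds a [decontam_thresholds()].
#' @param min_len minimum kept length after trimming.
#' @return A list with `validated` (the cleaned `seq_set`) and `report`
#'   (class `clean_report`: counts plus a per-sequence disposition table).
#' @export
clean_database <- function(db, lib, thresholds = decontam_thresholds(),
                           min_len = 100) {
  db <- as_seq_set(db)
  keep <- list(); disp <- character(nrow(db)); masked_bp <- integer(nrow(db))
  kept_start <- rep(NA_integer_, nrow(db)); kept_end <- kept_start
  for (i in seq_len(nrow(db))) {
    rec <- db[i, , drop = FALSE]; class(rec) <- c("seq_set", "data.frame")
    reg <- screen_contaminants(rec, lib, thresholds)
    masked_bp[i] <- if (nrow(reg)) sum(reg$end - reg$start + 1L) else 0L
    trimmed <- trim_sequence(rec, reg, min_len)
    if (is.null(trimmed)) {
      disp[i] <- "rejected"
    } else {
      disp[i] <- if (nchar(trimmed$residues) < nchar(rec$residues))
        "trimmed" else "kept"
      kr <- attr(trimmed, "kept_range")
      kept_start[i] <- kr[1]; kept_end[i] <- kr[2]
      keep[[length(keep) + 1L]] <- trimmed
    }
  }
  validated <- if (length(keep)) do.call(rbind, keep) else db[0, ]
  class(validated) <- c("seq_set", "data.frame")
  report <- structure(list(
    n_input = nrow(db),
    n_kept = sum(disp != "rejected"),
    n_trimmed = sum(disp == "trimmed"),
    n_rejected = sum(disp == "rejected"),
    dispositions = data.frame(seq_id = db$id, disposition = disp,
                              kept_start = kept_start, kept_end = kept_end,
                              masked_bp = masked_bp,
                              stringsAsFactors = FALSE)),
    class = "clean_report")
  list(validated = validated, report = report)
}

#' @export
print.clean_report <- function(x, ...) {
  cat("contamination cleaning:", x$n_input, "in,", x$n_kept, "kept (",
      x$n_trimmed, "trimmed ),", x$n_rejected, "rejected\n")
  invisible(x)
}
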