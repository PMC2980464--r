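#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end annotation run.  Both search
#' passes share one E-value threshold (default 1e-2, the pipeline-wide
#' significance cut-off) unless `p2_e_threshold` is set explicitly.
#'
#' @param e_threshold significance cut-off used by every search stage.
#' @param p2_e_threshold optional override for pass 2 (defaults to
#'   `e_threshold`; overriding it is discouraged).
#' @param search_mode `"nucleotide"` (default; robust to frameshift
#'   noise) or `"translated"` for the clone-vs-EST passes.
#' @param consensus_mode `"pair"` (default, stricter) or `"clone"`.
#' @param clean_clones trim vector from the clone library before pass 1
#'   (default `TRUE`).
#' @param screen_only if `TRUE`, pass 2 uses the untrimmed sequences of
#'   the ESTs that survived screening, rather than their trimmed
#'   versions.
#' @param min_len minimum sequence length kept after trimming.
#' @param identity_min,coverage_min direct-assignment thresholds
#'   (percent), see [exact_match_assign()].
#' @param hierarchy_level category depth for [rollup()].
#' @param keywords keywords for enzyme-candidate extraction.
#' @param top_n,consistency_min reciprocal-verification settings.
#' @param nt_scheme,prot_scheme scoring schemes for the two modes.
#' @param decontam a [decontam_thresholds()].
#' @param seed RNG seed for simulation-backed runs.
#' @param paths named list of input paths (`clones`, `ests`, `refs`,
#'   `ref_annotations`, `hierarchy`, `proteins`, `protein_annotations`,
#'   `vectors`, `primers`); ignored when `sim` is given.
#' @param sim optional [sim_config()]; when present the inputs are
#'   generated instead of read.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(e_threshold = 1e-2,
                            p2_e_threshold = NULL,
                            search_mode = c("nucleotide", "translated"),
                            consensus_mode = c("pair", "clone"),
                            clean_clones = TRUE,
                            screen_only = FALSE,
                            min_len = 100,
                            identity_min = 95, coverage_min = 80,
                            hierarchy_level = 1,
                            keywords = c("methylation", "dehydrogenation",
                                         "reduction", "hydroxylation"),
                            top_n = 50, consistency_min = 0.9,
                            nt_scheme = nucleotide_scheme(),
                            prot_scheme = protein_scheme(),
                            decontam = decontam_thresholds(),
                            seed = 1,
                            paths = list(),
                            sim = NULL) {
  if (e_threshold <= 0) stop("e_threshold must be positive")
  cfg <- as.list(environment())
  cfg$search_mode <- match.arg(search_mode)
  cfg$consensus_mode <- match.arg(consensus_mode)
  if (is.null(cfg$p2_e_threshold)) cfg$p2_e_threshold <- e_threshold
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments; a
#' `paths:` block maps onto input paths and a `sim:` block onto
#' [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), c("sim", "paths"))]
  args <- args[names(args) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, c(args, list(paths = y$paths, sim = sim)))
}

.config_hash <- function(cfg) {
  f <- tempfile(); on.exit(unlink(f))
  dput(cfg[order(names(unclass(cfg)))], file = f)
  unname(tools::md5sum(f))
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) return(generate_bundle(cfg$sim))
  need <- function(key, what) {
    p <- cfg$paths[[key]]
    if (is.null(p) || !file.exists(p))
      stop("missing ", what, " input (path '", key, "')")
    p
  }
  refs <- read_fasta(need("refs", "reference"), "nucleotide")
  ra <- utils::read.delim(need("ref_annotations", "reference annotation"),
                          stringsAsFactors = FALSE)
  i <- match(refs$id, ra$id)
  pa <- utils::read.delim(need("protein_annotations", "protein annotation"),
                          stringsAsFactors = FALSE)
  prots <- read_fasta(need("proteins", "protein"), "protein")
  j <- match(prots$id, pa$id)
  prim <- utils::read.delim(need("primers", "primer"),
                            stringsAsFactors = FALSE)
  primers <- lapply(seq_len(nrow(prim)), function(k)
    primer_pair(prim$name[k], prim$forward[k], prim$reverse[k]))
  names(primers) <- prim$name
  list(clones = read_fasta(need("clones", "clone library")),
       est_db = read_fasta(need("ests", "EST database")),
       ref_db = reference_db(refs, ra$function_label[i],
                             ra$category_path[i]),
       hierarchy = read_hierarchy(need("hierarchy", "hierarchy")),
       protein_db = protein_db(prots, pa$function_label[j],
                               pa$keywords[j]),
       contaminant_lib = read_fasta(need("vectors", "contaminant library")),
       primers = primers, truth = NULL, config = NULL)
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Per-clone functional call from consensus EST assignments
#'
#' Each consensus clone inherits the majority function label among its
#' consensus ESTs' best-hit assignments (ties broken by the label of the
#' highest-scoring assignment).
#'
#' @param cset a [consensus()] result.
#' @param assignments best-hit assignments of the consensus ESTs.
#' @return Data frame `clone_id`, `function_label`, `category_path`,
#'   `n_ests_assigned`.
#' @export
clone_annotations <- function(cset, assignments) {
  pairs <- merge(cset$pairs, assignments,
                 by.x = "est_id", by.y = "est_id")
  out <- lapply(split(pairs, pairs$clone_id), function(d) {
    tab <- sort(table(d$function_label), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    lab <- if (length(top) == 1) top else
      d$function_label[which.max(d$score)]
    data.frame(clone_id = d$clone_id[1], function_label = lab,
               category_path = d$category_path[match(lab,
                                                     d$function_label)],
               n_ests_assigned = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(
    data.frame(clone_id = character(), function_label = character(),
               category_path = character(), n_ests_assigned = integer(),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Run the full annotation pipeline
#'
#' Executes the stages in order: (optional clone cleaning) -> pass 1
#' against the raw EST database -> contamination cleaning of the matched
#' ESTs -> pass 2 against the validated ESTs -> consensus -> translated
#' annotation transfer and direct assignment -> category roll-up ->
#' keyword candidate screening with reciprocal verification -> in-silico
#' PCR of any supplied primer pairs.  Every stage's counts are logged and
#' written to `outdir` alongside the result tables.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir directory for result files (`funnel.tsv`,
#'   `assignments.tsv`, `profile.tsv`, `candidates.tsv`,
#'   `consistency.tsv`, `amplicons.tsv`, `run.log`); `NULL` writes
#'   nothing.
#' @param quiet suppress progress messages.
#' @return A list of class `pipeline_result` with all stage outputs
#'   (`funnel`, `p1`, `clean`, `p2`, `cset`, `assignments`, `direct`,
#'   `profile`, `clone_calls`, `candidates`, `consistency`, `amplicons`,
#'   `inputs`, `config_hash`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  t0 <- Sys.time()
  logs <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logs <<- c(logs, msg)
    if (!quiet) message(msg)
  }
  hash <- .config_hash(cfg)
  say("estbridge pipeline (config %s)", hash)

  inputs <- .stage("inputs", say, .load_inputs(cfg))
  clones <- inputs$clones
  say("inputs: %d clones, %d ESTs, %d references, %d proteins",
      nrow(clones), nrow(inputs$est_db), nrow(inputs$ref_db),
      nrow(inputs$protein_db))

  if (isTRUE(cfg$clean_clones)) {
    cc <- .stage("clean_clones", say,
                 clean_database(clones, inputs$contaminant_lib,
                                cfg$decontam, cfg$min_len))
    clones <- cc$validated
    say("clone cleaning: %d kept (%d trimmed), %d rejected",
        cc$report$n_kept, cc$report$n_trimmed, cc$report$n_rejected)
  }

  scheme_p <- if (cfg$search_mode == "nucleotide") cfg$nt_scheme
              else cfg$prot_scheme
  p1 <- .stage("bridge", say,
               run_pass(clones, inputs$est_db, scheme_p, cfg$e_threshold,
                        pass_id = 1, mode = cfg$search_mode))
  say("pass 1: %d clones matched %d ESTs (%d pairs)",
      length(unique(p1$hits$query_id)), length(unique(p1$hits$subject_id)),
      nrow(p1$hits))

  matched_ids <- unique(p1$hits$subject_id)
  matched <- inputs$est_db[inputs$est_db$id %in% matched_ids, , drop = FALSE]
  class(matched) <- c("seq_set", "data.frame")
  cl <- .stage("clean", say,
               clean_database(matched, inputs$contaminant_lib,
                              cfg$decontam, cfg$min_len))
  say("EST cleaning: %d matched -> %d validated (%d trimmed, %d rejected)",
      cl$report$n_input, cl$report$n_kept, cl$report$n_trimmed,
      cl$report$n_rejected)
  p2_subjects <- if (isTRUE(cfg$screen_only)) {
    keep <- cl$report$dispositions$seq_id[
      cl$report$dispositions$disposition != "rejected"]
    s <- inputs$est_db[inputs$est_db$id %in% keep, , drop = FALSE]
    class(s) <- c("seq_set", "data.frame"); s
  } else cl$validated

  p2 <- .stage("bridge", say,
               run_pass(clones, p2_subjects, scheme_p, cfg$p2_e_threshold,
                        pass_id = 2, mode = cfg$search_mode))
  say("pass 2: %d clones matched %d ESTs (%d pairs)",
      length(unique(p2$hits$query_id)), length(unique(p2$hits$subject_id)),
      nrow(p2$hits))

  cset <- .stage("consensus", say, consensus(p1, p2, cfg$consensus_mode))
  say("consensus (%s mode): %d clones matching %d ESTs",
      cfg$consensus_mode, length(cset$clones), length(cset$ests))

  cons_ests <- p2_subjects[p2_subjects$id %in% cset$ests, , drop = FALSE]
  class(cons_ests) <- c("seq_set", "data.frame")
  assignments <- .stage("annotate", say,
                        transfer_annotations(cons_ests, inputs$ref_db,
                                             cfg$prot_scheme,
                                             cfg$e_threshold))
  say("annotation: %d/%d consensus ESTs assigned by best hit",
      nrow(assignments), nrow(cons_ests))
  direct <- .stage("annotate", say,
                   exact_match_assign(cons_ests, inputs$ref_db,
                                      cfg$identity_min, cfg$coverage_min,
                                      cfg$nt_scheme))
  say("direct assignment: %d/%d ESTs by near-exact match",
      nrow(direct), nrow(cons_ests))

  profile <- if (nrow(assignments))
    .stage("rollup", say, rollup(assignments, cfg$hierarchy_level))
  else NULL
  clone_calls <- .stage("annotate", say,
                        clone_annotations(cset, assignments))

  enzymes <- .stage("candidates", say,
                    extract_by_keyword(inputs$protein_db, cfg$keywords))
  cands <- .stage("candidates", say,
                  match_candidates(enzymes, clones, cfg$prot_scheme,
                                   cfg$e_threshold))
  say("candidates: %d enzyme proteins extracted, %d candidate matches",
      nrow(enzymes), nrow(cands))
  consistency <- .stage("candidates", say, {
    if (nrow(cands)) {
      reps <- lapply(seq_len(nrow(cands)), function(k)
        reciprocal_verify(cands[k, , drop = FALSE], inputs$protein_db,
                          cfg$top_n, cfg$e_threshold, cfg$consistency_min,
                          cfg$prot_scheme))
      data.frame(clone_id = cands$clone_id, protein_id = cands$protein_id,
                 target_activity = cands$target_activity,
                 region_aa = nchar(cands$matched_region_aa),
                 n_hits = vapply(reps, `[[`, 0L, "n_hits"),
                 n_consistent = vapply(reps, `[[`, 0L, "n_consistent"),
                 consistency_fraction = vapply(reps, `[[`, 0,
                                               "consistency_fraction"),
                 verdict = vapply(reps, `[[`, "", "verdict"),
                 stringsAsFactors = FALSE)
    } else data.frame()
  })
  if (nrow(consistency))
    say("verification: %d supported, %d undetermined, %d contradicted",
        sum(consistency$verdict == "supported"),
        sum(consistency$verdict == "undetermined"),
        sum(consistency$verdict == "contradicted"))

  amplicons <- .stage("pcr", say, {
    rows <- list()
    for (nm in names(inputs$primers)) {
      tpl <- clones[clones$id == nm, , drop = FALSE]
      if (nrow(tpl) == 0) next
      class(tpl) <- c("seq_set", "data.frame")
      amp <- insilico_pcr(tpl, inputs$primers[[nm]])
      if (nrow(amp)) rows[[length(rows) + 1L]] <- amp
    }
    do.call(rbind, c(rows, list(data.frame(
      template_id = character(), start = integer(), end = integer(),
      length = integer(), strand = character(), stringsAsFactors = FALSE))))
  })
  if (length(inputs$primers))
    say("in-silico PCR: %d amplicon(s) from %d primer pair(s)",
        nrow(amplicons), length(inputs$primers))

  funnel <- .stage("funnel", say,
                   build_funnel(clones, p1, cl$report, p2, cset,
                                assignments, direct))
  say(paste(utils::capture.output(print(funnel)), collapse = "\n"))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- structure(list(funnel = funnel, p1 = p1, clean = cl, p2 = p2,
                        cset = cset, assignments = assignments,
                        direct = direct, profile = profile,
                        clone_calls = clone_calls, candidates = cands,
                        consistency = consistency, amplicons = amplicons,
                        inputs = inputs, config_hash = hash, log = logs),
                   class = "pipeline_result")
  if (!is.null(outdir)) .write_results(res, outdir)
  res
}

.write_results <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  f <- res$funnel
  wt(data.frame(stage = names(unclass(f)),
                count = unlist(unclass(f), use.names = FALSE)),
     "funnel.tsv")
  wt(rbind(res$assignments, res$direct), "assignments.tsv")
  if (!is.null(res$profile))
    wt(data.frame(category = names(res$profile$counts),
                  count = res$profile$counts,
                  fraction = res$profile$fractions), "profile.tsv")
  wt(res$candidates[, setdiff(names(res$candidates), "matched_region_aa")],
     "candidates.tsv")
  wt(res$consistency, "consistency.tsv")
  wt(res$amplicons, "amplicons.tsv")
  wt(res$clone_calls, "clone_annotations.tsv")
  hits1 <- res$p1$hits; hits1$pass <- 1L
  hits2 <- res$p2$hits; hits2$pass <- 2L
  wt(rbind(hits1, hits2)[, c("pass", .alignment_columns[1:11])],
     "pass_hits.tsv")
  writeLines(c(paste0("# config ", res$config_hash), res$log), p("run.log"))
  invisible(outdir)
}
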