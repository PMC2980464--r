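#' Configuration for the synthetic-data generator
#'
#' Defines the conditions the generator emulates: a subtracted cDNA
#' library of short inserts (142 clones, median 396 nt) drawn from a set
#' of reference gene families plus orphans with no homolog, an EST
#' collection of diverged family fragments with a contaminated fraction
#' carrying vector/primer segments and substitution+indel (frameshift)
#' noise, an annotated reference collection with a functional hierarchy,
#' and a keyword-annotated protein collection with enzyme families for
#' the four target activities (O-methylation, dehydrogenation, reduction,
#' hydroxylation).
#'
#' @param seed integer seed; fans out to per-component substreams so
#'   regenerating one component never disturbs another.
#' @param n_families number of reference gene families.
#' @param family_len_range nt length range of family sequences.
#' @param n_clones clones in the library (default 142).
#' @param clone_len_median median clone insert length in nt (default
#'   396; lengths are lognormal around the median).
#' @param orphan_fraction fraction of clones with no homolog anywhere.
#' @param n_ests ESTs in the database.
#' @param est_divergence per-base substitution rate between an EST and
#'   its source family.
#' @param indel_rate per-base probability of a length-1 indel
#'   (frameshift noise).
#' @param contamination_fraction fraction of ESTs carrying a vector or
#'   primer segment.
#' @param clone_contamination_fraction fraction of (non-pathway) clones
#'   carrying a terminal vector segment, as raw reads would.
#' @param junk_fraction fraction of the contaminated ESTs that are
#'   essentially pure vector (rejected, not trimmed, by cleaning).
#' @param est_exact_fraction fraction of ESTs generated near-identical
#'   to their reference (direct-assignment material).
#' @param vector_len length of the synthetic cloning vector.
#' @param n_activities number of target enzyme activities (default 4).
#' @param pathway_clone_count clones that are back-translated enzyme
#'   fragments (default 3).
#' @param proteins_per_activity enzyme family size per activity.
#' @param protein_len enzyme length in amino acids.
#' @param hypothetical_fraction fraction of families annotated only as
#'   hypothetical proteins.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_families = 25,
                       family_len_range = c(700, 900),
                       n_clones = 142,
                       clone_len_median = 396,
                       orphan_fraction = 0.2,
                       n_ests = 300,
                       est_divergence = 0.15,
                       indel_rate = 0.005,
                       contamination_fraction = 0.1,
                       clone_contamination_fraction = 0.1,
                       junk_fraction = 0.1,
                       est_exact_fraction = 0.1,
                       vector_len = 600,
                       n_activities = 4,
                       pathway_clone_count = 3,
                       proteins_per_activity = 4,
                       protein_len = 300,
                       hypothetical_fraction = 0.2) {
  cfg <- as.list(environment())
  rates <- c("orphan_fraction", "est_divergence", "indel_rate",
             "contamination_fraction", "clone_contamination_fraction",
             "junk_fraction", "est_exact_fraction", "hypothetical_fraction")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  for (cnt in c("n_families", "n_clones", "n_ests", "vector_len",
                "n_activities", "proteins_per_activity", "protein_len"))
    if (cfg[[cnt]] <= 0) stop(cnt, " must be positive")
  if (cfg$pathway_clone_count > cfg$n_clones)
    stop("pathway_clone_count exceeds n_clones (infeasible configuration)")
  class(cfg) <- "sim_config"
  cfg
}

.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
.rand_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                              "")[[1]], n,
                                     replace = TRUE), collapse = "")

#' Mutate a sequence with substitutions and length-1 indels
#'
#' Each base independently substitutes with probability `sub_rate`
#' (always to a different base) and suffers a length-1 insertion or
#' deletion with probability `indel_rate` (frameshift noise).
#' Deterministic under the session RNG state, or under `seed` if given.
#'
#' @param seq nucleotide string (or 1-row `seq_set`).
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability.
#' @param seed optional local seed.
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed = NULL) {
  if (inherits(seq, "seq_set")) seq <- seq$residues
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old)); set.seed(seed)
  }
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  if (n == 0) return(seq)
  sub_at <- stats::runif(n) < sub_rate
  if (any(sub_at))
    v[sub_at] <- vapply(v[sub_at], function(b)
      sample(setdiff(bases, b), 1), character(1))
  ind_at <- which(stats::runif(n) < indel_rate)
  if (length(ind_at)) {
    ins <- stats::runif(length(ind_at)) < 0.5
    pieces <- v
    # insertions add a random base after the position; deletions blank it
    pieces[ind_at[ins]] <- paste0(pieces[ind_at[ins]],
                                  sample(bases, sum(ins), replace = TRUE))
    pieces[ind_at[!ins]] <- ""
    v <- pieces
  }
  paste(v, collapse = "")
}

# deterministic back-translation: one fixed codon per amino acid
.codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
               X = "NNN", `*` = "TAA")

.back_translate <- function(pep) {
  paste(.codon_of[strsplit(pep, "")[[1]]], collapse = "")
}

.sub_seed <- function(cfg, k) (cfg$seed %% 100000L) * 20000L + k

#' Generate a complete synthetic input bundle with ground truth
#'
#' Emits every input the pipeline needs -- clone library, EST database,
#' annotated reference collection with hierarchy, keyword-annotated
#' protein collection, contaminant library and primer pairs -- together
#' with the planted truth (clone-family links, contamination calls,
#' enzyme activities, expected amplicon sizes).  Regenerating with the
#' same configuration yields identical data.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_bundle` with elements `clones`,
#'   `est_db`, `ref_db`, `hierarchy`, `protein_db`, `contaminant_lib`,
#'   `primers`, `truth` and `config`.
#' @export
generate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))

  ## contaminant library ----------------------------------------------
  set.seed(.sub_seed(cfg, 1L))
  contaminant_lib <- seq_set(
    c("VEC1", "PRIM1", "PRIM2"),
    c(.rand_nt(cfg$vector_len), .rand_nt(24), .rand_nt(24)),
    description = c("synthetic cloning vector", "synthetic primer",
                    "synthetic primer"))
  # contamination fragments are read from the vector's cloning-site end,
  # so contaminated reads share sequence and can cross-match
  vec_frag <- function(len) substr(contaminant_lib$residues[1], 1, len)

  ## reference families and hierarchy ---------------------------------
  set.seed(.sub_seed(cfg, 2L))
  fam_len <- sample(cfg$family_len_range[1]:cfg$family_len_range[2],
                    cfg$n_families, replace = TRUE)
  fam_ids <- sprintf("FAM%02d", seq_len(cfg$n_families))
  families <- seq_set(fam_ids, vapply(fam_len, .rand_nt, character(1)))
  top_cats <- c("protein synthesis", "metabolism",
                "nucleic acid processes", "cytoskeleton and transport",
                "ubiquitin system", "stress response")
  n_hypo <- round(cfg$hypothetical_fraction * cfg$n_families)
  labels <- character(cfg$n_families)
  paths <- character(cfg$n_families)
  hypo_idx <- if (n_hypo > 0) seq_len(n_hypo) else integer(0)
  for (i in seq_len(cfg$n_families)) {
    if (i %in% hypo_idx) {
      labels[i] <- "hypothetical"; paths[i] <- "hypothetical"
    } else {
      cat_i <- top_cats[((i - n_hypo - 1) %% length(top_cats)) + 1]
      labels[i] <- sprintf("%s protein %02d", cat_i, i)
      paths[i] <- paste(cat_i, labels[i], sep = "/")
    }
  }
  hierarchy <- data.frame(leaf = labels, path = paths,
                          stringsAsFactors = FALSE)
  ref_db <- reference_db(
    seq_set(paste0("REF_", fam_ids), families$residues,
            description = labels),
    function_label = labels, category_path = paths)

  ## protein collection ------------------------------------------------
  set.seed(.sub_seed(cfg, 3L))
  activities <- c("O-methylation", "dehydrogenation", "reduction",
                  "hydroxylation", "sulfation", "acetylation")
  activities <- activities[seq_len(cfg$n_activities)]
  kw_of <- c(`O-methylation` = "methylation",
             dehydrogenation = "dehydrogenation",
             reduction = "reduction", hydroxylation = "hydroxylation",
             sulfation = "sulfation", acetylation = "acetylation")
  prot_rows <- list()
  mutate_aa <- function(pep, rate) {
    v <- strsplit(pep, "")[[1]]
    at <- stats::runif(length(v)) < rate
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    v[at] <- vapply(v[at], function(a) sample(setdiff(aas, a), 1),
                    character(1))
    paste(v, collapse = "")
  }
  for (a in activities) {
    base <- .rand_aa(cfg$protein_len)
    for (k in seq_len(cfg$proteins_per_activity)) {
      lab <- if (k == cfg$proteins_per_activity && k > 2) "" else a
      prot_rows[[length(prot_rows) + 1L]] <- list(
        id = sprintf("ENZ_%s_%d", gsub("[^A-Za-z]", "", a), k),
        residues = if (k == 1) base else mutate_aa(base, 0.10),
        label = lab,
        keywords = if (nzchar(lab)) kw_of[[a]] else "uncharacterized")
    }
  }
  n_bg <- 8L
  bg_labels <- c("protein kinase", "serine protease", "ion channel",
                 "chitin synthase")
  for (k in seq_len(n_bg))
    prot_rows[[length(prot_rows) + 1L]] <- list(
      id = sprintf("BGP_%02d", k), residues = .rand_aa(cfg$protein_len),
      label = bg_labels[((k - 1) %% length(bg_labels)) + 1],
      keywords = "binding; catalysis")
  proteins <- protein_db(
    seq_set(vapply(prot_rows, `[[`, "", "id"),
            vapply(prot_rows, `[[`, "", "residues"), alphabet = "protein"),
    function_label = vapply(prot_rows, `[[`, "", "label"),
    keywords = vapply(prot_rows, `[[`, "", "keywords"))
  protein_truth <- data.frame(
    protein_id = proteins$id,
    activity = vapply(prot_rows, `[[`, "", "label"),
    stringsAsFactors = FALSE)

  ## clone library -----------------------------------------------------
  set.seed(.sub_seed(cfg, 4L))
  n_orphan <- round(cfg$orphan_fraction * cfg$n_clones)
  n_pathway <- cfg$pathway_clone_count
  n_fam_clones <- cfg$n_clones - n_orphan - n_pathway
  if (n_fam_clones < 0) stop("orphan_fraction and pathway_clone_count ",
                             "leave no family clones")
  lens <- pmax(150L, round(stats::rlnorm(cfg$n_clones,
                                         log(cfg$clone_len_median), 0.25)))
  clone_ids <- sprintf("WD%03d", seq_len(cfg$n_clones))
  types <- c(rep("family", n_fam_clones), rep("orphan", n_orphan),
             rep("pathway", n_pathway))
  clone_fam <- rep(NA_character_, cfg$n_clones)
  clone_act <- rep(NA_character_, cfg$n_clones)
  clone_enzyme <- rep(NA_character_, cfg$n_clones)
  residues <- character(cfg$n_clones)
  for (i in seq_len(cfg$n_clones)) {
    len <- lens[i]
    if (types[i] == "family") {
      fi <- ((i - 1) %% cfg$n_families) + 1      # cycle: cover all families
      fam <- families$residues[fi]
      len <- min(len, nchar(fam))
      s <- sample(nchar(fam) - len + 1L, 1)
      residues[i] <- substr(fam, s, s + len - 1L)
      clone_fam[i] <- fam_ids[fi]
    } else if (types[i] == "orphan") {
      residues[i] <- .rand_nt(len)
    } else {
      ai <- ((i - n_fam_clones - n_orphan - 1) %% cfg$n_activities) + 1
      enz <- proteins$residues[proteins$id ==
        sprintf("ENZ_%s_1", gsub("[^A-Za-z]", "", activities[ai]))]
      aa_len <- min(len %/% 3L, nchar(enz))
      s <- sample(nchar(enz) - aa_len + 1L, 1)
      residues[i] <- .back_translate(substr(enz, s, s + aa_len - 1L))
      clone_act[i] <- activities[ai]
      clone_enzyme[i] <- sprintf("ENZ_%s_1",
                                 gsub("[^A-Za-z]", "", activities[ai]))
    }
  }
  # raw-read vector carry-over on some non-pathway clones
  contam_clone <- rep(FALSE, cfg$n_clones)
  eligible <- which(types != "pathway")
  n_cc <- round(cfg$clone_contamination_fraction * length(eligible))
  if (n_cc > 0) {
    picked <- sample(eligible, n_cc)
    for (i in picked) {
      frag <- vec_frag(sample(30:60, 1))
      residues[i] <- if (stats::runif(1) < 0.5)
        paste0(frag, residues[i]) else paste0(residues[i], frag)
      contam_clone[i] <- TRUE
    }
  }
  clones <- seq_set(clone_ids, residues,
                    description = paste0("type=", types))

  ## EST database ------------------------------------------------------
  set.seed(.sub_seed(cfg, 5L))
  est_ids <- sprintf("EST%04d", seq_len(cfg$n_ests))
  est_fam <- fam_ids[((seq_len(cfg$n_ests) - 1) %% cfg$n_families) + 1]
  n_exact <- round(cfg$est_exact_fraction * cfg$n_ests)
  exactish <- seq_len(cfg$n_ests) %in%
    sample(cfg$n_ests, n_exact)
  est_res <- character(cfg$n_ests)
  for (i in seq_len(cfg$n_ests)) {
    fam <- families$residues[match(est_fam[i], fam_ids)]
    len <- round(0.85 * nchar(fam))
    s <- sample(nchar(fam) - len + 1L, 1)
    frag <- substr(fam, s, s + len - 1L)
    est_res[i] <- if (exactish[i])
      mutate_sequence(frag, 0.01, 0)
    else
      mutate_sequence(frag, cfg$est_divergence, cfg$indel_rate)
  }
  n_contam <- round(cfg$contamination_fraction * cfg$n_ests)
  contam_ids <- if (n_contam > 0) sample(cfg$n_ests, n_contam) else integer(0)
  junk <- rep(FALSE, cfg$n_ests)
  for (i in contam_ids) {
    if (stats::runif(1) < cfg$junk_fraction) {
      est_res[i] <- vec_frag(sample(250:450, 1))   # essentially pure vector
      est_fam[i] <- NA_character_
      junk[i] <- TRUE
    } else {
      frag <- vec_frag(sample(30:80, 1))
      est_res[i] <- if (stats::runif(1) < 0.5)
        paste0(frag, est_res[i]) else paste0(est_res[i], frag)
    }
  }
  est_db <- seq_set(est_ids, est_res)

  ## primer pairs for the pathway clones -------------------------------
  set.seed(.sub_seed(cfg, 6L))
  primer_rows <- list(); primers <- list()
  for (i in which(types == "pathway")) {
    tmpl <- residues[i]
    prod <- min(nchar(tmpl), sample(160:235, 1))
    fwd <- substr(tmpl, 1, 27)
    rev <- reverse_complement(substr(tmpl, prod - 25, prod))
    primers[[clone_ids[i]]] <- primer_pair(clone_ids[i], fwd, rev)
    primer_rows[[length(primer_rows) + 1L]] <-
      data.frame(name = clone_ids[i], forward = fwd, reverse = rev,
                 expected_length = prod, stringsAsFactors = FALSE)
  }

  truth <- list(
    clone_to_family = data.frame(clone_id = clone_ids, family_id = clone_fam,
                                 type = types, contaminated = contam_clone,
                                 stringsAsFactors = FALSE),
    est_to_family = data.frame(est_id = est_ids, family_id = est_fam,
                               contaminated = seq_len(cfg$n_ests) %in%
                                 contam_ids,
                               junk = junk, exactish = exactish,
                               stringsAsFactors = FALSE),
    contaminated_est_ids = est_ids[sort(contam_ids)],
    protein_to_activity = protein_truth,
    pathway_clones = data.frame(
      clone_id = clone_ids[types == "pathway"],
      activity = clone_act[types == "pathway"],
      enzyme_id = clone_enzyme[types == "pathway"],
      stringsAsFactors = FALSE),
    family_label = stats::setNames(labels, fam_ids),
    primer_truth = do.call(rbind, c(primer_rows, list(
      data.frame(name = character(), forward = character(),
                 reverse = character(), expected_length = integer(),
                 stringsAsFactors = FALSE)))))

  structure(list(clones = clones, est_db = est_db, ref_db = ref_db,
                 hierarchy = hierarchy, protein_db = proteins,
                 contaminant_lib = contaminant_lib, primers = primers,
                 truth = truth, config = cfg),
            class = "sim_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits FASTA files for the sequence sets, TSVs for annotations,
#' hierarchy, primers and ground truth.  Regenerating from the same
#' configuration reproduces the files byte-for-byte.
#'
#' @param bundle a [generate_bundle()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(bundle$clones, p("clones.fasta"))
  write_fasta(bundle$est_db, p("ests.fasta"))
  write_fasta(as_seq_set(bundle$ref_db), p("refs.fasta"))
  write_fasta(as_seq_set(bundle$protein_db, "protein"), p("proteins.fasta"))
  write_fasta(bundle$contaminant_lib, p("vectors.fasta"))
  write_hierarchy(bundle$hierarchy, p("hierarchy.tsv"))
  utils::write.table(
    data.frame(id = bundle$ref_db$id,
               function_label = bundle$ref_db$function_label,
               category_path = bundle$ref_db$category_path),
    p("ref_annotations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = bundle$protein_db$id,
               function_label = bundle$protein_db$function_label,
               keywords = vapply(bundle$protein_db$keywords,
                                 paste, "", collapse = ";")),
    p("protein_annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(bundle$truth$primer_truth[, c("name", "forward",
                                                   "reverse")],
                     p("primers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in c("clone_to_family", "est_to_family", "protein_to_activity",
               "pathway_clones"))
    utils::write.table(bundle$truth[[nm]],
                       p(paste0("truth_", nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
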