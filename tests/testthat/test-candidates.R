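toy_proteins <- function() {
  protein_db(
    seq_set(c("P_dehyd", "P_meth", "P_both", "P_bg"),
            c(rand_aa(120), rand_aa(120), rand_aa(120), rand_aa(120)),
            alphabet = "protein"),
    function_label = c("dehydrogenation", "O-methylation", "bifunctional",
                       "kinase"),
    keywords = c("dehydrogenation;oxidoreductase",
                 "Methylation;transferase",
                 "methylation;reduction", "phosphorylation"))
}

test_that("keyword extraction is case-insensitive whole-word, any/all modes", {
  set.seed(61)
  db <- toy_proteins()
  expect_equal(extract_by_keyword(db, "dehydrogenation")$id, "P_dehyd")
  expect_setequal(extract_by_keyword(db, "Dehydrogenation")$id, "P_dehyd")
  expect_setequal(extract_by_keyword(db, c("methylation"))$id,
                  c("P_meth", "P_both"))
  expect_equal(extract_by_keyword(db, c("methylation", "reduction"),
                                  mode = "all")$id, "P_both")
  expect_equal(nrow(extract_by_keyword(db, "sulfation")), 0L)
  # substrings are not whole words
  expect_equal(nrow(extract_by_keyword(db, "methyl")), 0L)
  expect_error(extract_by_keyword(db, character(0)), "non-empty")
})

test_that("back-translated enzyme fragments surface as candidates", {
  set.seed(62)
  db <- toy_proteins()
  frag <- substr(db$residues[db$id == "P_dehyd"], 21, 130)
  clones <- seq_set(c("WD_path", "WD_rand"),
                    c(estbridge:::.back_translate(frag), rand_nt(330)))
  cands <- match_candidates(db, clones)
  expect_true(all(cands$clone_id == "WD_path"))
  hit <- cands[cands$protein_id == "P_dehyd", ]
  expect_equal(hit$target_activity, "dehydrogenation")
  expect_equal(nchar(hit$matched_region_aa),
               hit$q_end - hit$q_start + 1)
  # the stored region re-aligned to the clone reproduces the stored score
  re <- protein_vs_translated_search(
    seq_set("region", hit$matched_region_aa, alphabet = "protein"),
    seq_set("WD_path", clones$residues[1]), e_threshold = 1)
  expect_equal(re$score, hit$score)
})

test_that("a clone spanning two enzyme domains is called for both activities", {
  set.seed(63)
  db <- toy_proteins()
  fragA <- substr(db$residues[db$id == "P_dehyd"], 1, 60)
  fragB <- substr(db$residues[db$id == "P_meth"], 1, 60)
  dual <- seq_set("WD_dual", paste0(estbridge:::.back_translate(fragA),
                                    estbridge:::.back_translate(fragB)))
  cands <- match_candidates(db, dual)
  expect_setequal(
    unique(cands$target_activity[cands$clone_id == "WD_dual"]),
    c("dehydrogenation", "O-methylation"))
})

test_that("reciprocal verification classifies supported/undetermined/contradicted", {
  set.seed(64)
  base <- rand_aa(150)
  mut <- function(rate) {
    v <- strsplit(base, "")[[1]]
    at <- runif(length(v)) < rate
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    v[at] <- vapply(v[at], function(a) sample(setdiff(aas, a), 1), "")
    paste(v, collapse = "")
  }
  # 7 same-label and 3 other-label relatives, all alignable to the region
  fam <- protein_db(
    seq_set(c("SRC", sprintf("REL%d", 1:10)),
            c(base, vapply(rep(0.1, 10), mut, "")), alphabet = "protein"),
    function_label = c("reduction", rep("reduction", 7), rep("kinase", 3)),
    keywords = rep("reduction", 11))
  cand <- data.frame(clone_id = "WD1", protein_id = "SRC",
                     target_activity = "reduction", q_start = 1L,
                     q_end = 150L, s_frame = 1L, score = 700L,
                     evalue = 1e-30, identity_pct = 100,
                     matched_region_aa = base, stringsAsFactors = FALSE)
  rep10 <- reciprocal_verify(cand, fam, top_n = 10)
  expect_equal(rep10$n_hits, 10L)
  expect_equal(rep10$consistency_fraction, 0.7)
  expect_equal(rep10$verdict, "contradicted")
  # only the consistent relatives: fully supported
  consistent <- fam[fam$function_label != "kinase", ]
  class(consistent) <- class(fam)
  expect_equal(reciprocal_verify(cand, consistent, top_n = 10)$verdict,
               "supported")
  # nothing alignable: undetermined
  lonely <- protein_db(seq_set("X", rand_aa(150), alphabet = "protein"),
                       "kinase", "phosphorylation")
  cand2 <- cand; cand2$protein_id <- "Y"
  expect_equal(reciprocal_verify(cand2, lonely)$verdict, "undetermined")
  # regions under 20 aa cannot be verified
  tiny <- cand; tiny$matched_region_aa <- substr(base, 1, 15)
  expect_warning(out <- reciprocal_verify(tiny, fam), "20 aa")
  expect_equal(out$verdict, "undetermined")
})

test_that("in-silico PCR predicts the constructed amplicon on both strands", {
  set.seed(65)
  fwd <- "GGGGGTAATAATTCTAGCGCGCCTACC"              # 27 nt
  rev <- "CCGTCACCAGCAAGGAATA AACAACG"              # typeset space inside
  pp <- primer_pair("WD008", paste0("5'-", fwd, "-3'"), rev)
  expect_equal(nchar(pp$reverse), 26L)               # whitespace stripped
  tmpl <- paste0(fwd, rand_nt(110), reverse_complement(pp$reverse))
  amp <- insilico_pcr(seq_set("T", tmpl), pp)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 27L + 110L + 26L)         # 163 nt
  expect_equal(amp$strand, "+")
  # same template reverse-complemented: same length, minus strand
  amp_rc <- insilico_pcr(seq_set("Trc", reverse_complement(tmpl)), pp)
  expect_equal(amp_rc$length, amp$length)
  expect_equal(amp_rc$strand, "-")
  # primers absent: empty result
  expect_equal(nrow(insilico_pcr(seq_set("R", rand_nt(400)), pp)), 0L)
  # a mismatch in the 3' clamp kills the site; one outside is tolerated
  bad <- tmpl
  substr(bad, 26, 26) <- "A"                         # clamp position of fwd
  expect_equal(nrow(insilico_pcr(seq_set("B", bad), pp)), 0L)
  tol <- tmpl
  substr(tol, 3, 3) <- if (substr(tol, 3, 3) == "A") "C" else "A"
  pp1 <- primer_pair("WD008", fwd, rev, max_mismatch = 1)
  expect_equal(insilico_pcr(seq_set("M", tol), pp1)$length, 163L)
  expect_error(primer_pair("x", "ACGTACGTACGT", rev), "15 nt")
})
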