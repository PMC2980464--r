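test_that("scoring scheme invariants are enforced", {
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_extend")
  expect_error(scoring_scheme(karlin_lambda = 0), "positive")
  s <- nucleotide_scheme()
  expect_true(s$karlin_lambda > 0 && s$karlin_K > 0)
})

test_that("self-alignment and disjoint-alphabet cases behave as defined", {
  al <- smith_waterman("ACGTACGT", "ACGTACGT", nucleotide_scheme())
  expect_equal(al$score, 16L)          # 8 matches at +2, no gaps
  expect_equal(al$identity_pct, 100)
  expect_equal(c(al$q_start, al$q_end), c(1L, 8L))
  none <- smith_waterman("AAAA", "GGGG", nucleotide_scheme())
  expect_equal(nrow(none), 0L)         # no positive-scoring cell
  expect_error(
    smith_waterman(seq_set("p", "MKLV", alphabet = "protein"), "ACGT",
                   nucleotide_scheme()),
    "alphabet")
})

test_that("engine scores equal the naive DP oracle on random pairs", {
  set.seed(21)
  nts <- nucleotide_scheme()
  nt_fun <- function(x, y) if (x == y) 2 else -3
  for (i in 1:30) {
    a <- rand_nt(sample(5:40, 1)); b <- rand_nt(sample(5:40, 1))
    expect_equal(pkg_score(a, b, nts), sw_oracle(a, b, nt_fun, 5, 2))
  }
  ps <- protein_scheme()
  mat <- estbridge:::.protein_matrix("BLOSUM62")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]
  for (i in 1:30) {
    a <- paste(sample(aas, sample(5:35, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:35, 1), TRUE), collapse = "")
    expect_equal(pkg_score(a, b, ps),
                 sw_oracle(a, b, function(x, y) mat[x, y], 11, 1))
  }
})

test_that("E-value follows the Karlin-Altschul closed form", {
  sch <- scoring_scheme(karlin_lambda = 1.37, karlin_K = 0.711)
  expect_equal(evalue(10, 100, 100, sch), 0.711 * 1e4 * exp(-13.7))
  expect_equal(evalue(10, 100, 200, sch), 2 * evalue(10, 100, 100, sch))
  expect_lt(evalue(11, 100, 100, sch), evalue(10, 100, 100, sch))
  expect_error(evalue(0, 100, 100, sch), "positive")
  expect_error(evalue(10, 0, 100, sch), "positive")
})

test_that("database search ranks a planted homolog first and respects thresholds", {
  set.seed(22)
  fam <- rand_nt(300)
  homolog <- mutate_sequence(fam, 0.2, 0)    # ~80% identity
  db <- seq_set(c(sprintf("D%03d", 1:100), "HOM"),
                c(vapply(rep(300, 100), rand_nt, ""), homolog))
  hits <- search_db(seq_set("q", fam), db, nucleotide_scheme(), 1e-2)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$subject_id[1], "HOM")    # top by score
  # an exact copy in the db always ranks first
  db2 <- seq_set(c("COPY", "R1", "R2"),
                 c(fam, rand_nt(300), rand_nt(300)))
  h2 <- search_db(seq_set("q", fam), db2, nucleotide_scheme(), 1e-2)
  expect_equal(h2$subject_id[1], "COPY")
  # empty database: no hits, not an error
  expect_equal(nrow(search_db(seq_set("q", fam), db[0, ],
                              nucleotide_scheme())), 0L)
  # hit sets grow monotonically with the threshold
  h_lo <- search_db(seq_set("q", fam), db, nucleotide_scheme(), 1e-6)
  h_hi <- search_db(seq_set("q", fam), db, nucleotide_scheme(), 1e-1)
  expect_true(all(h_lo$subject_id %in% h_hi$subject_id))
})

test_that("translated 6x6 search finds the best frame pair and is symmetric", {
  set.seed(23)
  cds <- rand_nt(120)
  self <- translated_search(seq_set("q", cds), seq_set("s", cds))
  peps <- six_frame_translate(cds)$peptide
  self_scores <- vapply(peps, function(p) {
    if (!nzchar(p)) return(0L)
    pkg_score(p, p, protein_scheme())
  }, integer(1))
  expect_equal(self$score, max(self_scores))
  expect_equal(self$q_frame, self$s_frame)
  a <- rand_nt(150); b <- rand_nt(150)
  expect_equal(translated_search(seq_set("a", a), seq_set("b", b))$score,
               translated_search(seq_set("b", b), seq_set("a", a))$score)
})

test_that("a single inserted base moves the alignment to a shifted frame pair", {
  set.seed(24)
  gene <- rand_nt(240)
  partner <- mutate_sequence(gene, 0.1, 0)
  clean_score <- translated_search(seq_set("g", gene),
                                   seq_set("p", partner))$score
  pos <- 120
  shifted <- paste0(substr(partner, 1, pos), "A",
                    substr(partner, pos + 1, nchar(partner)))
  sh <- translated_search(seq_set("g", gene), seq_set("p", shifted))
  expect_gte(sh$score, 0.4 * clean_score)
})

test_that("protein vs translated search recovers an embedded coding segment", {
  set.seed(25)
  prot <- rand_aa(60)
  embedded <- estbridge:::.back_translate(prot)
  clone <- paste0(rand_nt(30), embedded, rand_nt(33))
  db <- seq_set(c("C1", "C2"), c(clone, rand_nt(240)))
  hits <- protein_vs_translated_search(
    seq_set("P", prot, alphabet = "protein"), db)
  expect_equal(hits$subject_id, "C1")
  expect_equal(hits$identity_pct, 100)
  expect_equal(c(hits$q_start, hits$q_end), c(1L, 60L))
  # subject coordinates (aa on frame +1, since the prefix is 30 nt) map
  # inside the embedded segment
  expect_equal(hits$s_frame, 1L)
  nt_start <- 3 * (hits$s_start - 1) + 1
  nt_end <- 3 * hits$s_end
  expect_gte(nt_start, 31)
  expect_lte(nt_end, 30 + nchar(embedded))
  # a scrambled protein finds nothing at the significance threshold
  scram <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
  expect_equal(nrow(protein_vs_translated_search(
    seq_set("S", scram, alphabet = "protein"),
    seq_set("C2", rand_nt(240)), e_threshold = 1e-2)), 0L)
})

test_that("empirical calibration recovers parameters of the right magnitude", {
  est <- calibrate_scheme(nucleotide_scheme(), n_pairs = 300, m = 80,
                          n = 120, seed = 5)
  expect_gt(est["lambda"], 0.3)
  expect_lt(est["lambda"], 1.0)
  expect_gt(est["K"], 0.01)
})
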