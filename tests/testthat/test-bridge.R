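# compact constructor for hand-built pass results
fake_pass <- function(pass_id, pairs) {
  hits <- estbridge:::.empty_alignment()
  if (length(pairs)) {
    parts <- strsplit(pairs, ":", fixed = TRUE)
    for (p in parts) {
      row <- estbridge:::.empty_alignment()[0, ]
      hits <- rbind(hits, data.frame(
        query_id = p[1], subject_id = p[2], q_start = 1L, q_end = 10L,
        s_start = 1L, s_end = 10L, q_frame = 0L, s_frame = 0L,
        score = 20L, evalue = 1e-4, identity_pct = 100,
        aligned_query = "A", aligned_subject = "A",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(pass_id = as.integer(pass_id), hits = hits,
                 e_threshold = 1e-2, mode = "nucleotide"),
            class = "pass_result")
}

test_that("consensus intersects pairs and honours pair vs clone semantics", {
  p1 <- fake_pass(1, c("c1:e1", "c1:e2", "c2:e3"))
  p2 <- fake_pass(2, c("c1:e1", "c2:e4"))
  cs <- consensus(p1, p2, "pair")
  expect_equal(cs$pairs,
               data.frame(clone_id = "c1", est_id = "e1",
                          stringsAsFactors = FALSE))
  # clone mode keeps every pass-2 pair whose clone matched in pass 1
  cc <- consensus(p1, p2, "clone")
  expect_setequal(paste(cc$pairs$clone_id, cc$pairs$est_id),
                  c("c1 e1", "c2 e4"))
  # identical passes: consensus equals either pass
  same <- consensus(p1, fake_pass(2, c("c1:e1", "c1:e2", "c2:e3")), "pair")
  expect_equal(nrow(same$pairs), 3L)
  expect_error(consensus(p2, p1), "pass 1 and pass 2")
})

test_that("run_pass finds planted homologs, skips orphans, grows with threshold", {
  set.seed(41)
  fam <- rand_nt(500)
  clones <- seq_set(c("cl_fam", "cl_orphan"),
                    c(substr(fam, 50, 420), rand_nt(370)))
  ests <- seq_set(c("est_fam", "est_rand"),
                  c(mutate_sequence(substr(fam, 1, 480), 0.1, 0.003),
                    rand_nt(480)))
  p <- run_pass(clones, ests, pass_id = 1)
  expect_true("cl_fam" %in% p$hits$query_id)
  expect_false("cl_orphan" %in% p$hits$query_id)
  expect_true(all(p$hits$evalue <= 1e-2))
  p_tight <- run_pass(clones, ests, e_threshold = 1e-8)
  expect_lte(nrow(p_tight$hits), nrow(p$hits))
  expect_error(run_pass(clones[0, ], ests), "empty")
})

test_that("an EST matched only through vector is lost after cleaning", {
  set.seed(42)
  vec <- rand_nt(300)
  lib <- seq_set("VEC", vec)
  # clone carries a vector tail; the 'EST' shares only that vector stretch
  clone <- seq_set("cl", paste0(rand_nt(350), substr(vec, 1, 45)))
  est <- seq_set("bad_est", paste0(substr(vec, 1, 260), rand_nt(60)))
  p1 <- run_pass(clone, est, pass_id = 1)
  expect_true("bad_est" %in% p1$hits$subject_id)   # spurious pass-1 match
  cl <- clean_database(est, lib)
  expect_equal(cl$report$n_rejected, 1L)           # mostly vector: rejected
  p2 <- run_pass(clone, cl$validated, pass_id = 2)
  cs <- consensus(p1, p2)
  expect_equal(nrow(cs$pairs), 0L)
})

test_that("funnel counts are internally consistent and provenance is checked", {
  set.seed(43)
  fam <- rand_nt(600)
  clones <- seq_set(c("c1", "c2", "c3"),
                    c(substr(fam, 1, 400), substr(fam, 150, 550),
                      rand_nt(400)))
  ests <- seq_set(c("e1", "e2"),
                  c(mutate_sequence(substr(fam, 1, 500), 0.08, 0),
                    rand_nt(500)))
  lib <- seq_set("VEC", rand_nt(300))
  p1 <- run_pass(clones, ests, pass_id = 1)
  matched <- ests[ests$id %in% p1$hits$subject_id, ]
  class(matched) <- c("seq_set", "data.frame")
  cl <- clean_database(matched, lib)
  p2 <- run_pass(clones, cl$validated, pass_id = 2)
  cs <- consensus(p1, p2)
  f <- build_funnel(clones, p1, cl$report, p2, cs)
  expect_equal(f$n_clones, 3L)
  expect_lte(f$n_clones_consensus, f$n_clones_matched_p1)
  expect_lte(f$n_ests_validated, f$n_ests_matched_p1)
  expect_lte(f$n_ests_consensus, f$n_ests_validated)
  # no contamination: validated count equals matched count
  expect_equal(f$n_ests_validated, f$n_ests_matched_p1)
  # a clean report over a different input set is inconsistent provenance
  other <- clean_database(ests, lib)
  expect_error(build_funnel(clones, p1, other$report, p2, cs),
               "provenance")
})

test_that("an all-orphan library yields an all-zero downstream funnel", {
  set.seed(44)
  clones <- seq_set(sprintf("o%d", 1:4), vapply(rep(380, 4), rand_nt, ""))
  ests <- seq_set(sprintf("e%d", 1:6), vapply(rep(500, 6), rand_nt, ""))
  p1 <- run_pass(clones, ests, pass_id = 1)
  expect_equal(nrow(p1$hits), 0L)
  matched <- ests[0, ]
  class(matched) <- c("seq_set", "data.frame")
  cl <- clean_database(matched, seq_set("VEC", rand_nt(300)))
  p2 <- run_pass(clones, cl$validated, pass_id = 2)
  f <- build_funnel(clones, p1, cl$report, p2, consensus(p1, p2))
  expect_equal(f$n_clones_matched_p1, 0L)
  expect_equal(f$n_ests_consensus, 0L)
})
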