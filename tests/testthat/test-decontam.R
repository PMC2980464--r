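test_that("terminal and whole-sequence contamination are located exactly", {
  set.seed(31)
  lib <- seq_set("VEC", rand_nt(300))
  insert <- rand_nt(370)
  contaminated <- paste0(insert, substr(lib$residues, 1, 30))
  reg <- screen_contaminants(seq_set("c", contaminated), lib)
  expect_equal(nrow(reg), 1L)
  expect_true(reg$terminal)
  expect_equal(c(reg$start, reg$end), c(371L, 400L))
  # vector-free sequence: nothing reported
  expect_equal(nrow(screen_contaminants(seq_set("c", insert), lib)), 0L)
  # a sequence equal to a vector record is one full-length region
  self <- screen_contaminants(seq_set("v", lib$residues), lib)
  expect_equal(nrow(self), 1L)
  expect_equal(c(self$start, self$end), c(1L, 300L))
  expect_error(screen_contaminants(seq_set("c", insert), lib[0, ]), "empty")
})

test_that("trimming removes terminal masks and keeps the longest clean fragment", {
  set.seed(32)
  s <- seq_set("s", rand_nt(400))
  term <- data.frame(seq_id = "s", start = 371L, end = 400L,
                     source_id = "VEC", score = 30L, terminal = TRUE)
  tr <- trim_sequence(s, term)
  expect_equal(nchar(tr$residues), 370L)
  expect_equal(attr(tr, "kept_range"), c(1L, 370L))
  # internal mask splitting into 250 + 90: the 250 fragment survives
  internal <- data.frame(seq_id = "s", start = 251L, end = 310L,
                         source_id = "VEC", score = 30L, terminal = FALSE)
  tr2 <- trim_sequence(s, internal, min_len = 100)
  expect_equal(nchar(tr2$residues), 250L)
  expect_equal(attr(tr2, "kept_range"), c(1L, 250L))
  # whole-sequence mask is a rejection
  whole <- data.frame(seq_id = "s", start = 1L, end = 400L,
                      source_id = "VEC", score = 400L, terminal = TRUE)
  expect_null(trim_sequence(s, whole))
})

test_that("database cleaning matches planted ground truth and conserves counts", {
  set.seed(33)
  lib <- seq_set("VEC", rand_nt(300))
  n <- 20
  res <- vapply(rep(350, n), rand_nt, "")
  dirty <- sort(sample(n, 4))                    # 20% planted contamination
  res[dirty] <- paste0(res[dirty], substr(lib$residues, 1, 40))
  db <- seq_set(sprintf("E%02d", 1:n), res)
  out <- clean_database(db, lib)
  rep <- out$report
  expect_equal(rep$n_input, rep$n_kept + rep$n_rejected)
  expect_equal(rep$dispositions$disposition[dirty], rep("trimmed", 4))
  expect_equal(rep$dispositions$disposition[-dirty], rep("kept", n - 4))
  expect_equal(rep$n_trimmed, 4L)
  # all-clean database passes through unchanged
  clean <- seq_set(sprintf("C%02d", 1:5), vapply(rep(350, 5), rand_nt, ""))
  out2 <- clean_database(clean, lib)
  expect_equal(out2$validated$residues, clean$residues)
  expect_equal(out2$report$n_trimmed, 0L)
  expect_equal(out2$report$n_rejected, 0L)
})

test_that("cleaning is idempotent and leaves no internal-threshold match", {
  set.seed(34)
  lib <- seq_set(c("VEC", "PRIM"), c(rand_nt(300), rand_nt(24)))
  res <- vapply(rep(380, 12), rand_nt, "")
  res[1:3] <- paste0(substr(lib$residues[1], 1, 50), res[1:3])
  res[4] <- substr(lib$residues[1], 1, 320)      # essentially pure vector
  db <- seq_set(sprintf("E%02d", 1:12), res)
  once <- clean_database(db, lib)
  twice <- clean_database(once$validated, lib)
  expect_equal(twice$validated$residues, once$validated$residues)
  expect_equal(twice$report$n_trimmed, 0L)
  expect_equal(twice$report$n_rejected, 0L)
  th <- decontam_thresholds()
  for (i in seq_len(nrow(once$validated))) {
    r <- once$validated[i, , drop = FALSE]
    class(r) <- c("seq_set", "data.frame")
    reg <- screen_contaminants(r, lib, th)
    expect_false(any(reg$score >= th$internal_score))
  }
})
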