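make_refs <- function(ids, seqs, labels) {
  reference_db(seq_set(ids, seqs), labels,
               ifelse(labels == "hypothetical", "hypothetical",
                      paste0("cat/", labels)))
}

test_that("best-hit transfer assigns the top reference and breaks ties by id", {
  set.seed(51)
  gene <- rand_nt(450)
  refs <- make_refs(c("R_home", "R_other"), c(gene, rand_nt(450)),
                    c("kinase", "channel"))
  asn <- transfer_annotations(seq_set("est1", gene), refs)
  expect_equal(nrow(asn), 1L)
  expect_equal(asn$function_label, "kinase")
  expect_equal(asn$method, "besthit")
  # two references with identical sequence tie exactly; smaller id wins
  twins <- make_refs(c("R_b", "R_a"), c(gene, gene), c("late", "early"))
  tie <- transfer_annotations(seq_set("est1", gene), twins)
  expect_equal(tie$subject_id, "R_a")
  expect_equal(tie$function_label, "early")
  # losing qualifying hits are kept for audit
  expect_gte(nrow(attr(tie, "discarded")), 1L)
})

test_that("ESTs without a qualifying hit are reported unassigned", {
  set.seed(52)
  refs <- make_refs("R1", rand_nt(450), "kinase")
  asn <- transfer_annotations(seq_set("lonely", rand_nt(400)), refs,
                              e_threshold = 1e-2)
  expect_equal(nrow(asn), 0L)
  expect_equal(attr(asn, "unassigned"), "lonely")
  # empty reference collection: everything unassigned, not an error
  asn2 <- transfer_annotations(seq_set("x", rand_nt(400)), refs[0, ])
  expect_equal(attr(asn2, "unassigned"), "x")
})

test_that("direct assignment requires near-exact identity and coverage", {
  set.seed(53)
  gene <- rand_nt(500)
  refs <- make_refs("KO1", gene, "ribosomal protein")
  est_exact <- seq_set("e_exact", substr(gene, 1, 420))
  expect_equal(exact_match_assign(est_exact, refs)$method, "exact")
  # ~90% identity fails the 95% bar
  est_div <- seq_set("e_div", mutate_sequence(substr(gene, 1, 420), 0.1, 0))
  expect_equal(nrow(exact_match_assign(est_div, refs)), 0L)
  expect_equal(nrow(exact_match_assign(est_div, refs, identity_min = 80)), 1L)
  # exactly the k planted near-exact copies qualify
  ests <- seq_set(sprintf("e%d", 1:6),
                  c(vapply(1:3, function(i)
                      mutate_sequence(substr(gene, 1, 420), 0.01, 0), ""),
                    vapply(rep(420, 3), rand_nt, "")))
  got <- exact_match_assign(ests, refs)
  expect_setequal(got$est_id, c("e1", "e2", "e3"))
})

test_that("category rollup computes the printed fractions", {
  paths <- c(rep("hypothetical", 33),
             rep("genetic information processing/protein synthesis", 50),
             rep("metabolism/lipid metabolism", 48))
  labels <- c(rep("hypothetical", 33), rep("ribosomal protein", 50),
              rep("lipase", 48))
  asn <- data.frame(est_id = sprintf("e%03d", 1:131),
                    subject_id = "r", function_label = labels,
                    category_path = paths, score = 10L, evalue = 1e-3,
                    method = "besthit", stringsAsFactors = FALSE)
  prof <- rollup(asn, hierarchy_level = 1)
  expect_equal(prof$n_total, 131L)
  expect_equal(prof$fractions[["hypothetical"]], 33 / 131)
  expect_equal(sum(prof$fractions), 1)
  # deeper level splits on the second path component
  prof2 <- rollup(asn, hierarchy_level = 2)
  expect_true("metabolism/lipid metabolism" %in% names(prof2$counts))
  # order of assignments is irrelevant
  prof3 <- rollup(asn[sample(nrow(asn)), ], hierarchy_level = 1)
  expect_equal(prof3$counts[names(prof$counts)], prof$counts)
  # two categories of two: fractions 0.5 / 0.5
  half <- rollup(asn[c(1, 2, 40, 41), ], hierarchy_level = 1)
  expect_equal(unname(half$fractions), c(0.5, 0.5))
  expect_error(rollup(asn[0, ]), "empty")
})

test_that("function recovery on diverged family fragments stays above 90%", {
  set.seed(54)
  n_fam <- 5
  fams <- vapply(rep(750, n_fam), rand_nt, "")
  labels <- sprintf("family %d protein", 1:n_fam)
  refs <- make_refs(sprintf("R%d", 1:n_fam), fams, labels)
  n_est <- 30
  fam_of <- rep(1:n_fam, length.out = n_est)
  ests <- seq_set(sprintf("e%02d", 1:n_est), vapply(seq_len(n_est),
    function(i) {
      f <- fams[fam_of[i]]
      s <- sample(150, 1)
      mutate_sequence(substr(f, s, s + 590), 0.15, 0.005)
    }, ""))
  asn <- transfer_annotations(ests, refs)
  hit <- match(ests$id, asn$est_id)
  acc <- mean(asn$function_label[hit] == labels[fam_of], na.rm = FALSE)
  expect_gte(acc, 0.9)
})
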