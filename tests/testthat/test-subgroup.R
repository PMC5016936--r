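ltr_aln <- function(ltr_seq) {
  global_align(landmark_slice(fx_model(), "5ltr"), ltr_seq)
}

install_alts <- function(ltr, rows) {
  x <- strsplit(ltr, "")[[1]]
  x[rows$position] <- rows$alt_base
  paste(x, collapse = "")
}

test_that("genotyping the consensus LTR yields zero alt calls", {
  kp <- key_position_table()
  ltr <- landmark_slice(fx_model(), "5ltr")
  g <- genotype_key_positions(ltr_aln(ltr), kp, "5p_full", fx_model())
  expect_true(all(g$observed == g$ref_base))

  g7 <- genotype_key_positions(
    ltr_aln(install_alts(ltr, kp[kp$tier == "main", ])), kp, "5p_full",
    fx_model())
  main <- g7[g7$tier == "main", ]
  expect_equal(sum(main$observed == main$alt_base), 7L)
})

test_that("truncated forms restrict observability as in the LTR trees", {
  kp <- key_position_table()
  ltr <- landmark_slice(fx_model(), "5ltr")
  u3r <- substr(ltr, 1, 326)              # pseudogenic 3' LTR form
  g <- genotype_key_positions(ltr_aln(u3r), kp, "3p_U3R", fx_model())
  main_obs <- g[g$tier == "main" & !is.na(g$observed), "position"]
  expect_setequal(main_obs, c(43L, 95L, 100L, 180L, 254L))  # 5 of 7 maintained
  ru5 <- substr(ltr, 256, 780)            # pseudogenic 5' LTR form
  g2 <- genotype_key_positions(ltr_aln(ru5), kp, "5p_RU5", fx_model())
  main_obs2 <- g2[g2$tier == "main" & !is.na(g2$observed), "position"]
  expect_setequal(main_obs2, c(706L, 765L))
})

test_that("subgroup classification: 1, 2, 2A, 2B, dead zone, errors", {
  kp <- key_position_table()
  ltr <- landmark_slice(fx_model(), "5ltr")
  gref <- genotype_key_positions(ltr_aln(ltr), kp, "5p_full", fx_model())
  expect_equal(classify_subgroup(gref, gref)$label, "1")

  l2 <- install_alts(ltr, kp[kp$tier == "main", ])
  g2 <- genotype_key_positions(ltr_aln(l2), kp, "5p_full", fx_model())
  expect_equal(classify_subgroup(g2, g2)$label, "2")

  l2a <- install_alts(ltr, kp[kp$tier %in% c("main", "2A"), ])
  g2a <- genotype_key_positions(ltr_aln(l2a), kp, "5p_full", fx_model())
  expect_equal(classify_subgroup(g2a, g2a)$label, "2A")

  l2b <- install_alts(ltr, kp[kp$tier %in% c("main", "2B"), ])
  g2b <- genotype_key_positions(ltr_aln(l2b), kp, "5p_full", fx_model())
  expect_equal(classify_subgroup(g2b, g2b)$label, "2B")

  # both refinement tiers satisfied: conflict degrades to plain 2
  lab <- install_alts(ltr, kp)
  gab <- genotype_key_positions(ltr_aln(lab), kp, "5p_full", fx_model())
  expect_equal(classify_subgroup(gab, gab)$label, "2")

  # alt fraction 3/7 = 0.43 sits in the dead zone
  ldz <- install_alts(ltr, kp[kp$tier == "main", ][1:3, ])
  gdz <- genotype_key_positions(ltr_aln(ldz), kp, "5p_full", fx_model())
  expect_equal(classify_subgroup(gdz, NULL)$label, "unclassifiable")

  expect_error(classify_subgroup(NULL, NULL), "both LTRs absent")
})

test_that("a pseudogenic 3' LTR alone still classifies the subgroup", {
  kp <- key_position_table()
  ltr <- landmark_slice(fx_model(), "5ltr")
  l2 <- install_alts(ltr, kp[kp$tier == "main", ])
  u3r <- substr(l2, 1, 326)
  g <- genotype_key_positions(ltr_aln(u3r), kp, "3p_U3R", fx_model())
  call <- classify_subgroup(NULL, g)
  expect_gte(call$n_available, 3L)
  expect_equal(call$label, "2")
})

test_that("consensus building: majority, tie-to-reference, gap rule", {
  expect_error(build_consensus(list("ACGT"), reference = "ACGT"), ">= 2")
  # three identical copies reproduce the sequence
  expect_identical(build_consensus(c(a = "ACGTA", b = "ACGTA", c = "ACGTA"),
                                   reference = "ACGTA"), "ACGTA")
  # column {A,A,G} -> A; tie {A,G} with reference A -> A
  expect_identical(build_consensus(c(a = "A", b = "A", c = "G"),
                                   reference = "C"), "A")
  expect_identical(build_consensus(c(a = "A", b = "G"), reference = "A"), "A")
  # column gapped in > 50 % emits nothing
  expect_identical(build_consensus(c(a = "A-T", b = "A-T", c = "AGT"),
                                   reference = "ACT"), "AT")
})

test_that("subgroup-2 consensus round trip keeps the 7 main alt bases", {
  m <- fx_model()
  kp <- key_position_table()
  ltr <- landmark_slice(m, "5ltr")
  l2 <- install_alts(ltr, kp[kp$tier == "main", ])
  members <- vapply(1:6, function(s) mutate_sequence(l2, 0.06, seed = s), "")
  names(members) <- paste0("m", 1:6)
  cons <- build_consensus(members, reference = ltr)
  expect_equal(nchar(cons), 780L)
  x <- strsplit(cons, "")[[1]]
  main <- kp[kp$tier == "main", ]
  expect_identical(x[main$position], main$alt_base)
})
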