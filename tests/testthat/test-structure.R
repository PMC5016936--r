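test_that("retention: full element all 1.0; recurrent env deletion case", {
  m <- fx_model()
  ret <- compute_retention(fx_ref_self(), m)
  expect_true(all(ret$fraction == 1))
  expect_true(all(ret$retained))

  # env deletion 7928-9114 leaves 442/1629 = 0.271 of env: still retained
  el <- delete_intervals(m$sequence, list(c(7928L, 9114L)))
  aln <- project_to_reference(m, el)
  ret <- compute_retention(aln, m)
  env <- ret[ret$landmark == "env", ]
  expect_equal(env$fraction, 442 / 1629, tolerance = 1e-6)
  expect_true(env$retained)

  # 100 nt of gag (1474 nt) = 0.068: below theta, not retained
  el2 <- delete_intervals(m$sequence, list(c(2718L, 4091L)))
  aln2 <- project_to_reference(m, el2)
  ret2 <- compute_retention(aln2, m)
  gag <- ret2[ret2$landmark == "gag", ]
  expect_equal(gag$fraction, 100 / 1474, tolerance = 1e-6)
  expect_false(gag$retained)

  # theta tie counts as retained
  expect_true(compute_retention(aln, m, theta = 442 / 1629)$retained[4])
})

test_that("retention is monotone under additional deletion", {
  m <- fx_model()
  a1 <- project_to_reference(m, delete_intervals(m$sequence,
                                                 list(c(3000L, 3500L))))
  a2 <- project_to_reference(m, delete_intervals(m$sequence,
                                                 list(c(3000L, 3500L),
                                                      c(8000L, 8800L),
                                                      c(500L, 600L))))
  r1 <- compute_retention(a1, m)$fraction
  r2 <- compute_retention(a2, m)$fraction
  expect_true(all(r2 <= r1 + 1e-12))
})

test_that("indel annotation recovers constructed events", {
  m <- fx_model()
  expect_equal(nrow(annotate_indels(fx_ref_self())), 0L)

  aln <- project_to_reference(m, delete_intervals(m$sequence,
                                                  list(c(2780L, 3209L))))
  ind <- annotate_indels(aln)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$kind, "deletion")
  expect_equal(ind$length, 430L)
  # placement can shift one column when the flanking base ties in score
  expect_lte(abs(ind$ref_start - 2780L), 1L)
  expect_lte(abs(ind$ref_end - 3209L), 1L)

  # a random 50-mer can partially re-align and split; all inserted bases
  # must still be reported as insertions anchored at the junction
  ins <- paste0(substr(m$sequence, 1, 1000), rand_dna(50, 5),
                substr(m$sequence, 1001, m$length))
  ind2 <- annotate_indels(project_to_reference(m, ins))
  ins_rows <- ind2[ind2$kind == "insertion", ]
  expect_gte(nrow(ins_rows), 1L)
  expect_true(all(abs(ins_rows$ref_start - 1000L) <= 10L))
  expect_gte(sum(ins_rows$length), 45L)
  expect_lte(sum(ind2$length), 55L)
})

test_that("retroposition signatures are detected and degrade gracefully", {
  m <- fx_model()
  el <- simulate_element(m, simulation_spec("processed_pseudogene", "1",
                                            age_my = 5, seed = 21))
  sig <- detect_retro_signatures(el$sequence, el$flank5, el$flank3)
  expect_true(sig$polyA)
  expect_identical(sig$tsd, el$truth$tsd)
  expect_true(sig$tt_aaaa)

  # flanks sharing only a 4-mer: below the 5-bp TSD minimum
  f5 <- paste0(rand_dna(40, 6), "GATC")
  f3 <- paste0("GATC", rand_dna(40, 7))
  sig2 <- detect_retro_signatures(rand_dna(300, 8), f5, f3)
  expect_true(is.na(sig2$tsd))

  # empty flanks: undeterminable, not false
  sig3 <- detect_retro_signatures(el$sequence, "", "")
  expect_true(is.na(sig3$tsd))
  expect_true(is.na(sig3$tt_aaaa))
  expect_true(sig3$polyA)               # tail is inside the element
})

test_that("poly(A) detector tolerates a single interruption", {
  s <- paste0(rand_dna(100, 9), "AAAAGAAAAA")
  sig <- detect_retro_signatures(s, "", "")
  expect_true(sig$polyA)
  s2 <- paste0(rand_dna(100, 10), "AAAGTAAAG")
  expect_false(detect_retro_signatures(s2, "", "")$polyA)
})

test_that("classifier: provirus / pseudogene / undefined decision rule", {
  m <- fx_model()
  # simulated provirus and pseudogene, moderate age, recurrent deletions
  prov <- simulate_element(m, simulation_spec("provirus", "2", age_my = 25,
                                              deletions = m$recurrent_deletions[c(2, 4)],
                                              seed = 31))
  ann <- annotate_structure(prov, m)
  expect_equal(ann$label, "provirus")
  expect_equal(ann$ltr5_form, "U3-R-U5")

  pg <- simulate_element(m, simulation_spec("processed_pseudogene", "1",
                                            age_my = 25,
                                            deletions = m$recurrent_deletions[4],
                                            seed = 32))
  ann2 <- annotate_structure(pg, m)
  expect_equal(ann2$label, "processed_pseudogene")
  expect_equal(ann2$ltr5_form, "R-U5")
  expect_equal(ann2$ltr3_form, "U3-R")

  # both LTRs lost, no flank evidence: undefined
  l5 <- m$landmarks[["5ltr"]]; l3 <- m$landmarks[["3ltr"]]
  bare <- delete_intervals(m$sequence, list(l5, l3, c(7928L, 9114L)))
  ann3 <- annotate_structure(list(sequence = bare), m)
  expect_equal(ann3$label, "undefined")
  expect_equal(ann3$ltr5_form, "absent")
})

test_that("zero-mutation classification is exact", {
  m <- fx_model()
  for (cl in c("provirus", "processed_pseudogene")) {
    el <- simulate_element(m, simulation_spec(cl, "1", age_my = 0, seed = 44))
    expect_equal(annotate_structure(el, m)$label, cl, info = cl)
  }
})
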