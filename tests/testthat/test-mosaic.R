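test_that("discordance counting: substitutions and the gap-run rule", {
  s <- rand_dna(324, 1)
  expect_equal(count_discordant(list(s, s)), 0L)

  sv <- strsplit(s, "")[[1]]
  sv[c(10, 150, 300)] <- chartr("ACGT", "GTAC", sv[c(10, 150, 300)])
  s2 <- paste(sv, collapse = "")
  aln <- global_align(s, s2)
  expect_equal(count_discordant(aln), 3L)
  expect_equal(aln$identity, 321 / 324, tolerance = 1e-9)

  # one 5-nt deletion = one discordance under the gap-run rule
  a <- paste0(substr(s, 1, 100), strrep("-", 5), substr(s, 106, 324))
  b <- s
  expect_equal(count_discordant(list(a, b)), 1L)
  expect_equal(count_discordant(list(a, b), gap_run_rule = FALSE), 5L)
})

test_that("locus ranking by identity, discordance, then id", {
  s <- rand_dna(1000, 10)
  x <- mutate_sequence(s, 0.05, seed = 11)
  db <- c(lx = s, ly = x)
  qv <- strsplit(s, "")[[1]]
  qv[c(5, 500)] <- chartr("ACGT", "GTAC", qv[c(5, 500)])
  q <- paste(qv, collapse = "")
  r <- best_matching_locus(q, db)
  expect_equal(r$locus_id[1], "lx")
  expect_equal(r$discordant[1], 2L)

  r2 <- best_matching_locus(s, db)
  expect_equal(r2$identity[1], 1.0)
  expect_error(best_matching_locus(s, character()), "empty locus database")
  expect_warning(r3 <- best_matching_locus(strrep("A", 1000),
                                           c(z = rand_dna(1000, 12))),
                 "no locus")
  expect_equal(nrow(r3), 0L)
})

test_that("segment_query: single locus, chimera, and penalty limits", {
  a <- rand_dna(1000, 20)
  b <- mutate_sequence(a, 0.05, seed = 21)
  cands <- c(A = a, B = b)

  r <- segment_query(a, cands)
  expect_equal(nrow(r$segments), 1L)
  expect_equal(r$segments$locus_id, "A")
  expect_equal(r$total_mismatches, 0)

  chim <- simulate_recombinant_transcript(a, b, breakpoints = 500)
  r2 <- segment_query(chim, cands)
  expect_equal(nrow(r2$segments), 2L)
  expect_identical(r2$segments$locus_id, c("A", "B"))
  expect_lt(abs(r2$breakpoints[1] - 501), 20)
  expect_lt(r2$total_mismatches, r2$single_locus_mismatches)

  # infinite penalty degenerates to the single best locus
  r3 <- segment_query(chim, cands, mosaic_config(switch_penalty = 1e9))
  expect_equal(nrow(r3$segments), 1L)
  expect_equal(r3$segments$locus_id, r3$single_locus_id)
  expect_equal(r3$total_mismatches, r3$single_locus_mismatches)

  expect_error(segment_query(a, character()), "at least one candidate")
})

test_that("DP cost matches exhaustive segmentation on small instances", {
  hervw:::with_seed(555, {
    for (k in 1:12) {
      n <- sample(100:300, 1)
      base <- rand_dna(n)
      cands <- vapply(1:3, function(i)
        mutate_sequence(base, runif(1, 0.02, 0.08), seed = sample.int(1e6, 1)),
        "")
      names(cands) <- c("A", "B", "C")
      bps <- sort(sample(seq(20, n - 20), sample(0:2, 1)))
      q <- base
      if (length(bps) >= 1)
        q <- simulate_recombinant_transcript(cands[["A"]], cands[["B"]], bps)
      lam <- 4
      got <- segment_query(q, cands, mosaic_config(switch_penalty = lam))
      cost <- mosaic_cost_matrix(q, cands)
      expect_equal(got$dp_cost, oracle_segmentation(cost, lam, max_bp = 2),
                   info = k)
    }
  })
})

test_that("mismatches are non-increasing in allowed breakpoints", {
  a <- rand_dna(800, 30); b <- mutate_sequence(a, 0.06, seed = 31)
  chim <- simulate_recombinant_transcript(a, b, breakpoints = c(300, 600))
  cands <- c(A = a, B = b)
  lams <- c(1e9, 20, 4, 0.5)
  tm <- vapply(lams, function(l)
    segment_query(chim, cands, mosaic_config(switch_penalty = l))$total_mismatches,
    numeric(1))
  expect_true(all(diff(tm) <= 0))
  r <- segment_query(chim, cands, mosaic_config(switch_penalty = 4))
  expect_lte(r$total_mismatches, r$single_locus_mismatches)
})

test_that("the framed locus database projects loci onto the reference grid", {
  m <- fx_model()
  loci <- c(full = m$sequence,
            delgag = delete_intervals(m$sequence, list(c(2780L, 3209L))))
  db <- mosaic_locus_db(m, loci)
  expect_true(all(nchar(db) == m$length))
  expect_false(grepl("-", db[["full"]]))
  # the excised 430 nt appear as one gap run; placement may shift by one
  # column when flanking bases tie in score
  gaps <- gregexpr("-+", db[["delgag"]])[[1]]
  expect_equal(sum(attr(gaps, "match.length")), 430L)
  expect_lte(abs(gaps[1] - 2780L), 2L)
})
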