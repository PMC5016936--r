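test_that("mutate_sequence: identity at zero divergence, determinism, bounds", {
  s <- rand_dna(500, 1)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  expect_identical(mutate_sequence(s, 0.1, seed = 7),
                   mutate_sequence(s, 0.1, seed = 7))
  expect_false(identical(mutate_sequence(s, 0.1, seed = 7),
                         mutate_sequence(s, 0.1, seed = 8)))
  expect_equal(nchar(mutate_sequence(s, 0.3, seed = 1)), 500L)
  expect_error(mutate_sequence(s, 0.75), "0.75")
})

test_that("realized divergence matches the binomial expectation", {
  s <- rand_dna(10000, 2)
  mut <- mutate_sequence(s, 0.05, seed = 11)
  ham <- mean(strsplit(s, "")[[1]] != strsplit(mut, "")[[1]])
  tol <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(ham - 0.05), tol)
})

test_that("transition fraction follows kappa/(kappa+2)", {
  s <- rand_dna(20000, 3)
  kappa <- 2
  mut <- mutate_sequence(s, 0.2, kappa = kappa, seed = 5)
  a <- strsplit(s, "")[[1]]; b <- strsplit(mut, "")[[1]]
  ch <- which(a != b)
  pur <- c("A", "G")
  ts_frac <- mean((a[ch] %in% pur) == (b[ch] %in% pur))
  p <- kappa / (kappa + 2)
  expect_lt(abs(ts_frac - p), 3 * sqrt(p * (1 - p) / length(ch)))
})

test_that("age-0 subgroup-1 provirus reproduces the reference exactly", {
  m <- fx_model()
  el <- simulate_element(m, simulation_spec("provirus", "1", age_my = 0,
                                            seed = 1))
  expect_identical(el$sequence, m$sequence)
  expect_equal(nchar(el$flank5), 100L)
  expect_equal(nchar(el$flank3), 100L)
  # TSD present verbatim on both sides
  tsd <- el$truth$tsd
  expect_true(endsWith(el$flank5, tsd))
  expect_true(startsWith(el$flank3, tsd))
})

test_that("pseudogene simulation carries truncation, poly(A) and TT/AAAA", {
  m <- fx_model()
  sp <- simulation_spec("processed_pseudogene", "1", age_my = 0,
                        tsd_length = 9L, polyA_length = 12L, seed = 4)
  el <- simulate_element(m, sp)
  # 5' end starts at LTR position 256, 3' end stops at LTR position 326
  ltr <- landmark_slice(m, "5ltr")
  expect_identical(substr(el$sequence, 1, 30), substr(ltr, 256, 285))
  body_len <- nchar(el$sequence) - sp$polyA_length
  expect_identical(substr(el$sequence, body_len - 29, body_len),
                   substr(ltr, 297, 326))
  # poly(A) tail
  expect_identical(substr(el$sequence, body_len + 1, nchar(el$sequence)),
                   strrep("A", 12))
  # TT ends the 5' flank before the TSD; TSD starts AAAA
  tsd <- el$truth$tsd
  expect_equal(nchar(tsd), 9L)
  expect_true(startsWith(tsd, "AAAA"))
  n5 <- nchar(el$flank5)
  expect_identical(substr(el$flank5, n5 - 10, n5 - 9), "TT")
  expect_true(endsWith(el$flank5, tsd))
  expect_true(startsWith(el$flank3, tsd))
})

test_that("subgroup-2 variants are installed in both LTRs", {
  m <- fx_model()
  kp <- key_position_table()
  el <- simulate_element(m, simulation_spec("provirus", "2B", age_my = 0,
                                            seed = 2))
  x <- strsplit(el$sequence, "")[[1]]
  main2b <- kp[kp$tier %in% c("main", "2B"), ]
  l3 <- m$landmarks[["3ltr"]]
  expect_identical(x[main2b$position], main2b$alt_base)
  expect_identical(x[l3[1] - 1 + main2b$position], main2b$alt_base)
  # 2A positions stay at reference
  p2a <- kp[kp$tier == "2A", ]
  expect_identical(x[p2a$position], p2a$ref_base)
})

test_that("realized LTR-LTR divergence tracks two independent branches", {
  m <- fx_model()
  age <- 20; rate <- 0.13; kappa <- 2
  p <- rate * age / 100                       # per-branch substitution prob
  t <- kappa / (kappa + 2)
  # analytic P(sites differ): one branch hit, or both hit different targets
  p_diff <- 2 * p * (1 - p) + p^2 * (1 - (t^2 + (1 - t)^2 / 2))
  divs <- vapply(1:40, function(s)
    simulate_element(m, simulation_spec("provirus", "1", age_my = age,
                                        seed = s))$truth$realized_ltr_divergence,
    numeric(1))
  se <- sqrt(p_diff * (1 - p_diff) / 780 / 40)
  expect_lt(abs(mean(divs) - p_diff), 3 * se)
  # and the paper-level sanity: near 2 x 20 x 0.13 % = 5.2 %
  expect_lt(abs(mean(divs) - 0.052), 0.008)
})

test_that("simulation is bit-reproducible from its spec", {
  m <- fx_model()
  sp <- simulation_spec("processed_pseudogene", "2A", age_my = 17,
                        deletions = m$recurrent_deletions[2], seed = 33)
  e1 <- simulate_element(m, sp)
  e2 <- simulate_element(m, sp)
  expect_identical(e1$sequence, e2$sequence)
  expect_identical(e1$flank5, e2$flank5)
  expect_identical(e1$truth$realized_ltr_divergence,
                   e2$truth$realized_ltr_divergence)
})

test_that("recombinant transcripts alternate template segments", {
  a <- strrep("A", 100); b <- strrep("C", 100)
  expect_identical(simulate_recombinant_transcript(a, b), a)
  ch <- simulate_recombinant_transcript(a, b, breakpoints = 50)
  expect_identical(ch, paste0(strrep("A", 50), strrep("C", 50)))
  ch2 <- simulate_recombinant_transcript(a, b, breakpoints = c(30, 70))
  expect_identical(ch2, paste0(strrep("A", 30), strrep("C", 40),
                               strrep("A", 30)))
  expect_error(simulate_recombinant_transcript(a, b, c(70, 30)),
               "strictly increasing")
  expect_error(simulate_recombinant_transcript(a, b, 150),
               "outside shared aligned span")
  expect_error(simulate_recombinant_transcript(a, substr(b, 1, 50), 10),
               "equal length")
})

test_that("cohorts write FASTA plus a consistent truth table", {
  m <- fx_model()
  co <- simulate_cohort(m, 4, class_labels = c("provirus",
                                               "processed_pseudogene"),
                        subgroups = c("1", "2"), ages = c(10, 20),
                        deletion_prob = 0.5, seed = 9)
  expect_length(co$elements, 4L)
  expect_equal(nrow(co$truth), 4L)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_cohort(co, fa, tsv)
  seqs <- read_fasta(fa)
  expect_equal(length(seqs), 4L)
  tt <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(tt$id, names(seqs))
})
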