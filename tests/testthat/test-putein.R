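syn_protein <- function() read_fasta(hervw_file("synthetic_syncytin1.fasta"))[[1]]
syn_cds <- function() {
  m <- fx_model()
  substr(m$sequence, 7720, 7720 + 538 * 3 - 1 + 3)   # CDS incl. stop codon
}

test_that("the packaged Env precursor fixture is 538 aa with its domains", {
  p <- syn_protein()
  expect_equal(nchar(p), 538L)
  cfg <- env_domain_config()
  expect_identical(substr(p, cfg$domains$furin_rknr$start,
                          cfg$domains$furin_rknr$end), "RKNR")
  expect_identical(substr(p, cfg$domains$su_cwic$start,
                          cfg$domains$su_cwic$end), "CWIC")
  expect_false(grepl("LQMV", p))          # the 4-aa R-peptide deletion
})

test_that("a clean single-frame CDS reconstructs idempotently", {
  put <- reconstruct_putein(syn_cds())
  expect_equal(put$length_aa, 538L)
  expect_equal(put$n_internal_stops, 0L)
  expect_equal(put$n_frameshifts, 0L)
  expect_equal(nrow(put$frame_segments), 1L)
  expect_equal(put$frame_segments$frame, 0L)
  # sequence equals the direct frame-0 translation over the aligned span
  expect_identical(gsub("\\*", "", put$sequence), syn_protein())
  expect_error(reconstruct_putein(substr(syn_cds(), 1, 100)), "150")
  expect_error(reconstruct_putein(rand_dna(600, 1)), "not Env-homologous")
})

test_that("an inserted nucleotide produces exactly one frameshift", {
  cds <- syn_cds()
  mutated <- paste0(substr(cds, 1, 300), "G", substr(cds, 301, nchar(cds)))
  put <- reconstruct_putein(mutated)
  expect_equal(put$n_frameshifts, 1L)
  expect_equal(put$n_internal_stops, 0L)
  expect_equal(sort(unique(put$frame_segments$frame)), c(0L, 1L))
  expect_gte(put$length_aa, 530L)
})

test_that("an engineered TGA at codon 39 is an internal stop", {
  cds <- syn_cds()
  x <- strsplit(cds, "")[[1]]
  x[(39 - 1) * 3 + 1:3] <- c("T", "G", "A")
  put <- reconstruct_putein(paste(x, collapse = ""))
  expect_equal(put$n_internal_stops, 1L)
  expect_equal(put$n_frameshifts, 0L)
  expect_identical(substr(put$sequence, 39, 39), "*")
})

test_that("planted well-separated indels yield matching frameshift counts", {
  cds <- syn_cds()
  hervw:::with_seed(777, {
    hits <- 0L; n_try <- 12L
    for (k in 1:n_try) {
      nshift <- sample(1:3, 1)
      pos <- sort(sample(seq(150, nchar(cds) - 250, by = 3), nshift))
      while (nshift > 1 && min(diff(pos)) < 240) # >= 80 codons apart
        pos <- sort(sample(seq(150, nchar(cds) - 250, by = 3), nshift))
      s <- cds
      for (p in rev(pos)) {
        if (runif(1) < 0.5) s <- paste0(substr(s, 1, p), "A",
                                        substr(s, p + 1, nchar(s)))
        else s <- paste0(substr(s, 1, p), substr(s, p + 2, nchar(s)))
      }
      put <- reconstruct_putein(s)
      if (put$n_frameshifts == nshift) hits <- hits + 1L
    }
    expect_gte(hits / n_try, 0.9)
  })
})

test_that("domain report on the reference protein itself", {
  rep <- annotate_env_domains(syn_protein())
  expect_equal(rep$furin_rknr$status, "conserved")
  expect_equal(rep$su_cwic$status, "conserved")
  expect_equal(rep$tm_cx6cc$status, "conserved")
  expect_equal(rep$rbd_sdggg$status, "conserved")
  expect_equal(rep$fusion_peptide_332$status, "conserved")
  expect_equal(rep$heptad_433$status, "conserved")
  expect_equal(rep$r_peptide_lqmv$status, "deleted")
})

test_that("domain substitutions and the LQMV insertion are reported", {
  p <- syn_protein()
  cfg <- env_domain_config()
  x <- strsplit(p, "")[[1]]
  x[cfg$domains$furin_rknr$start] <- "C"          # R -> C at RKNR position 1
  i_pos <- cfg$domains$su_cwic$start + 2L
  x[i_pos] <- "M"                                  # CWIC -> CWMC
  mut <- paste(x, collapse = "")
  rep <- annotate_env_domains(mut)
  expect_equal(rep$furin_rknr$status, "substituted")
  expect_match(rep$furin_rknr$substitutions[1], "^R\\d+C$")
  expect_equal(rep$su_cwic$status, "substituted")
  expect_match(rep$su_cwic$substitutions[1], "I\\d+M")

  # residue checks
  y <- strsplit(p, "")[[1]]
  y[cfg$residue_checks$heptad_433$position] <- "Q"
  rep2 <- annotate_env_domains(paste(y, collapse = ""))
  expect_equal(rep2$heptad_433$status, "substituted")
  expect_match(rep2$heptad_433$substitutions, "R433Q")

  # an ancestral-style putein carrying LQMV at the cleavage window
  at <- cfg$lqmv_window[1] + 5L
  withins <- paste0(substr(p, 1, at), "LQMV", substr(p, at + 1, nchar(p)))
  rep3 <- annotate_env_domains(withins)
  expect_equal(rep3$r_peptide_lqmv$status, "present")

  # truncated putein: C-terminal domains become absent
  rep4 <- annotate_env_domains(substr(p, 1, 200))
  expect_equal(rep4$furin_rknr$status, "absent")
  expect_equal(rep4$su_cwic$status, "conserved")
})
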