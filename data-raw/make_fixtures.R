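# Deterministically regenerates every packaged fixture under inst/extdata/.
# All biological reference objects here are SYNTHETIC stand-ins: they reproduce
# the coordinate geometry and motif content of the HERV-W group reference
# (LTR17-HERV17-LTR17, 10,186 nt), the LTR17 key-position table, a tRNA 3'-end
# library and a 538-aa Env precursor, but not the real base/residue identities,
# which require RepBase / tRNAdb / NCBI access.
#
# Run from the package root:  Rscript data-raw/make_fixtures.R

set.seed(20160909L)

BASES <- c("A", "C", "G", "T")
rand_dna <- function(n, prob = c(.25, .25, .25, .25)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## fixed reverse-translation codon table (one codon per amino acid)
CODON <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
           G="GGT", H="CAT", I="ATT", L="CTT", K="AAA", M="ATG", F="TTT",
           P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT", `*`="TAA")
rev_translate <- function(aa) paste(CODON[strsplit(aa, "")[[1]]], collapse = "")

## ---- LTR (780 nt), key positions at their LTR17 reference bases ----------
key_positions <- data.frame(
  position = c(43L, 95L, 100L, 180L, 254L, 706L, 765L,
               456L, 498L, 133L, 188L, 252L),
  ref_base = c("C", "C", "T", "C", "A", "A", "G", "C", "A", "A", "C", "G"),
  alt_base = c("T", "T", "C", "T", "G", "G", "A", "T", "G", "G", "A", "G"),
  tier     = c(rep("main", 7), "2A", "2A", "2B", "2B", "2B"),
  stringsAsFactors = FALSE
)
# 2B table row 252 is C>G in the paper's numbering
key_positions$ref_base[key_positions$position == 252L] <- "C"
key_positions$alt_base[key_positions$position == 252L] <- "G"

ltr <- strsplit(rand_dna(780), "")[[1]]
ltr[key_positions$position] <- key_positions$ref_base
# keep the LTR tail free of poly(A)-like runs (the detector looks at the last
# 30 nt of an element, which for a provirus is the LTR 3' end)
tail_ix <- 751:780
ltr[tail_ix] <- strsplit("GTCGTCATGCGTACGATCGTCGATGCATGC", "")[[1]]
ltr <- paste(ltr, collapse = "")
stopifnot(nchar(ltr) == 780)

## ---- tRNA 3'-end library: every PBS starts TGG <=> every tRNA ends CCA ---
pbs_codes <- c("W", "R", "F", "I", "S", "P", "L", "N", "E", "G")
repeat {
  tails <- t(replicate(length(pbs_codes), sample(BASES, 15, replace = TRUE)))
  dmin <- min(as.dist(outer(seq_len(nrow(tails)), seq_len(nrow(tails)),
                            Vectorize(function(i, j) sum(tails[i, ] != tails[j, ])))))
  if (dmin >= 6) break
}
pbs_seqs <- apply(tails, 1, function(x) paste0("TGG", paste(x, collapse = "")))
names(pbs_seqs) <- pbs_codes
trna_tails <- vapply(pbs_seqs, revcomp, "")
stopifnot(all(substr(trna_tails, 16, 18) == "CCA"))

## ---- synthetic 538-aa Env precursor (Syncytin-1 stand-in) ----------------
# background alphabet excludes C and W so planted Cys/Trp motifs are unique
bg <- c("A","R","N","D","Q","E","G","H","I","L","K","M","F","P","S","T","Y","V")
repeat {
  env_aa <- sample(bg, 538, replace = TRUE)
  env_aa[1] <- "M"
  env_aa[105:115] <- strsplit("SDGGGAADAAR", "")[[1]]
  env_aa[186:189] <- strsplit("CWIC", "")[[1]]
  env_aa[314:317] <- strsplit("RKNR", "")[[1]]
  env_aa[332]     <- "A"
  env_aa[340:348] <- strsplit("CAILVSTCC", "")[[1]]          # CX6CC
  env_aa[370:386] <- strsplit("LQNRRGLDLLFLKEGGL", "")[[1]]  # ISD stand-in
  env_aa[433]     <- "R"
  p <- paste(env_aa, collapse = "")
  # Syncytin-1 carries the 4-aa deletion at the R-peptide cleavage site:
  # the stand-in must NOT contain LQMV; also avoid chance motif duplicates
  if (!grepl("LQMV", p) &&
      length(gregexpr("RKNR", p)[[1]]) == 1 &&
      length(gregexpr("SDGGG", p)[[1]]) == 1) break
}
env_protein <- p
env_cds <- paste0(rev_translate(env_protein), "TAA")
stopifnot(nchar(env_cds) == 538 * 3 + 3)

## ---- assemble the 10,186-nt reference ------------------------------------
L <- 10186L
ref <- strsplit(rand_dna(L), "")[[1]]
put <- function(ref, at, s) { ref[at:(at + nchar(s) - 1)] <- strsplit(s, "")[[1]]; ref }

ref <- put(ref, 1L, ltr)                         # 5' LTR 1-780
ref <- put(ref, 784L, pbs_seqs[["W"]])           # PBS, internal nt 4-21
# AG-rich leader stretch (purine fraction ~0.8) between 5' LTR and gag
ref <- put(ref, 1300L, rand_dna(400, prob = c(.45, .10, .35, .10)))
# gag NC zinc fingers: CX2CX4HX4C at 4021 (14 aa), CX2CX3HX4C at 4093 (13 aa,
# 39 nt -- one codon beyond the 38-nt paper interval 4093-4130)
ref <- put(ref, 4021L, rev_translate("CAKCLIVSHQERTC"))
ref <- put(ref, 4093L, rev_translate("CTRCMLPHGDSAC"))
# IN C-terminal GPY/F motif, WX3GPYXV, last codon ends at 7521
ref <- put(ref, 7495L, rev_translate("WAKLGPYAV"))
ref <- put(ref, 7720L, env_cds)                  # env CDS 7720-9336
# 3' LTR: the group reference prints 9406-10186 (781 nt) but LTR17 is 780 nt;
# we use 9407-10186 so both LTR landmarks are identical 780-nt copies
ref <- put(ref, 9407L, ltr)
ref <- paste(ref, collapse = "")
stopifnot(nchar(ref) == L,
          substr(ref, 1, 780) == substr(ref, 9407, 10186))

## ---- write fixtures -------------------------------------------------------
out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    cat(">", nm, "\n", sep = "", file = con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
}

write_fasta(list(synthetic_LTR17_HERV17_LTR17 = ref),
            file.path(out, "synthetic_reference.fasta"))
write_fasta(as.list(trna_tails), file.path(out, "synthetic_trna_3prime_library.fasta"))
write_fasta(list(synthetic_syncytin1_538aa = env_protein),
            file.path(out, "synthetic_syncytin1.fasta"))
write.table(key_positions, file.path(out, "key_positions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

landmarks <- list(
  version = "1.0",
  ltr_length = 780L,
  pseudo_5p_anchor = 256L,
  pseudo_3p_anchor = 326L,
  pbs_window = c(784L, 801L),
  landmarks = list(
    `5ltr`      = c(1L, 780L),
    leader      = c(781L, 2717L),
    gag         = c(2718L, 4191L),
    `pro-pol`   = c(4195L, 7692L),
    pro         = c(4195L, 4980L),
    pol_rt      = c(4981L, 6400L),
    pol_in      = c(6401L, 7692L),
    env         = c(7720L, 9348L),
    `3ltr`      = c(9407L, 10186L),
    nc_zf1      = c(4021L, 4062L),
    nc_zf2      = c(4093L, 4130L),
    gpyf        = c(7501L, 7521L),
    env_island  = c(8289L, 8318L)
  ),
  ltr_regions = list(u3 = c(1L, 255L), r = c(256L, 326L), u5 = c(327L, 780L)),
  recurrent_deletions = list(c(2780L, 3209L), c(4513L, 6184L),
                             c(6797L, 7692L), c(7928L, 9114L))
)
jsonlite::write_json(landmarks, file.path(out, "landmarks.json"),
                     auto_unbox = TRUE, pretty = TRUE)

env_domains <- list(
  reference_length = 538L,
  domains = list(
    furin_rknr   = list(start = 314L, end = 317L, motif = "RKNR"),
    su_cwic      = list(start = 186L, end = 189L, motif = "CWIC"),
    tm_cx6cc     = list(start = 340L, end = 348L, pattern = "C.{6}CC"),
    rbd_sdggg    = list(start = 105L, end = 115L, pattern = "SDGGG.{2}D.{2}R"),
    isd          = list(start = 370L, end = 386L)
  ),
  residue_checks = list(
    fusion_peptide_332 = list(position = 332L, ref = "A"),
    heptad_433         = list(position = 433L, ref = "R")
  ),
  lqmv_window = c(480L, 538L)
)
jsonlite::write_json(env_domains, file.path(out, "synthetic_env_domains.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat("fixtures written to", out, "\n")
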