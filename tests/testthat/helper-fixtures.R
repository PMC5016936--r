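# lazily computed shared fixtures (expensive objects built once per run)
.fx <- new.env(parent = emptyenv())

fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- load_reference()
  .fx$model
}

# projection of the reference onto itself (identity alignment)
fx_ref_self <- function() {
  if (is.null(.fx$ref_self)) {
    m <- fx_model()
    .fx$ref_self <- project_to_reference(m, m$sequence)
  }
  .fx$ref_self
}

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) draw() else hervw:::with_seed(seed, draw())
}

# reference with 1-based inclusive intervals excised
delete_intervals <- function(seq, intervals) {
  keep <- rep(TRUE, nchar(seq))
  for (iv in intervals) keep[iv[1]:iv[2]] <- FALSE
  paste(strsplit(seq, "")[[1]][keep], collapse = "")
}
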