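## standard genetic code; ambiguous codons (any non-ACGT) translate to X
.GENCODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aa <- character(64)
  tab <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
           ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
           TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
           ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
           TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
           AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
           TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
           AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  tab
})

#' Translate DNA in a given frame
#'
#' @param nt DNA string.
#' @param frame Frame offset 0, 1 or 2.
#' @return Protein string with stops as \code{"*"} and ambiguous codons as
#'   \code{"X"}; trailing partial codons are dropped.
#' @export
translate_frame <- function(nt, frame = 0L) {
  nt <- toupper(nt)
  n <- nchar(nt)
  ncod <- (n - frame) %/% 3L
  if (ncod < 1L) return("")
  starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- .GENCODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## amino acid substitution matrix extended with X and * rows
.aa_matrix <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  data_env$BLOSUM62
}

## align a frame translation to the reference protein; returns the aligned
## query residue (or NA) and query position per reference residue
.frame_alignment <- function(frame_aa, ref_protein) {
  if (!nzchar(frame_aa)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_protein), Biostrings::AAString(frame_aa),
    substitutionMatrix = .aa_matrix(), gapOpening = 12, gapExtension = 2,
    type = "global")
  ra <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  qa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  rpos <- cumsum(ra != "-")
  qpos <- cumsum(qa != "-")
  keep <- ra != "-"
  res <- rep(NA_character_, nchar(ref_protein))
  qp <- rep(NA_integer_, nchar(ref_protein))
  res[rpos[keep]] <- ifelse(qa[keep] == "-", NA, qa[keep])
  qp[rpos[keep]] <- ifelse(qa[keep] == "-", NA, qpos[keep])
  list(res = res, qpos = qp,
       identity = {
       both <- keep & qa != "-"
       if (any(both)) mean(ra[both] == qa[both]) else 0
       })
}

#' Reconstruct an Env putative protein across reading frames
#'
#' Translates the nucleotide sequence in all three frames, aligns each
#' translation to the reference protein, and stitches a single putein by
#' dynamic programming over reference residues: per position the chosen
#' frame contributes its aligned residue, and switching frames costs
#' \code{shift_penalty} matched residues (so a frameshift must be supported
#' by a sustained identity gain, preventing single-residue frame hops).
#' Stop codons landing before the final 5 % of the aligned reference span
#' count as internal.
#'
#' @param env_nt Nucleotide sequence (>= 150 nt).
#' @param reference_protein Reference Env precursor (packaged synthetic
#'   Syncytin-1 stand-in by default).
#' @param shift_penalty Frameshift penalty in match-equivalents (default 10).
#' @param min_identity Minimum identity of the best single frame (default
#'   0.3); below it the sequence is rejected as not Env-homologous.
#' @return A \code{Putein}: list with \code{sequence} (stops as \code{"*"}),
#'   \code{frame_segments} (data.frame nt_start, nt_end, frame),
#'   \code{n_internal_stops}, \code{n_frameshifts}, \code{length_aa}
#'   (excluding stops), \code{identity}.
#' @export
reconstruct_putein <- function(env_nt,
                               reference_protein = read_fasta(
                                 hervw_file("synthetic_syncytin1.fasta"))[[1]],
                               shift_penalty = 10, min_identity = 0.3) {
  if (nchar(env_nt) < 150L)
    stop("input error: env sequence shorter than 150 nt", call. = FALSE)
  R <- nchar(reference_protein)
  frames <- lapply(0:2, function(f)
    .frame_alignment(translate_frame(env_nt, f), reference_protein))
  ok <- !vapply(frames, is.null, logical(1))
  if (!any(ok) || max(vapply(frames[ok], `[[`, 0, "identity")) < min_identity)
    stop("not Env-homologous: no frame aligns with identity >= ",
         min_identity, call. = FALSE)
  refc <- strsplit(reference_protein, "")[[1]]

  ## emission: 1 for an identical aligned residue, 0 otherwise
  emit <- matrix(0, nrow = 3, ncol = R)
  mapped <- matrix(FALSE, nrow = 3, ncol = R)
  for (f in 1:3) if (ok[f]) {
    mapped[f, ] <- !is.na(frames[[f]]$res)
    emit[f, mapped[f, ]] <-
      as.numeric(frames[[f]]$res[mapped[f, ]] == refc[mapped[f, ]])
  }
  ## Viterbi over reference residues, states = frames
  score <- matrix(-Inf, nrow = 3, ncol = R)
  back <- matrix(NA_integer_, nrow = 3, ncol = R)
  score[, 1] <- emit[, 1]
  for (r in 2:R) {
    for (f in 1:3) {
      stay <- score[f, r - 1]
      sw <- max(score[, r - 1]) - shift_penalty
      if (stay >= sw) {
        score[f, r] <- stay + emit[f, r]; back[f, r] <- f
      } else {
        prev <- which.max(score[, r - 1])
        score[f, r] <- sw + emit[f, r]; back[f, r] <- prev
      }
    }
  }
  path <- integer(R)
  path[R] <- which.max(score[, R])
  for (r in R:2) path[r - 1] <- back[path[r], r]

  ## collapse to segments over reference positions that the chosen frame maps
  aligned_r <- which(mapped[cbind(path, seq_len(R))])
  if (!length(aligned_r))
    stop("not Env-homologous: empty stitched alignment", call. = FALSE)
  span <- range(aligned_r)
  ## segment boundaries: frame changes between consecutive *mapped* positions
  segs <- list()
  cur_f <- path[aligned_r[1]]
  cur_start <- aligned_r[1]
  prev_r <- aligned_r[1]
  for (r in aligned_r[-1]) {
    if (path[r] != cur_f) {
      segs[[length(segs) + 1L]] <- c(cur_f, cur_start, prev_r)
      cur_f <- path[r]; cur_start <- r
    }
    prev_r <- r
  }
  segs[[length(segs) + 1L]] <- c(cur_f, cur_start, prev_r)

  ## emit residues per segment, including query insertions inside the block
  seq_out <- character(); refpos_out <- integer()
  seg_rows <- list()
  for (sg in segs) {
    f <- sg[1]; a <- sg[2]; b <- sg[3]
    qp <- frames[[f]]$qpos[a:b]
    qp <- qp[!is.na(qp)]
    q1 <- min(qp); q2 <- max(qp)
    faa <- translate_frame(env_nt, f - 1L)
    res <- strsplit(substr(faa, q1, q2), "")[[1]]
    ## approximate reference position per emitted residue (for the stop rule)
    rp <- stats::approx(x = c(q1, q2), y = c(a, b), xout = q1:q2,
                        method = "linear", rule = 2)$y
    seq_out <- c(seq_out, res)
    refpos_out <- c(refpos_out, round(rp))
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      frame = f - 1L,
      nt_start = (q1 - 1L) * 3L + f,
      nt_end = q2 * 3L + f - 1L,
      ref_start = a, ref_end = b)
  }
  sequence <- paste(seq_out, collapse = "")
  cutoff <- span[1] + 0.95 * (span[2] - span[1])
  stops <- which(seq_out == "*")
  n_internal <- sum(refpos_out[stops] < cutoff)
  frame_segments <- do.call(rbind, seg_rows)
  structure(list(sequence = sequence, frame_segments = frame_segments,
                 n_internal_stops = as.integer(n_internal),
                 n_frameshifts = nrow(frame_segments) - 1L,
                 length_aa = sum(seq_out != "*"),
                 identity = max(vapply(frames[ok], `[[`, 0, "identity"))),
            class = "Putein")
}

#' @export
print.Putein <- function(x, ...) {
  cat("Putein:", x$length_aa, "aa,", x$n_internal_stops, "internal stop(s),",
      x$n_frameshifts, "frameshift(s)\n")
  invisible(x)
}

#' Load the packaged Env domain coordinate configuration
#' @param path JSON path (default: the synthetic stand-in configuration).
#' @return Nested list of domain coordinates on the reference protein.
#' @export
env_domain_config <- function(path = hervw_file("synthetic_env_domains.json")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Report the status of the Env functional domains
#'
#' Aligns the putein to the reference Env precursor and classifies every
#' configured domain: the furin cleavage site (RKNR), the SU CWIC and TM
#' CX6CC disulfide motifs, the receptor-binding SDGGGX2DX2R motif, the
#' fusion-peptide and heptad-repeat residue checks, the immunosuppressive
#' domain, and the R-peptide LQMV cleavage site (reported \code{deleted}
#' when the four residues are absent at the cleavage position -- as in the
#' reference itself, which owes its constitutive fusogenicity to that
#' deletion).
#'
#' @param putein A [reconstruct_putein()] result (or a plain protein string).
#' @param reference_protein Reference Env precursor.
#' @param config From [env_domain_config()].
#' @return An \code{EnvDomainReport}: named list of per-domain status lists
#'   with fields \code{status} (\code{conserved}, \code{substituted},
#'   \code{truncated}, \code{absent}, or \code{present}/\code{deleted} for
#'   the LQMV site) and \code{substitutions} (ref->obs with reference
#'   residue numbers).
#' @export
annotate_env_domains <- function(putein,
                                 reference_protein = read_fasta(
                                   hervw_file("synthetic_syncytin1.fasta"))[[1]],
                                 config = env_domain_config()) {
  pseq <- if (inherits(putein, "Putein")) putein$sequence else putein
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(reference_protein),
    Biostrings::AAString(gsub("\\*", "X", pseq)),
    substitutionMatrix = .aa_matrix(), gapOpening = 12, gapExtension = 2,
    type = "global")
  ra <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  qa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ## restore stops in the aligned query
  porig <- strsplit(pseq, "")[[1]]
  qpos <- cumsum(qa != "-")
  qa[qa != "-"] <- porig[qpos[qa != "-"]]
  rpos <- cumsum(ra != "-")
  at_ref <- function(i) {
    cols <- which(ra != "-")[i]
    qa[cols]
  }
  refc <- strsplit(reference_protein, "")[[1]]

  classify_stretch <- function(start, end, motif = NULL, pattern = NULL) {
    obs <- at_ref(start:end)
    if (all(obs == "-")) return(list(status = "absent", substitutions = character()))
    if (mean(obs == "-") > 0.3 || obs[1] == "-" || obs[length(obs)] == "-")
      return(list(status = "truncated", substitutions = character()))
    obs_str <- paste(obs[obs != "-"], collapse = "")
    okpat <- if (!is.null(motif)) identical(obs_str, motif)
             else if (!is.null(pattern)) grepl(paste0("^", pattern, "$"), obs_str)
             else TRUE
    subs <- character()
    idx <- start:end
    for (k in seq_along(idx)) {
      if (obs[k] != "-" && obs[k] != refc[idx[k]])
        subs <- c(subs, sprintf("%s%d%s", refc[idx[k]], idx[k], obs[k]))
    }
    if (is.null(motif) && is.null(pattern)) okpat <- !length(subs)
    ## a pattern domain stays "conserved" while its invariant residues hold,
    ## even if spacer residues drifted (substitutions still listed)
    list(status = if (okpat) "conserved" else "substituted",
         substitutions = subs)
  }
  report <- list()
  for (nm in names(config$domains)) {
    dm <- config$domains[[nm]]
    report[[nm]] <- classify_stretch(dm$start, dm$end,
                                     motif = dm$motif, pattern = dm$pattern)
  }
  for (nm in names(config$residue_checks)) {
    rc <- config$residue_checks[[nm]]
    obs <- at_ref(rc$position)
    report[[nm]] <- if (obs == "-") list(status = "absent", substitutions = character())
    else if (obs == rc$ref) list(status = "conserved", substitutions = character())
    else list(status = "substituted",
              substitutions = sprintf("%s%d%s", rc$ref, rc$position, obs))
  }
  ## LQMV R-peptide site: present iff the literal motif occurs with its
  ## aligned reference position inside the configured window
  lw <- config$lqmv_window
  hit <- gregexpr("LQMV", pseq)[[1]]
  present <- FALSE
  if (hit[1] != -1L) {
    colfor <- function(qp) which(qa != "-")[qp]  # alignment column of query pos
    for (h in as.integer(hit)) {
      col <- colfor(h)
      refp <- rpos[col]
      if (!is.na(refp) && refp >= lw[1] && refp <= lw[2]) present <- TRUE
    }
  }
  report$r_peptide_lqmv <- list(status = if (present) "present" else "deleted",
                                substitutions = character())
  structure(report, class = "EnvDomainReport")
}
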