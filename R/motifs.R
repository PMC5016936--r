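#' Read the packaged tRNA 3'-end library
#'
#' Record ids are one-letter amino acid codes; sequences are the 18 3'
#' terminal nucleotides of each tRNA (all ending CCA).  The PBS of an element
#' is complementary to one of these, so matching is done against their
#' reverse complements.
#'
#' @param path Library FASTA (default: the packaged synthetic stand-in).
#' @return Named character vector code -> 18-nt tRNA 3' end.
#' @export
trna_library <- function(path = hervw_file("synthetic_trna_3prime_library.fasta")) {
  lib <- read_fasta(path)
  stopifnot(all(nchar(lib) == 18L))
  lib
}

#' Reverse complement
#' @param s DNA string.
#' @return Reverse complement string.
#' @export
reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                 collapse = ""))
}

#' Locate and assign the primer binding site
#'
#' Extracts the 18-nt window at the reference PBS coordinates (the window
#' sits a few nt downstream of the 5' LTR; a \code{slack} of +/- 3 nt of
#' offset is scanned and the best-scoring offset kept) and assigns the tRNA
#' type whose 3' end is complementary with the fewest mismatches, requiring
#' at most \code{max_mismatch} mismatches and a unique best hit.
#'
#' @param aln Element projection onto the reference (\code{AlignedPair}).
#' @param model Reference model (provides \code{pbs_window}).
#' @param trna_lib From [trna_library()].
#' @param max_mismatch Assignment cap (default 4).
#' @param slack Offset slack in nt (default 3).
#' @return A \code{PBSCall}: list with \code{sequence}, \code{ref_offset},
#'   \code{assignment} (code, \code{"ambiguous"} or \code{"absent"}),
#'   \code{mismatches_best}, \code{runner_up_gap}.
#' @export
find_pbs <- function(aln, model, trna_lib = trna_library(),
                     max_mismatch = 4L, slack = 3L) {
  w <- model$pbs_window
  expected <- vapply(trna_lib, reverse_complement, "")
  ## minimum mismatch per tRNA code over all window offsets
  percode <- stats::setNames(rep(Inf, length(expected)), names(expected))
  winof <- stats::setNames(rep(NA_integer_, length(expected)), names(expected))
  winsq <- stats::setNames(rep(NA_character_, length(expected)), names(expected))
  any_window <- FALSE
  for (off in -slack:slack) {
    s <- w[1] + off; e <- w[2] + off
    if (s < 1L || e > nchar(aln$ref)) next
    win <- query_at_reference(aln, s, e)
    wc <- strsplit(win, "")[[1]]
    if (mean(wc == "-") > 0.5) next               # window mostly deleted
    any_window <- TRUE
    mms <- vapply(expected, function(p) sum(wc != strsplit(p, "")[[1]]),
                  numeric(1))
    upd <- mms < percode
    percode[upd] <- mms[upd]
    winof[upd] <- off
    winsq[upd] <- win
  }
  if (!any_window)
    return(structure(list(sequence = NA_character_, ref_offset = NA_integer_,
                          assignment = "absent",
                          mismatches_best = NA_integer_,
                          runner_up_gap = NA_integer_), class = "PBSCall"))
  o <- order(percode)
  best_mm <- percode[o[1]]
  gap <- if (length(percode) > 1L) percode[o[2]] - best_mm else Inf
  assignment <- if (best_mm > max_mismatch || gap < 1) "ambiguous"
                else names(percode)[o[1]]
  structure(list(sequence = winsq[[o[1]]], ref_offset = winof[[o[1]]],
                 assignment = assignment,
                 mismatches_best = as.integer(best_mm),
                 runner_up_gap = if (is.finite(gap)) as.integer(gap) else NA_integer_),
            class = "PBSCall")
}

#' Scan a protein for gammaretroviral motifs
#'
#' Non-overlapping regular-expression matches of the nucleocapsid zinc
#' fingers (canonical \code{CX2CX4HX4C} and the group's second, shortened
#' \code{CX2CX3HX4C}) and the integrase C-terminal GPY/F motif
#' (\code{WXnGPY/FXV}, spacer bounded at 3-30 residues).
#'
#' @param protein Protein string.
#' @param which Subset of \code{c("zf_cx2cx4hx4c", "zf_cx2cx3hx4c", "gpyf")}.
#' @return data.frame: \code{motif_name}, \code{start}, \code{end},
#'   \code{match} (residue coordinates).
#' @export
scan_protein_motifs <- function(protein,
                                which = c("zf_cx2cx4hx4c", "zf_cx2cx3hx4c",
                                          "gpyf")) {
  if (!nzchar(protein)) stop("empty protein", call. = FALSE)
  pats <- c(zf_cx2cx4hx4c = "C.{2}C.{4}H.{4}C",
            zf_cx2cx3hx4c = "C.{2}C.{3}H.{4}C",
            gpyf = "W.{3,30}?GP[YF].V")
  which <- match.arg(which, names(pats), several.ok = TRUE)
  out <- list()
  for (nm in which) {
    m <- gregexpr(pats[[nm]], protein, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    out[[nm]] <- data.frame(motif_name = nm, start = as.integer(m),
                            end = as.integer(m) + len - 1L,
                            match = substring(protein, m, m + len - 1L),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(motif_name = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Base composition and purine-bias flags
#'
#' The group shows a weak purine bias: richer in adenine (about 30 %) and
#' poorer in guanine (around 22 %).  Flags: A-rich when the A fraction
#' exceeds \code{a_rich}, G-poor when the G fraction is below \code{g_poor}.
#'
#' @param seq DNA string (>= 100 nt).
#' @param a_rich,g_poor Flag thresholds.
#' @return List: \code{fractions} (named A/C/G/T), \code{a_rich},
#'   \code{g_poor}.
#' @export
composition_stats <- function(seq, a_rich = 0.28, g_poor = 0.24) {
  x <- strsplit(toupper(seq), "")[[1]]
  x <- x[x %in% c("A", "C", "G", "T")]
  if (length(x) < 100L)
    stop("sequence shorter than 100 informative nt", call. = FALSE)
  f <- table(factor(x, levels = c("A", "C", "G", "T"))) / length(x)
  f <- stats::setNames(as.numeric(f), c("A", "C", "G", "T"))
  list(fractions = f, a_rich = f[["A"]] > a_rich, g_poor = f[["G"]] < g_poor)
}

#' Position frequency matrix with per-column information content
#'
#' @param strings Equal-length aligned strings (>= 2).
#' @param alphabet Symbol alphabet (default DNA).
#' @return List: \code{pfm} (|alphabet| x L relative frequencies over
#'   in-alphabet symbols) and \code{ic} (bits per column,
#'   \code{log2(|alphabet|) - H}).
#' @export
position_frequency_matrix <- function(strings,
                                      alphabet = c("A", "C", "G", "T")) {
  strings <- unlist(strings)
  stopifnot(length(strings) >= 2L)
  if (length(unique(nchar(strings))) != 1L)
    stop("input error: unequal lengths", call. = FALSE)
  m <- do.call(rbind, strsplit(strings, ""))
  L <- ncol(m)
  pfm <- vapply(seq_len(L), function(j) {
    col <- m[, j][m[, j] %in% alphabet]
    if (!length(col)) return(rep(0, length(alphabet)))
    as.numeric(table(factor(col, levels = alphabet))) / length(col)
  }, numeric(length(alphabet)))
  rownames(pfm) <- alphabet
  ic <- apply(pfm, 2L, function(p) {
    p <- p[p > 0]
    log2(length(alphabet)) + sum(p * log2(p))
  })
  list(pfm = pfm, ic = ic)
}

#' Longest AG-rich stretch in the leader region
#'
#' The region between the 5' LTR and gag carries an AG-rich expansion of
#' variable length; reported as the longest window of at least
#' \code{min_len} nt with purine fraction >= \code{purine_frac} (descriptive
#' only).
#'
#' @param aln Element projection.
#' @param model Reference model.
#' @param min_len Minimum window length (default 100).
#' @param purine_frac Purine fraction threshold (default 0.7).
#' @return List: \code{found}, \code{ref_start}, \code{ref_end},
#'   \code{length}, \code{purine_fraction}; or \code{found = FALSE}.
#' @export
ag_rich_leader <- function(aln, model, min_len = 100L, purine_frac = 0.7) {
  iv <- model$landmarks[["leader"]]
  s <- query_at_reference(aln, iv[1], iv[2])
  x <- strsplit(s, "")[[1]]
  pur <- as.integer(x %in% c("A", "G"))
  valid <- as.integer(x != "-")
  n <- length(x)
  cp <- c(0L, cumsum(pur)); cv <- c(0L, cumsum(valid))
  best <- NULL
  for (len in n:min_len) {
    starts <- 1:(n - len + 1L)
    nb <- cv[starts + len] - cv[starts]
    np <- cp[starts + len] - cp[starts]
    ok <- nb >= min_len & np / pmax(nb, 1L) >= purine_frac
    if (any(ok)) {
      st <- starts[which(ok)[1L]]
      best <- list(found = TRUE, ref_start = iv[1] + st - 1L,
                   ref_end = iv[1] + st + len - 2L, length = len,
                   purine_fraction = np[which(ok)[1L]] / nb[which(ok)[1L]])
      break
    }
  }
  if (is.null(best)) best <- list(found = FALSE)
  best
}
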