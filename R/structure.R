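#' Per-landmark retention of a projected element
#'
#' An element "retains" a landmark when at least a fraction \code{theta}
#' (default 0.20, ties retained) of the landmark's reference positions carry
#' an aligned element base.
#'
#' @param aln \code{AlignedPair} from [project_to_reference()].
#' @param model Reference model.
#' @param theta Retention threshold.
#' @param landmarks Which landmarks to score (default: the six classical
#'   retroviral elements).
#' @return data.frame: \code{landmark}, \code{fraction}, \code{retained}.
#' @export
compute_retention <- function(aln, model, theta = 0.20,
                              landmarks = c("5ltr", "gag", "pro-pol",
                                            "env", "3ltr")) {
  frac <- vapply(landmarks, function(nm) {
    iv <- model$landmarks[[nm]]
    mean(!is.na(aln$ref_map[iv[1]:iv[2]]))
  }, numeric(1))
  data.frame(landmark = landmarks, fraction = unname(frac),
             retained = unname(frac >= theta), stringsAsFactors = FALSE)
}

#' Detect L1-retroposition signatures
#'
#' Scores the three processed-pseudogene hallmarks: a poly(A) tail (a run of
#' >= 8 A's, at most one non-A tolerated, within the last 30 nt of the
#' element or the first 30 nt of the 3' flank), a 5-15 bp target site
#' duplication shared verbatim by the two flank junctions, and the TT/AAAA
#' L1 endonuclease junction motif.  With empty flanks the TSD and TT/AAAA
#' are reported as undeterminable (\code{NA}), not false.
#'
#' @param element_seq Element sequence.
#' @param flank5,flank3 Genomic flanks (may be empty strings).
#' @return List: \code{polyA} (logical), \code{polyA_length}, \code{tsd}
#'   (string or \code{NA}), \code{tt_aaaa} (logical or \code{NA}).
#' @export
detect_retro_signatures <- function(element_seq, flank5 = "", flank3 = "") {
  tail30 <- substr(element_seq, max(1L, nchar(element_seq) - 29L),
                   nchar(element_seq))
  head30 <- substr(flank3, 1L, 30L)
  pa <- max(.max_polyA_run(tail30), .max_polyA_run(head30))
  polyA <- pa >= 8L

  if (!nzchar(flank5) || !nzchar(flank3)) {
    return(list(polyA = polyA, polyA_length = pa,
                tsd = NA_character_, tt_aaaa = NA))
  }
  n5 <- nchar(flank5)
  tsd <- NA_character_
  for (k in 15:5) {
    if (k > n5 || k > nchar(flank3)) next
    if (substr(flank5, n5 - k + 1L, n5) == substr(flank3, 1L, k)) {
      tsd <- substr(flank3, 1L, k)
      break
    }
  }
  k <- if (is.na(tsd)) 0L else nchar(tsd)
  tt <- if (k > 0L) substr(flank5, n5 - k - 1L, n5 - k) == "TT"
        else substr(flank5, n5 - 1L, n5) == "TT"
  aaaa <- if (k > 0L) startsWith(tsd, "AAAA") else startsWith(flank3, "AAAA")
  list(polyA = polyA, polyA_length = pa, tsd = tsd, tt_aaaa = tt && aaaa)
}

## longest A-run allowing at most one interruption
.max_polyA_run <- function(s) {
  if (!nzchar(s)) return(0L)
  x <- strsplit(s, "")[[1]] == "A"
  n <- length(x)
  best <- 0L
  for (i in seq_len(n)) {
    miss <- 0L
    for (j in i:n) {
      if (!x[j]) miss <- miss + 1L
      if (miss > 1L) break
      run <- j - i + 1L - miss          # count A's only
      if (x[j] && run > best) best <- run
    }
  }
  best
}

#' Annotate insertions and deletions relative to the reference
#'
#' Maximal gap runs in the query are deletions (with their reference
#' interval); maximal gap runs in the reference are insertions, anchored to
#' the preceding reference position.
#'
#' @param aln \code{AlignedPair}.
#' @param min_len Minimum indel length to report (default 1).
#' @return data.frame: \code{kind}, \code{ref_start}, \code{ref_end},
#'   \code{length}.
#' @export
annotate_indels <- function(aln, min_len = 1L) {
  rc <- strsplit(aln$ref_aligned, "")[[1]]
  qc <- strsplit(aln$qry_aligned, "")[[1]]
  rpos <- cumsum(rc != "-")
  out <- list()
  add <- function(kind, s, e, len) {
    out[[length(out) + 1L]] <<- data.frame(kind = kind, ref_start = s,
                                           ref_end = e, length = len,
                                           stringsAsFactors = FALSE)
  }
  r <- rle(qc == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    len <- r$lengths[k]
    if (len >= min_len)
      add("deletion", rpos[starts[k]], rpos[ends[k]], len)
  }
  r <- rle(rc == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    len <- r$lengths[k]
    if (len >= min_len)
      add("insertion", rpos[starts[k]], rpos[starts[k]], len)  # anchor
  }
  if (!length(out))
    return(data.frame(kind = character(), ref_start = integer(),
                      ref_end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$ref_start), , drop = FALSE]
}

## coverage and truncation geometry of both LTRs, in the 780-nt LTR frame
ltr_geometry <- function(aln, model) {
  geo <- function(l) {
    cov <- !is.na(aln$ref_map[l[1]:l[2]])
    reg <- model$ltr_regions
    ## truncation points come from the longest covered run: stray short
    ## alignments (e.g. a poly(A) tail matching an A-rich patch elsewhere in
    ## the LTR) must not move the observed terminus
    first <- NA_integer_; last <- NA_integer_
    if (any(cov)) {
      r <- rle(cov)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      main <- runs[which.max(r$lengths[runs])]
      first <- starts[main]; last <- ends[main]
    }
    list(u3 = mean(cov[reg$u3[1]:reg$u3[2]]),
         r  = mean(cov[reg$r[1]:reg$r[2]]),
         u5 = mean(cov[reg$u5[1]:reg$u5[2]]),
         any = any(cov), first = first, last = last)
  }
  list(ltr5 = geo(model$landmarks[["5ltr"]]),
       ltr3 = geo(model$landmarks[["3ltr"]]))
}

.ltr_form <- function(g, side) {
  if (!g$any) return("absent")
  if (g$u3 >= 0.5 && g$u5 >= 0.5) return("U3-R-U5")
  if (side == "5p" && g$u3 < 0.5 && g$u5 >= 0.5) return("R-U5")
  if (side == "3p" && g$u3 >= 0.5 && g$u5 < 0.5) return("U3-R")
  "partial"
}

#' Structural classification: provirus, processed pseudogene or undefined
#'
#' Decision rule: (a) \emph{provirus} when at least one LTR shows its
#' full-length diagnostic region -- the 5' LTR covers >= 50 % of U3 or the
#' 3' LTR covers >= 50 % of U5; (b) \emph{processed pseudogene} when no LTR
#' shows the full-length form, the observed truncation points of whichever
#' LTRs are present fall within \code{anchor_tol} nt of the R-U5/U3-R anchors
#' (256/326), and at least one retroposition signature holds; (c)
#' \emph{undefined} otherwise.
#'
#' @param aln \code{AlignedPair} of the element against the reference.
#' @param model Reference model.
#' @param signatures From [detect_retro_signatures()].
#' @param anchor_tol Truncation anchor tolerance in nt (default 25).
#' @param strict_signatures When \code{TRUE}, a pseudogene call additionally
#'   requires the TSD itself (not just any one signature).
#' @return List: \code{label}, \code{ltr5_form}, \code{ltr3_form},
#'   \code{geometry}.
#' @export
classify_structure <- function(aln, model, signatures,
                               anchor_tol = 25L, strict_signatures = FALSE) {
  g <- ltr_geometry(aln, model)
  form5 <- .ltr_form(g$ltr5, "5p")
  form3 <- .ltr_form(g$ltr3, "3p")
  label <- "undefined"
  if (g$ltr5$u3 >= 0.5 || g$ltr3$u5 >= 0.5) {
    label <- "provirus"
  } else {
    anchors_ok <-
      (!g$ltr5$any || abs(g$ltr5$first - model$pseudo_5p_anchor) <= anchor_tol) &&
      (!g$ltr3$any || abs(g$ltr3$last - model$pseudo_3p_anchor) <= anchor_tol)
    sig_ok <- isTRUE(signatures$polyA) ||
      (!is.na(signatures$tsd) && nzchar(signatures$tsd)) ||
      isTRUE(signatures$tt_aaaa)
    if (strict_signatures)
      sig_ok <- sig_ok && !is.na(signatures$tsd) && nzchar(signatures$tsd)
    if (anchors_ok && sig_ok) label <- "processed_pseudogene"
  }
  list(label = label, ltr5_form = form5, ltr3_form = form3, geometry = g)
}

#' Full structural annotation of one element
#'
#' Convenience wrapper running retention, indel annotation, signature
#' detection and classification in one pass.
#'
#' @param element List with \code{sequence}, optional \code{flank5},
#'   \code{flank3} (a \code{SimulatedElement} works directly).
#' @param model Reference model.
#' @param aln Optional precomputed projection.
#' @param theta Retention threshold.
#' @param ... Passed to [classify_structure()].
#' @return A \code{StructuralAnnotation} list: \code{label}, \code{retention},
#'   \code{indels}, \code{signatures}, \code{ltr5_form}, \code{ltr3_form},
#'   \code{aln}.
#' @export
annotate_structure <- function(element, model, aln = NULL, theta = 0.20, ...) {
  if (is.null(aln))
    aln <- project_to_reference(model, element$sequence)
  sig <- detect_retro_signatures(element$sequence,
                                 element$flank5 %||% "",
                                 element$flank3 %||% "")
  cls <- classify_structure(aln, model, sig, ...)
  structure(list(label = cls$label,
                 retention = compute_retention(aln, model, theta),
                 indels = annotate_indels(aln, min_len = 10L),
                 signatures = sig,
                 ltr5_form = cls$ltr5_form, ltr3_form = cls$ltr3_form,
                 aln = aln),
            class = "StructuralAnnotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
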