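#' Default global alignment parameters
#'
#' Long-indel-tolerant scores: most elements of this group carry kilobase
#' deletions, so gap extension is kept cheap relative to mismatches.
#' \code{N} matches any base at score 0.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (penalties negative).
#' @return A list of alignment parameters.
#' @export
alignment_params <- function(match = 1, mismatch = -2,
                             gap_open = -5, gap_extend = -1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment over the \{A,C,G,T,N\} alphabet
#' (compiled three-state DP).  A gap of length k costs
#' \code{-(|gap_open| + k |gap_extend|)}; \code{N} matches any base at
#' score 0.  Ties are broken deterministically: diagonal over gap-in-query
#' over gap-in-reference.
#'
#' @param ref,qry DNA strings (non-empty, alphabet A/C/G/T/N).
#' @param params See [alignment_params()].
#' @return An \code{AlignedPair}: list with \code{ref_aligned},
#'   \code{qry_aligned} (equal-length gapped strings), \code{score},
#'   \code{ref_map} (integer vector, one entry per reference position, query
#'   coordinate or NA), \code{identity} (fraction of matching bases over
#'   columns aligned in both), and \code{ref}, \code{qry} inputs.
#' @export
global_align <- function(ref, qry, params = alignment_params(),
                         band = NULL) {
  if (!nzchar(ref) || !nzchar(qry))
    stop("empty sequence", call. = FALSE)
  ref <- toupper(ref); qry <- toupper(qry)
  if (is.null(band)) band <- c(-nchar(ref), nchar(qry))   # full DP
  res <- .gotoh_align(ref, qry, params$match, params$mismatch,
                      params$gap_open, params$gap_extend,
                      as.integer(band[1]), as.integer(band[2]))
  aligned_pair(res$ref_aligned, res$qry_aligned, score = res$score,
               ref = ref, qry = qry)
}

## build an AlignedPair from two gapped strings
aligned_pair <- function(ref_aligned, qry_aligned, score = NA_real_,
                         ref = gsub("-", "", ref_aligned),
                         qry = gsub("-", "", qry_aligned)) {
  stopifnot(nchar(ref_aligned) == nchar(qry_aligned))
  rc <- strsplit(ref_aligned, "")[[1]]
  qc <- strsplit(qry_aligned, "")[[1]]
  rgap <- rc == "-"
  qgap <- qc == "-"
  both <- !rgap & !qgap
  identity <- if (any(both)) mean(rc[both] == qc[both]) else 0
  # per-reference-position query coordinate (NA where query is gapped)
  qpos <- cumsum(!qgap)
  ref_map <- ifelse(qgap, NA_integer_, qpos)[!rgap]
  structure(list(ref_aligned = ref_aligned, qry_aligned = qry_aligned,
                 score = score, ref_map = as.integer(ref_map),
                 identity = identity, ref = ref, qry = qry),
            class = "AlignedPair")
}

#' @export
print.AlignedPair <- function(x, ...) {
  cat("AlignedPair:", nchar(x$ref), "nt ref,", nchar(x$qry), "nt qry,",
      "identity", sprintf("%.3f", x$identity), "score", x$score, "\n")
  invisible(x)
}

#' Project an element onto the reference frame
#'
#' Globally aligns an element sequence against the model consensus so that
#' downstream modules can address element bases by reference coordinate via
#' \code{ref_map}.  Elements shorter than 200 nt are rejected as unalignable
#' fragments; an identity below 0.5 over aligned columns flags the result as
#' \code{not_group_member} (no error).
#'
#' @param model A [load_reference()] model.
#' @param element_seq Element DNA string (>= 200 nt).
#' @param params Alignment parameters.
#' @param band_margin Half-width added to the net length difference to form
#'   the alignment band (offsets of the optimal path are bracketed by the
#'   total indel load; the default 600 nt comfortably covers the group's
#'   recurrent deletions plus drift).  Set \code{NULL} for the full DP.
#' @return An \code{AlignedPair} with an added logical \code{not_group_member}.
#' @export
project_to_reference <- function(model, element_seq,
                                 params = alignment_params(),
                                 band_margin = 600L) {
  stopifnot(inherits(model, "ReferenceModel"))
  if (nchar(element_seq) < 200L)
    stop("input error: element shorter than 200 nt is rejected as an ",
         "unalignable fragment", call. = FALSE)
  band <- NULL
  if (!is.null(band_margin)) {
    net <- nchar(element_seq) - model$length
    band <- c(min(0L, net) - band_margin, max(0L, net) + band_margin)
  }
  aln <- global_align(model$sequence, element_seq, params, band = band)
  aln$not_group_member <- aln$identity < 0.5
  if (aln$not_group_member)
    warning("identity ", sprintf("%.2f", aln$identity),
            " < 0.5: not a group member", call. = FALSE)
  aln
}

#' Query bases over a reference interval
#'
#' @param aln An \code{AlignedPair} from [project_to_reference()].
#' @param start,end Reference interval (1-based inclusive).
#' @param gap Character used for reference positions with no query base.
#' @return Character string of length \code{end - start + 1}: the query base
#'   aligned at each reference position, or \code{gap}.
#' @export
query_at_reference <- function(aln, start, end, gap = "-") {
  idx <- aln$ref_map[start:end]
  qc <- strsplit(aln$qry, "")[[1]]
  out <- rep(gap, length(idx))
  ok <- !is.na(idx)
  out[ok] <- qc[idx[ok]]
  paste(out, collapse = "")
}

#' Contiguous query subsequence spanning a reference interval
#'
#' Unlike [query_at_reference()] this returns the query bases between the
#' first and last mapped position, including query insertions.
#' @inheritParams query_at_reference
#' @return Query substring, or "" when the interval is uncovered.
#' @export
query_span <- function(aln, start, end) {
  idx <- aln$ref_map[start:end]
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return("")
  substr(aln$qry, min(idx), max(idx))
}
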