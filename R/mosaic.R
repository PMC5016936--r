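#' Mosaic assignment configuration
#'
#' @param switch_penalty Breakpoint penalty in mismatch-equivalents
#'   (default 4: a template switch must save at least four discordant bases,
#'   preventing single-SNP "recombination" artifacts).
#' @param max_candidates Candidate loci retained from the ranking step.
#' @return A \code{MosaicConfig} list.
#' @export
mosaic_config <- function(switch_penalty = 4.0, max_candidates = 10L) {
  stopifnot(switch_penalty >= 0)
  list(switch_penalty = switch_penalty,
       max_candidates = as.integer(max_candidates))
}

#' Count discordant bases in an alignment
#'
#' Aligned columns with differing bases count one each; a contiguous gap run
#' of any length counts once (a k-nt indel is a single discordance).
#'
#' @param aln \code{AlignedPair}, or a list/vector of two equal-length
#'   gapped strings.
#' @param gap_run_rule Count each gap run once (\code{TRUE}, default) or
#'   each gapped column individually.
#' @return Integer discordance count.
#' @export
count_discordant <- function(aln, gap_run_rule = TRUE) {
  if (inherits(aln, "AlignedPair")) {
    a <- aln$ref_aligned; b <- aln$qry_aligned
  } else { a <- aln[[1]]; b <- aln[[2]] }
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  gap <- ac == "-" | bc == "-"
  subs <- sum(!gap & ac != bc)
  if (!any(gap)) return(as.integer(subs))
  if (gap_run_rule) {
    r <- rle(gap)
    as.integer(subs + sum(r$values))
  } else as.integer(subs + sum(gap))
}

#' Build a reference-framed locus database for mosaic analysis
#'
#' Projects each locus onto the reference once, so queries can be compared
#' to every locus on a common coordinate grid.
#'
#' @param model Reference model.
#' @param loci Named character vector of locus sequences (or a FASTA path).
#' @return Named character vector of reference-framed locus strings
#'   (length = reference length, gap \code{"-"}).
#' @export
mosaic_locus_db <- function(model, loci) {
  if (length(loci) == 1L && file.exists(loci[[1]])) loci <- read_fasta(loci[[1]])
  stopifnot(length(loci) >= 1L, !is.null(names(loci)))
  vapply(loci, function(s) {
    aln <- project_to_reference(model, s)
    query_at_reference(aln, 1L, model$length)
  }, "")
}

#' Rank candidate loci for a query transcript
#'
#' Each locus is compared to the query over the query's covered frame span;
#' ranking is by identity (descending), ties by fewer discordant bases,
#' then lexical locus id.
#'
#' @param query Reference-framed query string (same frame as the database),
#'   e.g. from [mosaic_locus_db()] or a simulated chimera.
#' @param locus_db Named vector of reference-framed locus strings.
#' @param min_identity Loci below this identity are dropped; an empty result
#'   (with a warning) means the query maps to no locus.
#' @return data.frame: \code{locus_id}, \code{identity}, \code{discordant},
#'   ranked.
#' @export
best_matching_locus <- function(query, locus_db, min_identity = 0.8) {
  if (!length(locus_db)) stop("input error: empty locus database", call. = FALSE)
  qc <- strsplit(query, "")[[1]]
  qcov <- which(qc != "-")
  if (!length(qcov)) stop("input error: empty query", call. = FALSE)
  span <- min(qcov):max(qcov)
  rows <- lapply(names(locus_db), function(id) {
    lc <- strsplit(locus_db[[id]], "")[[1]]
    a <- paste(qc[span], collapse = ""); b <- paste(lc[span], collapse = "")
    ap <- framed_pair(a, b)
    data.frame(locus_id = id, identity = ap$identity,
               discordant = count_discordant(ap), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$identity, res$discordant, res$locus_id,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  keep <- res$identity >= min_identity
  if (!any(keep)) {
    warning("query maps to no locus with identity >= ", min_identity,
            call. = FALSE)
    return(res[0, , drop = FALSE])
  }
  res[keep, , drop = FALSE]
}

#' Segment a query over candidate loci (breakpoint-penalized DP)
#'
#' Viterbi-style dynamic program over the query's covered columns with
#' states = candidate loci: each mismatch costs 1 (gap runs cost 1, as in
#' [count_discordant()]) and each template switch costs
#' \code{switch_penalty}.  Returns the minimum-cost path compressed to
#' segments, plus the best single-locus alternative.
#'
#' @param query Reference-framed query string.
#' @param candidates Named vector of reference-framed candidate locus
#'   strings (>= 1).
#' @param config A [mosaic_config()].
#' @return A \code{MosaicAssignment}: list with \code{segments} (data.frame
#'   query_start, query_end, ref_start, ref_end, locus_id, mismatches),
#'   \code{breakpoints} (query positions of segment starts after the first),
#'   \code{total_mismatches}, \code{single_locus_mismatches},
#'   \code{single_locus_id}, \code{identity_best}.
#' @export
segment_query <- function(query, candidates, config = mosaic_config()) {
  if (length(candidates) < 1L)
    stop("input error: need at least one candidate locus", call. = FALSE)
  lam <- config$switch_penalty
  qc <- strsplit(query, "")[[1]]
  cols <- which(qc != "-")                 # query-covered frame columns
  n <- length(cols)
  S <- length(candidates)
  ids <- names(candidates)
  cmat <- do.call(rbind, strsplit(unlist(candidates), ""))

  ## column cost per state: mismatch = 1; candidate-gap runs cost 1 at the
  ## run's first covered column and 0 inside the run
  cost <- matrix(0, nrow = S, ncol = n)
  for (s in seq_len(S)) {
    cb <- cmat[s, cols]
    gap <- cb == "-"
    mis <- !gap & cb != qc[cols]
    cost[s, ] <- as.numeric(mis)
    if (any(gap)) {
      r <- rle(gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cost[s, starts[r$values]] <- cost[s, starts[r$values]] + 1
    }
  }
  ## single-locus alternative
  single_tot <- rowSums(cost)
  sbest <- order(single_tot, ids, method = "radix")[1L]

  ## Viterbi
  D <- matrix(Inf, nrow = S, ncol = n)
  B <- matrix(NA_integer_, nrow = S, ncol = n)
  D[, 1] <- cost[, 1]
  if (n > 1) for (j in 2:n) {
    prevmin <- min(D[, j - 1])
    argmin <- order(D[, j - 1], ids, method = "radix")[1L]
    for (s in seq_len(S)) {
      stay <- D[s, j - 1]
      sw <- prevmin + lam
      if (stay <= sw) { D[s, j] <- stay + cost[s, j]; B[s, j] <- s }
      else { D[s, j] <- sw + cost[s, j]; B[s, j] <- argmin }
    }
  }
  last <- order(D[, n], ids, method = "radix")[1L]
  path <- integer(n); path[n] <- last
  if (n > 1) for (j in n:2) path[j - 1] <- B[path[j], j]

  ## compress to segments (query coordinates = index among covered columns)
  r <- rle(path)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ## canonicalize each breakpoint to the midpoint of its cost-tie interval:
  ## between two informative columns every placement is cost-optimal, and
  ## the midpoint is the minimax choice
  if (length(r$values) > 1L) {
    for (k in seq_len(length(r$values) - 1L)) {
      s1 <- r$values[k]; s2 <- r$values[k + 1L]
      b <- starts[k + 1L]                      # current boundary column
      lo <- b
      while (lo - 1L > starts[k] &&
             cost[s1, lo - 1L] == cost[s2, lo - 1L]) lo <- lo - 1L
      hi <- b
      while (hi <= ends[k + 1L] - 1L && cost[s1, hi] == cost[s2, hi])
        hi <- hi + 1L
      mid <- as.integer(floor((lo + hi) / 2))
      mid <- max(starts[k] + 1L, min(mid, ends[k + 1L]))
      starts[k + 1L] <- mid
      ends[k] <- mid - 1L
    }
  }
  segs <- data.frame(
    query_start = starts, query_end = ends,
    ref_start = cols[starts], ref_end = cols[ends],
    locus_id = ids[r$values],
    mismatches = vapply(seq_along(r$values), function(k)
      sum(cost[r$values[k], starts[k]:ends[k]]), numeric(1)),
    stringsAsFactors = FALSE)
  total <- sum(segs$mismatches)
  structure(list(
    segments = segs,
    breakpoints = if (nrow(segs) > 1L) segs$query_start[-1L] else integer(),
    total_mismatches = total,
    single_locus_mismatches = single_tot[sbest],
    single_locus_id = ids[sbest],
    identity_best = 1 - single_tot[sbest] / n,
    dp_cost = D[last, n]
  ), class = "MosaicAssignment")
}

#' @export
print.MosaicAssignment <- function(x, ...) {
  cat("MosaicAssignment:", nrow(x$segments), "segment(s),",
      x$total_mismatches, "mismatches (single-locus",
      x$single_locus_mismatches, "via", x$single_locus_id, ")\n")
  invisible(x)
}
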