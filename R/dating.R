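#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns with a gap in either sequence are excluded; with
#' \code{exclude_cpg}, every column that is part of a CG dinucleotide in
#' either ungapped sequence is also excluded (both positions of the
#' dinucleotide).  The distance is
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)}
#' with \eqn{P} and \eqn{Q} the transition and transversion fractions over
#' the retained columns.
#'
#' @param aln An \code{AlignedPair}, or a list/vector of two equal-length
#'   gapped strings.
#' @param exclude_cpg Exclude CpG-context columns (default TRUE).
#' @param min_sites Minimum comparable columns (default 50).
#' @return A \code{K2PResult}: list with \code{P}, \code{Q},
#'   \code{sites_used}, \code{d}, \code{excluded_cpg_columns}.
#' @export
k2p_distance <- function(aln, exclude_cpg = TRUE, min_sites = 50L) {
  if (inherits(aln, "AlignedPair")) {
    a <- aln$ref_aligned; b <- aln$qry_aligned
  } else {
    a <- aln[[1]]; b <- aln[[2]]
  }
  stopifnot(nchar(a) == nchar(b))
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  base <- c("A", "C", "G", "T")
  comparable <- ac %in% base & bc %in% base

  n_cpg_excluded <- 0L
  if (exclude_cpg) {
    cpg_mask <- function(x) {
      gapless <- x %in% c(base, "N")
      s <- x[gapless]
      m <- rep(FALSE, length(s))
      cg <- which(s[-length(s)] == "C" & s[-1] == "G")
      m[cg] <- TRUE; m[cg + 1L] <- TRUE
      out <- rep(FALSE, length(x))
      out[gapless] <- m
      out
    }
    cpg <- cpg_mask(ac) | cpg_mask(bc)
    n_cpg_excluded <- sum(cpg & comparable)
    comparable <- comparable & !cpg
  }
  n <- sum(comparable)
  if (n < min_sites)
    stop("insufficient sites: ", n, " comparable columns (< ", min_sites, ")",
         call. = FALSE)
  x <- ac[comparable]; y <- bc[comparable]
  diff <- x != y
  purine <- c("A", "G")
  is_ts <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(is_ts) / n
  Q <- sum(diff & !is_ts) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("saturated divergence: K2P correction undefined (P=",
         sprintf("%.3f", P), ", Q=", sprintf("%.3f", Q), ")", call. = FALSE)
  d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  structure(list(P = P, Q = Q, sites_used = n, d = d,
                 excluded_cpg_columns = n_cpg_excluded),
            class = "K2PResult")
}

#' Integration age from a divergence value
#'
#' Applies the molecular-clock relation \eqn{T = D\% / rate} (in million
#' years, rate 0.13 %/nt/My by default).  For the LTR-versus-LTR method the
#' result is halved, since the two LTRs of one provirus are identical at
#' integration and accumulate substitutions independently.
#'
#' @param d K2P distance (substitutions/site) or a \code{K2PResult}.
#' @param method One of \code{"ltr_vs_ltr"}, \code{"ltr_vs_consensus"},
#'   \code{"gene_vs_consensus"}.
#' @param rate Substitution rate, percent/nt/My.
#' @return Estimated age in million years.
#' @export
estimate_age <- function(d, method = c("ltr_vs_ltr", "ltr_vs_consensus",
                                       "gene_vs_consensus"),
                         rate = 0.13) {
  method <- match.arg(method)
  if (inherits(d, "K2PResult")) d <- d$d
  if (rate <= 0) stop("input error: rate must be positive", call. = FALSE)
  if (d < 0) stop("input error: negative distance", call. = FALSE)
  D_percent <- 100 * d
  T_my <- D_percent / rate
  if (method == "ltr_vs_ltr") T_my <- T_my / 2
  T_my
}

#' Aggregate per-method age estimates for one element
#'
#' Mean and sample standard deviation over the available method estimates;
#' the element is flagged low-confidence when sd/mean exceeds 0.20 (the
#' cohort-level convention is to exclude flagged elements from summaries).
#' A single estimate has sd 0 and is never flagged.
#'
#' @param estimates Numeric vector of per-method ages (My).
#' @return An \code{AgeEstimate} summary: \code{mean_my}, \code{sd_my},
#'   \code{flagged}, \code{n_methods}.
#' @export
aggregate_ages <- function(estimates) {
  estimates <- estimates[is.finite(estimates)]
  if (!length(estimates))
    stop("input error: no age estimates", call. = FALSE)
  m <- mean(estimates)
  s <- if (length(estimates) > 1L) stats::sd(estimates) else 0
  structure(list(mean_my = m, sd_my = s,
                 flagged = is.finite(s / m) && (s / m) > 0.20,
                 n_methods = length(estimates)),
            class = "AgeEstimate")
}

## frame-mediated pairwise alignment of two reference-framed strings
framed_pair <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  keep <- !(av == "-" & bv == "-")
  aligned_pair(paste(av[keep], collapse = ""), paste(bv[keep], collapse = ""))
}

#' Three-method integration dating of one element
#'
#' Computes (1) the 5'-versus-3' LTR divergence of the element (halved T),
#' (2) each LTR versus the subgroup consensus LTR, and (3) 150-300 nt gene
#' windows (gag, pro, pol RT, pol IN, env) versus the subgroup consensus,
#' each as a K2P distance with gap and CpG exclusion, then aggregates.
#'
#' @param aln Element projection onto the reference.
#' @param model Reference model.
#' @param consensus_ltr Subgroup consensus LTR in the 780-nt frame (default:
#'   the reference LTR itself).
#' @param consensus_internal Subgroup consensus in the full reference frame
#'   (default: the reference sequence), used for the gene windows.
#' @param rate Substitution rate, percent/nt/My.
#' @param gene_window Gene window width in nt (default 300; the retained
#'   portion is used when shorter).
#' @param methods Subset of methods to run.
#' @return List: \code{per_method} (data.frame method, D_percent, T_my),
#'   \code{summary} (an \code{AgeEstimate}).
#' @export
date_element <- function(aln, model, consensus_ltr = NULL,
                         consensus_internal = NULL, rate = 0.13,
                         gene_window = 300L,
                         methods = c("ltr_vs_ltr", "ltr_vs_consensus",
                                     "gene_vs_consensus")) {
  l5 <- model$landmarks[["5ltr"]]; l3 <- model$landmarks[["3ltr"]]
  f5 <- query_at_reference(aln, l5[1], l5[2])
  f3 <- query_at_reference(aln, l3[1], l3[2])
  if (is.null(consensus_ltr)) consensus_ltr <- landmark_slice(model, "5ltr")
  if (is.null(consensus_internal)) consensus_internal <- model$sequence

  rows <- list()
  try_k2p <- function(a, b, method, label) {
    res <- tryCatch(k2p_distance(framed_pair(a, b)), error = function(e) NULL)
    if (!is.null(res))
      rows[[length(rows) + 1L]] <<- data.frame(
        method = label, D_percent = 100 * res$d,
        T_my = estimate_age(res, method, rate), stringsAsFactors = FALSE)
  }
  if ("ltr_vs_ltr" %in% methods)
    try_k2p(f5, f3, "ltr_vs_ltr", "ltr_vs_ltr")
  if ("ltr_vs_consensus" %in% methods) {
    try_k2p(f5, consensus_ltr, "ltr_vs_consensus", "ltr5_vs_consensus")
    try_k2p(f3, consensus_ltr, "ltr_vs_consensus", "ltr3_vs_consensus")
  }
  if ("gene_vs_consensus" %in% methods) {
    for (g in c("gag", "pro", "pol_rt", "pol_in", "env")) {
      iv <- model$landmarks[[g]]
      mid <- floor((iv[1] + iv[2]) / 2)
      half <- min(gene_window, iv[2] - iv[1] + 1L) %/% 2L
      s <- max(iv[1], mid - half); e <- min(iv[2], mid + half)
      try_k2p(query_at_reference(aln, s, e),
              substr(consensus_internal, s, e),
              "gene_vs_consensus", paste0(g, "_vs_consensus"))
    }
  }
  per_method <- if (length(rows)) do.call(rbind, rows)
  else data.frame(method = character(), D_percent = numeric(),
                  T_my = numeric(), stringsAsFactors = FALSE)
  summary <- if (nrow(per_method)) aggregate_ages(per_method$T_my) else NULL
  list(per_method = per_method, summary = summary)
}
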