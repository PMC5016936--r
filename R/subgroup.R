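#' The LTR key-position table
#'
#' Diagnostic single-nucleotide positions in the 780-nt LTR frame that
#' separate the two subgroups: seven main-tier substitutions shared by
#' 95-100 % of subgroup-2 members and essentially absent (0-3.5 %) from
#' subgroup 1, plus the additional 2A (456 C>T, 498 A>G) and 2B (133 A>G,
#' 188 C>A, 252 C>G) tiers.
#'
#' @param path TSV path; defaults to the packaged canonical table.
#' @return data.frame with columns \code{position}, \code{ref_base},
#'   \code{alt_base}, \code{tier}.
#' @export
key_position_table <- function(path = hervw_file("key_positions.tsv")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("position", "ref_base", "alt_base", "tier") %in% names(tab)))
  tab
}

#' Genotype the key positions of one LTR
#'
#' @param aln \code{AlignedPair} of the LTR against the 780-nt LTR reference
#'   frame (reference = LTR consensus, query = the element's LTR).
#' @param table Key-position table.
#' @param ltr_kind Which structural form the LTR has; truncated pseudogenic
#'   forms restrict which positions are observable (\code{5p_RU5} observes
#'   only positions >= 256, \code{3p_U3R} only positions <= 326).
#' @param model Reference model (for the truncation anchors).
#' @return data.frame: \code{position}, \code{tier}, \code{ref_base},
#'   \code{alt_base}, \code{observed} (base, \code{"-"} for gap, \code{NA}
#'   for positions outside the truncated form).
#' @export
genotype_key_positions <- function(aln, table = key_position_table(),
                                   ltr_kind = c("5p_full", "3p_full",
                                                "5p_RU5", "3p_U3R", "solo"),
                                   model = NULL) {
  ltr_kind <- match.arg(ltr_kind)
  a5 <- if (is.null(model)) 256L else model$pseudo_5p_anchor
  a3 <- if (is.null(model)) 326L else model$pseudo_3p_anchor
  observable <- switch(ltr_kind,
                       "5p_RU5" = table$position >= a5,
                       "3p_U3R" = table$position <= a3,
                       rep(TRUE, nrow(table)))
  qc <- strsplit(aln$qry, "")[[1]]
  observed <- rep(NA_character_, nrow(table))
  for (i in which(observable)) {
    qpos <- aln$ref_map[table$position[i]]
    observed[i] <- if (is.na(qpos)) "-" else qc[qpos]
  }
  data.frame(position = table$position, tier = table$tier,
             ref_base = table$ref_base, alt_base = table$alt_base,
             observed = observed, stringsAsFactors = FALSE)
}

#' Classify an element's subgroup from its genotyped LTRs
#'
#' Pools the observable main-tier positions of both LTRs and votes:
#' subgroup 2 when the alt fraction is >= 0.6, subgroup 1 when <= 0.4
#' (at least 3 observations either way), unclassifiable in the dead zone or
#' with fewer than 3 observations.  Subgroup-2 calls are refined to 2A when
#' both observable 2A positions carry the alt and the 2B criterion is not
#' met, and to 2B when >= 2 of 3 observable 2B positions carry the alt and
#' the 2A criterion is not met; conflicts and insufficiency stay plain 2.
#'
#' @param call_5p,call_3p Genotype tables from [genotype_key_positions()]
#'   (either may be \code{NULL} when that LTR is absent).
#' @return A \code{SubgroupCall}: list with \code{label} (\code{"1"},
#'   \code{"2"}, \code{"2A"}, \code{"2B"} or \code{"unclassifiable"}),
#'   \code{n_available}, \code{n_alt} (main tier) and the pooled genotypes.
#' @export
classify_subgroup <- function(call_5p = NULL, call_3p = NULL) {
  if (is.null(call_5p) && is.null(call_3p))
    stop("input error: both LTRs absent", call. = FALSE)
  pooled <- rbind(call_5p, call_3p)
  main <- pooled[pooled$tier == "main" & !is.na(pooled$observed) &
                   pooled$observed %in% c("A", "C", "G", "T"), , drop = FALSE]
  n_av <- nrow(main)
  n_alt <- sum(main$observed == main$alt_base)
  label <- if (n_av < 3L) "unclassifiable"
  else {
    ratio <- n_alt / n_av
    if (ratio >= 0.6) "2" else if (ratio <= 0.4) "1" else "unclassifiable"
  }
  if (identical(label, "2")) {
    tier_state <- function(tier, need) {
      tt <- pooled[pooled$tier == tier & !is.na(pooled$observed) &
                     pooled$observed %in% c("A", "C", "G", "T"), , drop = FALSE]
      pos <- unique(tt$position)
      n_obs <- length(pos)
      n_hit <- sum(vapply(pos, function(p)
        any(tt$observed[tt$position == p] == tt$alt_base[tt$position == p]),
        logical(1)))
      list(met = n_obs >= need && n_hit >= need, n_obs = n_obs, n_hit = n_hit)
    }
    a <- tier_state("2A", 2L)
    b <- tier_state("2B", 2L)
    if (a$met && !b$met) label <- "2A"
    if (b$met && !a$met) label <- "2B"
  }
  structure(list(label = label, n_available = n_av, n_alt = n_alt,
                 genotypes = pooled), class = "SubgroupCall")
}

#' Majority-rule consensus of reference-framed sequences
#'
#' Per reference column: the majority base among non-gap observations, ties
#' broken toward the reference base; columns gapped in more than half of the
#' sequences emit no base (a consensus deletion).
#'
#' @param aligned_set List of \code{AlignedPair} objects sharing the same
#'   reference, or a character vector of equal-length framed strings (gap
#'   \code{"-"}).
#' @param reference The reference string (required for the tie rule when
#'   framed strings are supplied; inferred from \code{AlignedPair}s).
#' @return The consensus sequence (gaps removed).
#' @export
build_consensus <- function(aligned_set, reference = NULL) {
  if (length(aligned_set) < 2L)
    stop("input error: consensus requires >= 2 sequences", call. = FALSE)
  if (inherits(aligned_set[[1]], "AlignedPair")) {
    if (is.null(reference)) reference <- aligned_set[[1]]$ref
    framed <- vapply(aligned_set, function(a)
      query_at_reference(a, 1L, nchar(reference)), "")
  } else {
    framed <- unlist(aligned_set)
    if (is.null(reference))
      stop("reference required with framed-string input", call. = FALSE)
  }
  stopifnot(all(nchar(framed) == nchar(reference)))
  m <- do.call(rbind, strsplit(framed, ""))
  refc <- strsplit(reference, "")[[1]]
  n <- nrow(m)
  out <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    bases <- col[col %in% c("A", "C", "G", "T")]
    if (length(bases) < n - length(bases) || !length(bases)) return("")  # > 50 % gapped
    tab <- table(bases)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L && refc[j] %in% top) refc[j] else top[1L]
  }, "")
  paste(out, collapse = "")
}
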