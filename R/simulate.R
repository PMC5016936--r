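#' Specification of one simulated element
#'
#' The generator's defaults are the group's stated world: a neutral
#' substitution clock of 0.13 %/nt/My, truncation anchors 256/326 for
#' L1-processed pseudogenes, 5-15 bp target site duplications, and the
#' recurrent internal deletions observed across the group.
#'
#' @param class_label One of \code{"provirus"}, \code{"processed_pseudogene"},
#'   \code{"solo_ltr"}.
#' @param subgroup Subgroup ground truth: \code{"1"}, \code{"2"}, \code{"2A"}
#'   or \code{"2B"}.
#' @param age_my Age in million years (>= 0).
#' @param rate Substitution rate in percent/nt/My (default 0.13).
#' @param kappa Transition/transversion ratio (default 2, generic mammalian).
#' @param deletions List of reference intervals \code{c(start, end)} to excise.
#' @param tsd_length Target site duplication length, 5-15.
#' @param polyA_length Poly(A) tail length (pseudogenes), >= 8.
#' @param flank_length Genomic flank length on each side.
#' @param seed Integer seed; the truth fully determines the element.
#' @return A \code{SimulationSpec} list.
#' @export
simulation_spec <- function(class_label = c("provirus", "processed_pseudogene",
                                            "solo_ltr"),
                            subgroup = c("1", "2", "2A", "2B"),
                            age_my = 0, rate = 0.13, kappa = 2,
                            deletions = list(), tsd_length = 10L,
                            polyA_length = 12L, flank_length = 100L,
                            seed = 1L) {
  class_label <- match.arg(class_label)
  subgroup <- match.arg(as.character(subgroup), c("1", "2", "2A", "2B"))
  stopifnot(age_my >= 0, rate > 0, kappa >= 0,
            tsd_length >= 5L, tsd_length <= 15L, polyA_length >= 8L)
  structure(list(class_label = class_label, subgroup = subgroup,
                 age_my = age_my, rate = rate, kappa = kappa,
                 deletions = deletions, tsd_length = as.integer(tsd_length),
                 polyA_length = as.integer(polyA_length),
                 flank_length = as.integer(flank_length),
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Neutral substitution of a sequence under a Kimura-style process
#'
#' Each site is substituted independently with probability
#' \code{expected_divergence}; conditional on substitution, a transition is
#' chosen with probability \code{kappa/(kappa + 2)}, otherwise one of the two
#' transversions uniformly.  Length is preserved; no indels are introduced.
#'
#' @param seq DNA string.
#' @param expected_divergence Per-site substitution probability in [0, 0.75).
#' @param kappa Transition/transversion ratio.
#' @param seed Integer seed (same seed, same output).
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(seq, expected_divergence, kappa = 2, seed = 1L) {
  if (expected_divergence < 0 || expected_divergence >= 0.75)
    stop("input error: expected_divergence must lie in [0, 0.75)", call. = FALSE)
  if (expected_divergence == 0) return(seq)
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  tvers <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))
  with_seed(seed, {
    x <- strsplit(toupper(seq), "")[[1]]
    hit <- which(runif(length(x)) < expected_divergence & x %in% names(transit))
    if (length(hit)) {
      is_ts <- runif(length(hit)) < kappa / (kappa + 2)
      for (k in seq_along(hit)) {
        i <- hit[k]
        x[i] <- if (is_ts[k]) transit[[x[i]]] else sample(tvers[[x[i]]], 1L)
      }
    }
    paste(x, collapse = "")
  })
}

## positions (reference frame) of the key-position alt bases for a subgroup
.subgroup_variants <- function(subgroup, table = key_position_table()) {
  tiers <- switch(subgroup, "1" = character(), "2" = "main",
                  "2A" = c("main", "2A"), "2B" = c("main", "2B"))
  table[table$tier %in% tiers, , drop = FALSE]
}

#' Simulate one element with known ground truth
#'
#' Builds an element from the reference model by (1) installing the subgroup
#' key variants in both LTRs, (2) excising the requested deletions,
#' (3) truncating the LTRs and appending a poly(A) tail for pseudogenes (or
#' keeping a single LTR for solo LTRs), (4) mutating the element under the
#' neutral clock with an independent substream per LTR, and (5) synthesizing
#' random flanks that carry the target site duplication, plus the TT/AAAA
#' junction for pseudogenes.
#'
#' @param model A [load_reference()] model.
#' @param spec A [simulation_spec()].
#' @return A \code{SimulatedElement}: list with \code{id}, \code{sequence},
#'   \code{flank5}, \code{flank3} and a \code{truth} record (the spec plus
#'   realized mutation counts, realized LTR-LTR divergence, the TSD, and the
#'   element-coordinate intervals of both LTR portions).
#' @export
simulate_element <- function(model, spec) {
  stopifnot(inherits(model, "ReferenceModel"), inherits(spec, "SimulationSpec"))
  sub_seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, 5L))

  l5 <- model$landmarks[["5ltr"]]; l3 <- model$landmarks[["3ltr"]]
  chars <- strsplit(model$sequence, "")[[1]]
  vars <- .subgroup_variants(spec$subgroup)
  if (nrow(vars)) {
    chars[l5[1] - 1L + vars$position] <- vars$alt_base
    chars[l3[1] - 1L + vars$position] <- vars$alt_base
  }

  keep <- rep(TRUE, model$length)
  for (iv in spec$deletions) keep[iv[1]:iv[2]] <- FALSE
  if (spec$class_label == "provirus") {
    u3_5p <- l5[1]:(l5[1] - 1L + model$ltr_regions$u3[2])
    u5_3p <- (l3[1] - 1L + model$ltr_regions$u5[1]):l3[2]
    if (!any(keep[u3_5p]) && !any(keep[u5_3p]))
      warning("will be unclassifiable: deletions cover both LTR diagnostic regions",
              call. = FALSE)
  }
  if (spec$class_label == "processed_pseudogene") {
    keep[l5[1]:(l5[1] - 2L + model$pseudo_5p_anchor)] <- FALSE  # lose U3 of 5' LTR
    keep[(l3[1] + model$pseudo_3p_anchor):model$length] <- FALSE # lose U5 of 3' LTR
  }
  if (spec$class_label == "solo_ltr") {
    keep[] <- FALSE
    keep[l5[1]:l5[2]] <- TRUE
  }
  coords <- which(keep)

  ## mutate with independent substreams: 5' LTR, 3' LTR, internal
  in5 <- coords >= l5[1] & coords <= l5[2]
  in3 <- coords >= l3[1] & coords <= l3[2]
  div <- spec$rate * spec$age_my / 100
  piece <- function(ix, sd) {
    if (!any(ix)) return(character())
    s <- mutate_sequence(paste(chars[coords[ix]], collapse = ""), div,
                         spec$kappa, sd)
    strsplit(s, "")[[1]]
  }
  out <- character(length(coords))
  out[in5] <- piece(in5, sub_seeds[1])
  out[in3] <- piece(in3, sub_seeds[2])
  out[!(in5 | in3)] <- piece(!(in5 | in3), sub_seeds[3])

  n_mut_5 <- sum(out[in5] != chars[coords[in5]])
  n_mut_3 <- sum(out[in3] != chars[coords[in3]])
  ## realized LTR-LTR divergence over the shared frame (full LTRs for
  ## proviruses; only meaningful when both LTR portions exist)
  realized_div <- NA_real_
  if (spec$class_label == "provirus" && any(in5) && any(in3)) {
    f5 <- coords[in5] - l5[1] + 1L
    f3 <- coords[in3] - l3[1] + 1L
    shared <- intersect(f5, f3)
    if (length(shared)) {
      a <- out[in5][match(shared, f5)]
      b <- out[in3][match(shared, f3)]
      realized_div <- mean(a != b)
    }
  }

  sequence <- paste(out, collapse = "")
  if (spec$class_label == "processed_pseudogene")
    sequence <- paste0(sequence, strrep("A", spec$polyA_length))

  ## flanks with TSD; pseudogenes get the L1 TT/AAAA endonuclease signature
  flanks <- with_seed(sub_seeds[4], {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    if (spec$class_label == "processed_pseudogene") {
      tsd <- paste0("AAAA", rand(spec$tsd_length - 4L))
      f5 <- paste0(rand(spec$flank_length - spec$tsd_length - 2L), "TT", tsd)
    } else {
      tsd <- rand(spec$tsd_length)
      f5 <- paste0(rand(spec$flank_length - spec$tsd_length), tsd)
    }
    f3 <- paste0(tsd, rand(spec$flank_length - spec$tsd_length))
    list(f5 = f5, f3 = f3, tsd = tsd)
  })

  ltr5_iv <- if (any(in5)) range(which(in5)) else NULL
  ltr3_iv <- if (any(in3)) range(which(in3)) else NULL
  structure(list(
    id = sprintf("sim_%s_sg%s_%dMy_seed%d", spec$class_label, spec$subgroup,
                 round(spec$age_my), spec$seed),
    sequence = sequence, flank5 = flanks$f5, flank3 = flanks$f3,
    truth = list(spec = spec, tsd = flanks$tsd,
                 n_mut_ltr5 = n_mut_5, n_mut_ltr3 = n_mut_3,
                 realized_ltr_divergence = realized_div,
                 ltr5_element_interval = ltr5_iv,
                 ltr3_element_interval = ltr3_iv,
                 element_ref_coords = coords)
  ), class = "SimulatedElement")
}

#' Simulate a recombinant (chimeric) transcript
#'
#' Builds a template-switch chimera from two locus sequences placed on a
#' common coordinate frame (equal-length strings, gaps allowed).  Segments
#' alternate A/B at the given breakpoints: positions \code{1..b1} come from A,
#' \code{b1+1..b2} from B, and so on.
#'
#' @param locusA,locusB Equal-length frame strings.
#' @param breakpoints Strictly increasing frame positions (possibly empty).
#' @param seed Seed for the optional per-base copy error process.
#' @param error_rate Per-base error probability of the copying process
#'   (default 0: exact template switching).
#' @return The chimeric frame string (same length as the inputs).
#' @export
simulate_recombinant_transcript <- function(locusA, locusB,
                                            breakpoints = integer(),
                                            seed = 1L, error_rate = 0) {
  n <- nchar(locusA)
  if (nchar(locusB) != n)
    stop("input error: loci must be pre-aligned to a common frame ",
         "(equal length)", call. = FALSE)
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints)) {
    if (any(diff(breakpoints) <= 0))
      stop("input error: breakpoints must be strictly increasing", call. = FALSE)
    if (min(breakpoints) < 1L || max(breakpoints) >= n)
      stop("input error: breakpoint outside shared aligned span", call. = FALSE)
  }
  bounds <- c(0L, breakpoints, n)
  a <- strsplit(locusA, "")[[1]]; b <- strsplit(locusB, "")[[1]]
  out <- a
  for (k in seq_len(length(bounds) - 1L)) {
    if (k %% 2L == 0L) {
      ix <- (bounds[k] + 1L):bounds[k + 1L]
      out[ix] <- b[ix]
    }
  }
  if (error_rate > 0)
    out <- strsplit(mutate_sequence(paste(out, collapse = ""), error_rate,
                                    kappa = 2, seed = seed), "")[[1]]
  paste(out, collapse = "")
}

#' Simulate a cohort of elements
#'
#' @param model Reference model.
#' @param n Number of elements.
#' @param class_labels,subgroups Vectors recycled over elements.
#' @param ages Ages in My (recycled); default uniform 10-40 My.
#' @param deletion_prob Probability that each recurrent deletion is applied.
#' @param seed Cohort seed.
#' @return List with \code{elements} (list of \code{SimulatedElement}) and
#'   \code{truth} (data.frame: id, class, subgroup, age_my, seed, tsd,
#'   deletions).
#' @export
simulate_cohort <- function(model, n, class_labels = "provirus",
                            subgroups = "1", ages = NULL,
                            deletion_prob = 0, seed = 1L) {
  params <- with_seed(seed, {
    list(ages = if (is.null(ages)) runif(n, 10, 40) else rep_len(ages, n),
         seeds = sample.int(.Machine$integer.max - 1L, n),
         tsd = sample(5:15, n, replace = TRUE),
         del = matrix(runif(n * length(model$recurrent_deletions)) < deletion_prob,
                      nrow = n))
  })
  class_labels <- rep_len(class_labels, n)
  subgroups <- rep_len(subgroups, n)
  elements <- vector("list", n)
  for (i in seq_len(n)) {
    dels <- model$recurrent_deletions[params$del[i, ]]
    sp <- simulation_spec(class_labels[i], subgroups[i],
                          age_my = params$ages[i], deletions = dels,
                          tsd_length = params$tsd[i], seed = params$seeds[i])
    elements[[i]] <- simulate_element(model, sp)
    elements[[i]]$id <- sprintf("el%03d_%s", i, elements[[i]]$id)
  }
  truth <- data.frame(
    id = vapply(elements, `[[`, "", "id"),
    class = class_labels, subgroup = subgroups,
    age_my = params$ages, seed = params$seeds, tsd = params$tsd,
    deletions = vapply(seq_len(n), function(i)
      paste(vapply(model$recurrent_deletions[params$del[i, ]],
                   function(iv) paste(iv, collapse = "-"), ""), collapse = ";"),
      ""),
    stringsAsFactors = FALSE)
  list(elements = elements, truth = truth)
}

#' Write a simulated cohort to FASTA plus a truth table
#'
#' By default the FASTA holds the element sequences and the flanks travel as
#' columns of the truth table (mirroring how real loci come with separate
#' flanking context); with \code{include_flanks = TRUE} the insert is written
#' as one flank5-element-flank3 string.
#'
#' @param cohort From [simulate_cohort()].
#' @param fasta,truth_tsv Output paths.
#' @param include_flanks Concatenate flanks into the FASTA records.
#' @export
write_cohort <- function(cohort, fasta, truth_tsv, include_flanks = FALSE) {
  seqs <- lapply(cohort$elements, function(e)
    if (include_flanks) paste0(e$flank5, e$sequence, e$flank3) else e$sequence)
  names(seqs) <- vapply(cohort$elements, `[[`, "", "id")
  write_fasta(seqs, fasta)
  truth <- cohort$truth
  truth$flank5 <- vapply(cohort$elements, `[[`, "", "flank5")
  truth$flank3 <- vapply(cohort$elements, `[[`, "", "flank3")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}
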