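#' Run the end-to-end characterization pipeline
#'
#' Projects every element onto the reference and runs structural annotation,
#' subgroup classification, dating, PBS/motif features and (optionally) Env
#' putein reconstruction, producing one master table row per element.
#' Stage failures are recorded per element and do not stop the run.
#'
#' @param elements List of elements, each a list with \code{id},
#'   \code{sequence} and optional \code{flank5}, \code{flank3} (the
#'   \code{elements} of a [simulate_cohort()] work directly), or a FASTA
#'   path (then flanks are unknown).
#' @param model Reference model.
#' @param out_dir Optional output directory: writes \code{master.tsv},
#'   per-subgroup consensus FASTA and a JSON run log (with a config hash).
#' @param run_putein Reconstruct Env puteins for elements retaining env.
#' @param rate Substitution rate for dating.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return List: \code{master} (data.frame), \code{errors} (per-element
#'   character), \code{consensus} (named list by subgroup).
#' @export
run_pipeline <- function(elements, model, out_dir = NULL,
                         run_putein = FALSE, rate = 0.13, seed = 1L) {
  if (is.character(elements) && length(elements) == 1L) {
    seqs <- read_fasta(elements)
    elements <- lapply(names(seqs), function(id)
      list(id = id, sequence = seqs[[id]], flank5 = "", flank3 = ""))
  }
  kp <- key_position_table()
  lib <- trna_library()
  ltr_ref <- landmark_slice(model, "5ltr")
  rows <- list(); errors <- character(); alns <- list(); subs <- character()

  for (el in elements) {
    res <- tryCatch({
      aln <- project_to_reference(model, el$sequence)
      ann <- annotate_structure(el, model, aln = aln)
      ## genotype whichever LTRs are present, in the 780-nt LTR frame
      g <- ltr_geometry(aln, model)
      geno <- function(iv, present, kind) {
        if (!present) return(NULL)
        s <- query_span(aln, iv[1], iv[2])
        if (nchar(s) < 30L) return(NULL)
        genotype_key_positions(global_align(ltr_ref, s), kp, kind, model)
      }
      kind5 <- if (ann$ltr5_form == "R-U5") "5p_RU5" else "5p_full"
      kind3 <- if (ann$ltr3_form == "U3-R") "3p_U3R" else "3p_full"
      g5 <- geno(model$landmarks[["5ltr"]], g$ltr5$any, kind5)
      g3 <- geno(model$landmarks[["3ltr"]], g$ltr3$any, kind3)
      sg <- if (is.null(g5) && is.null(g3))
        list(label = "unclassifiable") else classify_subgroup(g5, g3)
      dating <- date_element(aln, model, rate = rate)
      pbs <- find_pbs(aln, model, lib)
      put <- NULL
      env_frac <- ann$retention$fraction[ann$retention$landmark == "env"]
      if (run_putein && length(env_frac) && env_frac >= 0.5) {
        ei <- model$landmarks[["env"]]
        env_nt <- query_span(aln, ei[1], ei[2])
        put <- tryCatch(reconstruct_putein(env_nt), error = function(e) NULL)
      }
      ret <- stats::setNames(ann$retention$fraction, ann$retention$landmark)
      row <- data.frame(
        id = el$id, label = ann$label,
        ltr5_form = ann$ltr5_form, ltr3_form = ann$ltr3_form,
        subgroup = sg$label,
        ret_5ltr = ret[["5ltr"]], ret_gag = ret[["gag"]],
        ret_propol = ret[["pro-pol"]], ret_env = ret[["env"]],
        ret_3ltr = ret[["3ltr"]],
        n_indels = nrow(ann$indels),
        indels = paste(sprintf("%s%d-%d(%d)",
                               ifelse(ann$indels$kind == "deletion", "D", "I"),
                               ann$indels$ref_start, ann$indels$ref_end,
                               ann$indels$length), collapse = ";"),
        polyA = ann$signatures$polyA,
        tsd = ann$signatures$tsd %||% NA_character_,
        tt_aaaa = isTRUE(ann$signatures$tt_aaaa),
        pbs = pbs$assignment,
        age_mean_my = if (is.null(dating$summary)) NA_real_
                      else dating$summary$mean_my,
        age_sd_my = if (is.null(dating$summary)) NA_real_
                    else dating$summary$sd_my,
        age_flagged = if (is.null(dating$summary)) NA
                      else dating$summary$flagged,
        putein_len = if (is.null(put)) NA_integer_ else put$length_aa,
        putein_stops = if (is.null(put)) NA_integer_ else put$n_internal_stops,
        putein_shifts = if (is.null(put)) NA_integer_ else put$n_frameshifts,
        stringsAsFactors = FALSE)
      list(row = row, framed = query_at_reference(aln, 1L, model$length))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[el$id] <- conditionMessage(res)
    } else {
      rows[[el$id]] <- res$row
      alns[[el$id]] <- res$framed   # reference-framed element string
      subs[el$id] <- res$row$subgroup
    }
  }
  master <- if (length(rows)) do.call(rbind, rows)
  else data.frame()
  rownames(master) <- NULL

  ## per-subgroup consensus over elements with a clean subgroup label
  consensus <- list()
  for (sgl in intersect(unique(subs), c("1", "2", "2A", "2B"))) {
    ids <- names(subs)[subs == sgl]
    if (length(ids) >= 2L)
      consensus[[sgl]] <- build_consensus(alns[ids],
                                          reference = model$sequence)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(master, file.path(out_dir, "master.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(consensus))
      write_fasta(stats::setNames(unlist(consensus),
                                  paste0("consensus_subgroup", names(consensus))),
                  file.path(out_dir, "consensus.fasta"))
    cfg <- list(rate = rate, seed = seed, n_elements = length(elements),
                package_version = as.character(utils::packageVersion("hervw")))
    tmp <- tempfile(); jsonlite::write_json(cfg, tmp, auto_unbox = TRUE)
    cfg$config_md5 <- unname(tools::md5sum(tmp)); unlink(tmp)
    cfg$errors <- as.list(errors)
    jsonlite::write_json(cfg, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(master = master, errors = errors, consensus = consensus)
}
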