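#' Load the group reference model
#'
#' Reads the group consensus (an LTR-internal-LTR assembly, canonical model
#' 10,186 nt) together with its landmark configuration and returns a validated
#' \code{ReferenceModel}.  The model is the single source of truth for every
#' fixed coordinate the pipeline uses: gene intervals, LTR subregions (U3, R,
#' U5), motif positions, the PBS window, the pseudogene truncation anchors and
#' the recurrent internal deletions.  All coordinates are 1-based and
#' inclusive on both ends, matching the consensus numbering used throughout
#' the literature on this group.
#'
#' @param consensus_fasta Path to a single-record FASTA with the consensus.
#' @param landmarks_config Path to the landmark JSON configuration.
#' @return An object of class \code{ReferenceModel}: a list with fields
#'   \code{sequence}, \code{length}, \code{landmarks} (named list of
#'   \code{c(start, end)}), \code{ltr_length}, \code{pseudo_5p_anchor},
#'   \code{pseudo_3p_anchor}, \code{pbs_window}, \code{ltr_regions} and
#'   \code{recurrent_deletions}.
#' @examples
#' model <- load_reference()
#' model$length
#' model$landmarks$env
#' @export
load_reference <- function(consensus_fasta = hervw_file("synthetic_reference.fasta"),
                           landmarks_config = hervw_file("landmarks.json")) {
  seqs <- read_fasta(consensus_fasta)
  if (length(seqs) != 1L)
    stop("single record required: consensus FASTA contains ", length(seqs),
         " records", call. = FALSE)
  sequence <- toupper(seqs[[1L]])
  L <- nchar(sequence)

  cfg <- jsonlite::read_json(landmarks_config, simplifyVector = TRUE)
  required <- c("5ltr", "gag", "pro-pol", "env", "3ltr")
  missing <- setdiff(required, names(cfg$landmarks))
  if (length(missing))
    stop("missing landmark: ", paste(missing, collapse = ", "), call. = FALSE)

  landmarks <- lapply(cfg$landmarks, function(x) as.integer(x))
  for (nm in names(landmarks)) {
    iv <- landmarks[[nm]]
    if (length(iv) != 2L || is.na(iv[1]) || is.na(iv[2]) || iv[1] > iv[2])
      stop("malformed landmark interval: ", nm, call. = FALSE)
    if (iv[1] < 1L || iv[2] > L)
      stop("interval out of bounds: ", nm, " (", iv[1], "-", iv[2],
           " on ", L, "-nt reference)", call. = FALSE)
  }
  ltr_length <- as.integer(cfg$ltr_length)
  len5 <- diff(landmarks[["5ltr"]]) + 1L
  len3 <- diff(landmarks[["3ltr"]]) + 1L
  if (len5 != ltr_length || len3 != ltr_length)
    stop("LTR length mismatch: 5ltr=", len5, " 3ltr=", len3,
         " ltr_length=", ltr_length, call. = FALSE)

  a5 <- as.integer(cfg$pseudo_5p_anchor)
  a3 <- as.integer(cfg$pseudo_3p_anchor)
  ## the 5' truncation anchor (start of R-U5) must precede the 3' anchor
  ## (end of U3-R): the overlap a5..a3 is the R region shared by both forms
  if (!(1L <= a5 && a5 < a3 && a3 <= ltr_length))
    stop("truncation anchors violate 1 <= pseudo_5p_anchor < pseudo_3p_anchor <= ltr_length",
         call. = FALSE)

  dels <- cfg$recurrent_deletions
  if (is.matrix(dels)) dels <- lapply(seq_len(nrow(dels)), function(i) as.integer(dels[i, ]))
  model <- structure(list(
    sequence = sequence,
    length = L,
    landmarks = landmarks,
    ltr_length = ltr_length,
    pseudo_5p_anchor = a5,
    pseudo_3p_anchor = a3,
    pbs_window = as.integer(cfg$pbs_window),
    ltr_regions = lapply(cfg$ltr_regions, as.integer),
    recurrent_deletions = dels
  ), class = "ReferenceModel")
  model
}

#' Extract the subsequence of a named landmark
#'
#' @param model A \code{ReferenceModel}.
#' @param name Landmark name, e.g. \code{"env"} or \code{"5ltr"}.
#' @return The reference subsequence over the landmark interval.
#' @export
landmark_slice <- function(model, name) {
  stopifnot(inherits(model, "ReferenceModel"))
  iv <- model$landmarks[[name]]
  if (is.null(iv)) stop("unknown landmark: ", name, call. = FALSE)
  substr(model$sequence, iv[1], iv[2])
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat("ReferenceModel:", x$length, "nt,", length(x$landmarks), "landmarks,",
      "LTR", x$ltr_length, "nt\n")
  invisible(x)
}

#' Path to a packaged data file
#' @param ... File name components under the package's \code{extdata}.
#' @export
hervw_file <- function(...) {
  system.file("extdata", ..., package = "hervw", mustWork = TRUE)
}

## ---- plain FASTA I/O (used for small text fixtures and outputs) ----------

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector or list of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- unlist(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    cat(">", nm, "\n", sep = "", file = con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## internal: run expr with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
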