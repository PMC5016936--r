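#' p-distance matrix with pairwise deletion
#'
#' For each pair of reference-framed sequences: mismatches divided by the
#' number of columns where both carry a base (pairwise deletion).
#'
#' @param aligned_set Named character vector (or list) of equal-length framed
#'   strings (gap \code{"-"}), or a list of \code{AlignedPair}s sharing one
#'   reference.
#' @param min_overlap Minimum shared columns per pair (default 30).
#' @return A \code{DistanceMatrix}: symmetric numeric matrix with labels.
#' @export
p_distance_matrix <- function(aligned_set, min_overlap = 30L) {
  if (inherits(aligned_set[[1]], "AlignedPair")) {
    L <- nchar(aligned_set[[1]]$ref)
    framed <- vapply(aligned_set, function(a) query_at_reference(a, 1L, L), "")
  } else framed <- unlist(aligned_set)
  n <- length(framed)
  if (n < 3L) stop("input error: need >= 3 sequences", call. = FALSE)
  if (is.null(names(framed)) || anyDuplicated(names(framed)))
    names(framed) <- paste0("seq", seq_len(n))
  m <- do.call(rbind, strsplit(framed, ""))
  isbase <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(framed), names(framed)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- isbase[i, ] & isbase[j, ]
    nb <- sum(both)
    if (nb < min_overlap)
      stop("insufficient overlap between ", names(framed)[i], " and ",
           names(framed)[j], " (", nb, " shared columns)", call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / nb
  }
  structure(d, class = c("DistanceMatrix", "matrix", "array"))
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Own implementation of the canonical agglomerative algorithm with
#' deterministic tie-breaking (among minimal Q values, the lexicographically
#' smallest label pair is joined).  Negative branch lengths are clamped to 0
#' and counted.
#'
#' @param dm Symmetric distance matrix with row/col labels (n >= 3).
#' @return A \code{PhyloTree}: list with \code{phylo} (an \pkg{ape} tree,
#'   unrooted with a trifurcating root), \code{newick} and
#'   \code{n_negative_clamped}.
#' @export
nj_tree <- function(dm) {
  dm <- unclass(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("input error: non-symmetric matrix", call. = FALSE)
  n <- nrow(dm)
  stopifnot(n >= 3L)
  labels <- rownames(dm)
  ## each active cluster is a newick fragment string plus its label key
  frag <- labels
  key <- labels
  d <- dm
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; x <- 0 }
    sprintf("%.10g", x)
  }
  while (nrow(d) > 3L) {
    nn <- nrow(d)
    r <- rowSums(d)
    q <- (nn - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12 & upper.tri(q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      pair_key <- apply(cand, 1L, function(ix)
        paste(sort(c(key[ix[1]], key[ix[2]])), collapse = "\r"))
      cand <- cand[order(pair_key, method = "radix")[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
                      fmt(lj), ")")
    newkey <- min(key[i], key[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(d2) <- colnames(d2) <- key
    d <- d2
  }
  ## final three clusters join at the central node (three-point formulas)
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nw <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
               ",", frag[3], ":", fmt(lc), ");")
  phy <- ape::read.tree(text = nw)
  structure(list(phylo = phy, newick = nw, n_negative_clamped = clamped),
            class = "PhyloTree")
}

#' @export
print.PhyloTree <- function(x, ...) {
  cat("PhyloTree:", length(x$phylo$tip.label), "tips")
  if (x$n_negative_clamped)
    cat(",", x$n_negative_clamped, "negative branch(es) clamped")
  cat("\n")
  invisible(x)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; a split is canonicalized as
#' the sorted labels of the side not containing the alphabetically first
#' leaf, pasted with "|".
#'
#' @param phy An \pkg{ape} \code{phylo} object.
#' @return Character vector of canonical split keys (possibly empty), with
#'   the corresponding edge lengths as the \code{"lengths"} attribute.
#' @export
tree_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  anchor <- tips[1L]
  ntip <- length(phy$tip.label)
  out <- character(); lens <- numeric()
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    if (child <= ntip) next                       # pendant edge: trivial
    clade <- ape::extract.clade(phy, child)$tip.label
    side <- if (anchor %in% clade) setdiff(phy$tip.label, clade) else clade
    if (length(side) < 2L || length(side) > ntip - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
    lens <- c(lens, if (is.null(phy$edge.length)) NA_real_
              else phy$edge.length[e])
  }
  attr(out, "lengths") <- lens
  out
}

#' Column-resampling bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' fraction of replicates containing its bipartition.  Replicates in which a
#' pairwise distance is undefined (insufficient overlap) are dropped and
#' counted; more than 20 % dropped is an error.  Splits carried by
#' zero-length edges of the full-data tree are reported with support 1.0
#' (degenerate identical-sequence policy).
#'
#' @param aligned_set Framed strings as in [p_distance_matrix()].
#' @param n_reps Number of replicates (the group convention is 500; tests
#'   use 100 for speed).
#' @param seed Integer seed.
#' @param min_overlap Passed to [p_distance_matrix()].
#' @return A \code{PhyloTree} whose \code{phylo} has node labels carrying
#'   supports in [0,1], plus \code{supports} (named vector by split key) and
#'   \code{n_dropped}.
#' @export
bootstrap_support <- function(aligned_set, n_reps = 500L, seed = 1L,
                              min_overlap = 30L) {
  stopifnot(n_reps >= 1L)
  if (inherits(aligned_set[[1]], "AlignedPair")) {
    L <- nchar(aligned_set[[1]]$ref)
    framed <- vapply(aligned_set, function(a) query_at_reference(a, 1L, L), "")
  } else framed <- unlist(aligned_set)
  full <- nj_tree(p_distance_matrix(framed, min_overlap))
  splits <- tree_splits(full$phylo)
  counts <- stats::setNames(rep(0, length(splits)), splits)
  ncol_aln <- nchar(framed[[1]])
  chars <- do.call(rbind, strsplit(framed, ""))
  dropped <- 0L
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))
  for (b in seq_len(n_reps)) {
    cols <- with_seed(rep_seeds[b], sample.int(ncol_aln, ncol_aln, replace = TRUE))
    resampled <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(resampled) <- names(framed)
    tr <- tryCatch(nj_tree(p_distance_matrix(resampled, min_overlap)),
                   error = function(e) NULL)
    if (is.null(tr)) { dropped <- dropped + 1L; next }
    hit <- splits %in% tree_splits(tr$phylo)
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > 0.2 * n_reps)
    stop("bootstrap failed: ", dropped, "/", n_reps,
         " replicates dropped (> 20 %)", call. = FALSE)
  eff <- n_reps - dropped
  supports <- if (eff > 0) counts / eff else counts
  zl <- attr(splits, "lengths") == 0
  supports[zl] <- 1.0
  ## attach supports as internal node labels
  phy <- full$phylo
  ntip <- length(phy$tip.label)
  node_lab <- rep("", phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    if (child <= ntip) next
    clade <- ape::extract.clade(phy, child)$tip.label
    anchor <- sort(phy$tip.label)[1L]
    side <- if (anchor %in% clade) setdiff(phy$tip.label, clade) else clade
    k <- paste(sort(side), collapse = "|")
    if (k %in% names(supports))
      node_lab[child - ntip] <- sprintf("%.3f", supports[[k]])
  }
  phy$node.label <- node_lab
  out <- full
  out$phylo <- phy
  out$newick <- ape::write.tree(phy)
  out$supports <- supports
  out$n_dropped <- dropped
  out
}

#' Write a distance matrix in square PHYLIP format
#' @param dm Distance matrix.
#' @param path Output path.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(formatC(rownames(dm)[i], width = -10),
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  invisible(path)
}
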