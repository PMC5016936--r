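# Independent oracles: deliberately naive implementations used to check the
# package's optimized code paths.

# plain-R affine-gap global alignment score (Gotoh), same cost convention as
# the package: gap of length k costs |open| + k |extend|; N scores 0
oracle_nw_score <- function(ref, qry, match = 1, mismatch = -2,
                            open = -5, ext = -1) {
  r <- strsplit(ref, "")[[1]]; q <- strsplit(qry, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- open + ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- open + ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (r[i - 1] == "N" || q[j - 1] == "N") 0
         else if (r[i - 1] == q[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] + open + ext, X[i - 1, j] + ext,
                   Y[i - 1, j] + open + ext)
    Y[i, j] <- max(M[i, j - 1] + open + ext, X[i, j - 1] + open + ext,
                   Y[i, j - 1] + ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# column-by-column K2P audit on two gapped strings
oracle_k2p <- function(a, b, exclude_cpg = TRUE) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  cpg_cols <- function(x) {
    res <- rep(FALSE, length(x))
    gapless_idx <- which(x %in% c(bases, "N"))
    s <- x[gapless_idx]
    for (k in seq_len(length(s) - 1)) {
      if (s[k] == "C" && s[k + 1] == "G") {
        res[gapless_idx[k]] <- TRUE
        res[gapless_idx[k + 1]] <- TRUE
      }
    }
    res
  }
  excl <- if (exclude_cpg) cpg_cols(ac) | cpg_cols(bc) else rep(FALSE, length(ac))
  P <- Q <- 0L; n <- 0L
  for (k in seq_along(ac)) {
    if (!(ac[k] %in% bases) || !(bc[k] %in% bases) || excl[k]) next
    n <- n + 1L
    if (ac[k] != bc[k]) {
      pur <- c("A", "G")
      if ((ac[k] %in% pur) == (bc[k] %in% pur)) P <- P + 1L else Q <- Q + 1L
    }
  }
  if (n == 0) return(list(n = 0L, d = NA_real_))
  p <- P / n; q <- Q / n
  list(n = n, P = p, Q = q,
       d = -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q))
}

# explicit sliding-window zinc-finger scan (structure check, no regex)
oracle_zf_scan <- function(protein, spacer1) {
  # C X2 C X<spacer1> H X4 C
  x <- strsplit(protein, "")[[1]]
  len <- 1 + 2 + 1 + spacer1 + 1 + 4 + 1
  hits <- integer()
  i <- 1
  while (i + len - 1 <= length(x)) {
    ok <- x[i] == "C" && x[i + 3] == "C" && x[i + 4 + spacer1] == "H" &&
      x[i + len - 1] == "C"
    if (ok) { hits <- c(hits, i); i <- i + len } else i <- i + 1
  }
  as.integer(hits)
}

# random unrooted binary tree on n taxa; returns the additive distance
# matrix and the set of non-trivial splits
oracle_random_additive <- function(n, seed) {
  hervw:::with_seed(seed, {
    labels <- paste0("t", seq_len(n))
    topo <- ape::rtree(n, rooted = FALSE, tip.label = labels)
    topo$edge.length <- stats::runif(nrow(topo$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(topo)
    dm <- dm[labels, labels]
    list(tree = topo, dm = dm, splits = sort(tree_splits(topo)))
  })
}

# exhaustive mosaic segmentation (<= max_bp breakpoints) over an explicit
# per-state column cost matrix
oracle_segmentation <- function(cost, lambda, max_bp = 2) {
  n <- ncol(cost); S <- nrow(cost)
  cum <- t(apply(cost, 1, cumsum))
  seg_cost <- function(s, a, b) cum[s, b] - (if (a > 1) cum[s, a - 1] else 0)
  best <- Inf
  # 0 breakpoints
  for (s in 1:S) best <- min(best, seg_cost(s, 1, n))
  if (max_bp >= 1 && n >= 2) for (b1 in 2:n) for (s1 in 1:S) for (s2 in 1:S) {
    if (s1 == s2) next
    best <- min(best, seg_cost(s1, 1, b1 - 1) + seg_cost(s2, b1, n) + lambda)
  }
  if (max_bp >= 2 && n >= 3) for (b1 in 2:(n - 1)) for (b2 in (b1 + 1):n)
    for (s1 in 1:S) for (s2 in 1:S) for (s3 in 1:S) {
      if (s1 == s2 || s2 == s3) next
      best <- min(best, seg_cost(s1, 1, b1 - 1) + seg_cost(s2, b1, b2 - 1) +
                    seg_cost(s3, b2, n) + 2 * lambda)
    }
  best
}

# per-state column cost matrix exactly as segment_query defines it
mosaic_cost_matrix <- function(query, candidates) {
  qc <- strsplit(query, "")[[1]]
  cols <- which(qc != "-")
  S <- length(candidates)
  cost <- matrix(0, nrow = S, ncol = length(cols))
  for (s in seq_len(S)) {
    cb <- strsplit(candidates[[s]], "")[[1]][cols]
    gap <- cb == "-"
    cost[s, ] <- as.numeric(!gap & cb != qc[cols])
    if (any(gap)) {
      r <- rle(gap)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      cost[s, starts[r$values]] <- cost[s, starts[r$values]] + 1
    }
  }
  cost
}

# brute-force per-base interval relation for the context oracle
oracle_context_relation <- function(lstart, lend, exon_ivs, intron_ivs) {
  pos <- lstart:lend
  in_ex <- any(vapply(exon_ivs, function(iv)
    any(pos >= iv[1] & pos <= iv[2]), logical(1)))
  in_in <- any(vapply(intron_ivs, function(iv)
    any(pos >= iv[1] & pos <= iv[2]), logical(1)))
  if (in_ex && in_in) "mixed" else if (in_ex) "exonic"
  else if (in_in) "intronic" else "intergenic"
}
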