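# --- progressive alignment -------------------------------------------------

kmer_set <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# fraction of shared k-mers relative to the smaller set
kmer_distance_matrix <- function(seqs, k = 3L) {
  sets <- lapply(seqs, kmer_set, k = k)
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / max(1L, min(length(sets[[i]]),
                                                   length(sets[[j]])))
  }
  d
}

profile_freqs <- function(m) {
  # 20 x ncol residue frequency matrix (gaps carry zero mass)
  apply(m, 2L, function(col) {
    tabulate(match(col, AA_ALPHABET), 20L) / length(col)
  })
}

merge_alignment_groups <- function(m1, m2, gap_open, gap_extend) {
  B <- blosum62()
  P1 <- profile_freqs(m1); P2 <- profile_freqs(m2)
  if (is.null(dim(P1))) P1 <- matrix(P1, nrow = 20L)
  if (is.null(dim(P2))) P2 <- matrix(P2, nrow = 20L)
  S <- t(P1) %*% B %*% P2
  res <- affine_global_dp(S, gap_open, gap_extend)
  n1 <- nrow(m1); n2 <- nrow(m2)
  i <- 0L; j <- 0L
  cols <- vector("list", length(res$path))
  for (k in seq_along(res$path)) {
    st <- res$path[k]
    if (st == "M") { i <- i + 1L; j <- j + 1L; cols[[k]] <- c(m1[, i], m2[, j]) }
    else if (st == "X") { i <- i + 1L; cols[[k]] <- c(m1[, i], rep("-", n2)) }
    else { j <- j + 1L; cols[[k]] <- c(rep("-", n1), m2[, j]) }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- c(rownames(m1), rownames(m2))
  out
}

#' Progressive multiple alignment
#'
#' Desk-scale progressive aligner: a guide tree is built by average-linkage
#' clustering of k-mer distances (k = 3) over the input sequences sorted by
#' id (so the result does not depend on input order; ties resolve
#' lexicographically), then groups are merged by global profile–profile
#' alignment with affine gap penalties over BLOSUM62.
#'
#' @param records A `protein_set` with at least two rows.
#' @param gap_open,gap_extend Gap penalties (defaults 10 and 1, BLOSUM62
#'   half-bit units).
#' @return An `msa`; degapping any row recovers the corresponding input
#'   sequence.  Rows are ordered by id.
#' @export
align_progressive <- function(records, gap_open = 10, gap_extend = 1) {
  if (nrow(records) < 2L) stop("alignment needs at least two sequences")
  ord <- order(records$id)
  ids <- records$id[ord]; seqs <- records$residues[ord]
  n <- length(ids)
  if (n == 2L) {
    p <- align_pair(seqs[1], seqs[2], gap_open = gap_open,
                    gap_extend = gap_extend)
    return(msa(ids, c(p$aligned1, p$aligned2)))
  }
  d <- kmer_distance_matrix(seqs)
  dimnames(d) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- lapply(seq_len(n), function(k) {
    m <- matrix(strsplit(seqs[k], "")[[1]], nrow = 1L)
    rownames(m) <- ids[k]
    m
  })
  merged <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0L) groups[[-x]] else merged[[x]]
    merged[[s]] <- merge_alignment_groups(pick(hc$merge[s, 1L]),
                                          pick(hc$merge[s, 2L]),
                                          gap_open, gap_extend)
  }
  final <- merged[[n - 1L]]
  final <- final[order(rownames(final)), , drop = FALSE]
  msa_from_matrix(final)
}

#' Remove gapped columns from an alignment
#'
#' Retains columns whose gap fraction is at most `max_gap_fraction`
#' (default 0: any gap removes the column) and returns the old-to-new
#' column map needed to carry coordinates across the filtering.
#'
#' @param x An `msa`.
#' @param max_gap_fraction Highest tolerated per-column gap fraction.
#' @return List: `msa` (filtered), `col_map` (integer vector, old column ->
#'   new column or `NA` if removed), `retained` (new -> old).
#' @export
strip_gap_columns <- function(x, max_gap_fraction = 0) {
  m <- msa_matrix(x)
  gf <- colMeans(m == "-")
  retained <- which(gf <= max_gap_fraction)
  col_map <- rep(NA_integer_, ncol(m))
  col_map[retained] <- seq_along(retained)
  list(msa = msa_from_matrix(m[, retained, drop = FALSE]),
       col_map = col_map, retained = retained)
}

# --- distances and trees ---------------------------------------------------

#' Pairwise evolutionary distances from an alignment
#'
#' Kimura-corrected fractional mismatch over pairwise-complete (gap-free in
#' both rows) columns: \eqn{d = -\ln(1 - p - 0.2 p^2)}.  Pairs whose raw
#' mismatch fraction reaches the saturation bound (p >= 0.85) are capped
#' there and flagged in the `saturated` attribute.
#'
#' @param x An `msa` with at least two rows.
#' @return Symmetric numeric matrix (substitutions/site) with row/column
#'   names, attribute `saturated` (logical matrix).
#' @export
compute_distances <- function(x) {
  m <- msa_matrix(x)
  n <- nrow(m)
  if (n < 2L) stop("need at least two sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop(sprintf("no gap-free column for pair %s / %s",
                               rownames(m)[i], rownames(m)[j]))
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 0.85) {
      p <- 0.85
      sat[i, j] <- sat[j, i] <- TRUE
      warning(sprintf("distance %s / %s saturated; capped", rownames(m)[i],
                      rownames(m)[j]), call. = FALSE)
    }
    d[i, j] <- d[j, i] <- -log(1 - p - 0.2 * p^2)
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining ([ape::nj()]); negative branch lengths are
#' clamped to zero with the deficit moved onto the sibling edge so total
#' path lengths are approximately preserved.
#'
#' @param dm Symmetric distance matrix with row/column names.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(dm) {
  dm <- unclass(dm)
  attr(dm, "saturated") <- NULL
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(dm)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    sibs <- setdiff(which(tr$edge[, 1L] == tr$edge[e, 1L]), e)
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
    }
  }
  tr
}

# canonical bipartition strings of a tree's internal edges; trivial splits
# (one tip, or the whole leaf set) are dropped
tree_splits <- function(tree) {
  tips <- tree$tip.label
  anchor <- min(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  out
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance/NJ
#' tree per replicate, and labels each internal edge of the original tree
#' with the percentage of replicates containing its bipartition.
#'
#' @param x An `msa`.
#' @param n_replicates Number of bootstrap replicates (default 100; 0 skips
#'   support computation and returns the plain tree).
#' @param seed Integer RNG seed.
#' @return An [ape::phylo] tree; supports (0–100) in `node.label` (empty at
#'   the root and at trivial partitions).
#' @export
bootstrap_support <- function(x, n_replicates = 100, seed = 1) {
  tree0 <- nj_tree(compute_distances(x))
  if (n_replicates == 0L) return(tree0)
  set.seed(seed)
  m <- msa_matrix(x)
  rep_splits <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mb <- msa_from_matrix(m[, cols, drop = FALSE])
    tb <- try(nj_tree(suppressWarnings(compute_distances(mb))), silent = TRUE)
    rep_splits[[b]] <- if (inherits(tb, "try-error")) character(0) else
      stats::na.omit(tree_splits(tb))
  }
  counts <- table(unlist(rep_splits))
  sp0 <- tree_splits(tree0)
  supp <- ifelse(is.na(sp0), "",
                 as.character(round(100 * ifelse(is.na(counts[sp0]), 0,
                                                 counts[sp0]) / n_replicates)))
  tree0$node.label <- unname(supp)
  tree0
}

#' Assign subfamilies from labeled anchor leaves
#'
#' A query leaf is assigned subfamily L iff the smallest supported
#' bipartition side (support at least `min_support`; edges without a
#' recorded support count as 100) containing the query and at least one
#' anchor contains anchors of subfamily L only; a mixed-anchor side leaves
#' the query unclassified.  The whole leaf set acts as the last-resort
#' group.
#'
#' @param tree An [ape::phylo] tree, supports in `node.label` as produced by
#'   [bootstrap_support()].
#' @param anchors Named character vector: anchor leaf id -> subfamily label.
#' @param min_support Minimum bootstrap percentage for an edge to define a
#'   group (default 50).
#' @return Data frame with `protein_id`, `subfamily` (`NA` when
#'   unclassified), `support`, `status` (`assigned`/`unclassified`), one row
#'   per non-anchor leaf, ordered by id.
#' @export
assign_subfamilies <- function(tree, anchors, min_support = 50) {
  missing <- setdiff(names(anchors), tree$tip.label)
  if (length(missing) > 0L) {
    stop("anchors missing from tree: ", paste(missing, collapse = ", "))
  }
  tips <- tree$tip.label
  queries <- sort(setdiff(tips, names(anchors)))
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  nl <- tree$node.label
  supports <- if (is.null(nl)) rep(100, length(pp)) else {
    s <- suppressWarnings(as.numeric(nl))
    ifelse(is.na(s), 100, s)
  }
  sides <- list(); side_support <- numeric(0)
  for (k in seq_along(pp)) {
    clade <- labs[pp[[k]]]
    for (side in list(clade, setdiff(tips, clade))) {
      if (length(side) >= 2L && length(side) <= length(tips) - 1L) {
        sides[[length(sides) + 1L]] <- side
        side_support <- c(side_support, supports[k])
      }
    }
  }
  sides[[length(sides) + 1L]] <- tips
  side_support <- c(side_support, 100)
  out <- lapply(queries, function(q) {
    cand <- which(vapply(sides, function(s) q %in% s &&
                           any(names(anchors) %in% s), logical(1)) &
                    side_support >= min_support)
    if (length(cand) == 0L) {
      return(data.frame(protein_id = q, subfamily = NA_character_,
                        support = NA_real_, status = "unclassified",
                        stringsAsFactors = FALSE))
    }
    sizes <- vapply(cand, function(k) length(sides[[k]]), numeric(1))
    ord <- cand[order(sizes, -side_support[cand])]
    best <- ord[1L]
    fams <- unique(anchors[intersect(names(anchors), sides[[best]])])
    if (length(fams) == 1L) {
      data.frame(protein_id = q, subfamily = unname(fams),
                 support = side_support[best], status = "assigned",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = q, subfamily = NA_character_,
                 support = side_support[best], status = "unclassified",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
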