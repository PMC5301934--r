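# Affine-gap dynamic programming engines shared by the profile scanner, the
# pairwise reporter and the progressive aligner.  All are vectorised over the
# first index within each column of the DP table; the within-column gap state
# uses the running-maximum transform  X[i] = max_{k<i} M[k] - open - (i-1-k)*ext.

# Global (Needleman-Wunsch) alignment over an arbitrary position-pair score
# matrix S (n1 x n2).  States: M match, X gap in side 2 (consumes side 1),
# Y gap in side 1 (consumes side 2).  Gap-to-opposite-gap transitions are
# disallowed.  Returns score and a path string of M/X/Y steps.
affine_global_dp <- function(S, gap_open, gap_extend) {
  n1 <- nrow(S); n2 <- ncol(S)
  go <- gap_open; ge <- gap_extend
  M <- X <- Y <- matrix(-Inf, n1 + 1L, n2 + 1L)
  M[1L, 1L] <- 0
  if (n1 > 0L) X[2L:(n1 + 1L), 1L] <- -(go + (0L:(n1 - 1L)) * ge)
  if (n2 > 0L) Y[1L, 2L:(n2 + 1L)] <- -(go + (0L:(n2 - 1L)) * ge)
  idx <- seq_len(n1 + 1L)
  for (j in seq_len(n2)) {
    pM <- M[, j]; pX <- X[, j]; pY <- Y[, j]
    dM <- c(-Inf, pM[-(n1 + 1L)])
    dX <- c(-Inf, pX[-(n1 + 1L)])
    dY <- c(-Inf, pY[-(n1 + 1L)])
    Mc <- c(-Inf, S[, j]) + pmax(dM, dX, dY)
    Yc <- pmax(pM - go, pY - ge)
    g <- Mc - go + ge * idx
    Xc <- c(-Inf, cummax(g)[-(n1 + 1L)]) - ge * (idx - 1L)
    Xc[1L] <- -Inf
    M[, j + 1L] <- Mc; X[, j + 1L] <- Xc; Y[, j + 1L] <- Yc
  }
  ends <- c(M[n1 + 1L, n2 + 1L], X[n1 + 1L, n2 + 1L], Y[n1 + 1L, n2 + 1L])
  state <- c("M", "X", "Y")[which.max(ends)]
  score <- max(ends)
  # traceback
  tol <- 1e-9
  i <- n1; j <- n2
  path <- character(0)
  while (i > 0L || j > 0L) {
    r <- i + 1L; cjj <- j + 1L
    if (state == "M") {
      tgt <- M[r, cjj] - S[i, j]
      path <- c("M", path)
      i <- i - 1L; j <- j - 1L
      r <- i + 1L; cjj <- j + 1L
      state <- if (i == 0L && j == 0L) "" else
        if (abs(M[r, cjj] - tgt) < tol) "M" else
        if (abs(X[r, cjj] - tgt) < tol) "X" else "Y"
    } else if (state == "X") {
      tgt <- X[r, cjj]
      path <- c("X", path)
      i <- i - 1L
      r <- i + 1L
      state <- if (i == 0L && j == 0L) "" else
        if (abs(M[r, cjj] - go - tgt) < tol) "M" else "X"
    } else {
      tgt <- Y[r, cjj]
      path <- c("Y", path)
      j <- j - 1L
      cjj <- j + 1L
      state <- if (i == 0L && j == 0L) "" else
        if (abs(M[r, cjj] - go - tgt) < tol) "M" else "Y"
    }
  }
  list(score = score, path = path)
}

# Local (Smith-Waterman) alignment of a profile (columns j) against a
# sequence (positions i), over a precomputed score matrix S (L x m).
# Returns the best local hit; with traceback = TRUE also the hit extent on
# both axes and the model-column -> sequence-position map.
affine_local_dp <- function(S, gap_open, gap_extend, traceback = TRUE) {
  L <- nrow(S); m <- ncol(S)
  go <- gap_open; ge <- gap_extend
  if (L == 0L || m == 0L) return(NULL)
  M <- X <- Y <- matrix(-Inf, L, m)
  idx <- seq_len(L)
  for (j in seq_len(m)) {
    if (j == 1L) {
      dM <- dX <- dY <- rep(-Inf, L)
      pM <- pY <- rep(-Inf, L)
    } else {
      pM <- M[, j - 1L]; pY <- Y[, j - 1L]
      dM <- c(-Inf, pM[-L]); dX <- c(-Inf, X[-L, j - 1L]); dY <- c(-Inf, pY[-L])
    }
    Mc <- S[, j] + pmax(0, dM, dX, dY)
    Yc <- pmax(pM - go, pY - ge)
    g <- Mc - go + ge * idx
    Xc <- c(-Inf, cummax(g)[-L]) - ge * (idx - 1L)
    M[, j] <- Mc; X[, j] <- Xc; Y[, j] <- Yc
  }
  best <- max(M)
  if (!is.finite(best) || best <= 0) return(NULL)
  if (!traceback) return(list(score = best))
  w <- which(M == best, arr.ind = TRUE)[1L, ]
  i <- unname(w[1L]); j <- unname(w[2L])
  qend <- i; jend <- j
  model_map <- rep(NA_integer_, m)
  tol <- 1e-9
  state <- "M"
  qstart <- i; jstart <- j
  repeat {
    if (state == "M") {
      model_map[j] <- i
      qstart <- i; jstart <- j
      rest <- M[i, j] - S[i, j]
      if (abs(rest) < tol || i == 1L || j == 1L) break
      prevs <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which(abs(prevs - rest) < tol)[1L]
      if (is.na(k)) break
      state <- c("M", "X", "Y")[k]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      # gap in model: sequence residue i unaligned inside the hit
      tgt <- X[i, j]
      if (i > 1L && abs(M[i - 1L, j] - go - tgt) < tol) state <- "M"
      i <- i - 1L
      if (i < 1L) break
    } else {
      # model column j deleted
      tgt <- Y[i, j]
      if (j > 1L && abs(M[i, j - 1L] - go - tgt) < tol) state <- "M"
      j <- j - 1L
      if (j < 1L) break
    }
  }
  list(score = best, qstart = qstart, qend = qend,
       jstart = jstart, jend = jend, model_map = model_map)
}

#' Global pairwise protein alignment
#'
#' Needleman–Wunsch alignment with affine gap penalties over BLOSUM62 (or a
#' supplied substitution matrix).  The workhorse behind
#' [pairwise_paralog_report()] and the progressive aligner.
#'
#' @param seq1,seq2 Amino-acid strings.
#' @param submat Substitution matrix over [aa_alphabet()]; default BLOSUM62.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return List with `aligned1`, `aligned2` (equal-length gapped strings) and
#'   `score`.
#' @export
align_pair <- function(seq1, seq2, submat = NULL,
                       gap_open = 10, gap_extend = 1) {
  if (is.null(submat)) submat <- blosum62()
  a1 <- aa_to_int(seq1); a2 <- aa_to_int(seq2)
  S <- submat[a1, a2, drop = FALSE]
  S[is.na(S)] <- 0  # X residues are neutral
  res <- affine_global_dp(S, gap_open, gap_extend)
  c1 <- strsplit(seq1, "")[[1]]; c2 <- strsplit(seq2, "")[[1]]
  i <- 0L; j <- 0L
  out1 <- character(length(res$path)); out2 <- character(length(res$path))
  for (k in seq_along(res$path)) {
    st <- res$path[k]
    if (st == "M") { i <- i + 1L; j <- j + 1L; out1[k] <- c1[i]; out2[k] <- c2[j] }
    else if (st == "X") { i <- i + 1L; out1[k] <- c1[i]; out2[k] <- "-" }
    else { j <- j + 1L; out1[k] <- "-"; out2[k] <- c2[j] }
  }
  list(aligned1 = paste(out1, collapse = ""),
       aligned2 = paste(out2, collapse = ""),
       score = res$score)
}
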