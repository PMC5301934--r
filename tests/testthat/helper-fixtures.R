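# Shared fixture builders.  Everything is generated in code under a fixed
# seed; no data files are read from disk.

# a noisy family of n rows around a consensus string
noisy_family <- function(consensus, n = 5, rate = 0.05, prefix = "S") {
  rows <- vapply(seq_len(n), function(i) {
    paste(paraldiv:::mutate_sequence(strsplit(consensus, "")[[1]], rate,
                                     aa_background()), collapse = "")
  }, character(1))
  msa(sprintf("%s%02d", prefix, seq_len(n)), rows)
}

# a calibrated domain model plus its consensus, deterministic given seed
calibrated_model <- function(seed = 1, width = 50, n_shuffled = 150) {
  set.seed(seed)
  cons <- paraldiv:::sample_residues(width)
  seed_aln <- noisy_family(cons, 5)
  model <- build_profile(seed_aln, model_id = "dom")
  list(model = calibrate_evalue(model, n_shuffled = n_shuffled,
                                seed = seed + 1),
       consensus = cons)
}

# brute-force local alignment enumerator: recursively explores every local
# alignment of model columns to sequence positions with affine gap costs.
# Independent of the DP engine; exponential, for tiny inputs only.
brute_force_local_score <- function(match, seq_int, go, ge) {
  L <- length(seq_int); m <- ncol(match)
  best <- -Inf
  rec <- function(i, j, score) {
    best <<- max(best, score)
    if (i >= L || j >= m) return(invisible(NULL))
    # match next
    rec(i + 1L, j + 1L, score + match[seq_int[i + 1L], j + 1L])
    # skip k sequence residues (gap in model), then match
    for (k in seq_len(L - i - 1L)) {
      if (i + k + 1L > L || j + 1L > m) break
      rec(i + k + 1L, j + 1L,
          score - (go + (k - 1L) * ge) + match[seq_int[i + k + 1L], j + 1L])
    }
    # skip k model columns (deletion), then match
    for (k in seq_len(m - j - 1L)) {
      if (j + k + 1L > m || i + 1L > L) break
      rec(i + 1L, j + k + 1L,
          score - (go + (k - 1L) * ge) + match[seq_int[i + 1L], j + k + 1L])
    }
    invisible(NULL)
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(m)) {
    rec(i0, j0, match[seq_int[i0], j0])
  }
  best
}

# brute-force per-column divergence check mirroring the scan definition
brute_force_divergence <- function(x, reference_ids, partner_id, query_id,
                                   min_conservation = 0.9,
                                   max_gap_fraction = 0.2,
                                   require_partner = TRUE) {
  m <- msa_matrix(x)
  refs <- m[reference_ids, , drop = FALSE]
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- refs[, j]
    nongap <- col[col != "-"]
    if (length(nongap) == 0L) next
    gap_frac <- 1 - length(nongap) / length(col)
    cnt <- table(nongap)
    cons <- sort(names(cnt)[cnt == max(cnt)])[1]
    frac <- max(cnt) / length(nongap)
    q <- m[query_id, j]; p <- m[partner_id, j]
    if (frac >= min_conservation && gap_frac <= max_gap_fraction &&
        q != "-" && q != cons && (!require_partner || p == cons)) {
      out <- c(out, j)
    }
  }
  out
}
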