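#' Build a position-specific log-odds profile from a seed alignment
#'
#' Columns with gap fraction above 50% are dropped; the remaining columns
#' are scored as
#' \deqn{s(c,a) = \log_2 \frac{(n_{ca} + w\,b_a)/(n_c + w)}{b_a}}
#' where \eqn{n_{ca}} counts residue \eqn{a} in column \eqn{c}, \eqn{n_c} is
#' the column's non-gap count, \eqn{b} the background distribution and
#' \eqn{w} the pseudocount weight.  An `X` residue in a target sequence is
#' scored 0 at every column.
#'
#' @param seed An `msa` seed alignment (at least one row).
#' @param pseudocount_weight Positive pseudocount mass `w` (default 1).
#' @param background Named residue distribution (default [aa_background()]).
#' @param model_id Identifier stored with the model.
#' @param gap_open,gap_extend Gap penalties in bits used when scanning
#'   (defaults 4 and 1).
#' @return A `profile_model`: list with `model_id`, `n_cols`, `match`
#'   (21 x n_cols score matrix, rows [aa_alphabet()] plus `X`), `background`,
#'   gap penalties, `kept_columns` (indices into the seed), and `calibration`
#'   (`NULL` until [calibrate_evalue()] is run).
#' @export
build_profile <- function(seed, pseudocount_weight = 1,
                          background = aa_background(),
                          model_id = "profile",
                          gap_open = 4, gap_extend = 1) {
  stopifnot(inherits(seed, "msa"))
  if (length(seed$ids) < 1L) stop("empty seed alignment")
  if (pseudocount_weight <= 0) stop("pseudocount_weight must be positive")
  background <- background[AA_ALPHABET] / sum(background)
  m <- msa_matrix(seed)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0L) stop("all seed columns are gap-dominated")
  scores <- matrix(0, nrow = 21L, ncol = length(keep),
                   dimnames = list(c(AA_ALPHABET, "X"), NULL))
  w <- pseudocount_weight
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    f <- (as.numeric(cnt) + w * background) / (length(col) + w)
    scores[1:20, k] <- log2(f / background)
  }
  structure(list(model_id = model_id, n_cols = length(keep),
                 match = scores, background = background,
                 gap_open = gap_open, gap_extend = gap_extend,
                 kept_columns = keep, calibration = NULL),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model '%s': %d columns%s>\n", x$model_id, x$n_cols,
              if (is.null(x$calibration)) ", uncalibrated"
              else sprintf(", Gumbel mu=%.2f lambda=%.3f", x$calibration$mu,
                           x$calibration$lambda)))
  invisible(x)
}

# raw best local score of a model against one residue string
profile_best_score <- function(model, residues, traceback = FALSE,
                               mask = NULL) {
  a <- match(strsplit(residues, "")[[1]], rownames(model$match))
  a[is.na(a)] <- 21L  # unknowns behave like X
  S <- t(model$match)[, a, drop = FALSE]  # m x L -> transpose below
  S <- t(S)                               # L x m
  if (!is.null(mask) && length(mask) > 0L) S[mask, ] <- -Inf
  affine_local_dp(S, model$gap_open, model$gap_extend, traceback = traceback)
}

#' Calibrate E-values for a profile by shuffled-sequence simulation
#'
#' Scores `n_shuffled` random background sequences of length
#' `target_length`, fits a Gumbel distribution to the per-sequence maximal
#' local scores by maximum likelihood, and stores `(mu, lambda)` with the
#' calibration length.  E-values are then computed per search as
#' \deqn{E(S) = \frac{N_\mathrm{search}}{L_\mathrm{calib}}
#'   e^{-\lambda (S-\mu)},}
#' the expected number of exceedances over `N_search` scanned residues;
#' this is monotone non-increasing in the score.
#'
#' @param model A `profile_model`.
#' @param n_shuffled Number of null sequences (>= 100).
#' @param target_length Length of each null sequence (default 300).
#' @param seed Integer RNG seed.
#' @return The model with a `calibration` element.
#' @export
calibrate_evalue <- function(model, n_shuffled = 200, target_length = 300,
                             seed = 1) {
  stopifnot(inherits(model, "profile_model"))
  if (n_shuffled < 100) stop("n_shuffled must be at least 100")
  set.seed(seed)
  scores <- numeric(n_shuffled)
  for (k in seq_len(n_shuffled)) {
    s <- sample_residues(target_length, model$background)
    r <- profile_best_score(model, s, traceback = FALSE)
    scores[k] <- if (is.null(r)) 0 else r$score
  }
  if (stats::sd(scores) < 1e-8) {
    stop("degenerate null score distribution; cannot calibrate")
  }
  fit <- fit_gumbel(scores)
  model$calibration <- list(mu = fit$mu, lambda = fit$lambda,
                            length = target_length, n_shuffled = n_shuffled)
  model
}

#' Fit a Gumbel distribution by maximum likelihood
#'
#' Left-censored maximum likelihood: observations below the
#' `censor_quantile` contribute only through the CDF, so the fit is driven
#' by the upper tail — the region E-values are computed from.  (Empirical
#' maximal local alignment scores follow a Gumbel law only asymptotically;
#' a full-sample fit lets the bulk drag the tail slope.)  Method-of-moments
#' start, Nelder–Mead refinement.
#'
#' @param x Numeric sample (e.g. per-sequence maximal scores).
#' @param censor_quantile Quantile below which observations are censored
#'   (default 0.5; 0 gives the ordinary full-sample MLE).
#' @return List with `mu` (location) and `lambda` (inverse scale).
#' @export
fit_gumbel <- function(x, censor_quantile = 0.5) {
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772157 * beta0
  tau <- stats::quantile(x, censor_quantile, names = FALSE)
  hi <- x[x >= tau]
  n_lo <- sum(x < tau)
  nll <- function(p) {
    beta <- exp(p[2L])
    z <- (hi - p[1L]) / beta
    ztau <- (tau - p[1L]) / beta
    length(hi) * log(beta) + sum(z + exp(-z)) + n_lo * exp(-ztau)
  }
  o <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  list(mu = o$par[1L], lambda = 1 / exp(o$par[2L]))
}

# E-value of a score in a search over n_search_residues scanned residues
profile_evalue <- function(model, score, n_search_residues) {
  cal <- model$calibration
  if (is.null(cal)) stop("model '", model$model_id,
                         "' is not calibrated; run calibrate_evalue() first")
  (n_search_residues / cal$length) * exp(-cal$lambda * (score - cal$mu))
}

#' Scan one protein with a calibrated profile
#'
#' Finds the best-scoring local alignments of the model to the protein by
#' affine-gap dynamic programming; after each hit its residue interval is
#' masked and the scan repeated, so reported hits never overlap.  Hits are
#' returned in descending score order.
#'
#' @param model Calibrated `profile_model`.
#' @param protein One row of a `protein_set` (or a list with `id`,
#'   `locus_id`, `residues`).
#' @param n_search_residues Search-space size used for the E-value; defaults
#'   to the protein length (single-sequence search).  [survey_proteome()]
#'   passes the whole proteome size.
#' @param max_evalue Stop reporting once a hit's E-value exceeds this
#'   (default 10).
#' @param max_hits Cap on hits per protein.
#' @param min_coverage Model-coverage threshold for the `complete` flag.
#' @return Data frame of hits: `protein_id`, `locus_id`, `start`, `end`,
#'   `score`, `evalue`, `model_coverage`, `complete`, and a `model_map`
#'   list-column giving, per hit, the protein position aligned to each model
#'   column (NA where the column is deleted).
#' @export
scan_protein <- function(model, protein, n_search_residues = NULL,
                         max_evalue = 10, max_hits = 5L,
                         min_coverage = 0.8) {
  if (is.null(model$calibration)) stop("model must be calibrated before scanning")
  residues <- protein$residues
  empty <- data.frame(protein_id = character(0), locus_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      evalue = numeric(0), model_coverage = numeric(0),
                      complete = logical(0))
  empty$model_map <- list()
  L <- nchar(residues)
  if (L < 5L) return(empty)
  if (is.null(n_search_residues)) n_search_residues <- L
  mask <- integer(0)
  hits <- list()
  for (h in seq_len(max_hits)) {
    r <- profile_best_score(model, residues, traceback = TRUE, mask = mask)
    if (is.null(r)) break
    ev <- profile_evalue(model, r$score, n_search_residues)
    if (ev > max_evalue) break
    cov <- (r$jend - r$jstart + 1L) / model$n_cols
    hits[[h]] <- list(df = data.frame(
      protein_id = protein$id, locus_id = protein$locus_id,
      start = r$qstart, end = r$qend, score = r$score, evalue = ev,
      model_coverage = cov, complete = cov >= min_coverage,
      stringsAsFactors = FALSE), map = r$model_map)
    mask <- c(mask, r$qstart:r$qend)
    if (length(mask) >= L) break
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, lapply(hits, `[[`, "df"))
  out <- out[order(-out$score), , drop = FALSE]
  out$model_map <- lapply(hits, `[[`, "map")[order(-vapply(hits, function(x) x$df$score, numeric(1)))]
  rownames(out) <- NULL
  out
}

#' Survey a proteome with a domain profile
#'
#' Concatenates per-protein scans (E-values on the per-search scale: the
#' whole proteome is the search space), filters at the E-value cutoff and
#' orders hits by locus then descending score.
#'
#' @param model Calibrated `profile_model`.
#' @param proteome A `protein_set`.
#' @param evalue_cutoff Report hits with E-value at or below this
#'   (default 0.01).
#' @param min_coverage Completeness threshold (default 0.8).
#' @return Data frame of hits as in [scan_protein()].
#' @export
survey_proteome <- function(model, proteome, evalue_cutoff = 0.01,
                            min_coverage = 0.8) {
  if (nrow(proteome) == 0L) {
    empty <- data.frame(protein_id = character(0), locus_id = character(0),
                        start = integer(0), end = integer(0),
                        score = numeric(0), evalue = numeric(0),
                        model_coverage = numeric(0), complete = logical(0))
    empty$model_map <- list()
    return(empty)
  }
  n_total <- sum(nchar(proteome$residues))
  res <- lapply(seq_len(nrow(proteome)), function(k) {
    scan_protein(model, proteome[k, ], n_search_residues = n_total,
                 max_evalue = evalue_cutoff, min_coverage = min_coverage)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(res[[1]][0, ])
  ord <- order(out$locus_id, -out$score, out$protein_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a hit as complete or partial
#'
#' A domain occurrence is complete when it covers at least `min_coverage`
#' of the model's columns.
#' @param hit One hit row (needs `model_coverage`).
#' @param min_coverage Threshold (default 0.8).
#' @return Logical.
#' @export
classify_completeness <- function(hit, min_coverage = 0.8) {
  hit$model_coverage >= min_coverage
}

#' Reduce hits to one protein per locus
#'
#' Applies the unique-locus rule: among a locus's isoform hits, prefer a
#' complete domain over a partial one, then the longer protein, then the
#' lexicographically smallest accession.
#'
#' @param hits Hit data frame from [survey_proteome()].
#' @param proteome The `protein_set` scanned (supplies protein lengths).
#' @return Subset of `hits`, one row per locus, same column layout,
#'   ordered by locus.
#' @export
dedupe_loci <- function(hits, proteome) {
  if (nrow(hits) == 0L) return(hits)
  plen <- setNames(nchar(proteome$residues), proteome$id)
  # keep each protein's single best hit first
  best <- hits[order(hits$protein_id, -hits$score), , drop = FALSE]
  best <- best[!duplicated(best$protein_id), , drop = FALSE]
  best$.len <- plen[best$protein_id]
  ord <- order(best$locus_id, -best$complete, -best$.len, best$protein_id)
  best <- best[ord, , drop = FALSE]
  best <- best[!duplicated(best$locus_id), , drop = FALSE]
  best$.len <- NULL
  rownames(best) <- NULL
  best
}
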