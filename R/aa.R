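#' @importFrom stats optim runif rpois rgeom sd setNames hclust as.dist cophenetic quantile na.omit
#' @importFrom utils read.delim write.table data
NULL

# Canonical amino-acid alphabet used everywhere in the package.  Order is
# fixed so that integer-encoded sequences index score matrices directly.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in the fixed order used by all
#' scoring matrices in the package.
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA_ALPHABET

#' Background amino-acid frequencies
#'
#' Robinson–Robinson average composition of globular proteins, normalised to
#' sum to one.  Used as the default null model for profile log-odds scores and
#' for sampling synthetic background sequences.
#'
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
aa_background <- function() {
  f <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  f <- f[AA_ALPHABET]
  f / sum(f)
}

# integer encoding; X and gap map to NA (scored 0 / skipped by callers)
aa_to_int <- function(x) {
  chars <- if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else x
  match(chars, AA_ALPHABET)
}

validate_residues <- function(seq, id = "<sequence>", allow_x = TRUE) {
  ok <- AA_ALPHABET
  if (allow_x) ok <- c(ok, "X")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% ok))
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# cached BLOSUM62 restricted to the canonical alphabet
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .pkg_cache$blosum62
}

# sample n residues from a background distribution, returned as a string
sample_residues <- function(n, background = aa_background()) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = background), collapse = "")
}
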