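# Synthetic-data generators with recorded ground truth.  Every generator is
# fully determined by its arguments plus the integer seed; all coordinates in
# the truth tables are 1-based inclusive.

# draw one residue from `background` excluding `current` — guarantees a
# planted substitution is truly divergent
sample_divergent_residue <- function(current, background = aa_background()) {
  keep <- setdiff(AA_ALPHABET, current)
  sample(keep, 1L, prob = background[keep])
}

mutate_sequence <- function(chars, rate, background) {
  flip <- runif(length(chars)) < rate
  for (k in which(flip)) chars[k] <- sample_divergent_residue(chars[k], background)
  chars
}

#' Generate a synthetic proteome with planted domain instances
#'
#' Builds `n_proteins` background proteins and plants a noisy copy of the
#' domain consensus (point substitutions at `substitution_rate` per site)
#' into `n_with_domain` of them; `round(truncation_fraction * n_with_domain)`
#' of the copies are truncated to under 50% of the consensus length,
#' emulating incomplete gene models.  All planting coordinates are recorded.
#'
#' @param n_proteins Total number of proteins.
#' @param n_with_domain How many carry the domain (`<= n_proteins`).
#' @param domain_consensus Consensus residue string (length >= 10).
#' @param truncation_fraction Fraction of planted copies to truncate, in
#'   \[0, 1\].
#' @param background_freqs Background residue distribution.
#' @param seed Integer RNG seed.
#' @param substitution_rate Per-site substitution rate on planted copies
#'   (default 0.05).
#' @param length_range Host protein length range (default 150–400).
#' @return List: `proteins` (a `protein_set`) and `truth` (list with
#'   `planted_domains` data frame — `protein_id`, `start`, `end`,
#'   `truncated` — plus `rng_seed`).
#' @export
generate_proteome <- function(n_proteins, n_with_domain, domain_consensus,
                              truncation_fraction = 0,
                              background_freqs = aa_background(), seed = 1,
                              substitution_rate = 0.05,
                              length_range = c(150L, 400L)) {
  if (n_with_domain > n_proteins) stop("n_with_domain exceeds n_proteins")
  if (truncation_fraction < 0 || truncation_fraction > 1) {
    stop("truncation_fraction must be in [0, 1]")
  }
  if (n_with_domain > 0L && nchar(domain_consensus) < 10L) {
    stop("domain consensus must have at least 10 residues")
  }
  set.seed(seed)
  ids <- sprintf("SYNP%04d", seq_len(n_proteins))
  carriers <- if (n_with_domain > 0L) sort(sample.int(n_proteins, n_with_domain))
              else integer(0)
  n_trunc <- round(truncation_fraction * n_with_domain)
  truncated <- if (n_trunc > 0L) sort(sample(carriers, n_trunc)) else integer(0)
  cons <- strsplit(domain_consensus, "")[[1]]
  seqs <- character(n_proteins)
  rows <- list()
  for (k in seq_len(n_proteins)) {
    Lb <- sample(length_range[1L]:length_range[2L], 1L)
    bg <- strsplit(sample_residues(Lb, background_freqs), "")[[1]]
    if (k %in% carriers) {
      dom <- mutate_sequence(cons, substitution_rate, background_freqs)
      if (k %in% truncated) {
        keep <- max(5L, floor(runif(1, 0.25, 0.45) * length(cons)))
        dom <- dom[seq_len(keep)]
      }
      at <- sample.int(Lb + 1L, 1L) - 1L  # insert after position `at`
      seqs[k] <- paste(c(bg[seq_len(at)], dom,
                         if (at < Lb) bg[(at + 1L):Lb]), collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = ids[k], start = at + 1L, end = at + length(dom),
        truncated = k %in% truncated, stringsAsFactors = FALSE)
    } else {
      seqs[k] <- paste(bg, collapse = "")
    }
  }
  planted <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), truncated = logical(0))
  list(proteins = protein_set(ids, seqs),
       truth = list(planted_domains = planted, rng_seed = seed))
}

#' Plant secondary-motif copies into existing proteins
#'
#' Appends a noisy copy of a motif consensus at a random position of each
#' named protein (outside any planted domain is the caller's
#' responsibility), recording motif id and 1-based start per planting.
#'
#' @param proteins A `protein_set`.
#' @param motif_id Motif identifier recorded in the truth.
#' @param consensus Motif consensus string.
#' @param protein_ids Which proteins receive a copy.
#' @param substitution_rate Per-site substitution rate (default 0.05).
#' @param background_freqs Background distribution for substitutions.
#' @param seed Integer RNG seed.
#' @return List: `proteins` (modified set) and `truth` (data frame
#'   `protein_id`, `motif_id`, `start`).
#' @export
plant_motifs <- function(proteins, motif_id, consensus, protein_ids,
                         substitution_rate = 0.05,
                         background_freqs = aa_background(), seed = 1) {
  set.seed(seed)
  cons <- strsplit(consensus, "")[[1]]
  rows <- list()
  for (id in protein_ids) {
    k <- match(id, proteins$id)
    if (is.na(k)) stop("protein id not found: ", id)
    chars <- strsplit(proteins$residues[k], "")[[1]]
    mot <- mutate_sequence(cons, substitution_rate, background_freqs)
    at <- sample.int(length(chars) + 1L, 1L) - 1L
    proteins$residues[k] <- paste(c(chars[seq_len(at)], mot,
                                    if (at < length(chars))
                                      chars[(at + 1L):length(chars)]),
                                  collapse = "")
    rows[[length(rows) + 1L]] <- data.frame(protein_id = id,
                                            motif_id = motif_id,
                                            start = at + 1L,
                                            stringsAsFactors = FALSE)
  }
  list(proteins = proteins, truth = do.call(rbind, rows))
}

#' Simulate an ortholog-family alignment down a random tree
#'
#' Evolves a root sequence down a random bifurcating tree whose branch
#' lengths are rescaled so the mean root-to-tip path equals `depth`
#' (substitutions/site for a rate-1 column).  Each column belongs to a
#' conservation class drawn from `conservation_mixture`; its class
#' tolerance multiplies the branch length, so invariant-class columns are
#' near-frozen and variable-class columns churn.  Per-sequence indels
#' (geometric lengths, mean 2) shift ungapped residue numbering between
#' rows.
#'
#' @param n_refs Number of reference sequences (>= 4).
#' @param length Number of core alignment columns (>= 50).
#' @param conservation_mixture Named weights for the column classes
#'   (default 70% invariant, 30% variable).
#' @param tolerances Relative substitution rate per class (default 0.02 /
#'   0.5).
#' @param depth Mean root-to-tip path length (default 1 substitution/site;
#'   0 gives identical rows).
#' @param indel_rate Expected insertion + deletion events per column per
#'   sequence (default 0.01; 0 disables indels).
#' @param background_freqs Root/background residue distribution.
#' @param seed Integer RNG seed.
#' @return List: `msa` (rows `REF01`...), `truth` (list with `tree`
#'   ([ape::phylo]), `column_class` over core columns, `column_map`
#'   core-column -> final-column index, `rng_seed`).
#' @export
generate_ortholog_family <- function(n_refs, length,
                                     conservation_mixture = c(invariant = 0.7,
                                                              variable = 0.3),
                                     tolerances = c(invariant = 0.02,
                                                    variable = 0.5),
                                     depth = 1, indel_rate = 0.01,
                                     background_freqs = aa_background(),
                                     seed = 1) {
  if (n_refs < 4L) stop("need at least 4 reference sequences")
  if (length < 50L) stop("alignment length must be at least 50")
  set.seed(seed)
  ids <- sprintf("REF%02d", seq_len(n_refs))
  tree <- ape::rtree(n_refs, tip.label = ids)
  td <- ape::node.depth.edgelength(tree)[seq_len(n_refs)]
  if (mean(td) > 0) tree$edge.length <- tree$edge.length * depth / mean(td)
  if (depth == 0) tree$edge.length[] <- 0
  classes <- sample(names(conservation_mixture), length, replace = TRUE,
                    prob = conservation_mixture)
  rates <- unname(tolerances[classes])
  root <- strsplit(sample_residues(length, background_freqs), "")[[1]]
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n_nodes <- max(tree$edge)
  seqs_at <- vector("list", n_nodes)
  root_node <- n_refs + 1L
  seqs_at[[root_node]] <- root
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e]
    p <- 1 - exp(-rates * t_e)
    chars <- seqs_at[[parent]]
    flip <- which(runif(length(chars)) < p)
    for (k in flip) chars[k] <- sample_divergent_residue(chars[k], background_freqs)
    seqs_at[[child]] <- chars
  }
  m <- do.call(rbind, seqs_at[seq_len(n_refs)])
  rownames(m) <- ids
  # indels: deletions blank residues in one row; insertions add columns
  # private to one row
  insertions <- list()  # each: list(row, after_core_column, residues)
  if (indel_rate > 0) {
    for (r in seq_len(n_refs)) {
      n_del <- rpois(1L, indel_rate * length / 2)
      for (d in seq_len(n_del)) {
        len <- rgeom(1L, 0.5) + 1L
        at <- sample.int(length, 1L)
        m[r, at:min(length, at + len - 1L)] <- "-"
      }
      n_ins <- rpois(1L, indel_rate * length / 2)
      for (d in seq_len(n_ins)) {
        len <- rgeom(1L, 0.5) + 1L
        insertions[[length(insertions) + 1L]] <-
          list(row = r, after = sample.int(length + 1L, 1L) - 1L,
               residues = strsplit(sample_residues(len, background_freqs), "")[[1]])
      }
    }
  }
  expanded <- insert_private_columns(m, insertions)
  list(msa = msa_from_matrix(expanded$m),
       truth = list(tree = tree, column_class = classes,
                    column_map = expanded$column_map, rng_seed = seed))
}

# expand a core alignment matrix with single-row insertion events; returns
# the new matrix and the core-column -> new-column map
insert_private_columns <- function(m, insertions) {
  n_core <- ncol(m)
  if (length(insertions) == 0L) {
    return(list(m = m, column_map = seq_len(n_core)))
  }
  by_pos <- split(insertions,
                  vapply(insertions, function(x) x$after, numeric(1)))
  pieces <- list()
  column_map <- integer(n_core)
  new_j <- 0L
  for (core_j in 0L:n_core) {
    key <- as.character(core_j)
    if (!is.null(by_pos[[key]])) {
      for (ev in by_pos[[key]]) {
        block <- matrix("-", nrow(m), length(ev$residues))
        block[ev$row, ] <- ev$residues
        pieces[[length(pieces) + 1L]] <- block
        new_j <- new_j + ncol(block)
      }
    }
    if (core_j < n_core) {
      pieces[[length(pieces) + 1L]] <- m[, core_j + 1L, drop = FALSE]
      new_j <- new_j + 1L
      column_map[core_j + 1L] <- new_j
    }
  }
  out <- do.call(cbind, pieces)
  rownames(out) <- rownames(m)
  list(m = out, column_map = column_map)
}

#' Plant a diverged paralog pair onto a family alignment
#'
#' Adds two rows: `paralogA` carries the family consensus everywhere;
#' `paralogB` matches `paralogA` except at exactly `n_sites` sampled
#' deeply conserved columns (consensus fraction >= `min_conservation`, gap
#' fraction <= `max_gap_fraction`), where it carries a residue different
#' from the consensus.  The generative inverse of
#' [scan_paralog_divergence()].
#'
#' @param family An `msa` of reference rows (>= 4).
#' @param n_sites Number of divergent sites to plant.
#' @param min_conservation Conservation floor for eligible columns
#'   (default 0.9).
#' @param max_gap_fraction Gap ceiling for eligible columns (default 0.2).
#' @param background_freqs Distribution for the substituted residues.
#' @param seed Integer RNG seed.
#' @return List: `msa` (family plus `paralogA`, `paralogB`) and `truth`
#'   (data frame `column`, `consensus_residue`, `planted_residue`,
#'   `query_position`; plus `rng_seed` attribute).
#' @export
plant_paralog_divergence <- function(family, n_sites, min_conservation = 0.9,
                                     max_gap_fraction = 0.2,
                                     background_freqs = aa_background(),
                                     seed = 1) {
  if (length(family$ids) < 4L) stop("family must have at least 4 rows")
  set.seed(seed)
  prof <- conservation_profile(family, family$ids)
  eligible <- which(!is.na(prof$consensus_fraction) &
                      prof$consensus_fraction >= min_conservation &
                      prof$gap_fraction <= max_gap_fraction)
  if (length(eligible) < n_sites) {
    stop(sprintf("only %d columns reach conservation %.2f; cannot plant %d sites",
                 length(eligible), min_conservation, n_sites))
  }
  a <- ifelse(is.na(prof$consensus_residue), "-", prof$consensus_residue)
  b <- a
  sites <- if (n_sites > 0L) sort(sample(eligible, n_sites)) else integer(0)
  for (j in sites) b[j] <- sample_divergent_residue(a[j], background_freqs)
  out <- msa(c(family$ids, "paralogA", "paralogB"),
             c(family$seqs, paste(a, collapse = ""), paste(b, collapse = "")))
  qpos <- if (length(sites) > 0L)
    map_column_to_position(out, "paralogB", sites) else integer(0)
  truth <- data.frame(column = sites,
                      consensus_residue = a[sites],
                      planted_residue = b[sites],
                      query_position = qpos,
                      stringsAsFactors = FALSE)
  attr(truth, "rng_seed") <- seed
  list(msa = out, truth = truth)
}
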