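#' Build and calibrate a motif catalog
#'
#' Reads every seed alignment in a directory (files named `motifNN.*`,
#' aligned FASTA or Stockholm), builds a calibrated profile per motif, and
#' returns them keyed by motif id.  The id set is taken from the supplied
#' files — the catalog is data-driven, not hard-coded.
#'
#' @param dir Directory of motif seed alignments.
#' @param seed RNG seed for calibration (one derived seed per motif).
#' @param n_shuffled,target_length Calibration settings per motif.
#' @param ... Passed to [build_profile()].
#' @return A `motif_catalog`: named list of calibrated `profile_model`s.
#' @export
read_motif_catalog <- function(dir, seed = 1, n_shuffled = 150,
                               target_length = 300, ...) {
  files <- sort(list.files(dir, pattern = "^motif[0-9]+\\.", full.names = TRUE))
  if (length(files) == 0L) stop("no motifNN.* seed alignments in ", dir)
  ids <- sub("\\..*$", "", basename(files))
  seeds <- lapply(files, read_alignment)
  motif_catalog(setNames(seeds, ids), seed = seed, n_shuffled = n_shuffled,
                target_length = target_length, ...)
}

#' Construct a motif catalog from in-memory seed alignments
#'
#' @param seed_alignments Named list of `msa` objects; names are motif ids.
#' @param seed RNG seed; motif k is calibrated with `seed + k`.
#' @param n_shuffled,target_length Calibration settings.
#' @param ... Passed to [build_profile()].
#' @return A `motif_catalog`.
#' @export
motif_catalog <- function(seed_alignments, seed = 1, n_shuffled = 150,
                          target_length = 300, ...) {
  if (length(seed_alignments) == 0L) stop("empty motif catalog")
  if (is.null(names(seed_alignments)) || anyDuplicated(names(seed_alignments))) {
    stop("motif seed alignments must have unique names")
  }
  cat_list <- vector("list", length(seed_alignments))
  names(cat_list) <- names(seed_alignments)
  for (k in seq_along(seed_alignments)) {
    mod <- build_profile(seed_alignments[[k]], model_id = names(seed_alignments)[k], ...)
    cat_list[[k]] <- calibrate_evalue(mod, n_shuffled = n_shuffled,
                                      target_length = target_length,
                                      seed = seed + k)
  }
  structure(cat_list, class = "motif_catalog")
}

#' Screen proteins against a motif catalog
#'
#' For each (protein, motif) pair records the best local-scan E-value on the
#' per-search scale (all proteins screened form the search space).  A cell
#' is a presence call iff its E-value is at or below the cutoff, so lowering
#' the cutoff can only remove calls.
#'
#' @param proteins A `protein_set` (typically full-length family members).
#' @param catalog A `motif_catalog`.
#' @param evalue_cutoff Presence threshold (default 1, the conventional
#'   permissive cutoff for short secondary motifs).
#' @return A `motif_presence` object: numeric matrix of best E-values
#'   (rows = proteins, cols = motifs; `NA` where no local hit scored), with
#'   attributes `cutoff` and `presence` (logical matrix).
#' @export
screen_motifs <- function(proteins, catalog, evalue_cutoff = 1) {
  stopifnot(inherits(catalog, "motif_catalog"))
  if (length(catalog) == 0L) stop("empty motif catalog")
  n_total <- sum(nchar(proteins$residues))
  E <- matrix(NA_real_, nrow = nrow(proteins), ncol = length(catalog),
              dimnames = list(proteins$id, names(catalog)))
  for (j in seq_along(catalog)) {
    model <- catalog[[j]]
    for (i in seq_len(nrow(proteins))) {
      r <- profile_best_score(model, proteins$residues[i], traceback = FALSE)
      if (!is.null(r)) E[i, j] <- profile_evalue(model, r$score, n_total)
    }
  }
  pres <- !is.na(E) & E <= evalue_cutoff
  structure(E, cutoff = evalue_cutoff, presence = pres,
            class = c("motif_presence", class(E)))
}

#' Per-subfamily motif frequency table
#'
#' @param matrix A `motif_presence` from [screen_motifs()].
#' @param group_assignments Named character vector: protein id -> subfamily.
#'   Proteins absent from the map are pooled as `"unassigned"`.
#' @return Data frame: one row per subfamily plus a `TOTAL` row; columns
#'   `subfamily`, `n_members`, then one frequency column per motif.
#' @export
summarize_by_group <- function(matrix, group_assignments) {
  pres <- attr(matrix, "presence")
  ids <- rownames(pres)
  grp <- group_assignments[ids]
  grp[is.na(grp)] <- "unassigned"
  levs <- sort(unique(grp))
  rows <- lapply(levs, function(g) {
    sub <- pres[grp == g, , drop = FALSE]
    data.frame(subfamily = g, n_members = nrow(sub),
               t(colMeans(sub)), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  total <- data.frame(subfamily = "TOTAL", n_members = nrow(pres),
                      t(colMeans(pres)), check.names = FALSE,
                      stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), total)
  rownames(out) <- NULL
  out
}

#' Classify DNA-binding class from basic-region residues
#'
#' Uses the standard plant-bHLH diagnostic over the first 13 model columns
#' (the basic region): His at column 5, Glu at 9 and Arg at 13 call a G-box
#' binder; Glu-9 with Arg-13 but no His-5 an E-box binder.  A region with
#' fewer than `min_basic` basic residues (K/R/H) is a non-binder.  A hit
#' that does not map the diagnostic columns is `"undetermined"`.
#'
#' @param protein One `protein_set` row.
#' @param bhlh_hit One hit row from [scan_protein()] (must carry
#'   `model_map`).
#' @param diagnostic Integer vector of the three diagnostic model columns
#'   (default `c(5, 9, 13)`).
#' @param basic_region_len Number of leading model columns forming the
#'   basic region (default 13).
#' @param min_basic Minimum count of K/R/H residues (default 5).
#' @return One of `"G-box binder"`, `"E-box binder"`, `"non-binder"`,
#'   `"undetermined"`.
#' @export
classify_binding_class <- function(protein, bhlh_hit,
                                   diagnostic = c(5L, 9L, 13L),
                                   basic_region_len = 13L, min_basic = 5L) {
  map <- bhlh_hit$model_map
  if (is.list(map)) map <- map[[1L]]
  if (is.null(map) || length(map) < basic_region_len) return("undetermined")
  chars <- strsplit(protein$residues, "")[[1]]
  dpos <- map[diagnostic]
  if (any(is.na(dpos))) return("undetermined")
  region <- map[seq_len(basic_region_len)]
  region <- region[!is.na(region)]
  res <- chars[region]
  if (sum(res %in% c("K", "R", "H")) < min_basic) return("non-binder")
  d <- chars[dpos]
  if (d[1L] == "H" && d[2L] == "E" && d[3L] == "R") return("G-box binder")
  if (d[2L] == "E" && d[3L] == "R") return("E-box binder")
  "non-binder"
}
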