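#' Construct a protein sequence set
#'
#' The shared sequence container of the package: a data frame with one row
#' per protein and columns `id`, `locus_id`, `description`, `residues`.
#' Isoforms of one gene share a `locus_id`; by default it is derived from the
#' accession by stripping a trailing transcript suffix such as `_T02`
#' (the convention of the maize filtered gene set, e.g.
#' `GRMZM2G387528_T02` -> locus `GRMZM2G387528`).
#'
#' @param id Character vector of unique accessions.
#' @param residues Character vector of amino-acid strings (canonical 20
#'   letters plus `X`).
#' @param description Free-text descriptions (recycled).
#' @param locus_rule Function mapping an id to its locus id, or `NULL` to use
#'   the default suffix-stripping rule.
#' @return A `protein_set` data frame.
#' @export
protein_set <- function(id, residues, description = "", locus_rule = NULL) {
  if (length(id) != length(residues)) stop("id and residues lengths differ")
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate id '%s' in protein set", id[duplicated(id)][1]))
  }
  if (any(!nzchar(residues))) {
    stop(sprintf("record '%s': empty sequence", id[!nzchar(residues)][1]))
  }
  for (k in seq_along(id)) validate_residues(residues[k], id[k])
  if (is.null(locus_rule)) locus_rule <- default_locus_rule
  out <- data.frame(id = as.character(id),
                    locus_id = vapply(as.character(id), locus_rule, character(1),
                                      USE.NAMES = FALSE),
                    description = rep_len(as.character(description), length(id)),
                    residues = as.character(residues),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Default isoform-to-locus rule
#'
#' Strips a trailing `_T<digits>` or `_P<digits>` isoform suffix from an
#' accession, returning the locus identifier.
#' @param id Accession string.
#' @return Locus id string.
#' @export
default_locus_rule <- function(id) sub("_[TP][0-9]+$", "", id)

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @param locus_rule Optional id-to-locus function (see [protein_set()]).
#' @return A `protein_set`.
#' @export
read_fasta <- function(path, locus_rule = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  protein_set(id, as.character(ss), desc, locus_rule)
}

#' Write a protein set to FASTA
#'
#' Round-trips exactly with [read_fasta()]: ids, descriptions and sequences
#' are preserved.
#' @param records A `protein_set`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  ss <- Biostrings::BStringSet(records$residues)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Construct a multiple alignment
#'
#' Rows are (id, gapped string) pairs; all gapped strings must have equal
#' length; the gap character is `-` (a `.` is normalised to `-`).
#'
#' @param ids Character vector of row ids (unique).
#' @param seqs Gapped residue strings, equal lengths.
#' @return An object of class `msa` with elements `ids`, `seqs`,
#'   `n_columns`.
#' @export
msa <- function(ids, seqs) {
  seqs <- gsub(".", "-", as.character(seqs), fixed = TRUE)
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (anyDuplicated(ids)) stop("duplicate row id in alignment: ",
                               ids[duplicated(ids)][1])
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop(sprintf("unequal alignment row lengths: %s",
                 paste(sort(w), collapse = ", ")))
  }
  for (k in seq_along(ids)) {
    validate_residues(gsub("-", "", seqs[k]), ids[k])
  }
  structure(list(ids = as.character(ids), seqs = seqs, n_columns = w),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d rows x %d columns>\n", length(x$ids), x$n_columns))
  invisible(x)
}

#' Alignment as a character matrix
#' @param x An `msa`.
#' @return Character matrix, rows named by sequence id.
#' @export
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

msa_from_matrix <- function(m) {
  msa(rownames(m), apply(m, 1L, paste, collapse = ""))
}

#' Ungapped sequences of an alignment
#' @param x An `msa`.
#' @return Named character vector of degapped sequences.
#' @export
msa_ungap <- function(x) setNames(gsub("-", "", x$seqs), x$ids)

#' Read a multiple alignment
#'
#' Reads aligned FASTA or Stockholm.  Stockholm annotation lines (`#=GF`,
#' `#=GC`, ...) are tolerated and ignored; sequence lines for one id are
#' concatenated across blocks.  Ragged rows are rejected.
#'
#' @param path File path.
#' @param dialect `"fasta"` or `"stockholm"`; `"auto"` sniffs the first line.
#' @return An `msa`.
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (dialect == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("empty alignment file: ", path)
    return(msa(sub("\\s.*$", "", names(ss)), as.character(ss)))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequence lines in Stockholm file: ", path)
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*$", lines))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("malformed Stockholm sequence line: ", lines[bad][1])
  ids <- vapply(parts, `[[`, character(1), 2L)
  seqs <- vapply(parts, `[[`, character(1), 3L)
  agg <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                paste, character(1), collapse = "")
  msa(names(agg), unname(agg))
}

#' Write an alignment as aligned FASTA
#' @param x An `msa`.
#' @param path Output path.
#' @export
write_alignment <- function(x, path) {
  ss <- Biostrings::BStringSet(x$seqs)
  names(ss) <- x$ids
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are kept to six decimals and bootstrap supports, when
#' present as `node.label`, are written as internal node labels so the file
#' round-trips through [ape::read.tree()].
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6L)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file path.
#' @return An [ape::phylo] tree (node labels preserved).
#' @export
read_newick <- function(path) ape::read.tree(path)

# TSV writing with a commented provenance header; used by pipeline stages.
write_tsv_report <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Domain interval table
#'
#' Validates a data frame of labelled domain intervals (`label`, `start`,
#' `end`), 1-based inclusive, used to annotate divergent sites.
#' @param label Domain names (e.g. `PAS1`, `GAF`, `PHY`, `PAS2`).
#' @param start,end 1-based inclusive residue coordinates.
#' @return Validated data frame.
#' @export
domain_intervals <- function(label, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start)) {
    stop("domain intervals must satisfy 1 <= start <= end")
  }
  d <- data.frame(label = as.character(label), start = start, end = end,
                  stringsAsFactors = FALSE)
  d <- d[order(d$start), , drop = FALSE]
  if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
    stop("domain intervals overlap")
  }
  d
}
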