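#' Scan configuration for the paralog-divergence scan
#'
#' @param min_conservation Minimum consensus fraction among the references
#'   for a column to count as deeply conserved (default 0.9).  This is the
#'   single most result-sensitive knob of the scan.
#' @param max_gap_fraction Highest tolerated reference gap fraction per
#'   column (default 0.2).
#' @param require_partner_match Require the partner paralog to carry the
#'   consensus residue at a reported column (default `TRUE`).
#' @param min_refs Minimum number of reference sequences (default 10).
#' @param mode `"frequency"` (report when the query departs from a
#'   sufficiently frequent consensus) or `"unseen-residue"` (additionally
#'   require that the query residue was never observed among the
#'   references).
#' @return A `scan_config` list.
#' @export
scan_config <- function(min_conservation = 0.9, max_gap_fraction = 0.2,
                        require_partner_match = TRUE, min_refs = 10L,
                        mode = c("frequency", "unseen-residue")) {
  mode <- match.arg(mode)
  stopifnot(min_conservation >= 0, min_conservation <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1, min_refs >= 1)
  structure(list(min_conservation = min_conservation,
                 max_gap_fraction = max_gap_fraction,
                 require_partner_match = isTRUE(require_partner_match),
                 min_refs = as.integer(min_refs), mode = mode),
            class = "scan_config")
}

#' Per-column conservation profile over reference sequences
#'
#' For every alignment column, the modal residue among the non-gap
#' reference rows (paralogs excluded), its frequency with gaps removed from
#' the denominator, the gap fraction, and the effective reference count.
#' Modal ties are broken alphabetically and flagged.
#'
#' @param x An `msa`.
#' @param reference_ids Ids of the reference rows (at least 4, all present).
#' @return Data frame, one row per column: `column`, `consensus_residue`
#'   (`NA` in all-gap columns), `consensus_fraction`, `gap_fraction`,
#'   `n_refs_effective`, `tied`, `residues_seen` (list-column of residues
#'   observed among references).
#' @export
conservation_profile <- function(x, reference_ids) {
  absent <- setdiff(reference_ids, x$ids)
  if (length(absent) > 0L) {
    stop("reference ids absent from alignment: ", paste(absent, collapse = ", "))
  }
  if (length(reference_ids) < 4L) stop("need at least 4 reference sequences")
  m <- msa_matrix(x)[reference_ids, , drop = FALSE]
  nref <- nrow(m)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nongap <- col[col != "-"]
    gap_fraction <- 1 - length(nongap) / nref
    if (length(nongap) == 0L) {
      return(data.frame(column = j, consensus_residue = NA_character_,
                        consensus_fraction = NA_real_, gap_fraction = 1,
                        n_refs_effective = 0L, tied = FALSE,
                        stringsAsFactors = FALSE))
    }
    cnt <- table(nongap)
    top <- max(cnt)
    modal <- sort(names(cnt)[cnt == top])
    data.frame(column = j, consensus_residue = modal[1L],
               consensus_fraction = top / length(nongap),
               gap_fraction = gap_fraction,
               n_refs_effective = length(nongap),
               tied = length(modal) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$residues_seen <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]; sort(unique(col[col != "-"]))
  })
  rownames(out) <- NULL
  out
}

#' Map an alignment column to a row's residue position
#'
#' The 1-based residue position is the count of non-gap characters in the
#' row up to and including the column; a gap at the column returns `NA`.
#'
#' @param x An `msa`.
#' @param row_id Row identifier.
#' @param column Column index (vectorised).
#' @return Integer vector of residue positions (`NA` at gaps).
#' @export
map_column_to_position <- function(x, row_id, column) {
  k <- match(row_id, x$ids)
  if (is.na(k)) stop("row id not in alignment: ", row_id)
  chars <- strsplit(x$seqs[k], "")[[1]]
  pos <- cumsum(chars != "-")
  out <- pos[column]
  out[chars[column] == "-"] <- NA_integer_
  as.integer(out)
}

#' Scan a duplicated paralog pair for divergence at conserved positions
#'
#' The core computation: a column is reported iff (a) the reference
#' consensus fraction is at least `min_conservation`, (b) the reference gap
#' fraction is at most `max_gap_fraction`, (c) the partner paralog carries
#' the consensus residue (when `require_partner_match`), and (d) the query
#' paralog carries a non-gap residue different from the consensus (in
#' `"unseen-residue"` mode, one never observed among the references).
#' Sites are ordered by query residue position and labelled with the
#' conventional notation consensus residue + query position + query residue
#' (e.g. `F113L`).
#'
#' @param x An `msa` containing references and both paralogs.
#' @param reference_ids Reference row ids (paralogs must not be among them).
#' @param partner_id Row id of the conserved paralog (e.g. PHYB1).
#' @param query_id Row id of the diverged paralog under scrutiny (e.g.
#'   PHYB2).
#' @param config A [scan_config()].
#' @return Data frame of divergent sites: `column`, `consensus_residue`,
#'   `consensus_fraction`, `partner_residue`, `query_residue`,
#'   `query_position`, `partner_position`, `domain_label`
#'   (`"inter-domain"` until [annotate_domains()]), `notation`.
#' @export
scan_paralog_divergence <- function(x, reference_ids, partner_id, query_id,
                                    config = scan_config()) {
  if (partner_id %in% reference_ids || query_id %in% reference_ids) {
    stop("partner and query must not be in the reference set")
  }
  for (id in c(partner_id, query_id)) {
    if (!(id %in% x$ids)) stop("row id not in alignment: ", id)
  }
  if (length(reference_ids) < config$min_refs) {
    stop(sprintf("only %d references; config requires at least %d",
                 length(reference_ids), config$min_refs))
  }
  prof <- conservation_profile(x, reference_ids)
  m <- msa_matrix(x)
  partner <- m[partner_id, ]
  query <- m[query_id, ]
  eligible <- !is.na(prof$consensus_fraction) &
    prof$consensus_fraction >= config$min_conservation &
    prof$gap_fraction <= config$max_gap_fraction
  hit <- eligible &
    query != "-" & query != prof$consensus_residue
  if (config$require_partner_match) {
    hit <- hit & partner == prof$consensus_residue
  }
  if (config$mode == "unseen-residue") {
    seen <- mapply(function(res, obs) res %in% obs, query, prof$residues_seen)
    hit <- hit & !seen
  }
  cols <- which(hit)
  qpos <- map_column_to_position(x, query_id, cols)
  ppos <- map_column_to_position(x, partner_id, cols)
  out <- data.frame(column = cols,
                    consensus_residue = prof$consensus_residue[cols],
                    consensus_fraction = prof$consensus_fraction[cols],
                    partner_residue = partner[cols],
                    query_residue = query[cols],
                    query_position = qpos,
                    partner_position = ppos,
                    domain_label = rep("inter-domain", length(cols)),
                    stringsAsFactors = FALSE)
  out$notation <- paste0(out$consensus_residue, out$query_position,
                         out$query_residue)
  out <- out[order(out$query_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate divergent sites with domain context
#'
#' Sets each site's `domain_label` to the label of the (non-overlapping,
#' 1-based inclusive) interval containing its query position, or
#' `"inter-domain"`.
#'
#' @param sites Data frame from [scan_paralog_divergence()].
#' @param domains Data frame from [domain_intervals()] (`label`, `start`,
#'   `end`).
#' @return `sites` with `domain_label` filled in.
#' @export
annotate_domains <- function(sites, domains) {
  domains <- domain_intervals(domains$label, domains$start, domains$end)
  if (nrow(sites) == 0L) return(sites)
  sites$domain_label <- vapply(sites$query_position, function(p) {
    k <- which(domains$start <= p & p <= domains$end)
    if (length(k) == 0L) "inter-domain" else domains$label[k[1L]]
  }, character(1))
  sites
}

#' Pairwise identity and difference report for a paralog pair
#'
#' Globally aligns the two sequences (affine gaps, BLOSUM62) and reports
#' percent identity over aligned columns, the number of substitution
#' (mismatch) columns, and the number of gap-containing (indel) columns —
#' kept separate so either reading of "differences including indels" can be
#' checked.
#'
#' @param seqA,seqB Amino-acid strings or single `protein_set` rows.
#' @return List: `percent_identity`, `n_substitutions`, `n_indel_positions`,
#'   `n_columns`.
#' @export
pairwise_paralog_report <- function(seqA, seqB) {
  if (is.list(seqA) || is.data.frame(seqA)) seqA <- seqA$residues
  if (is.list(seqB) || is.data.frame(seqB)) seqB <- seqB$residues
  p <- align_pair(seqA, seqB)
  a <- strsplit(p$aligned1, "")[[1]]
  b <- strsplit(p$aligned2, "")[[1]]
  gap <- a == "-" | b == "-"
  match <- !gap & a == b
  list(percent_identity = 100 * sum(match) / length(a),
       n_substitutions = sum(!gap & a != b),
       n_indel_positions = sum(gap),
       n_columns = length(a))
}
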