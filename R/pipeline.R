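# Pipeline orchestration: a flat key=value config, upfront validation, and
# staged execution (survey -> dedupe -> motifs -> classify -> diverge) with
# seeded reproducibility and provenance headers on every output table.

#' Build a pipeline configuration
#'
#' Paths may be `NA` to skip the corresponding stage.  Thresholds are
#' validated here, before any stage runs.
#'
#' @param proteome FASTA of proteins to survey.
#' @param domain_seed Seed alignment (aligned FASTA/Stockholm) for the
#'   domain profile.
#' @param motif_dir Directory of `motifNN.*` motif seed alignments, or `NA`.
#' @param anchors_fasta FASTA of anchor sequences, or `NA`.
#' @param anchor_labels TSV (id, subfamily) labelling the anchors, or `NA`.
#' @param family_alignment Aligned FASTA for the divergence scan, or `NA`.
#' @param reference_ids File of reference row ids (one per line), or `NA`.
#' @param partner,query Paralog row ids for the divergence scan.
#' @param evalue_cutoff Survey E-value cutoff (default 0.01).
#' @param motif_evalue_cutoff Motif presence cutoff (default 1).
#' @param min_coverage Domain completeness threshold (default 0.8).
#' @param min_conservation Divergence-scan conservation floor (default 0.9).
#' @param max_gap_fraction Divergence-scan gap ceiling (default 0.2).
#' @param n_bootstrap Bootstrap replicates for classification (default 100).
#' @param min_support Support threshold for subfamily assignment
#'   (default 50).
#' @param rng_seed Run seed; every random draw derives from it.
#' @param outdir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(proteome, domain_seed, motif_dir = NA,
                            anchors_fasta = NA, anchor_labels = NA,
                            family_alignment = NA, reference_ids = NA,
                            partner = NA, query = NA,
                            evalue_cutoff = 0.01, motif_evalue_cutoff = 1,
                            min_coverage = 0.8, min_conservation = 0.9,
                            max_gap_fraction = 0.2, n_bootstrap = 100,
                            min_support = 50, rng_seed = 1,
                            outdir = "pipeline_out") {
  cfg <- list(proteome = proteome, domain_seed = domain_seed,
              motif_dir = motif_dir, anchors_fasta = anchors_fasta,
              anchor_labels = anchor_labels,
              family_alignment = family_alignment,
              reference_ids = reference_ids, partner = partner, query = query,
              evalue_cutoff = evalue_cutoff,
              motif_evalue_cutoff = motif_evalue_cutoff,
              min_coverage = min_coverage,
              min_conservation = min_conservation,
              max_gap_fraction = max_gap_fraction,
              n_bootstrap = n_bootstrap, min_support = min_support,
              rng_seed = rng_seed, outdir = outdir)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk <- function(x, lo, hi, name) {
    if (!is.numeric(x) || is.na(x) || x < lo || x > hi) {
      stop(sprintf("config: %s must be in [%s, %s]", name, lo, hi))
    }
  }
  chk(cfg$evalue_cutoff, 0, Inf, "evalue_cutoff")
  chk(cfg$motif_evalue_cutoff, 0, Inf, "motif_evalue_cutoff")
  chk(cfg$min_coverage, 0, 1, "min_coverage")
  chk(cfg$min_conservation, 0, 1, "min_conservation")
  chk(cfg$max_gap_fraction, 0, 1, "max_gap_fraction")
  chk(cfg$n_bootstrap, 0, 1e6, "n_bootstrap")
  chk(cfg$min_support, 0, 100, "min_support")
  for (p in c("proteome", "domain_seed")) {
    if (is.na(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop("config: required input missing or unreadable: ", p)
    }
  }
  for (p in c("motif_dir", "anchors_fasta", "anchor_labels",
              "family_alignment", "reference_ids")) {
    if (!is.na(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config: input does not exist: ", p, " = ", cfg[[p]])
    }
  }
  invisible(TRUE)
}

#' Write / read a flat key=value config file
#'
#' The on-disk form round-trips losslessly through
#' [read_pipeline_config()].
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) as.character(v), character(1))
  writeLines(paste0(names(cfg), " = ", vals), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @return `read_pipeline_config` returns the validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^\\s*(\\S+)\\s*=\\s*(.*?)\\s*$", lines))
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  num <- c("evalue_cutoff", "motif_evalue_cutoff", "min_coverage",
           "min_conservation", "max_gap_fraction", "n_bootstrap",
           "min_support", "rng_seed")
  args <- as.list(vals)
  names(args) <- keys
  for (k in intersect(num, keys)) args[[k]] <- as.numeric(args[[k]])
  for (k in setdiff(names(args), num)) {
    if (identical(args[[k]], "NA")) args[[k]] <- NA
  }
  do.call(pipeline_config, args)
}

pipeline_header <- function(cfg, stage) {
  c(sprintf("paraldiv %s | stage=%s", as.character(utils::packageVersion("paraldiv")), stage),
    sprintf("seed=%d evalue_cutoff=%g min_coverage=%g min_conservation=%g max_gap_fraction=%g n_bootstrap=%d",
            as.integer(cfg$rng_seed), cfg$evalue_cutoff, cfg$min_coverage,
            cfg$min_conservation, cfg$max_gap_fraction,
            as.integer(cfg$n_bootstrap)))
}

#' Run the full pipeline
#'
#' Stages: domain survey, locus dedup, motif screen (if a catalog is
#' given), subfamily classification (if anchors are given), and the
#' paralog-divergence scan (if a family alignment is given).  Each stage
#' writes a TSV with a provenance header into `cfg$outdir`; survey and
#' dedupe are deterministic, calibration and bootstrap draws derive from
#' `cfg$rng_seed`.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a named list of the stage outputs.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$outdir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "")
    cat(msg, "\n", sep = "", file = log, append = TRUE)
  }
  out <- list()
  say("[survey] building domain profile from %s", cfg$domain_seed)
  seed_aln <- read_alignment(cfg$domain_seed)
  model <- build_profile(seed_aln, model_id = "domain")
  model <- calibrate_evalue(model, seed = cfg$rng_seed)
  proteome <- read_fasta(cfg$proteome)
  hits <- survey_proteome(model, proteome, evalue_cutoff = cfg$evalue_cutoff,
                          min_coverage = cfg$min_coverage)
  say("[survey] %d hits at E <= %g", nrow(hits), cfg$evalue_cutoff)
  hits_out <- hits[, setdiff(names(hits), "model_map")]
  write_tsv_report(hits_out, file.path(cfg$outdir, "survey_hits.tsv"),
                   pipeline_header(cfg, "survey"))
  out$survey <- hits

  deduped <- dedupe_loci(hits, proteome)
  say("[dedupe] %d unique loci (%d with complete domain)",
      nrow(deduped), sum(deduped$complete))
  write_tsv_report(deduped[, setdiff(names(deduped), "model_map")],
                   file.path(cfg$outdir, "unique_loci.tsv"),
                   pipeline_header(cfg, "dedupe"))
  out$dedupe <- deduped
  members <- proteome[proteome$id %in% deduped$protein_id[deduped$complete], ]

  if (!is.na(cfg$motif_dir)) {
    catalog <- read_motif_catalog(cfg$motif_dir, seed = cfg$rng_seed)
    pres <- screen_motifs(members, catalog,
                          evalue_cutoff = cfg$motif_evalue_cutoff)
    say("[motifs] %d proteins x %d motifs, %d presence calls",
        nrow(pres), ncol(pres), sum(attr(pres, "presence")))
    cells <- ifelse(attr(pres, "presence"), formatC(unclass(pres), format = "g"), ".")
    write_tsv_report(data.frame(protein_id = rownames(pres), cells,
                                check.names = FALSE),
                     file.path(cfg$outdir, "motif_matrix.tsv"),
                     pipeline_header(cfg, "motifs"))
    out$motifs <- pres
  }

  if (!is.na(cfg$anchors_fasta) && !is.na(cfg$anchor_labels)) {
    anchors_seq <- read_fasta(cfg$anchors_fasta)
    lab <- read_tsv_report(cfg$anchor_labels)
    anchors <- setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
    pool <- protein_set(c(members$id, anchors_seq$id),
                        c(members$residues, anchors_seq$residues))
    aln <- align_progressive(pool)
    stripped <- strip_gap_columns(aln, max_gap_fraction = 0.5)
    tree <- bootstrap_support(stripped$msa, n_replicates = cfg$n_bootstrap,
                              seed = cfg$rng_seed)
    asg <- assign_subfamilies(tree, anchors, min_support = cfg$min_support)
    say("[classify] %d/%d queries assigned (NJ-based, %d bootstraps)",
        sum(asg$status == "assigned"), nrow(asg), as.integer(cfg$n_bootstrap))
    write_newick(tree, file.path(cfg$outdir, "classification.nwk"))
    write_tsv_report(asg, file.path(cfg$outdir, "subfamily_assignments.tsv"),
                     pipeline_header(cfg, "classify"))
    out$classify <- list(tree = tree, assignments = asg)
  }

  if (!is.na(cfg$family_alignment) && !is.na(cfg$reference_ids)) {
    fam <- read_alignment(cfg$family_alignment)
    refs <- readLines(cfg$reference_ids)
    refs <- refs[nzchar(trimws(refs))]
    sites <- scan_paralog_divergence(
      fam, refs, cfg$partner, cfg$query,
      scan_config(min_conservation = cfg$min_conservation,
                  max_gap_fraction = cfg$max_gap_fraction,
                  min_refs = min(10L, length(refs))))
    say("[diverge] %d divergent site(s): %s", nrow(sites),
        paste(sites$notation, collapse = ", "))
    write_tsv_report(sites[, setdiff(names(sites), "residues_seen")],
                     file.path(cfg$outdir, "divergent_sites.tsv"),
                     pipeline_header(cfg, "diverge"))
    out$diverge <- sites
  }
  invisible(out)
}

#' Write a seeded synthetic fixture bundle
#'
#' Front-end to the generators: emits a proteome FASTA with planted
#' domains, the matching truth TSV, a domain seed alignment, an
#' ortholog-family alignment with a planted diverged paralog pair, the
#' reference-id list and the divergence truth TSV.
#'
#' @param outdir Output directory.
#' @param seed Integer seed controlling the whole bundle.
#' @param n_proteins,n_with_domain,n_refs,family_columns,n_sites Bundle
#'   sizes (defaults: 50 proteins, 20 with domains, 20 references, 300
#'   columns, 4 planted sites).
#' @return Invisibly, the list of written paths.
#' @export
simulate_fixtures <- function(outdir, seed = 1, n_proteins = 50L,
                              n_with_domain = 20L, n_refs = 20L,
                              family_columns = 300L, n_sites = 4L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  consensus <- sample_residues(50L)
  seed_rows <- vapply(1:5, function(i) {
    paste(mutate_sequence(strsplit(consensus, "")[[1]], 0.05, aa_background()),
          collapse = "")
  }, character(1))
  gen <- generate_proteome(n_proteins, n_with_domain, consensus,
                           truncation_fraction = 0.1, seed = seed + 1L)
  fam <- generate_ortholog_family(n_refs, family_columns, seed = seed + 2L)
  div <- plant_paralog_divergence(fam$msa, n_sites, seed = seed + 3L)
  paths <- list(
    proteome = file.path(outdir, "proteome.fasta"),
    proteome_truth = file.path(outdir, "proteome_truth.tsv"),
    domain_seed = file.path(outdir, "domain_seed.afa"),
    family = file.path(outdir, "family.afa"),
    family_refs = file.path(outdir, "family_refs.txt"),
    divergence_truth = file.path(outdir, "divergence_truth.tsv"))
  write_fasta(gen$proteins, paths$proteome)
  write_tsv_report(gen$truth$planted_domains, paths$proteome_truth,
                   sprintf("synthetic truth | seed=%d", seed))
  write_alignment(msa(sprintf("SEED%02d", 1:5), seed_rows), paths$domain_seed)
  write_alignment(div$msa, paths$family)
  writeLines(fam$msa$ids, paths$family_refs)
  write_tsv_report(div$truth, paths$divergence_truth,
                   sprintf("synthetic truth | seed=%d", seed))
  invisible(paths)
}
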