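test_that("conservation profile counts match a direct oracle", {
  x <- msa(sprintf("r%d", 1:5), c("AG", "AG", "AG", "AG", "CG"))
  p <- conservation_profile(x, x$ids)
  expect_identical(p$consensus_residue, c("A", "G"))
  expect_equal(p$consensus_fraction, c(0.8, 1.0))
  expect_equal(p$gap_fraction, c(0, 0))
  # gaps leave the denominator; heavy gaps are visible in gap_fraction
  y <- msa(sprintf("r%d", 1:5), c("A", "A", "-", "-", "-"))
  py <- conservation_profile(y, y$ids)
  expect_equal(py$consensus_fraction, 1.0)
  expect_equal(py$gap_fraction, 0.6)
  expect_equal(py$n_refs_effective, 2L)
  # modal ties break alphabetically and are flagged
  z <- msa(sprintf("r%d", 1:4), c("T", "T", "C", "C"))
  pz <- conservation_profile(z, z$ids)
  expect_identical(pz$consensus_residue, "C")
  expect_true(pz$tied)
  expect_error(conservation_profile(x, c(x$ids, "nope")), "absent")
  expect_error(conservation_profile(x, x$ids[1:3]), "at least 4")
})

test_that("column-to-position mapping counts non-gap residues", {
  x <- msa(c("a", "b"), c("A-CD", "AQCD"))
  expect_equal(map_column_to_position(x, "a", 3), 2L)
  expect_equal(map_column_to_position(x, "a", 2), NA_integer_)
  expect_equal(map_column_to_position(x, "b", 1:4), 1:4)
  # inverse lookup identity on non-gap cells
  chars <- strsplit(x$seqs[1], "")[[1]]
  nongap <- which(chars != "-")
  pos <- map_column_to_position(x, "a", nongap)
  expect_identical(nongap[pos], nongap)
})

test_that("an undiverged paralog pair yields no sites", {
  fam <- generate_ortholog_family(12, 120, seed = 41)
  d <- plant_paralog_divergence(fam$msa, 0, seed = 2)
  sites <- scan_paralog_divergence(d$msa, fam$msa$ids, "paralogA", "paralogB",
                                   scan_config(min_refs = 10))
  expect_equal(nrow(sites), 0L)
  expect_equal(nrow(d$truth), 0L)
})

test_that("planted divergent columns are recovered exactly, matching brute force", {
  for (s in 1:20) {
    fam <- generate_ortholog_family(12, 150, seed = 100 + s)
    d <- plant_paralog_divergence(fam$msa, 3, seed = 200 + s)
    sites <- scan_paralog_divergence(d$msa, fam$msa$ids, "paralogA",
                                     "paralogB", scan_config(min_refs = 10))
    expect_identical(sites$column, d$truth$column)
    bf <- brute_force_divergence(d$msa, fam$msa$ids, "paralogA", "paralogB")
    expect_identical(sites$column, bf)
    # notation is reconstructible from the fields
    expect_identical(sites$notation,
                     paste0(sites$consensus_residue, sites$query_position,
                            sites$query_residue))
    expect_true(all(sites$partner_residue == sites$consensus_residue))
    expect_true(all(sites$query_residue != sites$consensus_residue))
  }
})

test_that("raising the conservation floor never adds sites; ref order is irrelevant", {
  fam <- generate_ortholog_family(15, 200, seed = 51)
  d <- plant_paralog_divergence(fam$msa, 5, seed = 52)
  floors <- c(0.7, 0.8, 0.9, 0.95, 1.0)
  counts <- vapply(floors, function(f) {
    nrow(scan_paralog_divergence(d$msa, fam$msa$ids, "paralogA", "paralogB",
                                 scan_config(min_conservation = f,
                                             min_refs = 10)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  sites1 <- scan_paralog_divergence(d$msa, fam$msa$ids, "paralogA", "paralogB",
                                    scan_config(min_refs = 10))
  sites2 <- scan_paralog_divergence(d$msa, rev(fam$msa$ids), "paralogA",
                                    "paralogB", scan_config(min_refs = 10))
  expect_identical(sites1, sites2)
  # swapping partner and query mirrors: the planted residues sit in paralogB,
  # so with the partner-match requirement on the new partner (= paralogB) no
  # column passes
  swapped <- scan_paralog_divergence(d$msa, fam$msa$ids, "paralogB",
                                     "paralogA", scan_config(min_refs = 10))
  expect_equal(nrow(swapped), 0L)
})

test_that("scan validates its configuration and inputs", {
  fam <- generate_ortholog_family(6, 80, seed = 61)
  d <- plant_paralog_divergence(fam$msa, 2, seed = 62)
  expect_error(scan_paralog_divergence(d$msa, fam$msa$ids, "paralogA",
                                       "paralogB",
                                       scan_config(min_refs = 10)),
               "references")
  expect_error(scan_paralog_divergence(d$msa, c(fam$msa$ids, "paralogA"),
                                       "paralogA", "paralogB",
                                       scan_config(min_refs = 4)),
               "must not")
  expect_error(scan_config(min_conservation = 1.5), "min_conservation")
})

test_that("unseen-residue mode only reports residues absent from the references", {
  # build a column where the query residue is rare-but-seen among refs
  refs <- c("AAAAAAAAAQ", "AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA",
            "AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA",
            "AAAAAAAAAA", "AAAAAAAAAA")
  x <- msa(c(sprintf("r%02d", 1:10), "pa", "pb"),
           c(refs, "AAAAAAAAAA", "CAAAAAAAAQ"))
  freq <- scan_paralog_divergence(x, sprintf("r%02d", 1:10), "pa", "pb",
                                  scan_config(min_refs = 10))
  expect_identical(freq$column, c(1L, 10L))
  # the query's Q at column 10 was observed once among the references, so
  # unseen-residue mode drops it; the C at column 1 was never seen
  unseen <- scan_paralog_divergence(x, sprintf("r%02d", 1:10), "pa", "pb",
                                    scan_config(min_refs = 10,
                                                mode = "unseen-residue"))
  expect_identical(unseen$column, 1L)
})

test_that("domain annotation places sites in inclusive intervals", {
  sites <- data.frame(column = c(400, 180, 480), consensus_residue = "P",
                      consensus_fraction = 1, partner_residue = "P",
                      query_residue = "Q",
                      query_position = c(343, 180, 480),
                      partner_position = c(341, 178, 478),
                      domain_label = "inter-domain",
                      notation = c("P343Q", "X180Y", "Z480W"),
                      stringsAsFactors = FALSE)
  domains <- data.frame(label = c("PAS1", "GAF"), start = c(80, 300),
                        end = c(200, 480))
  ann <- annotate_domains(sites, domains)
  expect_identical(ann$domain_label[ann$query_position == 343], "GAF")
  expect_identical(ann$domain_label[ann$query_position == 180], "PAS1")
  # boundary position equal to the interval end is inside
  expect_identical(ann$domain_label[ann$query_position == 480], "GAF")
  out <- annotate_domains(transform(sites, query_position = c(250, 550, 700)),
                          domains)
  expect_true(all(out$domain_label == "inter-domain"))
  expect_error(annotate_domains(sites, data.frame(label = c("a", "b"),
                                                  start = c(1, 100),
                                                  end = c(150, 200))),
               "overlap")
})

test_that("an upstream insertion in the query offsets the paired numbering", {
  fam <- generate_ortholog_family(12, 120, indel_rate = 0, seed = 71)
  d <- plant_paralog_divergence(fam$msa, 1, seed = 72)
  site_col <- d$truth$column[1]
  stopifnot(site_col >= 2L)
  # plant a 2-residue insertion in the query upstream of the flagged column:
  # two new columns where only paralogB has residues
  m <- msa_matrix(d$msa)
  at <- site_col
  ins <- matrix("-", nrow(m), 2, dimnames = list(rownames(m), NULL))
  ins["paralogB", ] <- c("G", "G")
  m2 <- cbind(m[, 1:(at - 1), drop = FALSE], ins,
              m[, at:ncol(m), drop = FALSE])
  x2 <- msa(rownames(m2), apply(m2, 1, paste, collapse = ""))
  sites <- scan_paralog_divergence(x2, fam$msa$ids, "paralogA", "paralogB",
                                   scan_config(min_refs = 10))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$partner_position, sites$query_position - 2L)
})
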