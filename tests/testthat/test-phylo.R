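test_that("gap-column stripping follows the rule and maps compose to identity", {
  x <- msa(sprintf("r%d", 1:4), c("ACDA", "A-DA", "ACDA", "ACDA"))
  s <- strip_gap_columns(x)
  expect_equal(s$msa$n_columns, 3L)
  expect_identical(s$retained, c(1L, 3L, 4L))
  expect_identical(s$col_map[s$retained], seq_along(s$retained))
  # gapless alignment is untouched
  g <- msa(c("a", "b"), c("ACD", "ACD"))
  sg <- strip_gap_columns(g)
  expect_identical(sg$msa$seqs, g$seqs)
  expect_identical(sg$col_map, 1:3)
  # relaxed threshold keeps the 25%-gap column
  expect_equal(strip_gap_columns(x, max_gap_fraction = 0.25)$msa$n_columns, 4L)
})

test_that("distances match the Kimura closed form, are symmetric, and saturate", {
  x <- msa(c("a", "b"),
           c(strrep("A", 100), paste0(strrep("C", 10), strrep("A", 90))))
  d <- compute_distances(x)
  expect_equal(d["a", "b"], -log(1 - 0.1 - 0.2 * 0.01))
  expect_equal(d["a", "a"], 0)
  set.seed(19)
  fam <- generate_ortholog_family(6, 80, indel_rate = 0.02, seed = 19)
  dr <- compute_distances(fam$msa)
  expect_equal(dr, t(dr), ignore_attr = TRUE)
  sat <- msa(c("a", "b"), c(strrep("A", 60), strrep("C", 60)))
  expect_warning(ds <- compute_distances(sat), "saturated")
  expect_true(is.finite(ds["a", "b"]))
  expect_true(attr(ds, "saturated")["a", "b"])
})

test_that("NJ recovers a 4-taxon additive tree with exact branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  dm <- cophenetic(tr)
  out <- nj_tree(dm)
  expect_identical(ape::dist.topo(ape::unroot(tr), out)[1], 0)
  term <- out$edge[, 2] <= 4
  expect_equal(sort(out$edge.length[term]), rep(1, 4))
  expect_equal(out$edge.length[!term], 2)   # the single internal edge
  # malformed matrices are rejected
  bad <- dm; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  bad2 <- dm; bad2[1, 2] <- bad2[2, 1] <- NaN
  expect_error(nj_tree(bad2), "finite")
})

test_that("NJ recovers random additive topologies and never emits negative edges", {
  set.seed(23)
  for (r in 1:20) {
    tr <- ape::rtree(8)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    out <- nj_tree(cophenetic(tr))
    expect_identical(ape::dist.topo(ape::unroot(tr), out)[1], 0)
    expect_true(all(out$edge.length >= 0))
  }
})

test_that("NJ agrees with brute-force minimum evolution on additive 5- and 6-taxon inputs", {
  skip_if_not_installed("phangorn")
  me_score <- function(topo, dm) {
    topo$edge.length <- rep(1, nrow(topo$edge))
    n <- length(topo$tip.label)
    pairs <- t(combn(n, 2))
    A <- matrix(0, nrow(pairs), nrow(topo$edge))
    for (k in seq_len(nrow(pairs))) {
      nodes <- ape::nodepath(topo, pairs[k, 1], pairs[k, 2])
      for (s in seq_len(length(nodes) - 1)) {
        e <- which((topo$edge[, 1] == nodes[s] & topo$edge[, 2] == nodes[s + 1]) |
                     (topo$edge[, 2] == nodes[s] & topo$edge[, 1] == nodes[s + 1]))
        A[k, e] <- 1
      }
    }
    dvec <- dm[cbind(topo$tip.label[pairs[, 1]], topo$tip.label[pairs[, 2]])]
    b <- qr.solve(A, dvec)
    sum(b)
  }
  set.seed(29)
  for (n in c(5, 6)) {
    for (r in 1:3) {
      tr <- ape::rtree(n)
      tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
      dm <- cophenetic(tr)
      all_topos <- phangorn::allTrees(n, rooted = FALSE,
                                      tip.label = rownames(dm))
      scores <- vapply(all_topos, me_score, numeric(1), dm = dm)
      best <- all_topos[[which.min(scores)]]
      out <- nj_tree(dm)
      expect_identical(ape::dist.topo(best, out)[1], 0)
    }
  }
})

test_that("bootstrap supports are high on well-separated clades and reproducible", {
  set.seed(31)
  anc <- paraldiv:::sample_residues(150)
  drift <- function(base, rate) paste(paraldiv:::mutate_sequence(
    strsplit(base, "")[[1]], rate, aa_background()), collapse = "")
  baseA <- drift(anc, 0.4); baseB <- drift(anc, 0.4)
  rows <- c(vapply(1:4, function(i) drift(baseA, 0.03), character(1)),
            vapply(1:4, function(i) drift(baseB, 0.03), character(1)))
  aln <- msa(c(paste0("A", 1:4), paste0("B", 1:4)), rows)
  t1 <- suppressWarnings(bootstrap_support(aln, n_replicates = 100, seed = 7))
  split_support <- function(tree) {
    sp <- paraldiv:::tree_splits(tree)
    # canonical splits exclude the side holding the lexicographically
    # smallest tip, so the A|B split is keyed by the B side
    key <- paste(sort(paste0("B", 1:4)), collapse = "|")
    as.numeric(tree$node.label[which(sp == key)])
  }
  expect_gte(split_support(t1), 95)
  t2 <- suppressWarnings(bootstrap_support(aln, n_replicates = 100, seed = 7))
  expect_identical(t1$node.label, t2$node.label)
  t0 <- suppressWarnings(bootstrap_support(aln, n_replicates = 0))
  expect_null(t0$node.label)
})

test_that("bipartition supports are invariant under leaf relabeling", {
  set.seed(33)
  fam <- generate_ortholog_family(8, 120, indel_rate = 0, seed = 33)
  t1 <- bootstrap_support(fam$msa, n_replicates = 50, seed = 5)
  # permute row order (labels travel with their sequences)
  m <- msa_matrix(fam$msa)
  perm <- sample(nrow(m))
  aln2 <- msa(rownames(m)[perm], apply(m[perm, ], 1, paste, collapse = ""))
  t2 <- bootstrap_support(aln2, n_replicates = 50, seed = 5)
  s1 <- setNames(t1$node.label, paraldiv:::tree_splits(t1))
  s2 <- setNames(t2$node.label, paraldiv:::tree_splits(t2))
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 0)
  expect_identical(s1[shared], s2[shared])
})

test_that("anchored subfamily assignment follows the smallest-pure-clade rule", {
  set.seed(35)
  anc <- paraldiv:::sample_residues(150)
  drift <- function(base, rate) paste(paraldiv:::mutate_sequence(
    strsplit(base, "")[[1]], rate, aa_background()), collapse = "")
  bases <- lapply(1:3, function(i) drift(anc, 0.35))
  ids <- c(); rows <- c(); truth <- c()
  for (g in 1:3) {
    for (k in 1:4) {
      ids <- c(ids, sprintf("G%d_%d", g, k))
      rows <- c(rows, drift(bases[[g]], 0.04))
      truth <- c(truth, c("I", "II", "III")[g])
    }
  }
  aln <- msa(ids, rows)
  tree <- suppressWarnings(bootstrap_support(aln, n_replicates = 100, seed = 11))
  anchors <- setNames(truth[c(1, 2, 5, 6, 9, 10)], ids[c(1, 2, 5, 6, 9, 10)])
  asg <- assign_subfamilies(tree, anchors)
  want <- setNames(truth, ids)[asg$protein_id]
  expect_true(all(asg$status == "assigned"))
  expect_identical(asg$subfamily, unname(want))
  # anchor input order cannot matter
  asg2 <- assign_subfamilies(tree, anchors[c(3, 1, 6, 2, 5, 4)])
  expect_identical(asg, asg2)
  # a query identical in sequence to an anchor joins that anchor's subfamily;
  # support stays high (bootstrap can merge other near-identical leaves into
  # the smallest pure group, so 100 is not guaranteed)
  aln3 <- msa(c(ids, "twin"), c(rows, rows[1]))
  tree3 <- suppressWarnings(bootstrap_support(aln3, n_replicates = 100, seed = 12))
  asg3 <- assign_subfamilies(tree3, anchors)
  twin <- asg3[asg3$protein_id == "twin", ]
  expect_identical(twin$subfamily, "I")
  expect_gte(twin$support, 70)
  expect_error(assign_subfamilies(tree, c(anchors, ghost = "IV")),
               "missing.*ghost")
})
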