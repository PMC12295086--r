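test_that("pairwise statistics: identity anchors, symmetry, brute-force score", {
  expect_equal(pairwise_stats("MKLVINW", "MKLVINW")$identity, 1.0)
  expect_error(pairwise_stats("", "MKLV"), "empty")

  set.seed(14)
  a <- paste(sample(names(glycanyon:::AA_BACKGROUND), 60, TRUE),
             collapse = "")
  b <- paste(sample(names(glycanyon:::AA_BACKGROUND), 60, TRUE),
             collapse = "")
  st_ab <- pairwise_stats(a, b)
  st_ba <- pairwise_stats(b, a)
  expect_equal(st_ab$identity, st_ba$identity, tolerance = 1e-12)
  expect_equal(st_ab$evalue, st_ba$evalue, tolerance = 1e-9)

  # unrelated sequence vs its reversal: identity near background, huge E
  rev_a <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  st <- pairwise_stats(a, rev_a)
  expect_lt(st$identity, 0.35)
  expect_gt(st$evalue, 1e-4)

  # local score against an independently written affine-gap recursion
  submat <- glycanyon:::get_submatrix("BLOSUM62")
  for (pair in list(c("MKWLV", "MKLV"), c("WWACDE", "WACDE"),
                    c("HNWYR", "HNYR"))) {
    got <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pair[1]), Biostrings::AAString(pair[2]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(got),
                 brute_global_score(pair[1], pair[2], submat),
                 tolerance = 1e-9)
  }
})

test_that("node collapse follows the greedy identity rule", {
  recs <- sequence_records(c("a", "b"), c("MKLVINWGG", "MKLVINWGG"))
  nodes <- collapse_nodes(recs, 0.9)
  expect_equal(nrow(nodes), 1L)
  expect_equal(nodes$n_members, 2L)

  # ~50% identity at threshold 0.9 -> two nodes
  recs2 <- sequence_records(
    c("a", "b"),
    c("MKLVINWGGERTASDFGH", "MKTVPNWAGERHASDAGW"))
  expect_equal(nrow(collapse_nodes(recs2, 0.9)), 2L)

  # founder plus 10 variants at 92% identity to it -> one node around the
  # founder representative
  fam <- make_family(family_spec(founder_length = 120, n_species = 10,
                                 families = list(A = 1L),
                                 within_identity = 0.92, seed = 3))
  with_founder <- rbind(
    sequence_records("founder", fam$founders[["A"]], "sp00"),
    fam$records)
  nodes3 <- collapse_nodes(with_founder, 0.9)
  expect_equal(nrow(nodes3), 1L)
  expect_equal(nodes3$n_members, 11L)
  expect_identical(nodes3$node, "founder")
})

test_that("SSN construction separates families and is cutoff-monotone", {
  fam <- make_family(family_spec(
    founder_length = 150, n_species = 4,
    families = list(A = 1L, B = 1L), within_identity = 0.75, seed = 21))
  nodes <- collapse_nodes(fam$records, 0.9)
  pairs <- ssn_pair_table(nodes)
  strict <- build_ssn(nodes, 1e-10, pairs = pairs)
  expect_equal(strict$n_components, 2L)
  # relaxing the cutoff can only merge components and add edges
  cuts <- c(1e-40, 1e-20, 1e-10, 1e-3, 1, 10)
  comp_counts <- integer(); edge_counts <- integer()
  for (ct in cuts) {
    g <- build_ssn(nodes, ct, pairs = pairs)
    comp_counts <- c(comp_counts, g$n_components)
    edge_counts <- c(edge_counts, nrow(g$edges))
  }
  expect_true(all(diff(edge_counts) >= 0))
  expect_true(all(diff(comp_counts) <= 0))

  single <- build_ssn(collapse_nodes(
    sequence_records("x", "MKLVINWGGERTASDFGHMKLVINWGG"), 0.9), 1e-10)
  expect_equal(single$n_components, 1L)
  expect_equal(nrow(single$edges), 0L)
})

test_that("co-distribution bookkeeping: means, venn, conservation of totals", {
  mk <- function(species, cluster) {
    data.frame(id = paste0(seq_along(species), cluster),
               species = species, cluster = cluster,
               stringsAsFactors = FALSE)
  }
  four_each <- mk(rep(c("P", "Q", "R"), each = 4), "A")
  expect_equal(co_distribution(four_each)$mean_paralogs[["A"]], 4.0)

  both <- rbind(
    mk(rep(sprintf("s%02d", 1:7), 2), rep(c("A", "B"), each = 7)),
    mk(c("s08", "s09"), "A"), mk("s10", "B"))
  cd <- co_distribution(both)
  expect_equal(cd$venn[["A+B"]], 7L)
  expect_equal(cd$venn[["A"]], 2L)
  expect_equal(cd$venn[["B"]], 1L)
  expect_equal(sum(cd$venn), 10L)

  bad <- mk(c("P", ""), "A")
  expect_error(co_distribution(bad), "missing species")
})

test_that("generator truth is recovered exactly", {
  spec <- family_spec(
    founder_length = 120, n_species = 6,
    families = list(A = 4L, B = c(1L, 1L, 1L, 1L, 0L, 0L)),
    within_identity = 0.85, seed = 17)
  fam <- make_family(spec)
  cd <- co_distribution(fam$truth)
  expect_equal(cd$mean_paralogs[["A"]], 4.0)
  expect_equal(cd$mean_paralogs[["B"]], 1.0)
  expect_equal(cd$venn[["A+B"]], 4L)
  expect_equal(cd$venn[["A"]], 2L)
  # identities hit the target exactly (mutated-position construction)
  founder <- fam$founders[["A"]]
  member <- fam$records$sequence[fam$truth$cluster == "A"][1]
  same <- mean(strsplit(founder, "")[[1]] == strsplit(member, "")[[1]])
  expect_equal(same, 0.85, tolerance = 1 / 120)
})

test_that("conservation profile anchors, invariances, and errors", {
  # all-W column scores exactly 1; background-frequency column scores ~0
  allw <- conservation_profile(rep(strrep("W", 3), 5))
  expect_equal(allw$per_column, rep(1, 3))
  # any invariant column scores 1 (per-column point-mass normalization)
  alla <- conservation_profile(rep("AAAA", 6))
  expect_equal(alla$per_column, rep(1, 4))

  # one column whose observed frequencies equal the background exactly
  bg <- glycanyon:::AA_BACKGROUND
  counts <- round(bg * 1000)
  prof_bg <- conservation_profile(matrix(rep(names(counts), counts),
                                         ncol = 1))
  expect_lt(prof_bg$per_column[1], 0.02)

  m <- make_msa(30, 60, conserved_columns = c(10, 20, 30), seed = 2)
  prof <- conservation_profile(m)
  expect_setequal(order(-prof$per_column)[1:3], c(10, 20, 30))
  # row-permutation invariance
  perm <- m[sample(nrow(m)), ]
  expect_equal(conservation_profile(perm)$per_column, prof$per_column)

  expect_error(conservation_profile(c("AAA", "AA")), "ragged")
  expect_error(conservation_profile(rep("AAA", 4)), ">= 5 rows")
  # gappy columns flagged
  gap <- rbind(matrix("-", 4, 2), matrix("A", 2, 2))
  expect_true(all(conservation_profile(gap)$low_confidence))
})

test_that("conservation maps onto structures and contrasts the canyon", {
  scaf <- toy_scaffold(5)
  pc <- glycanyon:::protein_ca(scaf$model)
  L <- nchar(pc$seq)
  # MSA whose first row is the scaffold sequence; identical rows
  msa <- do.call(rbind, replicate(6, strsplit(pc$seq, "")[[1]],
                                  simplify = FALSE))
  rownames(msa) <- sprintf("r%d", 1:6)
  prof <- conservation_profile(msa)
  mapped <- map_conservation(prof, msa, "r1", scaf$model)
  expect_equal(nrow(mapped), L)
  expect_equal(mapped$score, rep(1, L))

  # conserved only at planted canyon positions -> canyon mean higher
  fx <- planted_fixture(seed = 42, n_sites = 5, glcn_site = 2)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  lin <- canyon_lining(fx$scaffold$model, comp, 4.5)
  pc2 <- glycanyon:::protein_ca(fx$scaffold$model)
  canyon_cols <- match(lin$key, pc2$keys)
  set.seed(31)
  base <- vapply(seq_len(6), function(i) {
    paste(sample(names(glycanyon:::AA_BACKGROUND), nchar(pc2$seq),
                 replace = TRUE), collapse = "")
  }, "")
  m2 <- do.call(rbind, strsplit(base, ""))
  m2[1, ] <- strsplit(pc2$seq, "")[[1]]
  for (cc in canyon_cols) m2[, cc] <- m2[1, cc]   # conserve canyon columns
  rownames(m2) <- sprintf("r%d", 1:6)
  prof2 <- conservation_profile(m2)
  mapped2 <- map_conservation(prof2, m2, "r1", fx$scaffold$model,
                              min_identity = 0.0)
  contrast <- conservation_contrast(mapped2, lin)
  expect_gt(contrast$mean_in, contrast$mean_out)

  # profile row shorter than the modelled structure -> error
  short <- m2[, 1:10]
  expect_error(map_conservation(conservation_profile(short), short, "r1",
                                fx$scaffold$model),
               "shorter")
})
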