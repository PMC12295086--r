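test_that("single-linkage clustering merges and splits at the radius", {
  two_sugars <- function(sep) {
    a <- make_sugar("Man", seq_num = 1L)$atoms
    b <- make_sugar("Man", seq_num = 2L)$atoms
    b[, "x"] <- b[, "x"] + sep
    glycanyon:::new_structure_model("pair", rbind(a, b))
  }
  near <- cluster_subsites(two_sugars(0.5), 1.8)
  expect_length(near$subsites, 1L)
  expect_equal(near$subsites[[1]]$member_count, 2L)
  far <- cluster_subsites(two_sugars(6), 1.8)
  expect_length(far$subsites, 2L)
})

test_that("planted 9-site composite is fully recovered and labelled", {
  fx <- planted_fixture(seed = 42, jitter = 0.3)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  ss <- cluster_subsites(comp, 1.8)
  expect_length(ss$subsites, 9L)
  expect_true(all(vapply(ss$subsites, `[[`, 1L, "member_count") == 3L))

  glcn <- Filter(function(r) r$comp_name == "GCS", ss$rings)[[1]]
  map <- assign_labels(ss, fx$scaffold$annotation, fx$scaffold$model,
                       glcn_anchor = glcn)
  expect_identical(vapply(map$subsites, `[[`, 1L, "label"),
                   expected_labels_along_arc(9, 3))
  # +1 holds the GlcN anchor, whichever anchor is used
  glcn_lab <- map$assignments$label[map$assignments$comp_name == "GCS"]
  expect_true(all(glcn_lab == 1L))
  map_dd <- assign_labels(ss, fx$scaffold$annotation, fx$scaffold$model)
  expect_identical(vapply(map_dd$subsites, `[[`, 1L, "label"),
                   vapply(map$subsites, `[[`, 1L, "label"))
})

test_that("a terminal anchor yields a single negative-running chain", {
  fx <- planted_fixture(seed = 9, n_sites = 4, glcn_site = 1)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  ss <- cluster_subsites(comp, 1.8)
  glcn <- Filter(function(r) r$comp_name == "GCS", ss$rings)[[1]]
  map <- assign_labels(ss, fx$scaffold$annotation, fx$scaffold$model,
                       glcn_anchor = glcn)
  expect_identical(vapply(map$subsites, `[[`, 1L, "label"),
                   c(1L, -1L, -2L, -3L))
})

test_that("ligand transfer preserves pairwise geometry and tags sources", {
  fx <- planted_fixture(seed = 5, jitter = 0, n_soaks = 2)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  sug <- comp$atoms[comp$atoms$category == "saccharide", ]
  expect_setequal(unique(sug$source), c("soak1", "soak2"))
  # rigid transfer: within-soak ligand geometry preserved to 1e-3
  for (src in c("soak1", "soak2")) {
    orig <- fx$complexes[[match(src, c("soak1", "soak2"))]]
    oat <- orig$atoms[orig$atoms$category == "saccharide", ]
    tat <- sug[sug$source == src, ]
    expect_equal(
      as.matrix(stats::dist(as.matrix(tat[, c("x", "y", "z")]))),
      as.matrix(stats::dist(as.matrix(oat[, c("x", "y", "z")]))),
      tolerance = 1e-3, ignore_attr = TRUE)
  }
  # protein appears once (reference copy)
  expect_equal(sum(comp$atoms$category == "protein"),
               sum(fx$scaffold$model$atoms$category == "protein"))
})

test_that("occupancy matrix aggregates entities and ignores input order", {
  fx <- planted_fixture(seed = 12)
  comp_a <- transfer_ligands(fx$complexes, fx$scaffold$model)
  comp_b <- transfer_ligands(rev(fx$complexes), fx$scaffold$model)
  build_map <- function(comp) {
    ss <- cluster_subsites(comp, 1.8)
    glcn <- Filter(function(r) r$comp_name == "GCS", ss$rings)[[1]]
    assign_labels(ss, fx$scaffold$annotation, fx$scaffold$model,
                  glcn_anchor = glcn)
  }
  occ_a <- occupancy_matrix(build_map(comp_a))
  occ_b <- occupancy_matrix(build_map(comp_b))
  ord <- function(m) m[order(rownames(m)), , drop = FALSE]
  expect_identical(ord(occ_a), ord(occ_b))
  # mannose row spans the 8 planted Man sites; GlcN row is {+1}
  man_row <- occ_a["Man@soak1", ]
  expect_equal(sum(man_row), 8)
  glcn_row <- occ_a["GlcN@soak1", ]
  expect_identical(names(glcn_row)[glcn_row == 1], "1")
})

test_that("a planted disaccharide occupies adjacent subsites", {
  scaf <- toy_scaffold(5, plus1_index = 2)
  mb <- glycan_spec(c("Man", "Man"),
                    data.frame(donor = 1, acceptor = 2, position = 6,
                               anomer = "alpha"))
  placements <- list(
    list(what = "GlcN", site = 2),
    list(what = mb, site = 3)  # rings land on sites 3 and 4 -> -1/-2
  )
  cx <- make_complex(complex_spec(scaf, placements, n_soaks = 1,
                                  jitter = 0.1, seed = 8))
  comp <- transfer_ligands(cx$models, scaf$model)
  ss <- cluster_subsites(comp, 1.8)
  glcn <- Filter(function(r) r$comp_name == "GCS", ss$rings)[[1]]
  map <- assign_labels(ss, scaf$annotation, scaf$model,
                       glcn_anchor = glcn)
  occ <- occupancy_matrix(map)
  mb_row <- occ[grep("Man\\(a1-6\\)Man", rownames(occ)), ]
  expect_setequal(names(mb_row)[mb_row == 1], c("-1", "-2"))
})

test_that("glycan reassembly reports shape and flags unoccupied subsites", {
  fx <- planted_fixture(seed = 42)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  ss <- cluster_subsites(comp, 1.8)
  glcn <- Filter(function(r) r$comp_name == "GCS", ss$rings)[[1]]
  map <- assign_labels(ss, fx$scaffold$annotation, fx$scaffold$model,
                       glcn_anchor = glcn)
  # planted monosaccharides sit 6 A apart: the linkage-plausibility check
  # must flag the path
  expect_warning(res <- reassemble_glycan(map, c(1, -1, -2, -3)),
                 "apart")
  expect_equal(res$shape$n_residues, 4L)
  expect_equal(length(unique(res$model$atoms$seq_num)), 4L)
  expect_gt(res$shape$end_to_end, 0)
  expect_error(reassemble_glycan(map, c(1, -7)), "-7")
  # two-residue path: shape undefined
  two <- reassemble_glycan(map, c(1, -1))
  expect_identical(two$shape$shape_class, "undefined")
})

test_that("shape classification matches the published exemplars", {
  expect_identical(shape_descriptor(5, 19.4)$shape_class, "linear")
  expect_equal(shape_descriptor(5, 19.4)$per_residue, 4.85)
  expect_identical(shape_descriptor(4, 11.3)$shape_class, "C")
  expect_identical(shape_descriptor(5, 7.8)$shape_class, "U")
  expect_identical(shape_descriptor(2, 5.0)$shape_class, "undefined")
  # end-to-end is rigid-motion invariant (descriptor from moved glycan)
  sp <- glycan_spec(c("Man", "Man", "Man", "GlcN"),
                    data.frame(donor = c(1, 2, 3), acceptor = c(2, 3, 4),
                               position = c(2, 6, 4), anomer = "alpha"))
  g <- make_glycan(sp)
  e0 <- glycanyon:::glycan_end_to_end(g)
  set.seed(4)
  moved <- glycanyon:::transform_model(g, random_rotation(),
                                       stats::rnorm(3, 0, 15))
  expect_equal(glycanyon:::glycan_end_to_end(moved), e0, tolerance = 1e-9)
})

test_that("torsion tuning bends a glycan monotonically through the classes", {
  sp <- glycan_spec(c("Man", "Man", "Man", "GlcN"),
                    data.frame(donor = c(1, 2, 3), acceptor = c(2, 3, 4),
                               position = c(2, 6, 4), anomer = "alpha"))
  targets <- c(13.0, 11.3, 8.0)
  got <- vapply(targets, function(tg) {
    glycanyon:::glycan_end_to_end(
      make_glycan(tune_glycan_torsions(sp, tg), clash_min = 1.6))
  }, 0)
  expect_equal(got, targets, tolerance = 0.1)
  per <- got / 3
  expect_true(all(diff(per) < 0))
  expect_identical(shape_descriptor(4, got[2])$shape_class, "C")
})

test_that("disulfide detection applies the SG-SG cutoff", {
  cys_pair <- function(sep) {
    df <- data.frame(
      name = rep(c("N", "CA", "CB", "SG"), 2), altloc = " ",
      comp_name = "CYS", chain_id = "A",
      seq_num = rep(c(204L, 279L), each = 4), icode = " ",
      x = c(0, 1.5, 2.2, 3.0, 0 + sep + 3, 1.5 + sep + 3, 2.2 + sep + 1,
            3.0 + sep),
      y = 0, z = 0, occupancy = 1, b_iso = 0,
      element = rep(c("N", "C", "C", "S"), 2), het = FALSE,
      category = "protein", source = NA_character_,
      stringsAsFactors = FALSE)
    glycanyon:::new_structure_model("ss", df)
  }
  hit <- detect_disulfides(cys_pair(2.03))
  expect_equal(nrow(hit), 1L)
  expect_setequal(c(hit$seq_num_a, hit$seq_num_b), c(204L, 279L))
  expect_equal(nrow(detect_disulfides(cys_pair(3.5))), 0L)
})

test_that("canyon lining responds to distance and aromatic filters", {
  fx <- planted_fixture(seed = 42)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  lin <- canyon_lining(fx$scaffold$model, comp, 4.5)
  expect_gt(nrow(lin), 0)
  arom <- canyon_lining(fx$scaffold$model, comp, 4.5, aromatic_only = TRUE)
  expect_true(all(arom$comp_name %in% c("TRP", "TYR", "PHE", "HIS")))
  expect_true(nrow(arom) >= 1)

  # ligand 10 A away from every residue -> empty lining
  iso <- make_sugar("Man", chain_id = "L", seq_num = 500L)
  iso$atoms[, "z"] <- iso$atoms[, "z"] + 60
  far_comp <- comp
  far_comp$atoms <- rbind(
    comp$atoms[comp$atoms$category != "saccharide", ], iso$atoms)
  expect_equal(nrow(canyon_lining(fx$scaffold$model, far_comp, 4.5)), 0L)

  # one Trp side-chain atom planted at 3.5 A beyond the sugar's extremity
  sug <- make_sugar("Man", chain_id = "L", seq_num = 1L)
  xi <- which.max(sug$atoms$x)
  trp <- data.frame(
    name = c("N", "CA", "CB"), altloc = " ", comp_name = "TRP",
    chain_id = "A", seq_num = 10L, icode = " ",
    x = c(30, 31, sug$atoms$x[xi] + 3.5),
    y = c(0, 0, sug$atoms$y[xi]), z = c(0, 0, sug$atoms$z[xi]),
    occupancy = 1, b_iso = 0, element = c("N", "C", "C"), het = FALSE,
    category = "protein", source = NA_character_, stringsAsFactors = FALSE)
  ref <- glycanyon:::new_structure_model("w", trp)
  comp2 <- glycanyon:::new_structure_model("w2", rbind(trp, sug$atoms))
  got <- canyon_lining(ref, comp2, 4.5, aromatic_only = TRUE)
  expect_equal(got$seq_num, 10L)
  expect_equal(got$min_distance, 3.5, tolerance = 1e-6)
})

test_that("contact tables report heavy-atom pairs within the cutoff", {
  sug <- make_sugar("Man")
  lone <- detect_rings(sug)[[1]]
  empty <- contact_table(lone, toy_scaffold(3)$model, 3.6)
  expect_equal(nrow(empty), 0L)

  # an isolated O-O pair planted at exactly 2.80 A
  lone_o <- data.frame(
    name = "O3", altloc = " ", comp_name = "MAN", chain_id = "L",
    seq_num = 1L, icode = " ", x = 0, y = 0, z = 0,
    occupancy = 1, b_iso = 0, element = "O", het = TRUE,
    category = "saccharide", source = NA_character_,
    stringsAsFactors = FALSE)
  prot <- data.frame(
    name = "OG", altloc = " ", comp_name = "SER", chain_id = "A",
    seq_num = 7L, icode = " ", x = 2.8, y = 0, z = 0,
    occupancy = 1, b_iso = 0, element = "O", het = FALSE,
    category = "protein", source = NA_character_, stringsAsFactors = FALSE)
  m <- glycanyon:::new_structure_model("hb", prot)
  tb <- contact_table(glycanyon:::new_structure_model("o", lone_o), m, 3.6)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$distance, 2.8, tolerance = 1e-9)
  expect_identical(tb$sugar_atom, "O3")
  expect_identical(tb$protein_residue, "SER7")
  # sorted ascending by distance on a richer model
  full <- glycanyon:::new_structure_model("hb2", rbind(prot, sug$atoms))
  tb2 <- contact_table(detect_rings(full)[[1]], full, 3.6)
  expect_true(!is.unsorted(tb2$distance))
})

test_that("predicted-model occupancy comparison recovers planted fractions", {
  fx <- planted_fixture(seed = 42)
  comp <- transfer_ligands(fx$complexes, fx$scaffold$model)
  ss <- cluster_subsites(comp, 1.8)
  glcn <- Filter(function(r) r$comp_name == "GCS", ss$rings)[[1]]
  map <- assign_labels(ss, fx$scaffold$annotation, fx$scaffold$model,
                       glcn_anchor = glcn)

  # 30 predicted ligands over 5 models: 14 at true subsites, 16 displaced
  scaf <- fx$scaffold
  n_at_site <- c(3, 3, 3, 3, 2)
  predicted <- lapply(1:5, function(mi) {
    k_in <- n_at_site[mi]
    placements <- c(
      lapply(seq_len(k_in), function(k) list(what = "Man", site = k + 1)),
      lapply(seq_len(6 - k_in), function(k) {
        list(what = "Man",
             centroid = scaf$centroids[1, ] + c(10 + 6 * k, -14, 9))
      })
    )
    cx <- make_complex(complex_spec(scaf, placements, n_soaks = 1,
                                    jitter = 0.05, seed = 100 + mi))
    m <- cx$models[[1]]
    m$id <- paste0("pred", mi)
    m
  })
  res <- compare_occupancy(map, predicted, fx$scaffold$model)
  expect_equal(sum(res$per_model$n_ligands), 30L)
  expect_equal(sum(res$per_model$n_in_canyon), 14L)
  expect_equal(res$agreement, 14 / 30, tolerance = 1e-9)

  # a predicted model identical to an observed complex agrees fully
  same <- compare_occupancy(map, fx$complexes[1], fx$scaffold$model)
  expect_equal(same$per_model$n_outside, 0L)
})
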