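test_that("ring detection finds pyranoses and skips acyclic residues", {
  s <- make_sugar("Man", PUCKER_4C1, "alpha")
  rings <- detect_rings(s)
  expect_length(rings, 1L)
  expect_identical(rings[[1]]$anomeric$name, "C1")
  expect_identical(rings[[1]]$ring_atoms$name,
                   c("O5", "C1", "C2", "C3", "C4", "C5"))

  # glycerol: acyclic saccharide-like residue yields no ring, with warning
  gol <- data.frame(
    name = c("C1", "O1", "C2", "O2", "C3", "O3"), altloc = " ",
    comp_name = "GOL", chain_id = "X", seq_num = 1L, icode = " ",
    x = c(0, 0.7, 1.5, 1.5, 3.0, 3.7), y = c(0, 1.2, 0, 1.4, 0, 1.2),
    z = 0, occupancy = 1, b_iso = 0,
    element = c("C", "O", "C", "O", "C", "O"), het = TRUE,
    category = "saccharide", source = NA_character_,
    stringsAsFactors = FALSE)
  gm <- glycanyon:::new_structure_model("gol", gol)
  expect_warning(r <- detect_rings(gm), "no pyranose ring")
  expect_length(r, 0L)

  tri <- make_glycan(glycan_spec(
    c("Man", "Man", "Man"),
    data.frame(donor = c(1, 2), acceptor = c(2, 3), position = 6,
               anomer = "alpha")))
  expect_length(detect_rings(tri), 3L)
})

test_that("linkage detection reads positions and separates distant sugars", {
  for (p in c(2L, 3L, 6L)) {
    g <- make_glycan(glycan_spec(
      c("Man", "Man"),
      data.frame(donor = 1, acceptor = 2, position = p,
                 anomer = "alpha")))
    bonds <- detect_linkages(detect_rings(g), g)
    expect_length(bonds, 1L)
    expect_identical(bonds[[1]]$acceptor_position, p)
    expect_identical(bonds[[1]]$donor_position, 1L)
  }
  b13 <- make_glycan(glycan_spec(
    c("Glc", "Glc"),
    data.frame(donor = 1, acceptor = 2, position = 3, anomer = "beta")))
  bb <- detect_linkages(detect_rings(b13), b13)
  expect_identical(bb[[1]]$acceptor_position, 3L)
  expect_identical(bb[[1]]$anomericity, "beta")

  # two monosaccharides far apart: no bond
  a <- make_sugar("Man", seq_num = 1L)$atoms
  b <- make_sugar("Man", seq_num = 2L)$atoms
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + 15
  m <- glycanyon:::new_structure_model("pair", rbind(a, b))
  expect_length(detect_linkages(detect_rings(m), m), 0L)
})

test_that("bond detection is invariant under rigid motion", {
  g <- make_glycan(glycan_spec(
    c("Man", "Man"),
    data.frame(donor = 1, acceptor = 2, position = 6, anomer = "alpha")))
  set.seed(3)
  moved <- glycanyon:::transform_model(g, random_rotation(),
                                       stats::rnorm(3, 0, 20))
  b0 <- detect_linkages(detect_rings(g), g)
  b1 <- detect_linkages(detect_rings(moved), moved)
  expect_length(b1, length(b0))
  expect_identical(b1[[1]]$acceptor_position, b0[[1]]$acceptor_position)
  expect_identical(b1[[1]]$anomericity, b0[[1]]$anomericity)
})

test_that("anomericity covers both anomers and degenerate donors", {
  free_bond <- function(model) {
    r <- detect_rings(model)
    list(donor = 1L, bridge_oxygen = r[[1]]$anomeric_oxygen)
  }
  r_a <- detect_rings(make_sugar("Man", PUCKER_4C1, "alpha"))
  expect_identical(assign_anomericity(free_bond(
    make_sugar("Man", PUCKER_4C1, "alpha")), r_a), "alpha")
  r_b <- detect_rings(make_sugar("Glc", PUCKER_4C1, "beta"))
  expect_identical(assign_anomericity(free_bond(
    make_sugar("Glc", PUCKER_4C1, "beta")), r_b), "beta")
  # flattened donor -> undetermined, never an error
  flat <- make_sugar("Man", c(0.03, 0, 0), "alpha")
  rf <- detect_rings(flat)
  expect_identical(
    assign_anomericity(list(donor = 1L,
                            bridge_oxygen = rf[[1]]$anomeric_oxygen), rf),
    "undetermined")
})

test_that("glycan graphs: entities, reducing ends, branching, notation", {
  # GPI-core tetrasaccharide: linear chain, GlcN reducing end
  gpi <- make_glycan(glycan_spec(
    c("Man", "Man", "Man", "GlcN"),
    data.frame(donor = c(1, 2, 3), acceptor = c(2, 3, 4),
               position = c(2, 6, 4), anomer = "alpha")))
  rings <- detect_rings(gpi)
  bonds <- detect_linkages(rings, gpi)
  gg <- build_glycan_graph(rings, bonds)
  expect_length(gg$entities, 1L)
  expect_identical(gg$rings[[gg$reducing_end[1]]]$comp_name, "GCS")
  expect_identical(glycan_notation(gg), "Man(a1-2)Man(a1-6)Man(a1-4)GlcN")

  # branched trisaccharide: central ring accepts at 3 and 6
  br <- make_glycan(glycan_spec(
    c("Man", "Man", "Man"),
    data.frame(donor = c(1, 2), acceptor = c(3, 3), position = c(3, 6),
               anomer = "alpha")))
  rb <- detect_rings(br)
  bb <- detect_linkages(rb, br)
  gb <- build_glycan_graph(rb, bb)
  acc_pos <- sort(vapply(bb, `[[`, 1L, "acceptor_position"))
  expect_identical(acc_pos, c(3L, 6L))
  expect_identical(glycan_notation(gb), "Man(a1-3)[Man(a1-6)]Man")

  # three isolated sugars
  atoms <- do.call(rbind, lapply(1:3, function(i) {
    a <- make_sugar("Man", seq_num = i)$atoms
    a[, "x"] <- a[, "x"] + 20 * i
    a
  }))
  iso <- glycanyon:::new_structure_model("iso", atoms)
  gi <- build_glycan_graph(detect_rings(iso), detect_linkages(
    detect_rings(iso), iso))
  expect_length(gi$entities, 3L)
  expect_length(gi$bonds, 0L)
})

test_that("acyclic glycans satisfy the tree property and export JSON", {
  specs <- list(
    glycan_spec(c("Man", "Man"),
                data.frame(donor = 1, acceptor = 2, position = 6,
                           anomer = "alpha")),
    glycan_spec(c("Man", "Man", "Man"),
                data.frame(donor = c(1, 2), acceptor = c(3, 3),
                           position = c(3, 6), anomer = "alpha")),
    glycan_spec(c("Man", "Man", "Man", "GlcN"),
                data.frame(donor = c(1, 2, 3), acceptor = c(2, 3, 4),
                           position = c(2, 6, 4), anomer = "alpha"))
  )
  for (sp in specs) {
    g <- make_glycan(sp)
    rings <- detect_rings(g)
    bonds <- detect_linkages(rings, g)
    gg <- build_glycan_graph(rings, bonds)
    expect_equal(length(gg$entities) + length(gg$bonds), length(gg$rings))
  }
  js <- jsonlite::fromJSON(glycan_graph_json(
    build_glycan_graph(detect_rings(make_glycan(specs[[1]])),
                       detect_linkages(detect_rings(make_glycan(specs[[1]])),
                                       make_glycan(specs[[1]])))))
  expect_equal(nrow(js$rings), 2L)
  expect_equal(js$entities$notation, "Man(a1-6)Man")
})
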