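# Pyranose ring detection, glycosidic linkage detection, anomericity
# assignment, and glycan connectivity graphs.
#
# Covalent bonds are inferred by a single 1.8 A heavy-atom distance cutoff
# (deposited HETATM connectivity is unreliable, so CONECT records are never
# consulted). Only D-aldopyranoses are in scope: six-membered rings of five
# carbons and one oxygen.

BOND_CUTOFF <- 1.8

#' Detect pyranose rings in a structure
#'
#' Scans every saccharide residue for a six-membered cycle of five carbons
#' and one oxygen (bonds inferred at <= 1.8 A). Ring atoms are canonicalised
#' to start at the ring oxygen and proceed toward the anomeric carbon — the
#' ring carbon adjacent to the ring oxygen that carries an exocyclic oxygen
#' substituent. Saccharide residues without a detectable ring are skipped
#' with a warning.
#'
#' @param model A classified `structure_model`.
#' @param categories Residue categories searched for rings.
#' @return List of `sugar_ring` objects: each holds `residue_key`,
#'   `comp_name`, `chain_id`, `seq_num`, `source`, `structure_id`,
#'   `ring_atoms` (6-row data.frame, canonical order O5, C1..C5),
#'   `anomeric` (1-row data.frame or NULL), `anomeric_oxygen` (exocyclic O
#'   on the anomeric carbon, or NULL), `centroid`, and `atoms` (all heavy
#'   atoms of the residue).
#' @export
detect_rings <- function(model, categories = "saccharide") {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keys <- residue_key(a)
  rings <- list()
  skipped <- character()
  for (key in unique(keys[a$category %in% categories])) {
    res <- a[keys == key, , drop = FALSE]
    ring <- find_pyranose_ring(res)
    if (is.null(ring)) {
      skipped <- c(skipped, key)
      next
    }
    rings[[length(rings) + 1L]] <- build_sugar_ring(res, ring, model$id)
  }
  if (length(skipped)) {
    warning("no pyranose ring detected in saccharide residue(s): ",
            paste(skipped, collapse = ", "))
  }
  rings
}

# Find one 6-cycle of 5 C + 1 O in a residue's bond graph; returns indices
# ordered (O, C, C, C, C, C) around the cycle, or NULL.
find_pyranose_ring <- function(res) {
  heavy <- res$element %in% c("C", "O", "N")
  idx <- which(heavy)
  if (length(idx) < 6) return(NULL)
  xyz <- as.matrix(res[idx, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= BOND_CUTOFF & d > 0.5
  el <- res$element[idx]
  oxy <- which(el == "O")
  for (o in oxy) {
    cn <- which(adj[o, ] & el == "C")
    if (length(cn) < 2) next
    for (i in seq_along(cn)) for (k in seq_along(cn)) {
      if (i == k) next
      path <- ring_path(adj, el, o, cn[i], cn[k])
      if (!is.null(path)) return(idx[path])
    }
  }
  NULL
}

# DFS for a path of exactly 4 further carbons from `from` to `to`, avoiding
# the oxygen o; returns the full cycle (o, from, ..., to) or NULL.
ring_path <- function(adj, el, o, from, to) {
  walk <- function(cur, path) {
    if (length(path) == 5L) {
      if (adj[cur, to] && !(to %in% path)) return(c(path, to))
      return(NULL)
    }
    for (nb in which(adj[cur, ] & el == "C")) {
      if (nb %in% path || nb == to) next
      got <- walk(nb, c(path, nb))
      if (!is.null(got)) return(got)
    }
    NULL
  }
  res <- walk(from, c(o, from))
  res
}

build_sugar_ring <- function(res, ring_idx, structure_id) {
  ring <- res[ring_idx, , drop = FALSE]
  others <- res[-ring_idx, , drop = FALSE]
  # anomeric carbon: ring C adjacent to ring O carrying an exocyclic O
  cand <- c(2L, 6L)  # cycle neighbours of the oxygen (positions in ring)
  anom_pos <- NA_integer_
  anom_oxy <- NULL
  for (p in cand) {
    exo <- exocyclic_of(ring[p, ], others, "O")
    if (!is.null(exo)) {
      # prefer the carbon conventionally named C1 when both qualify
      if (is.na(anom_pos) || ring$name[p] == "C1") {
        anom_pos <- p
        anom_oxy <- exo
      }
    }
  }
  if (is.na(anom_pos)) {
    # anomeric oxygen may be absent (e.g. engaged in a glycosidic bond whose
    # bridge O belongs to the partner residue, or 1-deoxy): fall back to name
    anom_pos <- if ("C1" %in% ring$name[cand]) {
      cand[ring$name[cand] == "C1"][1]
    } else cand[1]
  }
  # canonical order: O first, walk toward the anomeric carbon
  ord <- if (anom_pos == 2L) 1:6 else c(1L, 6:2)
  ring <- ring[ord, , drop = FALSE]
  structure(
    list(
      residue_key = residue_key(res)[1], comp_name = res$comp_name[1],
      chain_id = res$chain_id[1], seq_num = res$seq_num[1],
      source = res$source[1], structure_id = structure_id,
      ring_atoms = ring, anomeric = ring[2, , drop = FALSE],
      anomeric_oxygen = anom_oxy,
      centroid = colMeans(as.matrix(ring[, c("x", "y", "z")])),
      atoms = res
    ),
    class = "sugar_ring"
  )
}

exocyclic_of <- function(atom, others, element) {
  if (!nrow(others)) return(NULL)
  sel <- others$element == element
  if (!any(sel)) return(NULL)
  cand <- others[sel, , drop = FALSE]
  d <- cross_dist(as.matrix(atom[, c("x", "y", "z")]),
                  as.matrix(cand[, c("x", "y", "z")]))[1, ]
  hit <- which(d <= BOND_CUTOFF)
  if (!length(hit)) return(NULL)
  cand[hit[which.min(d[hit])], , drop = FALSE]
}

#' @export
print.sugar_ring <- function(x, ...) {
  cat(sprintf("sugar_ring %s %s%d (%s), anomeric %s\n", x$comp_name,
              x$chain_id, x$seq_num, x$structure_id, x$anomeric$name))
  invisible(x)
}

#' Detect glycosidic linkages between detected rings
#'
#' For every oxygen bonded (<= 1.8 A) to the anomeric carbon of one ring and
#' to a carbon of a different residue carrying a ring, emits a typed bond.
#' The acceptor position is read from the acceptor carbon's PDB-convention
#' name (C2/C3/C4/C6), not recomputed from geometry. Bonds are deduplicated;
#' an oxygen bonded to more than two carbons is a chemically invalid input
#' and raises an error.
#'
#' @param rings List of `sugar_ring` from [detect_rings()].
#' @param model The `structure_model` the rings came from.
#' @return List of `glycosidic_bond`: `donor` / `acceptor` (ring indices
#'   into `rings`), `donor_position` (1), `acceptor_position`,
#'   `anomericity` (filled via [assign_anomericity()]), `bridge_oxygen`
#'   (1-row data.frame).
#' @export
detect_linkages <- function(rings, model) {
  if (!length(rings)) return(list())
  a <- model$atoms
  keys <- residue_key(a)
  ring_of_residue <- stats::setNames(
    seq_along(rings), vapply(rings, `[[`, "", "residue_key"))
  oxy <- a[a$element == "O" &
             keys %in% names(ring_of_residue), , drop = FALSE]
  oxy_keys <- residue_key(oxy)
  carb <- a[a$element == "C" & keys %in% names(ring_of_residue), ,
            drop = FALSE]
  carb_keys <- residue_key(carb)

  bonds <- list()
  seen <- character()
  for (di in seq_along(rings)) {
    ring <- rings[[di]]
    ac <- as.matrix(ring$anomeric[, c("x", "y", "z")])
    ring_o_key <- paste(ring$ring_atoms$name[1], ring$residue_key)
    d_o <- cross_dist(ac, as.matrix(oxy[, c("x", "y", "z")]))[1, ]
    near_o <- which(d_o <= BOND_CUTOFF)
    for (oi in near_o) {
      if (paste(oxy$name[oi], oxy_keys[oi]) == ring_o_key) next  # ring O5
      op <- as.matrix(oxy[oi, c("x", "y", "z")])
      d_c <- cross_dist(op, as.matrix(carb[, c("x", "y", "z")]))[1, ]
      near_c <- which(d_c <= BOND_CUTOFF)
      if (length(near_c) > 2) {
        stop("bridge oxygen ", oxy$name[oi], " of ", oxy_keys[oi],
             " bonded to >2 carbons: chemically invalid input")
      }
      for (ci in near_c) {
        if (carb_keys[ci] == ring$residue_key) next       # donor side
        ai <- ring_of_residue[[carb_keys[ci]]]
        if (is.null(ai) || ai == di) next
        pos <- suppressWarnings(
          as.integer(sub("^C", "", carb$name[ci])))
        if (is.na(pos) || !(pos %in% c(2L, 3L, 4L, 6L))) next
        id <- paste(di, ai, pos)
        if (id %in% seen) next
        seen <- c(seen, id)
        bond <- structure(
          list(donor = di, acceptor = ai, donor_position = 1L,
               acceptor_position = pos,
               anomericity = "undetermined",
               bridge_oxygen = oxy[oi, , drop = FALSE]),
          class = "glycosidic_bond"
        )
        bond$anomericity <- assign_anomericity(bond, rings)
        bonds[[length(bonds) + 1L]] <- bond
      }
    }
  }
  bonds
}

#' Assign anomeric configuration of a glycosidic bond
#'
#' Orients the donor ring's Cremer-Pople mean-plane normal by the right-hand
#' rule over the canonical atom order, then compares the signed perpendicular
#' displacements of the anomeric exocyclic (bridge) oxygen and of the C6
#' reference substituent at C5. Opposite signs give alpha, same signs beta
#' (D-sugar convention). A near-zero anomeric-oxygen displacement
#' (< `dead_zone`), a planar donor ring (Q < 0.05 A), or a missing C6 yields
#' `"undetermined"` — never an error. When the C6 *reference* displacement
#' falls inside the dead zone (C5 at a boat prow, e.g. B25, where the
#' substituent is isoclinal) the sidedness of C6 is recovered from the local
#' chirality at C5 instead — conformation-invariant and hydrogen-free — so
#' distorted transition-state-like rings still resolve.
#'
#' @param bond A `glycosidic_bond` (or a list with `donor` and
#'   `bridge_oxygen`).
#' @param rings The ring list the bond indexes into.
#' @param dead_zone Displacement (Angstrom) below which a mean-plane side
#'   assignment is not trusted.
#' @return `"alpha"`, `"beta"`, or `"undetermined"`.
#' @export
assign_anomericity <- function(bond, rings, dead_zone = 0.15) {
  donor <- rings[[bond$donor]]
  st <- cremer_pople(donor)
  if (st$Q < 0.05) return("undetermined")
  n <- ring_plane_normal(donor)
  centre <- donor$centroid
  zdisp <- function(v) sum((v - centre) * n)
  c6 <- donor$atoms[donor$atoms$name == "C6", , drop = FALSE]
  if (!nrow(c6)) return("undetermined")
  c6p <- as.numeric(c6[1, c("x", "y", "z")])
  o1p <- as.numeric(bond$bridge_oxygen[1, c("x", "y", "z")])
  z_ref <- zdisp(c6p)
  z_o1 <- zdisp(o1p)
  if (abs(z_o1) < dead_zone) return("undetermined")
  xyz <- ring_coords(donor)
  if (abs(z_ref) < dead_zone) {
    # chirality fallback: which of the two ideal exocyclic directions at C5
    # C6 occupies is pucker-invariant; map it back to the chair side.
    ref <- invert_cremer_pople(0.57, 0, 0)
    dref <- exo_directions(ref, 6L)
    chair_side <- sign(dref[, 3])[
      chir_row(xyz, 6L, c6p)]          # z-side C6 would take in the chair
    s_ref <- chair_side
  } else {
    s_ref <- sign(z_ref)
  }
  if (sign(z_o1) != s_ref) "alpha" else "beta"
}

# Which of the two tetrahedral exocyclic directions at ring position i the
# substituent at `sub` occupies (1 = +w choice, 2 = -w choice).
chir_row <- function(xyz, i, sub) {
  d <- exo_directions(xyz, i)
  u <- unitv(sub - xyz[i, ])
  which.max(d %*% u)
}

ring_plane_normal <- function(ring) {
  xyz <- ring_coords(ring)
  r <- sweep(xyz, 2, colMeans(xyz))
  beta <- 2 * pi * (0:5) / 6
  unitv(cross3(colSums(r * sin(beta)), colSums(r * cos(beta))))
}

#' Assemble rings and bonds into a glycan connectivity graph
#'
#' Computes connected components (glycan entities), identifies the reducing
#' end of each entity (the ring that donates no glycosidic bond, i.e. whose
#' anomeric oxygen is free), and supports branched topologies.
#'
#' @param rings List of `sugar_ring`.
#' @param bonds List of `glycosidic_bond`.
#' @return A `glycan_graph`: list with `rings`, `bonds`, `entities` (list of
#'   integer ring-index vectors), `reducing_end` (one ring index or NA per
#'   entity).
#' @export
build_glycan_graph <- function(rings, bonds) {
  n <- length(rings)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (b in bonds) comp[find(b$donor)] <- find(b$acceptor)
  roots <- vapply(seq_len(n), find, 1L)
  entities <- split(seq_len(n), roots)
  names(entities) <- NULL
  donors <- vapply(bonds, `[[`, 1L, "donor")
  reducing <- vapply(entities, function(e) {
    free <- setdiff(e, donors)
    if (length(free) == 1L) free else if (!length(free)) NA_integer_ else {
      # several rings without outgoing bond (isolated monosaccharides can't
      # occur inside one entity; defensive tie-break by ring order)
      min(free)
    }
  }, 1L)
  structure(list(rings = rings, bonds = bonds, entities = entities,
                 reducing_end = reducing),
            class = "glycan_graph")
}

SUGAR_SHORT <- c(MAN = "Man", BMA = "Man", GLC = "Glc", BGC = "Glc",
                 GAL = "Gal", GLA = "Gal", GCS = "GlcN", PA1 = "GlcN",
                 NAG = "GlcNAc", NDG = "GlcNAc")

sugar_short_name <- function(comp) {
  out <- SUGAR_SHORT[comp]
  out[is.na(out)] <- comp[is.na(out)]
  unname(out)
}

#' One-line text notation for a glycan entity
#'
#' Renders an entity as e.g. `"Man(a1-6)Man(a1-4)GlcN"`, reading from the
#' non-reducing end toward the reducing end; branches are bracketed.
#'
#' @param graph A `glycan_graph`.
#' @param entity Entity index (default 1).
#' @return Character scalar.
#' @export
glycan_notation <- function(graph, entity = 1L) {
  e <- graph$entities[[entity]]
  root <- graph$reducing_end[entity]
  if (is.na(root)) root <- e[1]
  fmt <- function(i) {
    inc <- Filter(function(b) b$acceptor == i, graph$bonds)
    inc <- inc[order(vapply(inc, `[[`, 1L, "acceptor_position"))]
    pre <- ""
    if (length(inc)) {
      parts <- vapply(inc, function(b) {
        an <- switch(b$anomericity, alpha = "a", beta = "b", "?")
        paste0(fmt(b$donor), "(", an, "1-", b$acceptor_position, ")")
      }, "")
      if (length(parts) > 1) {
        pre <- paste0(parts[1],
                      paste0("[", parts[-1], "]", collapse = ""))
      } else pre <- parts
    }
    paste0(pre, sugar_short_name(graph$rings[[i]]$comp_name))
  }
  fmt(root)
}

#' @export
print.glycan_graph <- function(x, ...) {
  cat(sprintf("glycan_graph: %d rings, %d bonds, %d entit%s\n",
              length(x$rings), length(x$bonds), length(x$entities),
              ifelse(length(x$entities) == 1, "y", "ies")))
  for (i in seq_along(x$entities)) {
    cat("  ", glycan_notation(x, i), "\n")
  }
  invisible(x)
}

#' Export a glycan graph as JSON
#'
#' @param graph A `glycan_graph`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @export
glycan_graph_json <- function(graph, path = NULL) {
  obj <- list(
    rings = lapply(graph$rings, function(r) list(
      residue = r$residue_key, comp_name = r$comp_name,
      centroid = round(unname(r$centroid), 3))),
    bonds = lapply(graph$bonds, function(b) list(
      donor = b$donor, acceptor = b$acceptor,
      acceptor_position = b$acceptor_position,
      anomericity = b$anomericity)),
    entities = lapply(seq_along(graph$entities), function(i) list(
      rings = graph$entities[[i]],
      reducing_end = graph$reducing_end[i],
      notation = glycan_notation(graph, i)))
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
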