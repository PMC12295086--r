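# Consensus subsite mapping of a glycan-binding canyon: transfer ligand
# fragments from many soaked complexes into one reference frame, cluster
# sugar positions into subsites, label them with glycosidase subsite
# nomenclature (cleavage between -1 and +1), build the occupancy matrix,
# reassemble composite glycans and classify their shape, and annotate the
# canyon (aromatic lining, DD motif, disulfides, contacts).

#' Active-site annotation
#'
#' Bundles the residue-level annotation used for subsite labelling: the
#' catalytic DD motif (two adjacent aspartates), the aromatic canyon lining,
#' disulfide pairs and named wing regions.
#'
#' @param dd_motif Character vector of the two DD-motif residue keys (or
#'   seq_num values when `chain` given) — must be adjacent in sequence.
#' @param aromatic_lining Optional residue keys.
#' @param disulfides Optional list of residue-key pairs.
#' @param wing_regions Optional named list of `c(start_seq, end_seq)` ranges
#'   (e.g. `list(WR1 = c(268, 283))`).
#' @return An `active_site_annotation`.
#' @export
active_site_annotation <- function(dd_motif, aromatic_lining = character(),
                                   disulfides = list(),
                                   wing_regions = list()) {
  stopifnot(length(dd_motif) == 2L)
  structure(list(dd_motif = dd_motif, aromatic_lining = aromatic_lining,
                 disulfides = disulfides, wing_regions = wing_regions),
            class = "active_site_annotation")
}

#' Locate the DD motif of a glycosidase model
#'
#' Finds adjacent aspartate pairs (consecutive seq_num, same chain) and
#' returns an annotation seeded with the first such pair.
#'
#' @param model A classified `structure_model`.
#' @param wing_regions Passed through to the annotation.
#' @return An `active_site_annotation`.
#' @export
find_dd_motif <- function(model, wing_regions = list()) {
  rt <- residue_table(model)
  asp <- rt[rt$comp_name == "ASP", , drop = FALSE]
  if (nrow(asp) >= 2) {
    for (i in seq_len(nrow(asp) - 1)) {
      if (asp$chain_id[i + 1] == asp$chain_id[i] &&
          asp$seq_num[i + 1] == asp$seq_num[i] + 1L) {
        return(active_site_annotation(c(asp$key[i], asp$key[i + 1]),
                                      wing_regions = wing_regions))
      }
    }
  }
  stop("no adjacent Asp-Asp (DD motif) pair found")
}

#' Merge ligands from soaked complexes into the reference frame
#'
#' Superposes each complex onto the reference via
#' [sequence_guided_align()] (skipping, with a warning, complexes that fail
#' to align or retain fewer than `min_pairs` Calpha pairs), maps all
#' saccharide residues into the reference frame tagged with their source
#' structure id, and returns the composite: the reference protein (and
#' waters) once plus all transferred sugars.
#'
#' @param complexes List of classified `structure_model`s.
#' @param reference A classified `structure_model`.
#' @param min_pairs Minimum retained Calpha pairs per complex.
#' @param max_cycles,reject_cutoff Passed to [sequence_guided_align()].
#' @return A composite `structure_model`; sugar atoms carry their source id
#'   in the `source` column.
#' @export
transfer_ligands <- function(complexes, reference, min_pairs = 50,
                             max_cycles = 5, reject_cutoff = 2.0) {
  stopifnot(inherits(reference, "structure_model"))
  out <- reference$atoms
  out$source <- reference$id
  out <- out[out$category != "saccharide", , drop = FALSE]
  for (cx in complexes) {
    sug <- cx$atoms[cx$atoms$category == "saccharide", , drop = FALSE]
    if (!nrow(sug)) next
    if (identical(cx$id, reference$id)) {
      fit <- list(rotation = diag(3), translation = c(0, 0, 0),
                  n_pairs = Inf)
    } else {
      fit <- tryCatch(
        sequence_guided_align(cx, reference, max_cycles = max_cycles,
                              reject_cutoff = reject_cutoff),
        error = function(e) e)
      if (inherits(fit, "error") || fit$n_pairs < min_pairs) {
        warning("complex ", cx$id, " skipped: ",
                if (inherits(fit, "error")) conditionMessage(fit)
                else paste0("only ", fit$n_pairs, " retained pairs"))
        next
      }
    }
    xyz <- as.matrix(sug[, c("x", "y", "z")])
    sug[, c("x", "y", "z")] <- sweep(xyz %*% t(fit$rotation), 2,
                                     fit$translation, "+")
    sug$source <- cx$id
    out <- rbind(out, sug)
  }
  rownames(out) <- NULL
  new_structure_model(paste0(reference$id, "-composite"), out,
                      source_path = reference$source_path)
}

#' Cluster composite sugar positions into subsites
#'
#' Single-linkage clustering of the detected sugar-ring centroids at
#' `merge_radius`; one (unlabelled) subsite per cluster with the mean
#' centroid and full provenance. Glycerol/water never enter (category
#' filter upstream of ring detection).
#'
#' @param composite Composite model from [transfer_ligands()].
#' @param merge_radius Single-linkage merge radius, Angstrom. The 1.8 A
#'   default sits below typical inter-subsite spacing (4-6 A for linked
#'   pyranoses) and above coordinate noise.
#' @return A `subsite_set`: list with `subsites` (list of subsite records:
#'   `label` (NA), `centroid`, `member_count`, `provenance`), `rings`, and
#'   `ring_subsite` (cluster index per ring).
#' @export
cluster_subsites <- function(composite, merge_radius = 1.8) {
  rings <- detect_rings(composite)
  if (!length(rings)) {
    return(structure(list(subsites = list(), rings = list(),
                          ring_subsite = integer()),
                     class = "subsite_set"))
  }
  cent <- do.call(rbind, lapply(rings, `[[`, "centroid"))
  cl <- if (nrow(cent) == 1L) 1L else {
    stats::cutree(stats::hclust(stats::dist(cent), method = "single"),
                  h = merge_radius)
  }
  subsites <- lapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    list(label = NA_integer_,
         centroid = colMeans(cent[idx, , drop = FALSE]),
         member_count = length(idx),
         provenance = data.frame(
           source = vapply(rings[idx], function(r) {
             if (is.na(r$source)) r$structure_id else r$source
           }, ""),
           residue = vapply(rings[idx], `[[`, "", "residue_key"),
           stringsAsFactors = FALSE),
         ring_idx = idx)
  })
  structure(list(subsites = subsites, rings = rings, ring_subsite = cl),
            class = "subsite_set")
}

#' Label subsites with glycosidase nomenclature
#'
#' Anchors subsite +1 on the cluster containing the glucosamine anchor when
#' provided, otherwise on the cluster nearest the DD-motif carboxylate
#' midpoint. Remaining subsites are ordered along the canyon by
#' nearest-neighbour chaining from +1. Signs: when a wing-region (WR1)
#' annotation is available, the chain direction whose far end lies nearer
#' WR1 is the negative (non-reducing, mannose) side; otherwise the shorter
#' branch is positive; a single-direction chain is negative. Ambiguous
#' (branching) chaining emits a warning and resolves by proximity to +1.
#'
#' @param subsite_set From [cluster_subsites()].
#' @param annotation An `active_site_annotation` for the reference.
#' @param reference The reference `structure_model`.
#' @param glcn_anchor Optional `sugar_ring` (or centroid vector) known to
#'   sit at +1.
#' @return A `subsite_map`: the subsite set with labels filled, plus
#'   `assignments` (data.frame ring/source/residue/label) and
#'   `reference_id`.
#' @export
assign_labels <- function(subsite_set, annotation, reference,
                          glcn_anchor = NULL) {
  subs <- subsite_set$subsites
  if (length(subs) < 2) stop("need >= 2 subsites to label")
  cent <- do.call(rbind, lapply(subs, `[[`, "centroid"))

  anchor_point <- if (!is.null(glcn_anchor)) {
    if (inherits(glcn_anchor, "sugar_ring")) glcn_anchor$centroid
    else as.numeric(glcn_anchor)
  } else {
    dd_carboxylate_midpoint(reference, annotation)
  }
  plus1 <- which.min(cross_dist(matrix(anchor_point, 1), cent)[1, ])

  path <- chain_path(cent, plus1)
  # two directed arms leaving +1
  pos_arm <- path$after; neg_arm <- path$before
  if (length(pos_arm) && length(neg_arm)) {
    wr_cent <- wing_region_centroid(reference, annotation)
    if (!is.null(wr_cent)) {
      d_after <- vnorm(cent[pos_arm[length(pos_arm)], ] - wr_cent)
      d_before <- vnorm(cent[neg_arm[length(neg_arm)], ] - wr_cent)
      if (d_after < d_before) {  # arm nearer WR1 is the negative side
        tmp <- pos_arm; pos_arm <- neg_arm; neg_arm <- tmp
      }
    } else if (length(pos_arm) > length(neg_arm)) {
      tmp <- pos_arm; pos_arm <- neg_arm; neg_arm <- tmp
    }
  } else if (length(pos_arm) && !length(neg_arm)) {
    neg_arm <- pos_arm; pos_arm <- integer()
  }

  labels <- integer(length(subs))
  labels[plus1] <- 1L
  if (length(pos_arm)) labels[pos_arm] <- 1L + seq_along(pos_arm)
  if (length(neg_arm)) labels[neg_arm] <- -seq_along(neg_arm)
  for (i in seq_along(subs)) subs[[i]]$label <- labels[i]

  assignments <- data.frame(
    ring = seq_along(subsite_set$rings),
    source = vapply(subsite_set$rings, function(r) {
      if (is.na(r$source)) r$structure_id else r$source
    }, ""),
    residue = vapply(subsite_set$rings, `[[`, "", "residue_key"),
    comp_name = vapply(subsite_set$rings, `[[`, "", "comp_name"),
    label = labels[subsite_set$ring_subsite],
    stringsAsFactors = FALSE
  )
  structure(list(subsites = subs, rings = subsite_set$rings,
                 ring_subsite = subsite_set$ring_subsite,
                 assignments = assignments,
                 reference_id = reference$id,
                 annotation = annotation),
            class = "subsite_map")
}

dd_carboxylate_midpoint <- function(reference, annotation) {
  a <- reference$atoms
  keys <- residue_key(a)
  pts <- lapply(annotation$dd_motif, function(k) {
    res <- a[keys == k | paste(a$chain_id, a$seq_num) == k, , drop = FALSE]
    if (!nrow(res)) stop("DD-motif residue not found: ", k)
    side <- res[res$name %in% c("CG", "OD1", "OD2"), , drop = FALSE]
    if (!nrow(side)) side <- res
    colMeans(as.matrix(side[, c("x", "y", "z")]))
  })
  (pts[[1]] + pts[[2]]) / 2
}

wing_region_centroid <- function(reference, annotation) {
  if (!length(annotation$wing_regions)) return(NULL)
  wr <- annotation$wing_regions[[1]]
  a <- reference$atoms
  sel <- a$category == "protein" & a$seq_num >= wr[1] & a$seq_num <= wr[2]
  if (!any(sel)) return(NULL)
  colMeans(as.matrix(a[sel, c("x", "y", "z")]))
}

# Greedy nearest-neighbour chaining through subsite centroids starting at
# `start`; returns the ordered arm grown after start and the arm grown
# before it. Branch ambiguity (two unvisited neighbours at similar
# distance off the arc) emits a warning.
chain_path <- function(cent, start) {
  n <- nrow(cent)
  d <- as.matrix(stats::dist(cent))
  visited <- rep(FALSE, n); visited[start] <- TRUE
  arms <- list(integer(), integer())
  tips <- c(start, start)
  while (!all(visited)) {
    best <- c(Inf, Inf)
    pick <- c(NA_integer_, NA_integer_)
    for (s in 1:2) {
      cand <- which(!visited)
      dd <- d[tips[s], cand]
      best[s] <- min(dd)
      pick[s] <- cand[which.min(dd)]
    }
    s <- which.min(best)
    # a fresh arm may only start from the +1 seed once per side
    arms[[s]] <- c(arms[[s]], pick[s])
    visited[pick[s]] <- TRUE
    tips[s] <- pick[s]
  }
  list(after = arms[[1]], before = arms[[2]])
}

#' Occupancy matrix of a labelled subsite map
#'
#' One row per (glycan entity, source structure), one column per subsite
#' label, entries in {0, 1}. Entities are glycan connected components
#' computed per source structure; rows are named `notation@source`.
#'
#' @param map A `subsite_map`.
#' @return Binary matrix with subsite-label columns ordered from the most
#'   positive to the most negative subsite.
#' @export
occupancy_matrix <- function(map) {
  labs <- sort(unique(vapply(map$subsites, `[[`, 1L, "label")),
               decreasing = TRUE)
  rows <- list()
  for (src in unique(map$assignments$source)) {
    idx <- which(map$assignments$source == src)
    rings <- map$rings[idx]
    sub <- subset_model_rings(rings)
    bonds <- detect_linkages(rings, sub)
    gg <- build_glycan_graph(rings, bonds)
    for (e in seq_along(gg$entities)) {
      ent <- gg$entities[[e]]
      nm <- paste0(glycan_notation(gg, e), "@", src)
      row <- rows[[nm]]
      if (is.null(row)) row <- stats::setNames(integer(length(labs)), labs)
      got <- map$assignments$label[idx[ent]]
      row[as.character(got)] <- 1L
      rows[[nm]] <- row   # same species in one structure shares a row
    }
  }
  if (!length(rows)) {
    return(matrix(integer(), 0, length(labs),
                  dimnames = list(NULL, labs)))
  }
  do.call(rbind, rows)
}

# Minimal model wrapping a set of rings (their residues' atoms).
subset_model_rings <- function(rings) {
  atoms <- do.call(rbind, lapply(rings, `[[`, "atoms"))
  rownames(atoms) <- NULL
  new_structure_model("rings-subset", atoms)
}

#' Write the occupancy matrix as TSV
#'
#' @param map A `subsite_map`.
#' @param path Output path.
#' @export
write_occupancy <- function(map, path) {
  m <- occupancy_matrix(map)
  df <- data.frame(glycan = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reassemble a composite glycan along a subsite path
#'
#' Chooses one representative sugar per requested subsite (highest mean
#' occupancy of its source observation; ties by source id then residue
#' order), checks linkage-plausible adjacency (anomeric C to acceptor ring
#' C within `adjacency_max`), and returns the composite glycan model
#' together with its shape descriptor.
#'
#' @param map A `subsite_map`.
#' @param path Integer vector of subsite labels, listed from the reducing
#'   end outward (e.g. `c(1, -1, -2, -3)` for the GPI-core path).
#' @param adjacency_max Maximum plausible anomeric-C-to-acceptor-C distance.
#' @param thresholds Shape thresholds, see [classify_shape()].
#' @return List with `model` (the composite glycan), `rings` (chosen
#'   representatives) and `shape` (a `shape_descriptor`).
#' @export
reassemble_glycan <- function(map, path, adjacency_max = 4.5,
                              thresholds = c(linear = 4.0, u = 2.5)) {
  labs <- vapply(map$subsites, `[[`, 1L, "label")
  chosen <- lapply(path, function(lb) {
    k <- which(labs == lb)
    if (!length(k)) stop("subsite ", lb, " is unoccupied or absent")
    idx <- map$subsites[[k]]$ring_idx
    occ <- vapply(map$rings[idx], function(r) mean(r$atoms$occupancy), 0)
    src <- vapply(map$rings[idx], function(r) {
      if (is.na(r$source)) r$structure_id else r$source
    }, "")
    ord <- order(-occ, src, idx)
    map$rings[[idx[ord[1]]]]
  })
  # adjacency sanity along the path
  for (i in seq_len(length(chosen) - 1)) {
    d <- min(cross_dist(
      as.matrix(chosen[[i]]$ring_atoms[, c("x", "y", "z")]),
      as.matrix(chosen[[i + 1]]$ring_atoms[, c("x", "y", "z")])))
    if (d > adjacency_max) {
      warning(sprintf(
        "subsites %d and %d: nearest ring atoms %.1f A apart (> %.1f)",
        path[i], path[i + 1], d, adjacency_max))
    }
  }
  atoms <- do.call(rbind, lapply(chosen, `[[`, "atoms"))
  rownames(atoms) <- NULL
  model <- new_structure_model("reassembled-glycan", atoms)
  first <- chosen[[1]]; last <- chosen[[length(chosen)]]
  e2e <- vnorm(coords_of(first$atoms, "C1") - coords_of(last$atoms, "C4"))
  shape <- shape_descriptor(length(chosen), e2e, thresholds)
  list(model = model, rings = chosen, shape = shape)
}

#' Shape descriptor of a (reassembled) glycan
#'
#' @param n_residues Number of sugar residues spanned.
#' @param end_to_end Distance (Angstrom) from C1 of the reducing-end ring to
#'   C4 of the terminal non-reducing ring.
#' @param thresholds Named vector `c(linear=, u=)` of per-residue
#'   thresholds.
#' @return A `shape_descriptor`: `n_residues`, `end_to_end`, `per_residue`,
#'   `shape_class`.
#' @export
shape_descriptor <- function(n_residues, end_to_end,
                             thresholds = c(linear = 4.0, u = 2.5)) {
  stopifnot(end_to_end >= 0)
  per <- if (n_residues > 1) end_to_end / (n_residues - 1) else NA_real_
  structure(list(n_residues = n_residues, end_to_end = end_to_end,
                 per_residue = per,
                 shape_class = classify_shape(n_residues, per, thresholds)),
            class = "shape_descriptor")
}

#' Classify glycan shape from its normalized extension
#'
#' Per-residue extension at or above the `linear` threshold is linear; at or
#' below the `u` threshold is U-shaped; between them C-shaped; fewer than 3
#' residues is undefined. Thresholds calibrated on published exemplars
#' (19.4 A / 5 residues linear, 11.3 A / 4 residues C, 7.8 A U).
#'
#' @param n_residues Residue count.
#' @param per_residue end_to_end / (n_residues - 1), Angstrom.
#' @param thresholds Named vector `c(linear=, u=)`.
#' @return `"linear"`, `"C"`, `"U"` or `"undefined"`.
#' @export
classify_shape <- function(n_residues, per_residue,
                           thresholds = c(linear = 4.0, u = 2.5)) {
  if (n_residues < 3 || is.na(per_residue)) return("undefined")
  if (per_residue >= thresholds[["linear"]]) "linear"
  else if (per_residue <= thresholds[["u"]]) "U"
  else "C"
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf(
    "shape: %d residues, end-to-end %.1f A (%.2f A/residue) -> %s\n",
    x$n_residues, x$end_to_end, x$per_residue, x$shape_class))
  invisible(x)
}

#' Residues lining the glycan-binding canyon
#'
#' Protein residues of the reference with at least one side-chain atom
#' within `cutoff` of any composite sugar atom.
#'
#' @param reference Reference `structure_model`.
#' @param composite Composite model carrying the transferred sugars.
#' @param cutoff Contact cutoff, Angstrom.
#' @param aromatic_only Restrict to Trp/Tyr/Phe/His.
#' @return data.frame of lining residues (key, chain, seq_num, comp_name,
#'   min_distance).
#' @export
canyon_lining <- function(reference, composite, cutoff = 4.5,
                          aromatic_only = FALSE) {
  prot <- reference$atoms[reference$atoms$category == "protein", ,
                          drop = FALSE]
  side <- prot[!(prot$name %in% c("N", "CA", "C", "O", "OXT")), ,
               drop = FALSE]
  if (aromatic_only) {
    side <- side[side$comp_name %in% c("TRP", "TYR", "PHE", "HIS"), ,
                 drop = FALSE]
  }
  sug <- composite$atoms[composite$atoms$category == "saccharide", ,
                         drop = FALSE]
  if (!nrow(side) || !nrow(sug)) {
    return(data.frame(key = character(), chain_id = character(),
                      seq_num = integer(), comp_name = character(),
                      min_distance = double()))
  }
  d <- cross_dist(as.matrix(side[, c("x", "y", "z")]),
                  as.matrix(sug[, c("x", "y", "z")]))
  mind <- apply(d, 1, min)
  side$min_distance <- mind
  hit <- side[mind <= cutoff, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(key = character(), chain_id = character(),
                      seq_num = integer(), comp_name = character(),
                      min_distance = double()))
  }
  key <- residue_key(hit)
  agg <- tapply(hit$min_distance, key, min)
  first <- hit[!duplicated(key), , drop = FALSE]
  first <- first[order(match(residue_key(first), names(agg))), ]
  out <- data.frame(key = names(agg),
                    chain_id = first$chain_id[
                      match(names(agg), residue_key(first))],
                    seq_num = first$seq_num[
                      match(names(agg), residue_key(first))],
                    comp_name = first$comp_name[
                      match(names(agg), residue_key(first))],
                    min_distance = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$seq_num), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect disulfide bridges
#'
#' Cysteine SG-SG pairs within `ss_cutoff`.
#'
#' @param model A classified `structure_model`.
#' @param ss_cutoff Maximum SG-SG distance, Angstrom.
#' @return data.frame with seq_num_a, seq_num_b, distance.
#' @export
detect_disulfides <- function(model, ss_cutoff = 2.5) {
  sg <- model$atoms[model$atoms$comp_name == "CYS" &
                      model$atoms$name == "SG", , drop = FALSE]
  out <- data.frame(seq_num_a = integer(), seq_num_b = integer(),
                    distance = double())
  if (nrow(sg) < 2) return(out)
  d <- as.matrix(stats::dist(as.matrix(sg[, c("x", "y", "z")])))
  for (i in seq_len(nrow(sg) - 1)) for (k in (i + 1):nrow(sg)) {
    if (d[i, k] <= ss_cutoff) {
      out <- rbind(out, data.frame(
        seq_num_a = sg$seq_num[i], seq_num_b = sg$seq_num[k],
        distance = d[i, k]))
    }
  }
  out
}

#' Protein-sugar contact table
#'
#' All protein-to-sugar heavy-atom pairs within `cutoff`, sorted by
#' distance (default 3.6 A targets the hydrogen-bond range).
#'
#' @param sugar A `sugar_ring` (contacts of its whole residue) or a
#'   one-residue model.
#' @param model Model providing the protein atoms.
#' @param cutoff Distance cutoff, Angstrom.
#' @return data.frame: protein residue/atom, sugar atom, distance.
#' @export
contact_table <- function(sugar, model, cutoff = 3.6) {
  sat <- if (inherits(sugar, "sugar_ring")) sugar$atoms else sugar$atoms
  prot <- model$atoms[model$atoms$category == "protein", , drop = FALSE]
  empty <- data.frame(protein_residue = character(),
                      protein_atom = character(),
                      sugar_atom = character(), distance = double())
  if (!nrow(prot) || !nrow(sat)) return(empty)
  d <- cross_dist(as.matrix(prot[, c("x", "y", "z")]),
                  as.matrix(sat[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(
    protein_residue = paste0(prot$comp_name[hit[, 1]],
                             prot$seq_num[hit[, 1]]),
    protein_atom = prot$name[hit[, 1]],
    sugar_atom = sat$name[hit[, 2]],
    distance = d[hit],
    stringsAsFactors = FALSE
  )
  out[order(out$distance), , drop = FALSE]
}

#' Compare predicted complexes against an observed subsite map
#'
#' Runs each predicted model through the same transfer/ring-detection
#' pipeline, assigns every predicted sugar ring to the nearest observed
#' subsite (within `assign_radius`) or counts it outside the canyon, and
#' summarises agreement.
#'
#' @param map Observed `subsite_map`.
#' @param predicted_models List of classified `structure_model`s sharing
#'   the reference protein (alignable).
#' @param reference Reference model of the observed map.
#' @param assign_radius Angstrom; ring centroids farther than this from all
#'   subsite centroids count as outside the canyon.
#' @return List: `per_model` data.frame (model, n_ligands, n_in_canyon,
#'   n_outside), `assignments` data.frame (model, residue, label, distance),
#'   `agreement` overall fraction of predicted sugars inside the canyon.
#' @export
compare_occupancy <- function(map, predicted_models, reference,
                              assign_radius = 2.5) {
  sub_cent <- do.call(rbind, lapply(map$subsites, `[[`, "centroid"))
  sub_lab <- vapply(map$subsites, `[[`, 1L, "label")
  per_model <- list(); assigns <- list()
  for (pm in predicted_models) {
    comp <- tryCatch(
      transfer_ligands(list(pm), reference),
      warning = function(w) w)
    if (inherits(comp, "warning")) {
      warning("predicted model ", pm$id, " skipped: ",
              conditionMessage(comp))
      next
    }
    rings <- detect_rings(comp)
    rings <- Filter(function(r) !is.na(r$source) && r$source == pm$id,
                    rings)
    if (!length(rings)) {
      per_model[[pm$id]] <- data.frame(model = pm$id, n_ligands = 0L,
                                       n_in_canyon = 0L, n_outside = 0L)
      next
    }
    cent <- do.call(rbind, lapply(rings, `[[`, "centroid"))
    d <- cross_dist(cent, sub_cent)
    nearest <- apply(d, 1, which.min)
    mind <- d[cbind(seq_len(nrow(d)), nearest)]
    lab <- ifelse(mind <= assign_radius, sub_lab[nearest], NA_integer_)
    per_model[[pm$id]] <- data.frame(
      model = pm$id, n_ligands = length(rings),
      n_in_canyon = sum(!is.na(lab)), n_outside = sum(is.na(lab)))
    assigns[[pm$id]] <- data.frame(
      model = pm$id,
      residue = vapply(rings, `[[`, "", "residue_key"),
      label = lab, distance = mind, stringsAsFactors = FALSE)
  }
  pm_df <- do.call(rbind, c(per_model, list(make.row.names = FALSE)))
  as_df <- do.call(rbind, c(assigns, list(make.row.names = FALSE)))
  list(per_model = pm_df, assignments = as_df,
       agreement = if (!is.null(pm_df) && sum(pm_df$n_ligands) > 0) {
         sum(pm_df$n_in_canyon) / sum(pm_df$n_ligands)
       } else NA_real_)
}

#' Export a subsite map as JSON
#'
#' @param map A `subsite_map`.
#' @param path Optional output path.
#' @export
subsite_map_json <- function(map, path = NULL) {
  obj <- list(
    reference = map$reference_id,
    subsites = lapply(map$subsites, function(s) list(
      label = s$label, centroid = round(unname(s$centroid), 3),
      member_count = s$member_count,
      provenance = s$provenance)),
    assignments = map$assignments
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @export
print.subsite_map <- function(x, ...) {
  labs <- sort(vapply(x$subsites, `[[`, 1L, "label"), decreasing = TRUE)
  cat(sprintf("subsite_map on %s: %d subsites (%s), %d sugar observations\n",
              x$reference_id, length(x$subsites),
              paste(sprintf("%+d", labs), collapse = ", "),
              length(x$rings)))
  invisible(x)
}
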