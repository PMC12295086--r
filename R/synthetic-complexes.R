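# Toy glycosidase scaffold and planted sugar complexes.
#
# The scaffold is a rigid arc of residues forming a concave canyon with
# parameterizable subsite centroids: two flanking walls, a floor residue
# under every subsite (aromatic, to exercise lining detection), an adjacent
# Asp-Asp (DD motif) pair under the +1 site, and a wing-region extension
# (WR1) beyond the negative end. Geometry is deliberately idealized — it
# exercises alignment, clustering, labelling and lining without any real
# structure.

SCAFFOLD_CYCLE <- c("ALA", "VAL", "SER", "LEU", "THR", "GLY", "GLU",
                    "LYS", "ILE", "PHE", "ASN")

#' Build the toy canyon scaffold
#'
#' @param n_sites Number of subsite centroids along the canyon arc.
#' @param site_spacing Arc spacing between adjacent centroids, Angstrom.
#'   The 6.0 A default sits at the roomy end of linked-pyranose subsite
#'   spacing (4-6 A) so that independently oriented fragment observations
#'   planted at neighbouring sites cannot chemically fuse.
#' @param plus1_index Index (from the positive end) of the subsite that
#'   carries the DD motif, i.e. the future +1 (default 3: labels run
#'   +3, +2, +1, -1, ... along the arc).
#' @param arc_radius Radius of the canyon arc, Angstrom.
#' @return List: `model` (classified `structure_model`), `centroids`
#'   (n_sites x 3), `annotation` (`active_site_annotation` incl. WR1),
#'   `plus1_index`.
#' @export
toy_scaffold <- function(n_sites = 9, site_spacing = 6.0, plus1_index = 3,
                         arc_radius = 25) {
  stopifnot(n_sites >= 2, plus1_index >= 1, plus1_index <= n_sites)
  dth <- site_spacing / arc_radius
  ang <- (seq_len(n_sites) - 1) * dth
  centroids <- cbind(arc_radius * cos(ang), arc_radius * sin(ang), 0)

  rows <- list()
  seq_counter <- 0L
  add_res <- function(comp, ca, cb_dir) {
    seq_counter <<- seq_counter + 1L
    th <- atan2(ca[2], ca[1])
    tang <- c(-sin(th), cos(th), 0)
    nm <- c("N", "CA", "C", "O", "CB")
    pos <- rbind(ca - 1.2 * tang + c(0, 0, 0.4), ca,
                 ca + 1.2 * tang + c(0, 0, 0.4),
                 ca + 1.2 * tang + c(0, 0, 1.6),
                 ca + 1.53 * unitv(cb_dir))
    el <- c("N", "C", "C", "O", "C")
    if (comp == "ASP") {
      nm <- c(nm, "CG", "OD1", "OD2")
      cg <- ca + 2.8 * unitv(cb_dir)
      pos <- rbind(pos, cg, cg + c(0.8, 0, 0.9), cg + c(-0.8, 0, 0.9))
      el <- c(el, "C", "O", "O")
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      name = nm, altloc = " ", comp_name = comp, chain_id = "A",
      seq_num = seq_counter, icode = " ",
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occupancy = 1, b_iso = 0, element = el, het = FALSE,
      category = "protein", source = NA_character_,
      stringsAsFactors = FALSE
    )
    seq_counter
  }
  wall <- function(radius, n, z) {
    dthw <- site_spacing / radius * (n_sites - 1) / (n - 1)
    for (i in seq_len(n)) {
      th <- (i - 1) * dthw
      ca <- c(radius * cos(th), radius * sin(th), z)
      inward <- unitv(c(arc_radius * cos(th), arc_radius * sin(th), 0.8) -
                        ca)
      add_res(SCAFFOLD_CYCLE[(i * 7L) %% length(SCAFFOLD_CYCLE) + 1L],
              ca, inward)
    }
  }
  # clearances: sugar atoms extend <= 3.75 A from their ring centroid, so
  # scaffold side chains sit ~6 A from the subsite line (no clash at the
  # 2.0 A rule, yet within the 4.5 A lining cutoff for typical poses)
  wall(arc_radius + 7.5, 24, -1.5)
  wall(arc_radius - 7.5, 24, -1.5)
  # aromatic floor residue under every subsite
  for (k in seq_len(n_sites)) {
    ca <- centroids[k, ] + c(0, 0, -7.6)
    add_res(if (k %% 2 == 0) "TRP" else "TYR", ca, c(0, 0, 1))
  }
  # DD motif: adjacent Asp pair below/inward of the +1 centroid
  inward1 <- -unitv(c(centroids[plus1_index, 1:2], 0))
  dd1 <- add_res("ASP", centroids[plus1_index, ] + 2 * inward1 +
                   c(0, 0, -9.3), c(0, 0, 1))
  dd2 <- add_res("ASP", centroids[plus1_index, ] + 2 * inward1 +
                   c(0.9, 0.9, -9.3), c(0, 0, 1))
  # WR1 wing: short hairpin extending past the negative (far) end
  wr_start <- seq_counter + 1L
  end_th <- (n_sites - 1) * dth
  for (i in 1:6) {
    th <- end_th + (i + 0.6) * dth
    ca <- c(arc_radius * cos(th), arc_radius * sin(th), 4.0)
    add_res("GLY", ca, c(0, 0, 1))
  }
  wr_end <- seq_counter

  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  model <- classify_residues(new_structure_model("toy-scaffold", atoms))
  ann <- active_site_annotation(
    dd_motif = c(paste("", "A", dd1, " ", sep = "|"),
                 paste("", "A", dd2, " ", sep = "|")),
    wing_regions = list(WR1 = c(wr_start, wr_end))
  )
  list(model = model, centroids = centroids, annotation = ann,
       plus1_index = plus1_index)
}

#' Specification of a planted-complex series
#'
#' @param scaffold Output of [toy_scaffold()] (or a compatible list with
#'   `model` and `centroids`).
#' @param placements List of placements; each a list with `what` (a sugar
#'   type string, or a `glycan_spec`), `site` (subsite index into the
#'   scaffold centroids; multi-ring glycans occupy `site`, `site+1`, ...
#'   toward the negative end) or an explicit `centroid`, and optional
#'   `anomer`, `pucker`.
#' @param n_soaks Number of independent jittered copies ("soaked crystals").
#' @param jitter Isotropic Gaussian sigma (Angstrom) applied as rigid-body
#'   translation per placement per soak.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `complex_spec`.
#' @export
complex_spec <- function(scaffold, placements, n_soaks = 3, jitter = 0.3,
                         seed = 1L) {
  stopifnot(jitter >= 0, n_soaks >= 1)
  structure(list(scaffold = scaffold, placements = placements,
                 n_soaks = n_soaks, jitter = jitter,
                 seed = as.integer(seed)),
            class = "complex_spec")
}

#' Generate planted sugar complexes
#'
#' For each soak, every placement's sugar (or glycan) is rigidly moved to
#' its target subsite centroid plus Gaussian jitter; monosaccharides get a
#' random (seeded) orientation, oligosaccharides are oriented along the
#' canyon so successive rings land on successive subsites. A placement
#' clashing with the scaffold (< 2.0 A) is retried and then rejected.
#'
#' @param spec A `complex_spec`.
#' @return List: `models` (one classified `structure_model` per soak, ids
#'   `soak1`, `soak2`, ...) and `truth` (data.frame: soak, placement,
#'   site, residue seq_num range, planted centroid).
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  scaf <- spec$scaffold
  models <- list()
  truth <- list()
  scaf_xyz <- as.matrix(scaf$model$atoms[, c("x", "y", "z")])
  for (soak in seq_len(spec$n_soaks)) {
    atoms <- scaf$model$atoms
    next_seq <- max(atoms$seq_num) + 1L
    for (pi in seq_along(spec$placements)) {
      pl <- spec$placements[[pi]]
      lig <- build_placement_model(pl, next_seq)
      placed <- place_ligand(lig, pl, scaf, spec$jitter)
      prev_lig <- atoms[atoms$category == "saccharide", , drop = FALSE]
      ok <- FALSE
      for (try in 1:60) {
        pxyz <- as.matrix(placed$atoms[, c("x", "y", "z")])
        dmin <- min(cross_dist(pxyz, scaf_xyz))
        # keep co-planted fragments just above the 1.8 A bond-inference
        # cutoff so separate observations never fuse chemically
        dlig <- if (nrow(prev_lig)) {
          min(cross_dist(pxyz, as.matrix(prev_lig[, c("x", "y", "z")])))
        } else Inf
        if (dmin >= 2.0 && dlig >= 1.9) { ok <- TRUE; break }
        placed <- place_ligand(lig, pl, scaf, spec$jitter)
      }
      if (!ok) stop("placement ", pi, " collides with scaffold")
      atoms <- rbind(atoms, placed$atoms)
      truth[[length(truth) + 1L]] <- data.frame(
        soak = soak, placement = pi,
        site = if (!is.null(pl$site)) pl$site else NA_integer_,
        seq_from = next_seq,
        seq_to = next_seq + placed$n_res - 1L,
        cx = placed$centroid[1], cy = placed$centroid[2],
        cz = placed$centroid[3])
      next_seq <- next_seq + placed$n_res
    }
    rownames(atoms) <- NULL
    models[[soak]] <- classify_residues(
      new_structure_model(paste0("soak", soak), atoms))
  }
  list(models = models, truth = do.call(rbind, truth))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

build_placement_model <- function(pl, seq_start) {
  if (inherits(pl$what, "glycan_spec")) {
    m <- make_glycan(pl$what, chain_id = "L")
    m$atoms$seq_num <- m$atoms$seq_num + seq_start - 1L
    m
  } else {
    make_sugar(pl$what,
               pucker = if (is.null(pl$pucker)) c(0.57, 0, 0) else pl$pucker,
               anomer = if (is.null(pl$anomer)) "alpha" else pl$anomer,
               chain_id = "L", seq_num = seq_start)
  }
}

place_ligand <- function(lig, pl, scaf, jitter) {
  rings <- suppressWarnings(detect_rings(lig))
  cent1 <- rings[[1]]$centroid
  target <- if (!is.null(pl$centroid)) as.numeric(pl$centroid)
            else scaf$centroids[pl$site, ]
  xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  if (length(rings) >= 2 && !is.null(pl$site)) {
    # orient the ring axis along the canyon (ring i -> subsite site+i-1)
    next_site <- min(pl$site + 1L, nrow(scaf$centroids))
    axis_to <- unitv(scaf$centroids[next_site, ] - target)
    axis_from <- unitv(rings[[2]]$centroid - cent1)
    rot <- rotate_a_to_b(axis_from, axis_to)
  } else {
    # fragments lie in the canyon with the bulky exocyclic substituent
    # pointing out of it; only the azimuthal spin is randomized
    rel <- sweep(xyz, 2, cent1)
    u_far <- unitv(rel[which.max(rowSums(rel^2)), ])
    tilt <- rotate_a_to_b(u_far, c(0, 0, 1))
    th <- stats::runif(1, 0, 2 * pi)
    spin <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                   3, byrow = TRUE)
    rot <- spin %*% tilt
  }
  xyz <- sweep(xyz, 2, cent1) %*% t(rot)
  # jitter = RMS of the 3D displacement (per-component sigma/sqrt(3))
  shift <- target + stats::rnorm(3, 0, jitter / sqrt(3))
  xyz <- sweep(xyz, 2, shift, "+")
  lig$atoms[, c("x", "y", "z")] <- xyz
  list(atoms = lig$atoms, n_res = length(unique(lig$atoms$seq_num)),
       centroid = shift)
}

# Minimal rotation taking unit vector a onto unit vector b.
rotate_a_to_b <- function(a, b) {
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-9) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    perp <- if (abs(a[1]) < 0.9) unitv(cross3(a, c(1, 0, 0)))
            else unitv(cross3(a, c(0, 1, 0)))
    return(rotation_about_axis(perp, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}
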