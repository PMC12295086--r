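# Synthetic D-pyranose and glycan builders.
#
# Heavy atoms only, ideal carbohydrate geometry (C-C 1.52 A, C-O 1.43 A,
# anomeric C-O 1.41 A, tetrahedral angles). Stereochemistry is encoded as
# chirality signs measured once on an ideal 4C1 reference ring and reused at
# any requested pucker, so a distorted (e.g. OS2 or B25) sugar keeps the
# configuration of its chair form.

SUGAR_COMP <- c(Man = "MAN", Glc = "GLC", GlcN = "GCS")

# Two tetrahedral exocyclic directions at ring position i (1 = O5 ... 6 = C5)
# for a 6x3 ring coordinate matrix in canonical order. Returned as a 2 x 3
# matrix; rows are the +w and -w choices (w = cross of the ring bonds).
exo_directions <- function(xyz, i) {
  prev <- if (i == 1L) 6L else i - 1L
  nxt <- if (i == 6L) 1L else i + 1L
  e1 <- unitv(xyz[prev, ] - xyz[i, ])
  e2 <- unitv(xyz[nxt, ] - xyz[i, ])
  bis <- -unitv(e1 + e2)
  w <- unitv(cross3(e1, e2))
  h <- 54.735 * pi / 180
  rbind(unitv(bis * cos(h) + w * sin(h)),
        unitv(bis * cos(h) - w * sin(h)))
}

# Chirality constants: for each substituted position, the w-sign (row of
# exo_directions) realising the D-sugar configuration, measured on an ideal
# 4C1 ring. alpha O1 is the axial (large |z|, below-plane) choice at C1;
# O2 equatorial defines gluco (manno is its 2-epimer); O3/O4 equatorial;
# C6 equatorial at C5 (ending up above the mean plane, the D-sugar
# reference side).
chirality_rows <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    xyz <- invert_cremer_pople(0.57, 0, 0)
    n <- c(0, 0, 1)
    pick <- function(i, mode) {
      d <- exo_directions(xyz, i)
      zz <- d %*% n
      if (mode == "axial") which.max(abs(zz)) else which.min(abs(zz))
    }
    cache <<- list(
      C1_alpha = pick(2L, "axial"),       # axial at C1 in 4C1 = alpha-D
      C2_gluco = pick(3L, "equatorial"),
      C3 = pick(4L, "equatorial"),
      C4 = pick(5L, "equatorial"),
      C6 = pick(6L, "equatorial")
    )
    cache
  }
})

other_row <- function(r) if (r == 1L) 2L else 1L

#' Build an ideal D-pyranose residue
#'
#' Constructs a single sugar residue (heavy atoms, PDB-convention names) at
#' a specified Cremer-Pople pucker: the ring comes from
#' [invert_cremer_pople()], exocyclic hydroxyls/C6 are placed at ideal bond
#' lengths with the axial/equatorial pattern of the requested D-sugar, and
#' the anomeric O1 realises the requested anomer.
#'
#' @param type `"Man"`, `"Glc"` or `"GlcN"` (2-amino-2-deoxy-glucose; N2
#'   replaces O2).
#' @param pucker Numeric `(Q, theta, phi)` (Angstrom, degrees); default the
#'   relaxed 4C1 chair.
#' @param anomer `"alpha"` or `"beta"`.
#' @param chain_id,seq_num Residue identity in the emitted model.
#' @param anomeric_oxygen Keep the free anomeric O1 (dropped when the sugar
#'   is engaged as a glycosyl donor by [make_glycan()]).
#' @return A one-residue `structure_model` (category saccharide).
#' @export
make_sugar <- function(type = c("Man", "Glc", "GlcN"),
                       pucker = c(0.57, 0, 0),
                       anomer = c("alpha", "beta"),
                       chain_id = "X", seq_num = 1L,
                       anomeric_oxygen = TRUE) {
  type <- match.arg(type)
  anomer <- match.arg(anomer)
  if (length(pucker) != 3L || pucker[1] < 0) {
    stop("invalid pucker: need (Q >= 0, theta, phi)")
  }
  atoms <- sugar_residue_df(type, pucker, anomer, chain_id, seq_num,
                            anomeric_oxygen)
  classify_residues(new_structure_model(
    paste0("synthetic-", type), atoms))
}

sugar_residue_df <- function(type, pucker, anomer, chain_id, seq_num,
                             anomeric_oxygen = TRUE) {
  xyz <- invert_cremer_pople(pucker[1], pucker[2], pucker[3])
  ch <- chirality_rows()
  place <- function(i, row_sel, bond) {
    d <- exo_directions(xyz, i)
    xyz[i, ] + d[row_sel, ] * bond
  }
  nm <- c("O5", "C1", "C2", "C3", "C4", "C5")
  el <- c("O", "C", "C", "C", "C", "C")
  pos <- lapply(seq_len(6), function(i) xyz[i, ])

  c1row <- if (anomer == "alpha") ch$C1_alpha else other_row(ch$C1_alpha)
  if (anomeric_oxygen) {
    nm <- c(nm, "O1"); el <- c(el, "O")
    pos <- c(pos, list(place(2L, c1row, 1.41)))
  }
  o2row <- if (type == "Man") other_row(ch$C2_gluco) else ch$C2_gluco
  if (type == "GlcN") {
    nm <- c(nm, "N2"); el <- c(el, "N")
    pos <- c(pos, list(place(3L, o2row, 1.47)))
  } else {
    nm <- c(nm, "O2"); el <- c(el, "O")
    pos <- c(pos, list(place(3L, o2row, 1.43)))
  }
  nm <- c(nm, "O3", "O4", "C6", "O6")
  el <- c(el, "O", "O", "C", "O")
  c6 <- place(6L, ch$C6, 1.52)
  o6 <- nerf_place(xyz[1, ], xyz[6, ], c6, 1.43, 109.47, 60)
  pos <- c(pos, list(place(4L, ch$C3, 1.43), place(5L, ch$C4, 1.43),
                     c6, o6))

  m <- do.call(rbind, pos)
  data.frame(
    name = nm, altloc = " ", comp_name = SUGAR_COMP[[type]],
    chain_id = chain_id, seq_num = as.integer(seq_num), icode = " ",
    x = m[, 1], y = m[, 2], z = m[, 3],
    occupancy = 1, b_iso = 0, element = el, het = TRUE,
    category = "saccharide", source = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic glycan
#'
#' @param residues Character vector of sugar types (`"Man"`, `"Glc"`,
#'   `"GlcN"`), listed from the non-reducing end toward the reducing end by
#'   convention.
#' @param linkages data.frame with columns `donor`, `acceptor` (residue
#'   indices), `position` (2, 3, 4 or 6) and `anomer` (`"alpha"`/`"beta"`).
#'   The linkage graph must be acyclic.
#' @param torsions Optional data.frame with per-linkage `phi`, `psi`
#'   (degrees); defaults give extended, clash-free geometry.
#' @param puckers Optional list/matrix of per-residue `(Q, theta, phi)`;
#'   default 4C1 for all.
#' @return A `glycan_spec` list.
#' @export
glycan_spec <- function(residues, linkages, torsions = NULL, puckers = NULL) {
  n <- length(residues)
  stopifnot(n >= 1, all(linkages$donor %in% seq_len(n)),
            all(linkages$acceptor %in% seq_len(n)),
            all(linkages$position %in% c(2L, 3L, 4L, 6L)),
            all(linkages$anomer %in% c("alpha", "beta")))
  if (any(linkages$donor == linkages$acceptor)) {
    stop("self-linkage in glycan spec")
  }
  if (is.null(torsions)) {
    torsions <- data.frame(phi = rep(-60, nrow(linkages)),
                           psi = rep(180, nrow(linkages)))
  }
  stopifnot(nrow(torsions) == nrow(linkages))
  if (is.null(puckers)) {
    puckers <- rep(list(c(0.57, 0, 0)), n)
  }
  structure(list(residues = residues, linkages = linkages,
                 torsions = torsions, puckers = puckers),
            class = "glycan_spec")
}

#' Build a 3D model of a specified glycan
#'
#' Residues are placed sequentially; each glycosidic linkage realises the
#' anomeric C -> bridge O -> acceptor C geometry (1.41 A anomeric bond,
#' ~114 deg glycosidic angle) at the specified (phi, psi) torsions. The
#' bridge oxygen is the donor's anomeric O1; the acceptor's substituent
#' oxygen at the linked position is removed. A clash check (>= 2.0 A between
#' non-bonded heavy atoms of different residues) triggers automatic psi
#' nudges and fails after bounded retries.
#'
#' @param spec A `glycan_spec`.
#' @param chain_id Chain for the emitted residues.
#' @param clash_min Minimum allowed non-bonded inter-residue distance.
#' @return A `structure_model` with one residue per sugar.
#' @export
make_glycan <- function(spec, chain_id = "X", clash_min = 2.0) {
  stopifnot(inherits(spec, "glycan_spec"))
  n <- length(spec$residues)
  locals <- lapply(seq_len(n), function(i) {
    an <- "alpha"
    dl <- which(spec$linkages$donor == i)
    if (length(dl)) an <- spec$linkages$anomer[dl[1]]
    sugar_residue_df(spec$residues[i], spec$puckers[[i]], an,
                     chain_id, i, anomeric_oxygen = TRUE)
  })
  placed <- vector("list", n)
  placed[[1]] <- locals[[1]]
  done <- 1L
  todo <- seq_len(nrow(spec$linkages))
  while (length(todo)) {
    prog <- FALSE
    for (li in todo) {
      lk <- spec$linkages[li, ]
      to <- spec$torsions[li, ]
      d_in <- lk$donor %in% done
      a_in <- lk$acceptor %in% done
      if (d_in == a_in) next  # both placed (cycle) or neither yet
      if (d_in && a_in) stop("cyclic glycan spec at linkage ", li)
      res <- place_linked_residue(placed, locals, lk, to, d_in, clash_min, li)
      new_i <- if (d_in) lk$acceptor else lk$donor
      placed[[new_i]] <- res$new_res
      placed[[res$trimmed_i]] <- res$trimmed
      done <- c(done, new_i)
      todo <- setdiff(todo, li)
      prog <- TRUE
      break
    }
    if (!prog) stop("glycan spec is disconnected or cyclic")
  }
  atoms <- do.call(rbind, placed)
  rownames(atoms) <- NULL
  classify_residues(new_structure_model("synthetic-glycan", atoms))
}

coords_of <- function(df, name) {
  as.numeric(df[df$name == name, c("x", "y", "z")][1, ])
}

acceptor_atoms <- function(position) {
  switch(as.character(position),
         "2" = c("C2", "O2", "C3"), "3" = c("C3", "O3", "C4"),
         "4" = c("C4", "O4", "C5"), "6" = c("C6", "O6", "C5"))
}

# Rigid placement of the not-yet-placed partner of one linkage. Targets are
# constructed by internal coordinates using the *local* bond lengths/angles
# of the moving residue, so the three-point Kabsch fit is exact.
place_linked_residue <- function(placed, locals, lk, to, donor_placed,
                                 clash_min, li) {
  aa <- acceptor_atoms(lk$position)
  psi_try <- c(0, 20, -20, 40, -40, 60, -60, 90, -90, 120, -120, 150,
               -150, 180)
  phi_try <- c(0, 30, -30, 60, -60)
  for (dphi in phi_try) for (dpsi in psi_try) {
    phi <- to$phi + dphi
    psi <- to$psi + dpsi
    if (donor_placed) {
      don <- placed[[lk$donor]]
      acc <- locals[[lk$acceptor]]
      if (!(aa[2] %in% acc$name)) {
        stop("linkage ", li, ": acceptor lacks atom ", aa[2])
      }
      o_pos <- coords_of(don, "O1")
      cx_t <- nerf_place(coords_of(don, "O5"), coords_of(don, "C1"),
                         o_pos, 1.43, 114, phi)
      cx_l <- coords_of(acc, aa[1]); ox_l <- coords_of(acc, aa[2])
      cr_l <- coords_of(acc, aa[3])
      ang <- angle_deg(ox_l, cx_l, cr_l)
      cr_t <- nerf_place(coords_of(don, "C1"), o_pos, cx_t,
                         vnorm(cr_l - cx_l), ang, psi)
      # local Ox-Cx distance may differ from the 1.43 used for cx_t; refit
      cx_t <- o_pos + unitv(cx_t - o_pos) * vnorm(cx_l - ox_l)
      fit <- kabsch(rbind(ox_l, cx_l, cr_l), rbind(o_pos, cx_t, cr_t))
      moved <- apply_fit(acc, fit)
      moved <- moved[moved$name != aa[2], , drop = FALSE]  # Ox == bridge O
      new_res <- moved; trimmed <- don; trimmed_i <- lk$donor
    } else {
      acc <- placed[[lk$acceptor]]
      don <- locals[[lk$donor]]
      if (!(aa[2] %in% acc$name)) {
        stop("linkage ", li, ": acceptor lacks atom ", aa[2])
      }
      o_pos <- coords_of(acc, aa[2])
      c1_l <- coords_of(don, "C1"); o1_l <- coords_of(don, "O1")
      o5_l <- coords_of(don, "O5")
      c1_t <- nerf_place(coords_of(acc, aa[3]), coords_of(acc, aa[1]),
                         o_pos, vnorm(c1_l - o1_l), 114, psi)
      o5_t <- nerf_place(coords_of(acc, aa[1]), o_pos, c1_t,
                         vnorm(o5_l - c1_l), angle_deg(o1_l, c1_l, o5_l),
                         phi)
      fit <- kabsch(rbind(o1_l, c1_l, o5_l), rbind(o_pos, c1_t, o5_t))
      moved <- apply_fit(don, fit)
      moved <- moved[moved$name != "O1", , drop = FALSE]   # O1 == bridge O
      new_res <- moved; trimmed <- acc; trimmed_i <- lk$acceptor
    }
    if (!glycan_clash(new_res, placed, o_pos, clash_min)) {
      return(list(new_res = new_res, trimmed = trimmed,
                  trimmed_i = trimmed_i))
    }
  }
  stop("unsatisfiable glycan spec: persistent clash at linkage ", li)
}

angle_deg <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

apply_fit <- function(res, fit) {
  xyz <- as.matrix(res[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
  res[, c("x", "y", "z")] <- xyz
  res
}

glycan_clash <- function(new_res, placed, bridge_o, clash_min) {
  old <- do.call(rbind, placed[!vapply(placed, is.null, TRUE)])
  if (is.null(old) || !nrow(old)) return(FALSE)
  dn <- cross_dist(as.matrix(new_res[, c("x", "y", "z")]),
                   as.matrix(old[, c("x", "y", "z")]))
  # ignore contacts through the bridge oxygen itself
  near_bridge_new <- cross_dist(as.matrix(new_res[, c("x", "y", "z")]),
                                matrix(bridge_o, 1))[, 1] < 1.9
  near_bridge_old <- cross_dist(as.matrix(old[, c("x", "y", "z")]),
                                matrix(bridge_o, 1))[, 1] < 1.9
  dn[near_bridge_new, ] <- Inf
  dn[, near_bridge_old] <- Inf
  min(dn) < clash_min
}

#' Tune glycan torsions toward a target end-to-end distance
#'
#' Simple Nelder-Mead search over all linkage (phi, psi) pairs minimising
#' the squared deviation of the built glycan's end-to-end distance (C1 of
#' the reducing-end ring to C4 of the terminal non-reducing ring) from a
#' target, with a soft clash penalty. Used to emulate published composite
#' glycan shapes in synthetic fixtures.
#'
#' @param spec A `glycan_spec`.
#' @param target Target end-to-end distance, Angstrom.
#' @param maxit Optimiser iteration budget.
#' @return The spec with tuned `torsions`.
#' @export
tune_glycan_torsions <- function(spec, target, maxit = 400) {
  n <- nrow(spec$linkages)
  obj <- function(par) {
    sp <- spec
    sp$torsions <- data.frame(phi = par[seq_len(n)],
                              psi = par[n + seq_len(n)])
    got <- tryCatch({
      m <- make_glycan(sp, clash_min = 1.6)
      glycan_end_to_end(m)
    }, error = function(e) NA_real_)
    if (is.na(got)) return(1e6)
    (got - target)^2
  }
  par0 <- c(spec$torsions$phi, spec$torsions$psi)
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  spec$torsions <- data.frame(phi = fit$par[seq_len(n)],
                              psi = fit$par[n + seq_len(n)])
  spec
}

# End-to-end distance of the single glycan entity in a model: C1 of the
# reducing-end ring to C4 of the graph-remotest terminal ring.
glycan_end_to_end <- function(model) {
  rings <- detect_rings(model)
  bonds <- detect_linkages(rings, model)
  gg <- build_glycan_graph(rings, bonds)
  ends <- entity_termini(gg, 1L)
  c1 <- coords_of(gg$rings[[ends$reducing]]$atoms, "C1")
  c4 <- coords_of(gg$rings[[ends$nonreducing]]$atoms, "C4")
  vnorm(c1 - c4)
}

# Reducing-end ring and the non-reducing ring farthest from it (bond hops).
entity_termini <- function(graph, entity = 1L) {
  e <- graph$entities[[entity]]
  red <- graph$reducing_end[entity]
  if (is.na(red)) red <- e[1]
  dist <- stats::setNames(rep(Inf, length(e)), e)
  dist[as.character(red)] <- 0
  queue <- red
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (b in graph$bonds) {
      nb <- if (b$donor == cur) b$acceptor
            else if (b$acceptor == cur) b$donor else next
      if (!(nb %in% e)) next
      if (dist[as.character(nb)] > dist[as.character(cur)] + 1) {
        dist[as.character(nb)] <- dist[as.character(cur)] + 1
        queue <- c(queue, nb)
      }
    }
  }
  list(reducing = red,
       nonreducing = as.integer(names(which.max(dist))))
}
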