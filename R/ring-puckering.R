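# Cremer-Pople puckering analysis for six-membered (pyranose) rings.
#
# Atom-order convention: the canonical ring order is O5, C1, C2, C3, C4, C5
# with the ring oxygen as j = 1. Under this convention the 4C1 chair of a
# D-pyranose maps to the theta = 0 pole (locked by a fixture test, since
# conventions differ across the literature).

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Computes the total puckering amplitude Q, polar angle theta and azimuthal
#' phase phi of a six-membered ring from atomic coordinates, using the
#' standard mean-plane construction: the ring is centred on its geometric
#' centre, the mean plane is defined by the sine/cosine weighted position
#' sums over the canonical atom order (O5, C1, ..., C5), and perpendicular
#' displacements z_j decompose into the (q2, phi2) pseudorotational pair and
#' the chair amplitude q3.
#'
#' @param ring Either a `sugar_ring` object (see [detect_rings()]) or a 6 x 3
#'   numeric matrix of ring-atom coordinates in canonical order.
#' @param planarity_q Amplitude (Angstrom) below which the ring is reported
#'   as planar (conformer `"planar"`, phi = 0 by convention).
#' @return An object of class `pucker_state`: list with `Q` (Angstrom),
#'   `theta` (degrees, 0..180), `phi` (degrees, 0..360), `conformer`
#'   (`NA` until [classify_conformer()] is applied, `"planar"` for flat
#'   rings) and `conformer_distance` (degrees).
#' @seealso [classify_conformer()], [invert_cremer_pople()]
#' @export
cremer_pople <- function(ring, planarity_q = 0.05) {
  xyz <- ring_coords(ring)
  if (nrow(xyz) != 6L) stop("cremer_pople requires exactly 6 ring atoms")
  if (any(!is.finite(xyz))) stop("non-finite ring coordinates")
  if (min(stats::dist(xyz)) < 1e-6) stop("coincident ring atoms")

  centre <- colMeans(xyz)
  r <- sweep(xyz, 2, centre)
  j <- 0:5
  beta <- 2 * pi * j / 6
  r1 <- colSums(r * sin(beta))
  r2 <- colSums(r * cos(beta))
  n <- cross3(r1, r2)
  nn <- vnorm(n)
  if (nn < 1e-9) stop("degenerate ring geometry: undefined mean plane")
  n <- n / nn
  z <- as.numeric(r %*% n)

  q2cos <- sqrt(1 / 3) * sum(z * cos(2 * beta))
  q2sin <- -sqrt(1 / 3) * sum(z * sin(2 * beta))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2cos^2 + q2sin^2)
  Q <- sqrt(q2^2 + q3^2)

  theta <- atan2(q2, q3) * 180 / pi
  phi <- if (q2 < 1e-10) 0 else deg_mod360(atan2(q2sin, q2cos) * 180 / pi)
  if (phi >= 360 - 1e-9) phi <- 0
  conformer <- if (Q < planarity_q) "planar" else NA_character_
  structure(
    list(Q = Q, theta = theta, phi = phi,
         conformer = conformer, conformer_distance = NA_real_),
    class = "pucker_state"
  )
}

ring_coords <- function(ring) {
  if (inherits(ring, "sugar_ring")) {
    as.matrix(ring$ring_atoms[, c("x", "y", "z")])
  } else {
    m <- as.matrix(ring)
    storage.mode(m) <- "double"
    m
  }
}

# The 38 canonical pyranose conformer reference points (theta, phi in deg).
# Equator: boats and skew-boats alternating every 30 deg; tropics: envelopes
# and half-chairs alternating every 30 deg (placed at the tetrahedral
# latitude 54.74 / 125.26 on the simplified classification grid).
conformer_reference <- function() {
  tropic <- 180 / pi * acos(1 / sqrt(3))  # 54.7356...
  equator_labels <- c("3OB", "3S1", "B14", "5S1", "25B", "2SO",
                      "B3O", "1S3", "14B", "1S5", "B25", "OS2")
  north_labels <- c("OE", "OH1", "E1", "2H1", "2E", "2H3",
                    "E3", "4H3", "4E", "4H5", "E5", "OH5")
  south_labels <- c("3E", "3H4", "E4", "5H4", "5E", "5HO",
                    "EO", "1HO", "1E", "1H2", "E2", "3H2")
  phi12 <- seq(0, 330, by = 30)
  data.frame(
    conformer = c("4C1", "1C4", equator_labels, north_labels, south_labels),
    theta = c(0, 180, rep(90, 12), rep(tropic, 12), rep(180 - tropic, 12)),
    phi = c(0, 0, phi12, phi12, phi12),
    stringsAsFactors = FALSE
  )
}

sphere_distance <- function(theta1, phi1, theta2, phi2) {
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180
  dp <- (phi1 - phi2) * pi / 180
  cd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dp)
  acos(pmin(1, pmax(-1, cd))) * 180 / pi
}

#' Classify a pucker state onto the canonical conformer itinerary
#'
#' Assigns the nearest of the 38 canonical pyranose conformers (2 chairs,
#' 6 boats, 6 skew-boats, 12 envelopes, 12 half-chairs) by great-circle
#' distance on the (theta, phi) puckering sphere. When the state lies more
#' than `like_threshold` degrees from its nearest reference point the label
#' gains a `"-like"` suffix, mirroring the hedged naming customary for
#' distorted rings.
#'
#' @param state A `pucker_state` from [cremer_pople()].
#' @param like_threshold Angular distance (degrees) beyond which the label
#'   is suffixed `"-like"`.
#' @return The input state with `conformer` and `conformer_distance` filled.
#' @export
classify_conformer <- function(state, like_threshold = 15) {
  stopifnot(inherits(state, "pucker_state"))
  if (identical(state$conformer, "planar")) return(state)
  refs <- conformer_reference()
  d <- sphere_distance(state$theta, state$phi, refs$theta, refs$phi)
  i <- which.min(d)
  lab <- refs$conformer[i]
  if (d[i] > like_threshold) lab <- paste0(lab, "-like")
  state$conformer <- lab
  state$conformer_distance <- d[i]
  state
}

#' Ideal ring coordinates from Cremer-Pople parameters
#'
#' Inverse of [cremer_pople()]: builds six ring-atom positions on a circle of
#' given radius in the mean plane, with out-of-plane displacements
#' reconstructed from (q2, phi2, q3). The forward transform applied to the
#' result recovers the inputs to machine precision. Atoms are returned in
#' canonical order (O5, C1, ..., C5); the in-plane placement runs clockwise
#' so that the mean-plane normal of the forward construction points along +z.
#'
#' @param Q Total puckering amplitude, Angstrom (>= 0).
#' @param theta Polar angle, degrees.
#' @param phi Azimuthal phase, degrees.
#' @param radius In-plane ring radius, Angstrom (1.45 approximates pyranose
#'   ring bond lengths).
#' @return 6 x 3 numeric matrix of coordinates.
#' @export
invert_cremer_pople <- function(Q, theta, phi, radius = 1.45) {
  if (Q < 0) stop("Q must be non-negative")
  if (radius <= 0) stop("radius must be positive")
  j <- 0:5
  beta <- 2 * pi * j / 6
  q2 <- Q * sin(theta * pi / 180)
  q3 <- Q * cos(theta * pi / 180)
  phir <- phi * pi / 180
  z <- sqrt(1 / 3) * q2 * cos(phir + 2 * beta) + sqrt(1 / 6) * q3 * (-1)^j
  cbind(x = radius * cos(-beta), y = radius * sin(-beta), z = z)
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("Pucker: Q = %.3f A, theta = %.1f, phi = %.1f, conformer = %s\n",
              x$Q, x$theta, x$phi,
              ifelse(is.na(x$conformer), "<unclassified>", x$conformer)))
  invisible(x)
}

#' Per-ring puckering table
#'
#' Convenience wrapper: computes and classifies puckering for a list of
#' detected rings and returns a TSV-ready data frame.
#'
#' @param rings List of `sugar_ring` objects.
#' @param structure_id Identifier recorded in the first column.
#' @param like_threshold Passed to [classify_conformer()].
#' @return data.frame with columns structure, chain, seq_num, comp_name, Q,
#'   theta, phi, conformer, conformer_distance.
#' @export
pucker_table <- function(rings, structure_id = "", like_threshold = 15) {
  rows <- lapply(rings, function(rg) {
    st <- classify_conformer(cremer_pople(rg), like_threshold = like_threshold)
    data.frame(
      structure = if (nzchar(structure_id)) structure_id else rg$structure_id,
      chain = rg$chain_id, seq_num = rg$seq_num, comp_name = rg$comp_name,
      Q = round(st$Q, 3), theta = round(st$theta, 3), phi = round(st$phi, 3),
      conformer = st$conformer,
      conformer_distance = round(st$conformer_distance, 3),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
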