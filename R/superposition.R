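# Rigid-body superposition: exact Kabsch on paired points and
# sequence-guided iterative Calpha alignment with outlier rejection.

#' Kabsch superposition of paired point sets
#'
#' Finds the least-squares optimal proper rotation and translation mapping
#' `points_a` onto `points_b` (SVD of the covariance, determinant-corrected
#' to exclude reflections) and the post-fit r.m.s.d.
#'
#' @param points_a,points_b N x 3 matrices of paired coordinates (N >= 3).
#' @param weights Optional non-negative per-pair weights.
#' @return A `superposition_result`: `rotation` (3 x 3), `translation`
#'   (length 3; the fit maps `a` to `a %*% t(rotation) + translation`),
#'   `rmsd`, `n_pairs`, `n_cycles` (1), `rejected` (empty).
#' @export
kabsch <- function(points_a, points_b, weights = NULL) {
  pa <- as.matrix(points_a); pb <- as.matrix(points_b)
  if (nrow(pa) != nrow(pb)) stop("point sets differ in length")
  n <- nrow(pa)
  if (n < 3) stop("kabsch requires at least 3 paired points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  ca <- colSums(pa * w); cb <- colSums(pb * w)
  pac <- sweep(pa, 2, ca); pbc <- sweep(pb, 2, cb)
  sv <- svd(crossprod(pac * w, pbc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate point set: points are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- pac %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - pbc)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cb - rot %*% ca),
         rmsd = rmsd, n_pairs = n, n_cycles = 1L,
         rejected = data.frame(index = integer())),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    "superposition: rmsd %.3f A over %d pairs (%d cycle%s, %d rejected)\n",
    x$rmsd, x$n_pairs, x$n_cycles, ifelse(x$n_cycles == 1, "", "s"),
    NROW(x$rejected)))
  invisible(x)
}

# Global Calpha-sequence alignment between two models; returns paired
# residue indices (into each model's protein_ca tables).
align_ca_pairs <- function(pa, pb, gap_open = 10, gap_extend = 0.5,
                           matrix_name = "BLOSUM62") {
  submat <- get_submatrix(matrix_name)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa$seq), Biostrings::AAString(pb$seq),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  both <- sa != "-" & sb != "-"
  cbind(a = ia[both], b = ib[both])
}

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Sequence-guided iterative structural alignment
#'
#' Globally aligns the Calpha sequences of two protein models (BLOSUM62,
#' affine gaps 10/0.5), seeds Calpha pairs from the aligned columns, then
#' iterates Kabsch fitting with rejection of pairs deviating more than
#' `reject_cutoff` after the fit, until no pair is removed or `max_cycles`
#' is reached. This emulates the interactive-graphics "align" behaviour
#' behind published r.m.s.d./aligned-atom figures.
#'
#' @param model_a,model_b `structure_model`s with >= 20 protein residues
#'   with Calpha.
#' @param max_cycles Maximum rejection cycles.
#' @param reject_cutoff Post-fit deviation (Angstrom) above which a pair is
#'   dropped.
#' @param chain_a,chain_b Optional chain restriction.
#' @return A `superposition_result` (transform maps model_a onto model_b)
#'   with `rejected` listing the dropped residue pairs.
#' @export
sequence_guided_align <- function(model_a, model_b, max_cycles = 5,
                                  reject_cutoff = 2.0,
                                  chain_a = NULL, chain_b = NULL) {
  pa <- protein_ca(model_a, chain_a)
  pb <- protein_ca(model_b, chain_b)
  if (nchar(pa$seq) < 20 || nchar(pb$seq) < 20) {
    stop("sequence_guided_align needs >= 20 protein residues with CA")
  }
  pairs <- align_ca_pairs(pa, pb)
  if (nrow(pairs) < 3) stop("fewer than 3 aligned residue pairs")
  keep <- seq_len(nrow(pairs))
  rejected <- integer()
  fit <- NULL
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    if (length(keep) < 3) stop("fewer than 3 surviving pairs after rejection")
    fit <- kabsch(pa$coords[pairs[keep, "a"], , drop = FALSE],
                  pb$coords[pairs[keep, "b"], , drop = FALSE])
    moved <- sweep(pa$coords[pairs[keep, "a"], , drop = FALSE] %*%
                     t(fit$rotation), 2, fit$translation, "+")
    dev <- sqrt(rowSums((moved -
                           pb$coords[pairs[keep, "b"], , drop = FALSE])^2))
    bad <- which(dev > reject_cutoff)
    if (!length(bad) || cycles >= max_cycles) break
    # progressive trimming: drop the gross outliers first so a fit tilted
    # by them does not drag well-fitting neighbours over the cutoff
    stage <- max(reject_cutoff, 0.8 * max(dev[bad]))
    bad <- bad[dev[bad] >= stage]
    rejected <- c(rejected, keep[bad])
    keep <- keep[-bad]
  }
  fit$n_cycles <- cycles
  fit$rejected <- data.frame(
    index = rejected,
    key_a = pa$keys[pairs[rejected, "a"]],
    key_b = pb$keys[pairs[rejected, "b"]],
    stringsAsFactors = FALSE
  )
  fit$pairs <- data.frame(
    key_a = pa$keys[pairs[keep, "a"]],
    key_b = pb$keys[pairs[keep, "b"]],
    stringsAsFactors = FALSE
  )
  fit
}

#' Export a superposition transform as JSON
#'
#' @param result A `superposition_result`.
#' @param path Optional file path.
#' @export
superposition_json <- function(result, path = NULL) {
  obj <- list(rotation = unname(apply(result$rotation, 1, as.numeric,
                                      simplify = FALSE)),
              translation = as.numeric(result$translation),
              rmsd = result$rmsd, n_pairs = result$n_pairs,
              n_cycles = result$n_cycles)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
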