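# Seeded generators for sequence families and alignments.

#' Specification of a synthetic sequence family set
#'
#' @param founder_length Founder sequence length (residues).
#' @param n_species Number of species.
#' @param families Named list: one entry per family (cluster); each value
#'   is the paralog count per species — a single integer (constant) or an
#'   integer vector of length `n_species` (0 allowed: species lacking the
#'   family).
#' @param within_identity Target within-family identity (exact by
#'   construction: the complement fraction of positions is mutated).
#' @param between_identity Expected ceiling on between-family identity;
#'   founders are independent random sequences, so this is validated as an
#'   upper bound, not synthesised.
#' @param seed Integer seed.
#' @return A `family_spec`.
#' @export
family_spec <- function(founder_length = 300, n_species = 10,
                        families = list(A = 1L, B = 1L),
                        within_identity = 0.9, between_identity = 0.3,
                        seed = 1L) {
  stopifnot(within_identity > 0, within_identity <= 1,
            within_identity > between_identity,
            founder_length >= 30, n_species >= 1, length(families) >= 1)
  structure(list(founder_length = founder_length, n_species = n_species,
                 families = families, within_identity = within_identity,
                 between_identity = between_identity,
                 seed = as.integer(seed)),
            class = "family_spec")
}

random_aa <- function(n) {
  sample(names(AA_BACKGROUND), n, replace = TRUE, prob = AA_BACKGROUND)
}

mutate_to_identity <- function(founder, identity) {
  L <- length(founder)
  n_mut <- round((1 - identity) * L)
  if (n_mut == 0) return(founder)
  pos <- sample.int(L, n_mut)
  out <- founder
  for (p in pos) {
    repl <- random_aa(1)
    while (repl == founder[p]) repl <- random_aa(1)
    out[p] <- repl
  }
  out
}

#' Generate a synthetic family set with truth tables
#'
#' Each family gets an independent random founder; every species contributes
#' the specified number of paralogs, each a seeded point-mutant of the
#' founder hitting the within-family identity exactly (mutated-position
#' count = round((1 - identity) * length)). Species tags and full
#' membership truth tables are attached.
#'
#' @param spec A `family_spec`.
#' @return List: `records` ([sequence_records()] data.frame), `truth`
#'   (data.frame id/species/cluster), `founders` (named character).
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  founders <- lapply(spec$families, function(x) {
    random_aa(spec$founder_length)
  })
  ids <- character(); seqs <- character(); sps <- character()
  clusters <- character()
  for (fam in names(spec$families)) {
    counts <- spec$families[[fam]]
    if (length(counts) == 1L) counts <- rep(counts, spec$n_species)
    stopifnot(length(counts) == spec$n_species)
    for (si in seq_len(spec$n_species)) {
      k <- counts[si]
      if (k < 1) next
      for (p in seq_len(k)) {
        ids <- c(ids, sprintf("%s_%s_p%d", fam, species[si], p))
        seqs <- c(seqs, paste(
          mutate_to_identity(founders[[fam]], spec$within_identity),
          collapse = ""))
        sps <- c(sps, species[si])
        clusters <- c(clusters, fam)
      }
    }
  }
  records <- sequence_records(ids, seqs, sps)
  list(records = records,
       truth = data.frame(id = ids, species = sps, cluster = clusters,
                          stringsAsFactors = FALSE),
       founders = vapply(founders, paste, "", collapse = ""))
}

#' Generate a synthetic MSA with designed conserved columns
#'
#' Designated columns are invariant (one seeded residue each, drawn from
#' the rarer half of the background so conservation anchors are
#' unambiguous); all other columns are drawn independently from the
#' background frequencies.
#'
#' @param n_rows Number of rows (>= 2; profiles downstream require >= 5).
#' @param length Alignment length.
#' @param conserved_columns Integer positions of invariant columns.
#' @param seed Integer seed.
#' @param gap_fraction Per-cell gap probability in non-conserved columns.
#' @return Character matrix (rows `r1`, `r2`, ...).
#' @export
make_msa <- function(n_rows, length, conserved_columns = integer(),
                     seed = 1L, gap_fraction = 0) {
  stopifnot(n_rows >= 1, length >= 1,
            all(conserved_columns >= 1), all(conserved_columns <= length))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rare <- names(sort(AA_BACKGROUND))[1:10]
  m <- matrix("", n_rows, length)
  for (j in seq_len(length)) {
    if (j %in% conserved_columns) {
      m[, j] <- sample(rare, 1)
    } else {
      col <- random_aa(n_rows)
      if (gap_fraction > 0) {
        col[stats::runif(n_rows) < gap_fraction] <- "-"
      }
      m[, j] <- col
    }
  }
  rownames(m) <- sprintf("r%d", seq_len(n_rows))
  m
}

#' Write sequence records to FASTA
#'
#' @param records data.frame from [sequence_records()].
#' @param path Output path.
#' @export
write_fasta_records <- function(records, path) {
  ss <- Biostrings::AAStringSet(records$sequence)
  names(ss) <- ifelse(is.na(records$species), records$id,
                      paste0(records$id, " species=", records$species))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
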