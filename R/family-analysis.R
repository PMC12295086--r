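# Desk-scale sequence family analysis: pairwise statistics, representative
# node collapsing, sequence similarity network, ortholog co-distribution,
# and conservation profiling mapped onto structures.
#
# All alignments share one configuration (BLOSUM62, gap open 10 / extend
# 0.5) with the structural module. E-values use fixed gapped
# Karlin-Altschul parameters (lambda = 0.267, K = 0.041) with an m*n search
# space — a deterministic approximation of BLAST-style statistics.

KA_LAMBDA <- 0.267
KA_K <- 0.041

# BLOSUM62 background amino-acid frequencies.
AA_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073
)

#' Sequence records
#'
#' Light constructor for the sequence container used across the family
#' module.
#'
#' @param id Character ids.
#' @param sequence Amino-acid strings (20-letter alphabet plus X).
#' @param species Optional species tags.
#' @return data.frame with columns id, species, sequence.
#' @export
sequence_records <- function(id, sequence, species = NA_character_) {
  stopifnot(length(id) == length(sequence))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(sequence))
  if (any(bad)) stop("non-amino-acid letters in: ",
                     paste(id[bad], collapse = ", "))
  data.frame(id = id, species = species, sequence = toupper(sequence),
             stringsAsFactors = FALSE)
}

#' Read sequence records from FASTA
#'
#' Species tags are taken from a `species=` token in the description when
#' present, else from the suffix after the last underscore of the id.
#'
#' @param path FASTA file.
#' @return data.frame as [sequence_records()].
#' @export
read_fasta_records <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("empty FASTA: ", path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  species <- ifelse(grepl("species=", full),
                    sub("^.*species=(\\S+).*$", "\\1", full),
                    sub("^.*_", "", id))
  sequence_records(id, as.character(ss), species)
}

#' Pairwise similarity statistics of two sequences
#'
#' Global identity (identical columns over aligned, non-double-gap
#' columns of a Needleman-Wunsch alignment) plus local Smith-Waterman
#' score converted to bits and a Karlin-Altschul E-value over the m*n
#' search space.
#'
#' @param seq_a,seq_b Amino-acid strings (non-empty).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return List: `identity`, `score` (local, raw), `bits`, `evalue`.
#' @export
pairwise_stats <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  submat <- get_submatrix("BLOSUM62")
  glob <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(glob)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(glob)), "")[[1]]
  aligned <- pa != "-" | pb != "-"
  identity <- sum(pa == pb & aligned) / sum(aligned)
  loc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(loc)
  m <- nchar(seq_a); n <- nchar(seq_b)
  list(identity = identity, score = s,
       bits = (KA_LAMBDA * s - log(KA_K)) / log(2),
       evalue = KA_K * m * n * exp(-KA_LAMBDA * s))
}

#' Collapse sequences into representative nodes
#'
#' Greedy CD-HIT-like clustering: sequences sorted by length (descending,
#' ties by input order); each joins the first existing representative with
#' global identity at or above the threshold, else founds a new node.
#'
#' @param records Sequence records ([sequence_records()]).
#' @param identity_threshold Fraction (default 0.9, the customary
#'   90 percent representative collapse).
#' @return data.frame of nodes: `node` (representative id), `members`
#'   (list-column of member ids), `n_members`, `sequence`.
#' @export
collapse_nodes <- function(records, identity_threshold = 0.9) {
  stopifnot(nrow(records) >= 1)
  ord <- order(-nchar(records$sequence), seq_len(nrow(records)))
  reps <- integer()
  membership <- integer(nrow(records))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      st <- pairwise_stats(records$sequence[i], records$sequence[r])
      if (st$identity >= identity_threshold) {
        membership[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); membership[i] <- i }
  }
  data.frame(
    node = records$id[reps],
    members = I(lapply(reps, function(r) records$id[membership == r])),
    n_members = vapply(reps, function(r) sum(membership == r), 1L),
    sequence = records$sequence[reps],
    stringsAsFactors = FALSE
  )
}

#' All-vs-all pairwise statistics between representative nodes
#'
#' @param nodes Node table from [collapse_nodes()].
#' @return data.frame with one row per unordered node pair: a, b, score,
#'   bits, evalue, identity.
#' @export
ssn_pair_table <- function(nodes) {
  n <- nrow(nodes)
  rows <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      st <- pairwise_stats(nodes$sequence[i], nodes$sequence[k])
      rows[[length(rows) + 1L]] <- data.frame(
        a = nodes$node[i], b = nodes$node[k], score = st$score,
        bits = st$bits, evalue = st$evalue, identity = st$identity,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(a = character(), b = character(), score = double(),
               bits = double(), evalue = double(), identity = double())
  }
}

#' Build a sequence similarity network
#'
#' All-vs-all [pairwise_stats()] between node representatives; edges kept
#' at `evalue <= evalue_cutoff`; connected components computed with igraph.
#'
#' @param nodes Node table from [collapse_nodes()].
#' @param evalue_cutoff E-value threshold (the family-analysis default
#'   1e-40 mirrors customary SSN practice).
#' @param pairs Optional precomputed [ssn_pair_table()] (so several
#'   cutoffs can reuse one set of alignments).
#' @return An `ssn_graph`: list with `nodes` (plus `component` column),
#'   `edges` (data.frame a, b, score, bits, evalue, identity), `graph`
#'   (igraph object), `n_components`.
#' @export
build_ssn <- function(nodes, evalue_cutoff = 1e-40, pairs = NULL) {
  if (is.null(pairs)) pairs <- ssn_pair_table(nodes)
  edges <- pairs[pairs$evalue <= evalue_cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = nodes$node))
  comp <- igraph::components(g)
  nodes$component <- comp$membership[nodes$node]
  structure(list(nodes = nodes, edges = edges, graph = g,
                 n_components = comp$no),
            class = "ssn_graph")
}

#' @export
print.ssn_graph <- function(x, ...) {
  cat(sprintf("ssn_graph: %d nodes (%d sequences), %d edges, %d components\n",
              nrow(x$nodes), sum(x$nodes$n_members), nrow(x$edges),
              x$n_components))
  invisible(x)
}

#' Export an SSN as edge-list TSV and GraphML
#'
#' @param ssn An `ssn_graph`.
#' @param edges_path Optional TSV path for the edge list.
#' @param graphml_path Optional GraphML path.
#' @export
write_ssn <- function(ssn, edges_path = NULL, graphml_path = NULL) {
  if (!is.null(edges_path)) {
    out <- ssn$edges
    out$evalue <- format(out$evalue, digits = 4)
    out$bits <- round(out$bits, 4)
    out$identity <- round(out$identity, 4)
    utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(ssn$graph, graphml_path, format = "graphml")
  }
  invisible(ssn)
}

#' Ortholog co-distribution statistics
#'
#' Per-species member counts per cluster, Venn subset-membership counts
#' over clusters, and mean paralog counts per cluster over the species
#' possessing at least one member.
#'
#' @param membership data.frame with columns `id`, `species`, `cluster`
#'   (cluster may be a subfamily label or an SSN component).
#' @return A `co_distribution`: `per_species_counts` (species x cluster
#'   matrix), `venn` (named counts by cluster subset, e.g. `"A+B"`),
#'   `mean_paralogs` (per cluster).
#' @export
co_distribution <- function(membership) {
  need <- c("id", "species", "cluster")
  stopifnot(all(need %in% names(membership)))
  miss <- membership$id[is.na(membership$species) |
                          !nzchar(membership$species)]
  if (length(miss)) {
    stop("missing species tag for: ", paste(miss, collapse = ", "))
  }
  tab <- table(membership$species, membership$cluster)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  subset_of <- apply(counts > 0, 1, function(r) {
    paste(colnames(counts)[r], collapse = "+")
  })
  venn <- table(subset_of[nzchar(subset_of)])
  mean_paralogs <- vapply(colnames(counts), function(cl) {
    has <- counts[, cl] > 0
    if (!any(has)) return(NA_real_)
    mean(counts[has, cl])
  }, 0)
  structure(list(per_species_counts = counts,
                 venn = stats::setNames(as.integer(venn), names(venn)),
                 mean_paralogs = mean_paralogs),
            class = "co_distribution")
}

#' @export
print.co_distribution <- function(x, ...) {
  cat("co-distribution over", nrow(x$per_species_counts), "species:\n")
  cat("  venn:", paste(sprintf("%s: %d", names(x$venn), x$venn),
                       collapse = ", "), "\n")
  cat("  mean paralogs:",
      paste(sprintf("%s: %.2f", names(x$mean_paralogs), x$mean_paralogs),
            collapse = ", "), "\n")
  invisible(x)
}

# ---- conservation -----------------------------------------------------------

jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Per-column conservation profile of an MSA
#'
#' Scores each column by the Jensen-Shannon divergence between its
#' gap-excluded amino-acid frequency vector and a background distribution,
#' normalized to [0, 1] by the largest point-mass divergence over the
#' column's observed letters (JSD is convex in its first argument, so the
#' ratio is at most 1, with equality exactly for invariant columns: any
#' fully conserved column scores 1.0, and a column matching the background
#' scores 0). Columns with more than 50 percent gaps are flagged
#' low-confidence. A simplified information-theoretic stand-in for
#' evolutionary-rate conservation scoring.
#'
#' @param msa Character vector of aligned rows (equal lengths, `-` gaps),
#'   or a matrix of single characters.
#' @param background Amino-acid frequency vector (named, 20 letters).
#' @return A `conservation_profile`: `per_column` scores, `low_confidence`
#'   logical, `gap_fraction`.
#' @export
conservation_profile <- function(msa, background = AA_BACKGROUND) {
  m <- msa_matrix(msa)
  if (nrow(m) < 5) stop("conservation profile requires >= 5 rows")
  background <- background / sum(background)
  aas <- names(background)
  point_jsd <- vapply(seq_along(aas), function(i) {
    p <- stats::setNames(numeric(length(aas)), aas)
    p[i] <- 1
    jsd(p, background)
  }, 0)
  names(point_jsd) <- aas
  scores <- numeric(ncol(m))
  gapf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gapf[j] <- mean(col == "-" | col == ".")
    res <- col[col %in% aas]
    if (!length(res)) { scores[j] <- NA_real_; next }
    p <- stats::setNames(numeric(length(aas)), aas)
    tt <- table(res)
    p[names(tt)] <- as.numeric(tt) / length(res)
    norm <- max(point_jsd[names(tt)])
    scores[j] <- min(1, jsd(p, background) / norm)
  }
  structure(list(per_column = scores, low_confidence = gapf > 0.5,
                 gap_fraction = gapf),
            class = "conservation_profile")
}

msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("ragged alignment: unequal row lengths")
  do.call(rbind, strsplit(toupper(msa), ""))
}

#' Map a conservation profile onto a structure
#'
#' Maps non-gap MSA columns of a query row to the reference structure's
#' protein residues in order (after checking >= 95 percent identity between
#' the gap-stripped query row and the modelled sequence).
#'
#' @param profile A `conservation_profile`.
#' @param msa The alignment the profile came from (rows named, or a
#'   character vector + `query_row` as index).
#' @param query_row Name or index of the query row.
#' @param reference A classified `structure_model`.
#' @param min_identity Required query/structure sequence identity.
#' @return data.frame: residue key, seq_num, column, score.
#' @export
map_conservation <- function(profile, msa, query_row, reference,
                             min_identity = 0.95) {
  m <- msa_matrix(msa)
  ri <- if (is.character(query_row)) {
    which(rownames(m) == query_row)[1]
  } else query_row
  if (is.na(ri) || ri < 1 || ri > nrow(m)) stop("query row not in MSA")
  row <- m[ri, ]
  nongap <- which(row != "-" & row != ".")
  qseq <- paste(row[nongap], collapse = "")
  pc <- protein_ca(reference)
  sseq <- pc$seq
  if (nchar(qseq) < nchar(sseq)) {
    stop("profile row shorter than the modelled structure sequence")
  }
  st <- pairwise_stats(qseq, sseq)
  if (st$identity < min_identity) {
    stop(sprintf("query/structure identity %.2f below %.2f", st$identity,
                 min_identity))
  }
  # align query to the modelled sequence to absorb unmodelled termini
  submat <- get_submatrix("BLOSUM62")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qseq), Biostrings::AAString(sseq),
    type = "global", substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- cumsum(qa != "-"); si <- cumsum(sa != "-")
  both <- qa != "-" & sa != "-"
  data.frame(
    key = pc$keys[si[both]], seq_num = pc$seq_num[si[both]],
    column = nongap[qi[both]],
    score = profile$per_column[nongap[qi[both]]],
    stringsAsFactors = FALSE
  )
}

#' Mean conservation inside vs outside a residue set
#'
#' Convenience contrast used to compare canyon lining against the rest of
#' the surface.
#'
#' @param mapped Output of [map_conservation()].
#' @param lining Output of [canyon_lining()] (or residue keys).
#' @return List: `mean_in`, `mean_out`, `n_in`, `n_out`.
#' @export
conservation_contrast <- function(mapped, lining) {
  keys <- if (is.data.frame(lining)) lining$key else lining
  inside <- mapped$key %in% keys
  list(mean_in = mean(mapped$score[inside], na.rm = TRUE),
       mean_out = mean(mapped$score[!inside], na.rm = TRUE),
       n_in = sum(inside), n_out = sum(!inside))
}
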