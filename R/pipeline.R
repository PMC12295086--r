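# Run configuration and one-shot pipelines: the full subsite-mapping chain
# and the family-analysis chain. Config round-trips through JSON; outputs
# use fixed precision (3 decimals for Angstrom, 4 for scores) for
# diffability. All randomness is controlled by config$seed.

#' Default run configuration
#'
#' All pipeline tunables with their documented defaults. Paths are NULL
#' until set. The configuration fully determines behaviour: no hidden
#' environment dependence.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    # inputs
    reference = NULL,        # reference PDB path
    complexes = character(), # soaked-complex PDB paths
    fasta = NULL,            # family FASTA path
    msa = NULL,              # MSA FASTA path
    msa_query = NULL,        # query row id for structure mapping
    out_dir = ".",
    # structure stage
    merge_radius = 1.8,      # subsite single-linkage radius, Angstrom
    reject_cutoff = 2.0,     # alignment outlier rejection, Angstrom
    max_cycles = 5,          # alignment rejection cycles
    min_transfer_pairs = 50, # Calpha pairs required to transfer ligands
    shape_linear = 4.0,      # per-residue threshold, linear shape
    shape_u = 2.5,           # per-residue threshold, U shape
    ss_cutoff = 2.5,         # disulfide SG-SG cutoff, Angstrom
    contact_cutoff = 3.6,    # H-bond-range contact cutoff, Angstrom
    lining_cutoff = 4.5,     # canyon lining cutoff, Angstrom
    planarity_q = 0.05,      # ring planarity threshold, Angstrom
    like_threshold = 15,     # conformer "-like" distance, degrees
    anomer_dead_zone = 0.15, # anomeric displacement dead zone, Angstrom
    adjacency_max = 4.5,     # plausible linkage C-C distance, Angstrom
    assign_radius = 2.5,     # predicted-ligand subsite radius, Angstrom
    wing_region = NULL,      # optional c(start_seq, end_seq) for WR1
    # family stage
    evalue_cutoff = 1e-40,   # SSN edge threshold
    identity_threshold = 0.9,# representative-node collapse
    seed = 1L
  ), class = "run_config")
}

#' Read / write run configuration
#'
#' JSON serialization; unknown keys are rejected, missing keys take
#' defaults, so a config file round-trips exactly.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  unknown <- setdiff(names(got), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (nm in names(got)) cfg[[nm]] <- got[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config[!vapply(config, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Full subsite-mapping pipeline
#'
#' parse -> classify -> align/transfer -> ring/linkage detection -> pucker
#' -> cluster -> label -> occupancy -> shape -> contacts -> report.
#' Writes, under `config$out_dir`: `composite.pdb`, `subsites.json`,
#' `occupancy.tsv`, `pucker.tsv`, `report.txt`. A reference with no ligand
#' sugars yields a "0 subsites" report and succeeds.
#'
#' @param config A `run_config` with `reference` and (optionally)
#'   `complexes` set; in-memory `structure_model`s are also accepted.
#' @return The `subsite_map` (invisibly NULL when no sugars present).
#' @export
run_map_subsites <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  load_model <- function(x) {
    if (inherits(x, "structure_model")) x else parse_structure(x)
  }
  reference <- tryCatch(load_model(config$reference),
                        error = function(e) {
                          stop("[reference] ", conditionMessage(e))
                        })
  complexes <- lapply(config$complexes, function(p) {
    tryCatch(load_model(p),
             error = function(e) stop("[complex] ", conditionMessage(e)))
  })
  if (!length(complexes)) complexes <- list(reference)

  composite <- transfer_ligands(complexes, reference,
                                min_pairs = config$min_transfer_pairs,
                                max_cycles = config$max_cycles,
                                reject_cutoff = config$reject_cutoff)
  write_structure(composite, file.path(config$out_dir, "composite.pdb"))
  ss <- cluster_subsites(composite, merge_radius = config$merge_radius)

  report <- file.path(config$out_dir, "report.txt")
  if (!length(ss$subsites)) {
    writeLines(c(sprintf("reference: %s", reference$id), "0 subsites"),
               report)
    return(invisible(NULL))
  }

  pt <- pucker_table(ss$rings, like_threshold = config$like_threshold)
  utils::write.table(pt, file.path(config$out_dir, "pucker.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  wr <- if (!is.null(config$wing_region)) {
    list(WR1 = config$wing_region)
  } else list()
  annotation <- tryCatch(find_dd_motif(reference, wing_regions = wr),
                         error = function(e) NULL)
  map <- NULL
  if (length(ss$subsites) >= 2 && !is.null(annotation)) {
    glcn <- Filter(function(r) r$comp_name %in% c("GCS", "PA1"), ss$rings)
    anchor <- if (length(glcn)) glcn[[1]] else NULL
    map <- assign_labels(ss, annotation, reference, glcn_anchor = anchor)
    subsite_map_json(map, file.path(config$out_dir, "subsites.json"))
    write_occupancy(map, file.path(config$out_dir, "occupancy.tsv"))
  }

  lining <- canyon_lining(reference, composite,
                          cutoff = config$lining_cutoff)
  aromatic <- canyon_lining(reference, composite,
                            cutoff = config$lining_cutoff,
                            aromatic_only = TRUE)
  disulf <- detect_disulfides(reference, ss_cutoff = config$ss_cutoff)

  lines <- c(
    sprintf("reference: %s", reference$id),
    sprintf("complexes: %s",
            paste(vapply(complexes, `[[`, "", "id"), collapse = ", ")),
    sprintf("%d subsites", length(ss$subsites)),
    if (!is.null(map)) {
      sprintf("labels: %s",
              paste(sprintf("%+d", sort(vapply(map$subsites, `[[`, 1L,
                                               "label"),
                                        decreasing = TRUE)),
                    collapse = ", "))
    },
    sprintf("sugar observations: %d", length(ss$rings)),
    sprintf("canyon lining residues (%.1f A): %d (%d aromatic)",
            config$lining_cutoff, nrow(lining), nrow(aromatic)),
    sprintf("disulfides: %s",
            if (nrow(disulf)) {
              paste(sprintf("%d-%d", disulf$seq_num_a, disulf$seq_num_b),
                    collapse = ", ")
            } else "none")
  )
  writeLines(lines, report)
  invisible(map)
}

#' Full family-analysis pipeline
#'
#' Reads family FASTA, collapses representative nodes, builds the SSN,
#' derives cluster membership from connected components, computes
#' co-distribution statistics, and (when an MSA is supplied) the
#' conservation profile. Writes `edges.tsv`, `network.graphml`,
#' `stats.json` and `conservation.tsv` under `config$out_dir`.
#'
#' @param config A `run_config` with `fasta` (path or records data.frame)
#'   set; optional `msa`.
#' @return List with `ssn`, `codist`, `profile` (invisible).
#' @export
run_family <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (is.data.frame(config$fasta)) config$fasta
             else read_fasta_records(config$fasta)
  nodes <- collapse_nodes(records,
                          identity_threshold = config$identity_threshold)
  ssn <- build_ssn(nodes, evalue_cutoff = config$evalue_cutoff)
  write_ssn(ssn, edges_path = file.path(config$out_dir, "edges.tsv"),
            graphml_path = file.path(config$out_dir, "network.graphml"))

  node_of <- stats::setNames(
    rep(ssn$nodes$node, vapply(ssn$nodes$members, length, 1L)),
    unlist(ssn$nodes$members))
  comp_of <- stats::setNames(ssn$nodes$component, ssn$nodes$node)
  membership <- data.frame(
    id = records$id, species = records$species,
    cluster = paste0("component", comp_of[node_of[records$id]]),
    stringsAsFactors = FALSE)
  codist <- co_distribution(membership)

  profile <- NULL
  if (!is.null(config$msa)) {
    msa <- if (is.matrix(config$msa)) config$msa else {
      ss <- Biostrings::readAAStringSet(config$msa)
      m <- do.call(rbind, strsplit(as.character(ss), ""))
      rownames(m) <- sub("\\s.*$", "", names(ss))
      m
    }
    profile <- conservation_profile(msa)
    utils::write.table(
      data.frame(column = seq_along(profile$per_column),
                 score = round(profile$per_column, 4),
                 low_confidence = profile$low_confidence),
      file.path(config$out_dir, "conservation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stats_obj <- list(
    n_sequences = nrow(records),
    n_nodes = nrow(ssn$nodes),
    n_edges = nrow(ssn$edges),
    n_components = ssn$n_components,
    venn = as.list(codist$venn),
    mean_paralogs = as.list(round(codist$mean_paralogs, 4))
  )
  jsonlite::write_json(stats_obj, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ssn = ssn, codist = codist, profile = profile))
}
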