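# PDB coordinate I/O and residue categorisation.
#
# A structure_model stores all atoms in a single data.frame (one row per
# atom) with residue identity carried by (source, chain_id, seq_num, icode).
# This is the idiomatic R layout for whole-structure vectorised geometry and
# satisfies the hierarchical atom/residue contract through the accessors
# below. Only the PDB dialect is supported (the deposited entries provide
# PDB); hydrogens are dropped, waters kept but flagged by category.

AMINO3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M")

atom_columns <- function() {
  data.frame(
    name = character(), altloc = character(), comp_name = character(),
    chain_id = character(), seq_num = integer(), icode = character(),
    x = double(), y = double(), z = double(),
    occupancy = double(), b_iso = double(), element = character(),
    het = logical(), category = character(), source = character(),
    stringsAsFactors = FALSE
  )
}

new_structure_model <- function(id, atoms, source_path = NA_character_) {
  structure(list(id = id, atoms = atoms, source_path = source_path),
            class = "structure_model")
}

#' Parse a PDB coordinate file
#'
#' Reads ATOM/HETATM records from a fixed-column PDB file into a
#' `structure_model`. Hydrogens are dropped; waters are retained (flagged by
#' [classify_residues()]). Alternate locations are resolved per
#' `altloc_policy`: the default keeps, for each atom name within a residue,
#' the conformer with the highest occupancy (ties broken by altloc character
#' order), yielding deterministic single-conformer geometry downstream.
#'
#' @param path Path to a PDB-format text file.
#' @param altloc_policy `"highest_occupancy"` (default) or `"all"`.
#' @param id Structure identifier; defaults to the file base name.
#' @return A `structure_model`: list with `id`, `atoms` (data.frame, one row
#'   per atom), `source_path`. Residue categories are filled by
#'   [classify_residues()] (called automatically).
#' @export
parse_structure <- function(path,
                            altloc_policy = c("highest_occupancy", "all"),
                            id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  if (!any(keep)) stop("empty model: no ATOM/HETATM records in ", path)
  ln <- lines[keep]
  lineno <- which(keep)

  fx <- function(a, b) substr(ln, a, b)
  xs <- suppressWarnings(as.numeric(fx(31, 38)))
  ys <- suppressWarnings(as.numeric(fx(39, 46)))
  zs <- suppressWarnings(as.numeric(fx(47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad)) {
    stop("parse error: unreadable coordinates at line ", lineno[bad[1]])
  }
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[!is.finite(occ)] <- 1
  b <- suppressWarnings(as.numeric(fx(61, 66)))
  b[!is.finite(b)] <- 0
  seq_num <- suppressWarnings(as.integer(fx(23, 26)))
  if (anyNA(seq_num)) {
    stop("parse error: unreadable residue number at line ",
         lineno[which(is.na(seq_num))[1]])
  }
  element <- trimws(fx(77, 78))
  name <- trimws(fx(13, 16))
  # fall back to the first letter of the atom name when element is absent
  noel <- !nzchar(element)
  element[noel] <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", name[noel]))
  element[noel] <- substr(toupper(element[noel]), 1,
                          ifelse(nchar(element[noel]) > 1 &
                                   toupper(element[noel]) %in%
                                   c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
                                 2, 1))

  atoms <- data.frame(
    name = name, altloc = substr(ln, 17, 17),
    comp_name = trimws(fx(18, 20)), chain_id = trimws(fx(22, 22)),
    seq_num = seq_num, icode = substr(ln, 27, 27),
    x = xs, y = ys, z = zs, occupancy = occ, b_iso = b,
    element = toupper(element), het = rec[keep] == "HETATM",
    category = NA_character_, source = NA_character_,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  if (!nrow(atoms)) stop("empty model: only hydrogen atoms in ", path)

  if (altloc_policy == "highest_occupancy") {
    key <- paste(atoms$chain_id, atoms$seq_num, atoms$icode, atoms$name)
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
    atoms$altloc <- " "
  }
  rownames(atoms) <- NULL
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  classify_residues(new_structure_model(id, atoms, source_path = path))
}

#' Built-in residue category table
#'
#' Returns the component-code table used by [classify_residues()], read from
#' the plain-text file shipped in `inst/extdata/residue_categories.tsv`.
#' Users can extend it via the `extra` argument of [classify_residues()].
#'
#' @return data.frame with columns `comp_name`, `category`.
#' @export
residue_category_table <- function() {
  path <- system.file("extdata", "residue_categories.tsv",
                      package = "glycanyon")
  if (!nzchar(path)) {       # during in-source development
    path <- file.path("inst", "extdata", "residue_categories.tsv")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Classify residues into protein / saccharide / water / other
#'
#' Assigns one category to every residue from the built-in component table
#' (20 amino acids + MSE; common pyranose component codes MAN, BMA, GLC,
#' BGC, GAL, GLA, GCS, PA1, NAG, NDG; HOH/WAT/DOD water). Unknown components
#' are labelled `other`, never dropped. Idempotent and total.
#'
#' @param model A `structure_model`.
#' @param extra Optional data.frame with columns `comp_name`, `category`
#'   appended to (and overriding) the built-in table.
#' @return The model with the atoms' `category` column filled.
#' @export
classify_residues <- function(model, extra = NULL) {
  stopifnot(inherits(model, "structure_model"))
  tab <- residue_category_table()
  if (!is.null(extra)) {
    stopifnot(all(c("comp_name", "category") %in% names(extra)))
    tab <- rbind(extra[, c("comp_name", "category")], tab)
    tab <- tab[!duplicated(tab$comp_name), , drop = FALSE]
  }
  cat_of <- stats::setNames(tab$category, tab$comp_name)
  got <- cat_of[model$atoms$comp_name]
  got[is.na(got)] <- "other"
  model$atoms$category <- unname(got)
  model
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (3-decimal coordinates) followed
#' by END. Round-trips losslessly through [parse_structure()] at the
#' format's precision.
#'
#' @param model A `structure_model` with at least one atom.
#' @param path Output file path.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (!nrow(a)) stop("cannot write empty model")
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # PDB atom-name column rules: names of <4 chars start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf(
    "%s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)) %% 100000L, nm,
    substr(paste0(a$altloc, " "), 1, 1), a$comp_name,
    substr(paste0(a$chain_id, "A"), 1, 1), a$seq_num %% 10000L,
    substr(paste0(a$icode, " "), 1, 1),
    a$x, a$y, a$z, a$occupancy, a$b_iso, a$element
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

# ---- residue-level accessors ------------------------------------------------

residue_key <- function(atoms) {
  src <- atoms$source
  src[is.na(src)] <- ""
  paste(src, atoms$chain_id, atoms$seq_num, atoms$icode, sep = "|")
}

#' Residue-level summary of a structure
#'
#' @param model A `structure_model`.
#' @return data.frame, one row per residue: `key`, `chain_id`, `seq_num`,
#'   `icode`, `comp_name`, `category`, `source`, `n_atoms` (ordered as in
#'   the file).
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- residue_key(a)
  first <- !duplicated(key)
  out <- data.frame(
    key = key[first], chain_id = a$chain_id[first],
    seq_num = a$seq_num[first], icode = a$icode[first],
    comp_name = a$comp_name[first], category = a$category[first],
    source = a$source[first],
    n_atoms = as.integer(table(key)[key[first]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

residue_atoms <- function(model, key) {
  model$atoms[residue_key(model$atoms) == key, , drop = FALSE]
}

# One-letter sequence + CA coordinates of the protein residues of a chain
# (all chains when chain is NULL), in residue order.
protein_ca <- function(model, chain = NULL) {
  a <- model$atoms
  sel <- a$category == "protein" & a$name == "CA"
  if (!is.null(chain)) sel <- sel & a$chain_id == chain
  ca <- a[sel, , drop = FALSE]
  ca <- ca[!duplicated(residue_key(ca)), , drop = FALSE]
  letters1 <- AMINO3[ca$comp_name]
  letters1[is.na(letters1)] <- "X"
  list(seq = paste(letters1, collapse = ""),
       coords = as.matrix(ca[, c("x", "y", "z")]),
       keys = residue_key(ca), seq_num = ca$seq_num)
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("structure_model '%s': %d atoms, %d residues (%s)\n",
              x$id, nrow(x$atoms), nrow(rt),
              paste(sprintf("%s: %d", names(table(rt$category)),
                            table(rt$category)), collapse = ", ")))
  invisible(x)
}

# Rigid transform applied to all atoms (rotation matrix + translation).
transform_model <- function(model, rotation, translation) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}
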