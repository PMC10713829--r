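#' @title Coordinate data model and multi-model PDB/mmCIF input
#' @name pdb-io
#' @description A `StructureModel` is a single set of atomic coordinates; an
#'   `Ensemble` is an ordered list of models, optionally guaranteed to share
#'   an identical atom-identity list ("shared topology"), as produced by
#'   multi-model PDB files (MODEL/ENDMDL blocks) such as deposited NMR or
#'   docking ensembles.
NULL

#' Construct a StructureModel
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer, author numbering), `icode` (character, insertion code, ""
#'   when absent), `resname` (3-letter code), `atom` (atom name), `element`
#'   (element symbol) and Cartesian coordinates `x`, `y`, `z` in Angstrom.
#' @param model_id integer model identifier.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  required <- c("chain", "resno", "icode", "resname", "atom", "element",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$icode <- as.character(atoms$icode)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- as.character(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in model ", model_id)
  key <- atom_identity(atoms)
  if (anyDuplicated(key))
    stop("duplicate atom identity in model ", model_id, ": ",
         key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "StructureModel")
}

atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel %d: %d atoms, %d residues, chains %s\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$icode))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Coordinate matrix of a model
#'
#' @param m StructureModel.
#' @param idx optional integer atom indices.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(m, idx = NULL) {
  xyz <- cbind(m$atoms$x, m$atoms$y, m$atoms$z)
  colnames(xyz) <- c("x", "y", "z")
  if (!is.null(idx)) xyz <- xyz[idx, , drop = FALSE]
  xyz
}

#' Replace coordinates of a model
#' @param m StructureModel.
#' @param xyz n x 3 matrix.
#' @return modified StructureModel.
#' @export
set_coords <- function(m, xyz) {
  stopifnot(nrow(xyz) == nrow(m$atoms), ncol(xyz) == 3L)
  m$atoms$x <- xyz[, 1L]
  m$atoms$y <- xyz[, 2L]
  m$atoms$z <- xyz[, 3L]
  m
}

#' Construct an Ensemble of structure models
#'
#' @param models list of `StructureModel`.
#' @param shared_topology logical; when `TRUE` all models must carry an
#'   identical atom-identity list in identical order (an error otherwise).
#' @return object of class `Ensemble`.
#' @export
ensemble <- function(models, shared_topology = TRUE) {
  stopifnot(length(models) >= 1L)
  for (m in models)
    if (!inherits(m, "StructureModel")) stop("all elements must be StructureModel")
  if (isTRUE(shared_topology)) {
    ref_id <- atom_identity(models[[1L]]$atoms)
    for (i in seq_along(models)) {
      idi <- atom_identity(models[[i]]$atoms)
      if (length(idi) != length(ref_id) || !all(idi == ref_id))
        stop("model ", i, " does not share the topology of model 1 ",
             "(atom identity mismatch)")
    }
  }
  structure(list(models = models, shared_topology = isTRUE(shared_topology)),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d models (%s topology), %d atoms in model 1\n",
              length(x$models),
              if (x$shared_topology) "shared" else "free",
              nrow(x$models[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.Ensemble <- function(x) length(x$models)

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  first <- toupper(substr(nm, 1L, 1L))
  two <- toupper(substr(nm, 1L, 2L))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE"), two,
         ifelse(first %in% c("C", "N", "O", "S", "P", "H", "F", "K", "I"),
                first, first))
}

parse_pdb_atom_lines <- function(lines) {
  f <- function(from, to) trimws(substr(lines, from, to))
  xyz_num <- function(from, to) as.numeric(substr(lines, from, to))
  atoms <- data.frame(
    chain = f(22, 22),
    resno = suppressWarnings(as.integer(f(23, 26))),
    icode = f(27, 27),
    resname = f(18, 20),
    atom = f(13, 16),
    element = f(77, 78),
    x = xyz_num(31, 38), y = xyz_num(39, 46), z = xyz_num(47, 54),
    altloc = f(17, 17),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z) |
                 is.na(atoms$resno))
  if (length(bad) > 0L)
    stop("unparseable coordinate record: '", lines[bad[1L]], "'")
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  blank <- atoms$element == ""
  atoms$element[blank] <- guess_element(atoms$atom[blank])
  atoms$altloc <- NULL
  atoms
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL blocks become separate models.
#' Alternate locations other than "A" are dropped; blank element columns are
#' inferred from the atom name.
#'
#' @param path file path.
#' @param shared_topology demand identical atom identities across models.
#' @return an `Ensemble`.
#' @export
read_pdb <- function(path, shared_topology = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no coordinate records in ", path)
  # assign model index by counting MODEL records seen before each atom line
  model_no <- cumsum(is_model)
  model_of_atom <- model_no[is_atom]
  if (all(model_of_atom == 0L)) model_of_atom[] <- 1L
  if (any(model_of_atom == 0L))
    stop("coordinate records outside MODEL blocks in a multi-model file")
  atom_lines <- lines[is_atom]
  models <- lapply(sort(unique(model_of_atom)), function(k) {
    structure_model(parse_pdb_atom_lines(atom_lines[model_of_atom == k]),
                    model_id = k)
  })
  ensemble(models, shared_topology = shared_topology)
}

#' Read coordinates from an mmCIF file
#'
#' Minimal `_atom_site` loop reader sufficient for standard single- and
#' multi-model coordinate files. Author chain/residue numbering is used.
#'
#' @inheritParams read_pdb
#' @return an `Ensemble`.
#' @export
read_mmcif <- function(path, shared_topology = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    headers <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      headers <- c(headers, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(headers, "_atom_site."))) next
    rows <- character()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
          ln == "loop_") break
      rows <- c(rows, ln)
      i <- i + 1L
    }
    tok <- strsplit(rows, "[[:space:]]+")
    n_col <- length(headers)
    if (any(lengths(tok) != n_col))
      stop("ragged _atom_site loop in ", path)
    tab <- as.data.frame(do.call(rbind, tok), stringsAsFactors = FALSE)
    names(tab) <- sub("^_atom_site\\.", "", headers)
    col <- function(opts, default = NA_character_) {
      for (o in opts) if (o %in% names(tab)) return(tab[[o]])
      rep(default, nrow(tab))
    }
    grp <- col("group_PDB", "ATOM")
    keep <- grp %in% c("ATOM", "HETATM")
    tab <- tab[keep, , drop = FALSE]
    clean <- function(v) { v[v %in% c(".", "?")] <- ""; gsub('"', "", v) }
    atoms <- data.frame(
      chain = clean(col(c("auth_asym_id", "label_asym_id"))[keep]),
      resno = as.integer(clean(col(c("auth_seq_id", "label_seq_id"))[keep])),
      icode = clean(col("pdbx_PDB_ins_code", "")[keep]),
      resname = clean(col(c("auth_comp_id", "label_comp_id"))[keep]),
      atom = clean(col(c("auth_atom_id", "label_atom_id"))[keep]),
      element = clean(col("type_symbol", "")[keep]),
      x = as.numeric(col("Cartn_x")[keep]),
      y = as.numeric(col("Cartn_y")[keep]),
      z = as.numeric(col("Cartn_z")[keep]),
      stringsAsFactors = FALSE
    )
    blank <- atoms$element == ""
    atoms$element[blank] <- guess_element(atoms$atom[blank])
    model_num <- clean(col("pdbx_PDB_model_num", "1")[keep])
    model_num[model_num == ""] <- "1"
    model_num <- as.integer(model_num)
    models <- lapply(sort(unique(model_num)), function(k)
      structure_model(atoms[model_num == k, , drop = FALSE], model_id = k))
    return(ensemble(models, shared_topology = shared_topology))
  }
  stop("no _atom_site loop found in ", path)
}

#' Read a coordinate file, dispatching on extension
#'
#' `.cif`/`.mmcif` files go through [read_mmcif()]; everything else is
#' treated as PDB.
#'
#' @inheritParams read_pdb
#' @return an `Ensemble`; single-model files yield an Ensemble of length 1.
#' @export
read_model_ensemble <- function(path, shared_topology = TRUE) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
    read_mmcif(path, shared_topology = shared_topology)
  else
    read_pdb(path, shared_topology = shared_topology)
}

format_pdb_atom_name <- function(name, element) {
  # element right-justified in cols 13-14 for 1-letter elements
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write an Ensemble (or single model) as a PDB file
#'
#' @param x `Ensemble` or `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "StructureModel")) x <- ensemble(list(x))
  stopifnot(inherits(x, "Ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x$models) > 1L
  for (k in seq_along(x$models)) {
    m <- x$models[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    a <- m$atoms
    bfac <- if (!is.null(m$bfactor)) m$bfactor else rep(0, nrow(a))
    serial <- seq_len(nrow(a))
    lines <- sprintf(
      "ATOM  %5d %s%s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ((serial - 1L) %% 99999L) + 1L,
      vapply(seq_len(nrow(a)),
             function(i) format_pdb_atom_name(a$atom[i], a$element[i]),
             character(1)),
      " ", a$resname, substr(a$chain, 1L, 1L), a$resno,
      substr(paste0(a$icode, " "), 1L, 1L),
      a$x, a$y, a$z, 1, pmin(pmax(bfac, -9.99), 999.99), toupper(a$element)
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
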