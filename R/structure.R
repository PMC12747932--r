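#' Coordinate data model
#'
#' A `structure3d` is a lightweight hierarchical coordinate model: a flat
#' atom table (one row per atom) whose `model`, `chain`, `resno`/`insert`
#' grouping expresses the model/chain/residue hierarchy, plus free-text
#' metadata. Author residue numbering is the canonical addressing scheme
#' throughout the package (structure papers in this area quote author
#' numbers, e.g. WDR5 24-334 and WIN-motif peptide 114-122). Waters are
#' first-class residues and are never dropped on read; hydrogens, when
#' present, are kept but all geometric criteria in the package operate on
#' heavy atoms.
#'
#' @param atoms data.frame with columns `model` (integer), `chain`,
#'   `resno` (integer author number), `insert` (insertion code, `""` if
#'   none), `resid` (3-letter residue name), `elety` (atom name), `alt`
#'   (alternate-location id, `""` if none), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstrom), `o` (occupancy), `b` (B-factor, Angstrom^2),
#'   `is_water`, `is_hetero` (logical).
#' @param id Identifier (accession or file stem).
#' @param metadata Named list of free-text metadata (e.g. `title`).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, id = "structure", metadata = list()) {
  required <- c("model", "chain", "resno", "insert", "resid", "elety",
                "alt", "elesy", "x", "y", "z", "o", "b",
                "is_water", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("a structure must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop("occupancies must lie in [0, 1]")
  }
  rownames(atoms) <- NULL
  obj <- list(id = id, metadata = metadata, atoms = atoms)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  res_key <- unique(paste(a$model, a$chain, a$resno, a$insert))
  cat(sprintf("<structure3d> %s\n", x$id))
  cat(sprintf("  %d atoms, %d residues, chains: %s, models: %s\n",
              nrow(a), length(res_key),
              paste(sort(unique(a$chain)), collapse = " "),
              paste(sort(unique(a$model)), collapse = " ")))
  cat(sprintf("  waters: %d, hetero atoms: %d\n",
              sum(a$is_water), sum(a$is_hetero)))
  invisible(x)
}

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Element guess for files lacking the element column: strip digits and
# primes, special-case waters; otherwise the first alphabetic character of
# the atom name (adequate for standard residues, where two-letter elements
# do not occur among heavy atoms).
guess_element <- function(elety, resid) {
  stripped <- gsub("[0-9']", "", trimws(elety))
  el <- substr(stripped, 1, 1)
  el[resid %in% WATER_NAMES] <- "O"
  toupper(el)
}

bio3d_to_atoms <- function(atom_df, model = 1L) {
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  resid <- as.character(atom_df$resid)
  elesy <- blank(atom_df$elesy)
  no_el <- elesy == ""
  elesy[no_el] <- guess_element(atom_df$elety[no_el], resid[no_el])
  data.frame(
    model = as.integer(model),
    chain = blank(atom_df$chain),
    resno = as.integer(atom_df$resno),
    insert = blank(atom_df$insert),
    resid = resid,
    elety = as.character(atom_df$elety),
    alt = blank(atom_df$alt),
    elesy = toupper(elesy),
    x = atom_df$x, y = atom_df$y, z = atom_df$z,
    o = ifelse(is.na(atom_df$o), 1, atom_df$o),
    b = ifelse(is.na(atom_df$b), 0, atom_df$b),
    is_water = resid %in% WATER_NAMES,
    is_hetero = atom_df$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("^_atom_site\\.", head_lines))) {
    return("mmcif")
  }
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", head_lines))) return("pdb")
  stop("cannot determine coordinate format of '", path, "'")
}

#' Read a PDB or mmCIF coordinate file
#'
#' Parsing is delegated to bio3d (`read.pdb`/`read.cif`); the result is
#' normalised into the package's [structure3d] model with author numbering,
#' all alternate locations, and waters retained.
#'
#' @param path Path to a local coordinate file. Accession fetching is out of
#'   band: this package only consumes local files.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (extension, then content
#'   sniffing).
#' @return A [structure3d].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- detect_format(path)
  parsed <- tryCatch(
    switch(format,
      pdb = bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                            multi = TRUE),
      mmcif = suppressWarnings(bio3d::read.cif(path))
    ),
    error = function(e) {
      stop(sprintf("failed to parse '%s' as %s: %s",
                   path, format, conditionMessage(e)), call. = FALSE)
    }
  )
  atoms <- tryCatch({
    n_models <- max(1L, nrow(parsed$xyz))
    per_model <- lapply(seq_len(n_models), function(m) {
      at <- bio3d_to_atoms(parsed$atom, model = m)
      if (n_models > 1L) {
        xyz <- matrix(parsed$xyz[m, ], ncol = 3, byrow = TRUE)
        at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      }
      at
    })
    do.call(rbind, per_model)
  }, error = function(e) {
    stop(sprintf("failed to parse '%s' as %s: malformed atom records (%s)",
                 path, format, conditionMessage(e)), call. = FALSE)
  })
  title <- tryCatch(paste(parsed$header, collapse = " "), error = function(e) "")
  structure3d(atoms,
              id = tools::file_path_sans_ext(basename(path)),
              metadata = list(title = title, source = path, format = format))
}

#' Collapse alternate locations
#'
#' Keeps exactly one location per atom. Under the `highest_occupancy` policy
#' the altloc with the largest occupancy wins; ties are broken by altloc
#' letter order (A before B).
#'
#' @param structure A [structure3d].
#' @param policy Resolution policy (only `"highest_occupancy"` is defined).
#' @return A [structure3d] with `alt` empty everywhere.
#' @export
resolve_altlocs <- function(structure, policy = "highest_occupancy") {
  policy <- match.arg(policy, "highest_occupancy")
  a <- structure$atoms
  if (all(a$alt == "")) return(structure)
  key <- paste(a$model, a$chain, a$resno, a$insert, a$resid, a$elety,
               sep = "\r")
  ord <- order(key, -a$o, a$alt)
  keep_idx <- ord[!duplicated(key[ord])]
  a <- a[sort(keep_idx), , drop = FALSE]
  a$alt <- ""
  structure3d(a, id = structure$id, metadata = structure$metadata)
}

#' Declarative atom selection
#'
#' Builds a reusable filter over chain, residue number range, residue name,
#' atom name, element, and water/hetero flags. All supplied conditions are
#' combined with AND; `NULL`/`NA` conditions are ignored. Selections are
#' idempotent: applying the same selection to an already-selected subset
#' returns it unchanged.
#'
#' @param chain Character vector of chain ids.
#' @param resno Integer vector of author residue numbers (ranges via `a:b`).
#' @param resid Character vector of 3-letter residue names.
#' @param elety Character vector of atom names.
#' @param elesy Character vector of element symbols.
#' @param water `TRUE` to keep only waters, `FALSE` to drop them, `NA` for
#'   either.
#' @param hetero As `water`, for HETATM records.
#' @return An object of class `selection`.
#' @export
selection <- function(chain = NULL, resno = NULL, resid = NULL, elety = NULL,
                      elesy = NULL, water = NA, hetero = NA) {
  stopifnot(is.logical(water), is.logical(hetero),
            length(water) == 1L, length(hetero) == 1L)
  obj <- list(chain = chain, resno = resno, resid = resid, elety = elety,
              elesy = elesy, water = water, hetero = hetero)
  class(obj) <- "selection"
  obj
}

#' @export
print.selection <- function(x, ...) {
  shown <- Filter(function(v) !is.null(v) && !all(is.na(v)), unclass(x))
  if (length(shown) == 0) {
    cat("<selection> (all atoms)\n")
  } else {
    cat("<selection>",
        paste(names(shown),
              vapply(shown, function(v) paste(v, collapse = ","), ""),
              sep = "=", collapse = " and "), "\n")
  }
  invisible(x)
}

selection_mask <- function(atoms, sel) {
  if (!inherits(sel, "selection")) stop("malformed selection expression")
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & atoms$resno %in% sel$resno
  if (!is.null(sel$resid)) keep <- keep & atoms$resid %in% sel$resid
  if (!is.null(sel$elety)) keep <- keep & atoms$elety %in% sel$elety
  if (!is.null(sel$elesy)) keep <- keep & atoms$elesy %in% toupper(sel$elesy)
  if (!is.na(sel$water)) keep <- keep & (atoms$is_water == sel$water)
  if (!is.na(sel$hetero)) keep <- keep & (atoms$is_hetero == sel$hetero)
  keep
}

#' Select atoms
#'
#' @param structure A [structure3d].
#' @param sel A [selection].
#' @return The matching atom rows (with residue context columns), in file
#'   order; possibly zero rows.
#' @export
select_atoms <- function(structure, sel = selection()) {
  structure$atoms[selection_mask(structure$atoms, sel), , drop = FALSE]
}

#' Subset a structure by a selection
#'
#' @inheritParams select_atoms
#' @return A [structure3d] containing only the matching atoms.
#' @export
subset_structure <- function(structure, sel) {
  atoms <- select_atoms(structure, sel)
  if (nrow(atoms) == 0L) stop("selection matches no atoms")
  structure3d(atoms, id = structure$id, metadata = structure$metadata)
}

#' Atom coordinates as a matrix
#'
#' @param structure A [structure3d] or an atom data.frame.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
atom_xyz <- function(structure) {
  a <- if (inherits(structure, "structure3d")) structure$atoms else structure
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

format_cif_num <- function(x) sprintf("%.6f", x)

write_mmcif <- function(structure, path) {
  a <- structure$atoms
  esd <- function(v, blank = ".") ifelse(v == "" | is.na(v), blank, v)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure$id)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    paste(
      ifelse(a$is_hetero, "HETATM", "ATOM"),
      seq_len(nrow(a)),
      esd(a$elesy, "?"),
      a$elety,
      esd(a$alt),
      a$resid,
      esd(a$chain),
      "1",
      a$resno,
      esd(a$insert, "?"),
      format_cif_num(a$x), format_cif_num(a$y), format_cif_num(a$z),
      sprintf("%.2f", a$o), sprintf("%.2f", a$b),
      "?",
      a$resno, a$resid, esd(a$chain), a$elety,
      a$model
    ),
    "#"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output preserves coordinates to 3 decimals (the format's fixed-width
#' limit); mmCIF output carries 6 decimals. Structures with more than 99999
#' atoms cannot be serialised to PDB (fixed 5-column serial field) and raise
#' an error; use mmCIF for such models.
#'
#' @param structure A [structure3d].
#' @param path Output path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- structure$atoms
  if (format == "mmcif") return(write_mmcif(structure, path))
  if (nrow(a) > 99999L) {
    stop("PDB serial field overflows beyond 99999 atoms; write mmCIF instead")
  }
  if (length(unique(a$model)) > 1L) {
    stop("multi-model PDB writing is not supported; write one model or mmCIF")
  }
  xyz <- as.numeric(t(atom_xyz(a)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", "", a$insert),
    alt = ifelse(a$alt == "", "", a$alt),
    o = a$o, b = a$b, elesy = a$elesy
  )
  invisible(path)
}

# Residue table: one row per residue with context, in file order.
residue_table <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  key <- paste(a$model, a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(model = a$model[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], is_water = a$is_water[first],
             stringsAsFactors = FALSE)
}

# Coordinates of one named atom of one residue (first altloc wins if
# unresolved); NULL if absent.
residue_atom_xyz <- function(structure, chain, resno, elety, insert = "") {
  a <- structure$atoms
  hit <- which(a$chain == chain & a$resno == resno & a$insert == insert &
                 a$elety == elety)
  if (length(hit) == 0L) return(NULL)
  as.numeric(a[hit[1], c("x", "y", "z")])
}
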