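#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records from PDB-format text into a tidy atom table.
#' Multi-model files are split on MODEL/ENDMDL records and a single model is
#' returned. Alternate locations are resolved to the highest-occupancy copy
#' (ties keep the first record in file order) and HETATM residues are dropped
#' unless whitelisted by residue name.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text.
#' @param model_index 1-based index of the model to return. Files without
#'   MODEL records have exactly one model.
#' @param id Identifier stored on the returned structure.
#' @param source Provenance tag (file path or a synthetic tag).
#' @param hetatm_keep Character vector of HETATM residue names to retain
#'   (default none: waters, ligands and ions are excluded).
#'
#' @return A `phs_structure`: a list with `id`, `source` and `atoms`, a tibble
#'   with one row per retained atom and columns `chain`, `resnum`, `icode`,
#'   `resname`, `atom`, `x`, `y`, `z`, `occupancy`, `element`, `record`.
#'   Residue identity is (`chain`, `resnum`, `icode`).
#' @export
#' @examples
#' pdb <- make_pair("ASP", "LYS", 4)
#' s <- parse_structure(pdb)
#' s$atoms
parse_structure <- function(pdb_text, model_index = 1L, id = "structure",
                            source = "text", hetatm_keep = character()) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  models <- split_models(lines)
  if (model_index < 1L || model_index > length(models)) {
    abort(sprintf("model %d not present; available models: %s",
                  model_index, paste(seq_along(models), collapse = ", ")))
  }
  block <- models[[model_index]]
  if (!any(grepl("^ATOM", block))) {
    abort("no ATOM records found in the requested model")
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(block, tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)

  at <- tibble(
    record    = pdb$atom$type,
    atom      = pdb$atom$elety,
    altloc    = pdb$atom$alt %||% NA_character_,
    resname   = pdb$atom$resid,
    chain     = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    resnum    = as.integer(pdb$atom$resno),
    icode     = ifelse(is.na(pdb$atom$insert), "", pdb$atom$insert),
    x         = pdb$atom$x,
    y         = pdb$atom$y,
    z         = pdb$atom$z,
    occupancy = ifelse(is.na(pdb$atom$o), 1, pdb$atom$o),
    element   = pdb$atom$elesy %||% NA_character_
  )
  at$element <- ifelse(is.na(at$element) | at$element == "",
                       toupper(substr(gsub("[0-9]", "", at$atom), 1, 1)),
                       toupper(at$element))

  at <- at[at$record == "ATOM" | at$resname %in% hetatm_keep, , drop = FALSE]
  if (nrow(at) == 0L) abort("no ATOM records found in the requested model")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    abort("non-finite coordinates in ATOM records")
  }

  # altloc resolution: keep highest occupancy per (residue, atom name);
  # ties resolved to the first record in file order (stable sort).
  at$.ord <- seq_len(nrow(at))
  at <- dplyr::arrange(at, .data$chain, .data$resnum, .data$icode, .data$atom,
                       dplyr::desc(.data$occupancy), .data$.ord)
  at <- dplyr::distinct(at, .data$chain, .data$resnum, .data$icode, .data$atom,
                        .keep_all = TRUE)
  at <- dplyr::arrange(at, .data$.ord)
  at$.ord <- NULL
  at$altloc <- NULL

  structure(list(id = id, source = source, atoms = at),
            class = "phs_structure")
}

# Split PDB lines into per-model blocks of ATOM/HETATM/TER records.
split_models <- function(lines) {
  starts <- grep("^MODEL ", lines)
  keep <- function(x) x[grepl("^(ATOM|HETATM|TER)", x)]
  if (length(starts) == 0L) return(list(keep(lines)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) keep(lines[starts[i]:ends[i]]))
}

#' Read a structure from a PDB file
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_structure
#' @return A [parse_structure()] `phs_structure`.
#' @export
read_structure <- function(path, model_index = 1L, hetatm_keep = character()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  parse_structure(readLines(path, warn = FALSE), model_index = model_index,
                  id = sub("\\.[^.]*$", "", basename(path)), source = path,
                  hetatm_keep = hetatm_keep)
}

#' @export
print.phs_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<phs_structure> %s (%s)\n", x$id, x$source))
  cat(sprintf("  %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(res),
              paste(unique(res$chain), collapse = " ")))
  invisible(x)
}

#' One row per residue of a structure
#'
#' @param s A `phs_structure`.
#' @return Tibble with `chain`, `resnum`, `icode`, `resname`, in file order.
#' @export
residue_table <- function(s) {
  dplyr::distinct(s$atoms, .data$chain, .data$resnum, .data$icode,
                  .data$resname)
}

#' Extract the one-letter sequence of a chain
#'
#' @param s A `phs_structure`.
#' @param chain Chain identifier; defaults to the first chain present.
#' @return Character scalar; non-standard residues become `X`.
#' @export
structure_sequence <- function(s, chain = NULL) {
  res <- residue_table(s)
  chain <- chain %||% res$chain[1]
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) abort(sprintf("chain '%s' not present", chain))
  aa <- bio3d::aa321(res$resname)
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Count residues used for per-amino-acid normalisation
#'
#' Residues with a CA atom in the analysed chains; stability and charge
#' profiles are divided by this count.
#'
#' @param s A `phs_structure`.
#' @param chains Optional chain subset.
#' @return Integer count.
#' @export
n_residues <- function(s, chains = NULL) {
  at <- s$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  ca <- at[at$atom == "CA", , drop = FALSE]
  nrow(dplyr::distinct(ca, .data$chain, .data$resnum, .data$icode))
}

#' Serialise a structure back to PDB-format text
#'
#' @param s A `phs_structure`.
#' @return Character vector of PDB lines (ATOM records plus END).
#' @export
write_pdb_text <- function(s) {
  at <- s$atoms
  fmt_atom_lines(
    serial = seq_len(nrow(at)), atom = at$atom, resname = at$resname,
    chain = at$chain, resnum = at$resnum, icode = at$icode,
    x = at$x, y = at$y, z = at$z, occupancy = at$occupancy,
    element = at$element
  )
}

# Fixed-width PDB ATOM record formatter (also used by the synthetic
# generator). Atom names of <= 3 characters start in column 14.
fmt_atom_lines <- function(serial, atom, resname, chain, resnum, icode,
                           x, y, z, occupancy = 1, element = NULL) {
  element <- element %||% toupper(substr(gsub("[0-9]", "", atom), 1, 1))
  name_fmt <- ifelse(nchar(atom) >= 4, sprintf("%-4s", atom),
                     sprintf(" %-3s", atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name_fmt, resname, chain, resnum,
    ifelse(icode == "", " ", icode), x, y, z, occupancy, 0, element
  )
  c(lines, "END")
}
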