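# Protein structures as tidy atom tables.
#
# A `protein_structure` is a tibble with one row per retained atom and the
# columns res_id (1-based residue position, the only index featurization is
# allowed to see), chain, resnum, icode, res_type, atom, element, x, y, z.
# Author residue numbers (resnum) are carried for reporting only: no feature
# anywhere may depend on them, which is what makes the method applicable to
# structures whose sequence connectivity is unknown.

AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_protein_structure <- function(df, mode, source = "unknown") {
  out <- tibble::as_tibble(df)
  structure(out,
    mode = mode, source = source,
    class = c("protein_structure", class(out))
  )
}

#' Construct a protein structure from an atom table
#'
#' @param df Data frame with columns `chain`, `resnum`, `res_type`, `atom`,
#'   `x`, `y`, `z` (optional `icode`, `element`). Rows are atoms; residue
#'   order follows first appearance.
#' @param mode `"backbone"` (heavy backbone atoms N, CA, C, O) or `"ca"`
#'   (C-alpha trace).
#' @param source Provenance string.
#' @return A `protein_structure` tibble.
#' @export
as_protein_structure <- function(df, mode = c("backbone", "ca"), source = "data.frame") {
  mode <- match.arg(mode)
  df <- tibble::as_tibble(df)
  needed <- c("chain", "resnum", "res_type", "atom", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) stop_validation("structure must contain at least one atom")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop_validation("atom coordinates must be finite")
  }
  if (!"icode" %in% names(df)) df$icode <- ""
  if (!"element" %in% names(df)) df$element <- substr(df$atom, 1, 1)
  df$res_type <- ifelse(df$res_type %in% AA3, df$res_type, "UNK")
  key <- paste(df$chain, df$resnum, df$icode, sep = "\r")
  df$res_id <- match(key, unique(key))
  keep_atoms <- if (mode == "ca") "CA" else BACKBONE_ATOMS
  df <- df[df$atom %in% keep_atoms, , drop = FALSE]
  if (nrow(df) == 0) stop_format("no atoms of the requested mode present")
  if (anyDuplicated(df[c("res_id", "atom")]) > 0) {
    stop_validation("duplicate atom name within a residue (resolve alternate locations first)")
  }
  has_ca <- unique(df$res_id[df$atom == "CA"])
  dropped <- setdiff(unique(df$res_id), has_ca)
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d residue(s) without a CA atom", length(dropped)))
    df <- df[df$res_id %in% has_ca, , drop = FALSE]
  }
  if (nrow(df) == 0) stop_format("no residues with CA atoms")
  df$res_id <- match(df$res_id, sort(unique(df$res_id)))
  df <- df[order(df$res_id), , drop = FALSE]
  new_protein_structure(
    df[c("res_id", "chain", "resnum", "icode", "res_type", "atom", "element", "x", "y", "z")],
    mode = mode, source = source
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (via bio3d), keeps heavy backbone atoms (`mode =
#' "backbone"`) or C-alpha atoms only (`mode = "ca"`), resolves alternate
#' locations by highest occupancy (ties by altloc character order), and
#' drops residues lacking a CA atom with a warning. One residue is created
#' per distinct (chain, residue number, insertion code).
#'
#' @param path Path to a PDB-format text file.
#' @param mode `"backbone"` or `"ca"`.
#' @return A `protein_structure` tibble.
#' @export
read_structure <- function(path, mode = c("backbone", "ca")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': file does not exist", path), class = "geosec_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop_format(sprintf("'%s' is not parseable as PDB: %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop_format(sprintf("'%s' contains no ATOM records", path))
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$chain <- ifelse(is.na(at$chain), "A", at$chain)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  # alternate locations: highest occupancy wins, ties by altloc order
  at <- at[order(at$chain, at$resno, at$insert, at$elety, -at$o, at$alt), , drop = FALSE]
  dup <- duplicated(at[c("chain", "resno", "insert", "elety")])
  at <- at[!dup, , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  as_protein_structure(
    tibble::tibble(
      chain = at$chain, resnum = at$resno, icode = at$insert,
      res_type = at$resid, atom = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "", substr(at$elety, 1, 1), at$elesy),
      x = at$x, y = at$y, z = at$z
    ),
    mode = mode, source = path
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf(
    "# protein_structure: %d residues, %d atoms, mode = %s\n",
    n_residues(x), nrow(x), structure_mode(x)
  ))
  NextMethod()
}

#' Number of residues of a structure
#' @param s A `protein_structure`.
#' @return Integer count.
#' @export
n_residues <- function(s) {
  if (nrow(s) == 0) return(0L)
  max(s$res_id)
}

#' Featurization mode of a structure ("backbone" or "ca")
#' @param s A `protein_structure`.
#' @return Character scalar.
#' @export
structure_mode <- function(s) attr(s, "mode") %||% "backbone"

#' One-row-per-residue summary of a structure
#'
#' @param s A `protein_structure`.
#' @return Tibble with `res_id`, `chain`, `resnum`, `icode`, `res_type`,
#'   `n_atoms` and `complete_backbone` (has N, CA and C).
#' @export
residue_table <- function(s) {
  df <- tibble::as_tibble(s)
  df |>
    dplyr::group_by(.data$res_id) |>
    dplyr::summarise(
      chain = dplyr::first(.data$chain),
      resnum = dplyr::first(.data$resnum),
      icode = dplyr::first(.data$icode),
      res_type = dplyr::first(.data$res_type),
      n_atoms = dplyr::n(),
      complete_backbone = all(c("N", "CA", "C") %in% .data$atom),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$res_id)
}

# List (length n_residues) of coordinate matrices, rownames = atom names.
residue_coords <- function(s) {
  n <- n_residues(s)
  xyz <- cbind(s$x, s$y, s$z)
  out <- vector("list", n)
  idx <- split(seq_len(nrow(s)), s$res_id)
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    m <- xyz[rows, , drop = FALSE]
    rownames(m) <- s$atom[rows]
    out[[as.integer(names(idx)[i])]] <- m
  }
  out
}

# n x 3 matrix of CA coordinates (NA rows impossible after read, kept safe).
ca_matrix <- function(s) {
  n <- n_residues(s)
  m <- matrix(NA_real_, n, 3)
  ca <- s[s$atom == "CA", , drop = FALSE]
  m[ca$res_id, ] <- cbind(ca$x, ca$y, ca$z)
  m
}
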