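# Secondary-structure labels.
#
# Reference labels use the eight DSSP states (H, G, I, E, B, T, S, -) and
# are collapsed into one of four classification schemes:
#   alpha-other      H -> 1, else 0
#   beta-other       E -> 1, else 0
#   alpha-beta-other H -> 0, E -> 1, else 2
#   all8             H,G,I,E,B,T,S,- -> 0..7
# The collapse rule for the reduced schemes (3-10/pi helices and isolated
# bridges count as Other) is configurable via `alpha_letters`/`beta_letters`.

DSSP_LETTERS <- c("H", "G", "I", "E", "B", "T", "S", "-")

SCHEMES <- c("alpha-other", "beta-other", "alpha-beta-other", "all8")

#' Number of classes of a labelling scheme
#' @param scheme One of `"alpha-other"`, `"beta-other"`, `"alpha-beta-other"`, `"all8"`.
#' @return Integer class count (2, 2, 3 or 8).
#' @export
n_classes <- function(scheme) {
  scheme <- match.arg(scheme, SCHEMES)
  switch(scheme, "alpha-other" = 2L, "beta-other" = 2L, "alpha-beta-other" = 3L, "all8" = 8L)
}

# Class ids of the alpha and beta classes under each scheme (NA = scheme has
# no such class); the remaining id(s) are "Other".
element_class_ids <- function(scheme) {
  scheme <- match.arg(scheme, SCHEMES)
  switch(scheme,
    "alpha-other" = c(alpha = 1L, beta = NA_integer_),
    "beta-other" = c(alpha = NA_integer_, beta = 1L),
    "alpha-beta-other" = c(alpha = 0L, beta = 1L),
    "all8" = c(alpha = 0L, beta = 3L)
  )
}

other_class_id <- function(scheme) {
  scheme <- match.arg(scheme, SCHEMES)
  switch(scheme, "alpha-other" = 0L, "beta-other" = 0L, "alpha-beta-other" = 2L, "all8" = 7L)
}

new_ss_labels <- function(df, scheme) {
  out <- tibble::as_tibble(df)
  structure(out, scheme = scheme, class = c("ss_labels", class(out)))
}

#' Labelling scheme of an `ss_labels` object
#' @param labels An `ss_labels` tibble.
#' @return Character scalar.
#' @export
label_scheme <- function(labels) attr(labels, "scheme")

#' Read per-residue labels from a DSSP output file
#'
#' Parses the classic fixed-width DSSP text output. Returns one row per
#' residue in file order with the 8-state letter (blank structure column is
#' reported as `"-"`). Chain-break rows (`!` in the amino-acid column) are
#' skipped.
#'
#' @param path Path to a DSSP output file.
#' @return Tibble with columns `chain`, `resnum`, `icode`, `letter`.
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': file does not exist", path), class = "geosec_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) {
    stop_format(sprintf("'%s' lacks the DSSP residue header line", path))
  }
  body <- lines[seq.int(hdr[1] + 1, length.out = max(0, length(lines) - hdr[1]))]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  if (length(body) == 0) stop_format(sprintf("'%s' contains no residue rows", path))
  letter <- substr(body, 17, 17)
  letter[letter == " "] <- "-"
  bad <- setdiff(unique(letter), DSSP_LETTERS)
  if (length(bad) > 0) {
    stop_format(paste0("unknown DSSP state letter(s): ", paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    chain = trimws(substr(body, 12, 12)),
    resnum = as.integer(substr(body, 6, 10)),
    icode = trimws(substr(body, 11, 11)),
    letter = letter
  )
}

#' Collapse 8-state letters into a classification scheme
#'
#' @param letters Character vector of DSSP letters, or a data frame with a
#'   `letter` column (e.g. the output of [read_dssp()]).
#' @param scheme Target scheme.
#' @param alpha_letters,beta_letters Which DSSP letters count as helix /
#'   strand in the reduced schemes (defaults: `"H"` and `"E"` only).
#' @return An `ss_labels` tibble with columns of the input plus `class_id`,
#'   carrying the scheme as an attribute.
#' @examples
#' map_labels(c("H", "H", "-", "E"), scheme = "alpha-beta-other")$class_id # 0 0 2 1
#' @export
map_labels <- function(letters, scheme = c("alpha-beta-other", "alpha-other", "beta-other", "all8"),
                       alpha_letters = "H", beta_letters = "E") {
  scheme <- match.arg(scheme)
  df <- if (is.data.frame(letters)) {
    tibble::as_tibble(letters)
  } else {
    tibble::tibble(letter = as.character(letters))
  }
  if (!"letter" %in% names(df)) stop_validation("`letters` must supply a `letter` column")
  bad <- setdiff(unique(df$letter), DSSP_LETTERS)
  if (length(bad) > 0) {
    stop_validation(paste0("unknown secondary-structure letter(s): ", paste(bad, collapse = ", ")))
  }
  df$class_id <- switch(scheme,
    "alpha-other" = ifelse(df$letter %in% alpha_letters, 1L, 0L),
    "beta-other" = ifelse(df$letter %in% beta_letters, 1L, 0L),
    "alpha-beta-other" = ifelse(df$letter %in% alpha_letters, 0L,
      ifelse(df$letter %in% beta_letters, 1L, 2L)
    ),
    "all8" = match(df$letter, DSSP_LETTERS) - 1L
  )
  if (!"res_id" %in% names(df)) df$res_id <- seq_len(nrow(df))
  new_ss_labels(df, scheme = scheme)
}

#' Write labels as a TSV file
#'
#' Columns: chain, resnum, letter, class_id (chain/resnum filled with
#' placeholders when absent).
#'
#' @param labels An `ss_labels` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- tibble::as_tibble(labels)
  if (!"chain" %in% names(df)) df$chain <- "A"
  if (!"resnum" %in% names(df)) df$resnum <- df$res_id
  if (!"letter" %in% names(df)) df$letter <- NA_character_
  utils::write.table(
    df[c("chain", "resnum", "letter", "class_id")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Align DSSP labels to the residues of a structure
#'
#' Inner-joins on (chain, residue number, insertion code) and orders by the
#' structure's residue index, so labels line up with graph nodes.
#'
#' @param s A `protein_structure`.
#' @param dssp Output of [read_dssp()] (or any data frame with `chain`,
#'   `resnum`, `icode`, `letter`).
#' @return Tibble with `res_id` and `letter`, one row per matched residue.
#' @export
align_labels <- function(s, dssp) {
  rt <- residue_table(s)
  dssp <- tibble::as_tibble(dssp)
  if (!"icode" %in% names(dssp)) dssp$icode <- ""
  joined <- dplyr::inner_join(
    rt[c("res_id", "chain", "resnum", "icode")],
    dssp[c("chain", "resnum", "icode", "letter")],
    by = c("chain", "resnum", "icode")
  )
  dplyr::arrange(joined, .data$res_id)[c("res_id", "letter")]
}
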