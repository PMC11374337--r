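#' Assigned chemical shift tables
#'
#' A shift table holds the assigned resonances observed at one titration
#' point: one row per (residue, atom) with the chemical shift in ppm.
#' Amide atoms are labelled `H` and `N`; the aromatic histidine carbons
#' used for zinc-coordination analysis are `CD2` and `CE1` (PDB naming).
#'
#' @param residue_number integer residue numbers (1-based, carried
#'   verbatim from the input; renumbering is always explicit via an
#'   `offset` argument elsewhere).
#' @param residue_type one- or three-letter amino-acid codes.
#' @param atom atom labels, a subset of [supported_atoms()].
#' @param shift_ppm chemical shifts in ppm; must be finite.
#' @param point_label short label for the titration point this table
#'   belongs to (e.g. `"L0"`).
#' @return A `shift_table`: a data.frame with columns `residue_number`,
#'   `residue_type`, `atom`, `shift_ppm` and attribute `point_label`.
#' @examples
#' shift_table(c(782, 782), c("N", "N"), c("H", "N"), c(8.21, 119.4))
#' @export
shift_table <- function(residue_number, residue_type, atom, shift_ppm,
                        point_label = "") {
  df <- data.frame(
    residue_number = as.integer(residue_number),
    residue_type = as.character(residue_type),
    atom = as.character(atom),
    shift_ppm = as.numeric(shift_ppm),
    stringsAsFactors = FALSE
  )
  validate_shift_table(df)
  attr(df, "point_label") <- as.character(point_label)
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Atom labels a shift table may contain
#'
#' @return Character vector of supported atom labels.
#' @export
supported_atoms <- function() c("H", "N", "CD2", "CE1")

validate_shift_table <- function(df) {
  required <- c("residue_number", "residue_type", "atom", "shift_ppm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("shift table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$shift_ppm))) {
    stop("shift table contains non-finite shift values", call. = FALSE)
  }
  bad <- setdiff(unique(df$atom), supported_atoms())
  if (length(bad) > 0) {
    stop("unsupported atom label(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(supported_atoms(), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$residue_number, df$atom)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (residue_number, atom) entry: ", dup, call. = FALSE)
  }
  invisible(df)
}

#' Read a shift table from CSV or TSV
#'
#' The file must carry a header with columns `residue_number`,
#' `residue_type`, `atom` and `shift_ppm`. Rows with non-finite or
#' unparseable shifts are rejected with an error; absence of a residue
#' is data (exchange-broadened or proline amides simply do not appear),
#' not an error.
#'
#' @param path path to the file.
#' @param dialect `"csv"` (comma, default) or `"tsv"` (tab).
#' @param point_label optional label; defaults to the file name.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, dialect = c("csv", "tsv"),
                             point_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("residue_number", "residue_type", "atom", "shift_ppm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(point_label)) point_label <- basename(path)
  shift_table(df$residue_number, df$residue_type, df$atom,
              as.numeric(df$shift_ppm), point_label = point_label)
}

#' Write a shift table to CSV or TSV
#'
#' Inverse of [read_shift_table()]; write-then-read is the identity on
#' valid tables.
#'
#' @param x a [shift_table()].
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_shift_table(x)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(as.data.frame(x)[, c("residue_number", "residue_type",
                                          "atom", "shift_ppm")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> %d records, %d residues, point '%s'\n",
              nrow(x), length(unique(x$residue_number)),
              attr(x, "point_label")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
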