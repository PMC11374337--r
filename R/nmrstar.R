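#' Read assigned chemical shifts from an NMR-STAR v3 file
#'
#' Extracts the assigned-chemical-shift loop (`_Atom_chem_shift.*` tags,
#' the dialect used by BMRB depositions) into a [shift_table()]. By
#' default only backbone amide `H` and `N` rows are kept; histidine mode
#' keeps the aromatic `CD2`/`CE1` carbons instead, which feed the
#' zinc-coordination classifier.
#'
#' Rows whose shift value does not parse as a number are skipped with a
#' warning and counted in the parse report (attribute `parse_report`,
#' a list with `n_skipped` and the offending lines), so nothing is
#' dropped silently.
#'
#' @param path path to an NMR-STAR v3 file containing an
#'   `_Atom_chem_shift` loop.
#' @param atoms atom labels to retain; default amide `c("H", "N")`.
#'   Use `c("CD2", "CE1")` (or `histidine_mode = TRUE`) for the
#'   histidine carbon extraction.
#' @param histidine_mode if `TRUE`, shorthand for
#'   `atoms = c("CD2", "CE1")` restricted to histidine residues.
#' @param point_label label for the resulting table.
#' @return A [shift_table()] with attribute `parse_report`.
#' @export
read_nmrstar_shifts <- function(path, atoms = c("H", "N"),
                                histidine_mode = FALSE,
                                point_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (histidine_mode) atoms <- c("CD2", "CE1")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)

  # locate the loop whose tag block contains _Atom_chem_shift.* tags
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  if (length(loop_starts) == 0) {
    stop("no loop_ found in ", path, call. = FALSE)
  }
  tags <- character(0)
  data_lines <- character(0)
  found <- FALSE
  for (ls in loop_starts) {
    i <- ls + 1
    cur_tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      cur_tags <- c(cur_tags, trimws(lines[i]))
      i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", cur_tags))) next
    found <- TRUE
    tags <- cur_tags
    while (i <= length(lines) && !grepl("^\\s*(stop_|loop_)\\s*$", lines[i])) {
      if (nzchar(trimws(lines[i]))) data_lines <- c(data_lines, lines[i])
      i <- i + 1
    }
    break
  }
  if (!found) {
    stop("no _Atom_chem_shift loop in ", path, call. = FALSE)
  }

  need <- c("_Atom_chem_shift.Seq_ID", "_Atom_chem_shift.Comp_ID",
            "_Atom_chem_shift.Atom_ID", "_Atom_chem_shift.Val")
  idx <- match(need, tags)
  if (anyNA(idx)) {
    stop("shift loop lacks tag(s): ",
         paste(need[is.na(idx)], collapse = ", "), call. = FALSE)
  }

  toks <- lapply(data_lines, function(l) {
    scan(text = l, what = character(), quiet = TRUE)
  })
  n_skipped <- 0L
  skipped <- character(0)
  rec <- list(res = integer(0), type = character(0),
              atom = character(0), val = numeric(0))
  for (k in seq_along(toks)) {
    tk <- toks[[k]]
    if (length(tk) < length(tags)) next
    seq_id <- suppressWarnings(as.integer(tk[idx[1]]))
    val <- suppressWarnings(as.numeric(tk[idx[4]]))
    atom <- tk[idx[3]]
    if (!(atom %in% atoms)) next
    if (is.na(seq_id) || is.na(val)) {
      n_skipped <- n_skipped + 1L
      skipped <- c(skipped, data_lines[k])
      next
    }
    rec$res <- c(rec$res, seq_id)
    rec$type <- c(rec$type, tk[idx[2]])
    rec$atom <- c(rec$atom, atom)
    rec$val <- c(rec$val, val)
  }
  if (histidine_mode) {
    keep <- toupper(rec$type) %in% c("HIS", "H")
    rec <- lapply(rec, `[`, keep)
  }
  if (n_skipped > 0) {
    warning(n_skipped, " shift row(s) skipped (unparseable value)",
            call. = FALSE)
  }
  if (is.null(point_label)) point_label <- basename(path)
  st <- shift_table(rec$res, rec$type, rec$atom, rec$val,
                    point_label = point_label)
  attr(st, "parse_report") <- list(n_skipped = n_skipped,
                                   skipped_lines = skipped)
  st
}
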