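#' Write per-residue scores into the B-factor column of a PDB model
#'
#' Standard trick for surface colouring in PyMOL/ChimeraX: each scored
#' residue's atoms get the score as their B-factor, every other residue
#' gets a sentinel. `offset` translates shift-table numbering into the
#' model's numbering (`model residue = shift residue + offset`), because
#' construct-local and full-length numbering frequently disagree.
#'
#' @param pdb a `bio3d` pdb object (from [bio3d::read.pdb()]) or a path
#'   to a PDB file.
#' @param scores named numeric vector; names are residue numbers in
#'   shift-table numbering.
#' @param path output PDB path.
#' @param offset integer added to score residue numbers to reach model
#'   numbering. Default 0.
#' @param sentinel B-factor for unscored residues. Default 0.
#' @return `path` invisibly, with attribute `skipped`: residue numbers
#'   (shift numbering) that mapped outside the model.
#' @export
write_structure_with_scores <- function(pdb, scores, path, offset = 0L,
                                        sentinel = 0) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  if (!inherits(pdb, "pdb")) stop("pdb must be a bio3d pdb object or path",
                                  call. = FALSE)
  if (length(scores) > 0 && is.null(names(scores))) {
    stop("scores must be named by residue number", call. = FALSE)
  }
  model_res <- unique(pdb$atom$resno)
  new_b <- rep(sentinel, nrow(pdb$atom))
  skipped <- integer(0)
  for (nm in names(scores)) {
    target <- as.integer(nm) + as.integer(offset)
    hit <- pdb$atom$resno == target
    if (!any(hit)) {
      skipped <- c(skipped, as.integer(nm))
      next
    }
    new_b[hit] <- scores[[nm]]
  }
  if (length(skipped) > 0) {
    warning("score residue(s) outside the model after offset ", offset,
            ": ", paste(skipped, collapse = ", "), call. = FALSE)
  }
  pdb$atom$b <- new_b
  bio3d::write.pdb(pdb, file = path, b = new_b)
  out <- invisible(path)
  attr(out, "skipped") <- skipped
  invisible(out)
}

#' Check numbering consistency between a shift table and a structure
#'
#' Compares residue types at shared positions after applying `offset`.
#' A wrong offset almost always makes the amino-acid types disagree, so
#' this is the cheap guard against silently mis-mapped interfaces.
#'
#' @param st a [shift_table()] (or data.frame with `residue_number`,
#'   `residue_type`).
#' @param pdb bio3d pdb object or path.
#' @param offset candidate offset (model = shift + offset).
#' @return list with `n_compared`, `n_mismatch`, `mismatches`
#'   (data.frame) and `consistent` (TRUE when no mismatches).
#' @export
check_numbering_consistency <- function(st, pdb, offset = 0L) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  ca <- pdb$atom[pdb$atom$elety == "CA", c("resno", "resid")]
  ca <- ca[!duplicated(ca$resno), ]
  sres <- unique(st[, c("residue_number", "residue_type")])
  sres$model_resno <- sres$residue_number + as.integer(offset)
  m <- merge(sres, ca, by.x = "model_resno", by.y = "resno")
  if (nrow(m) == 0) {
    return(list(n_compared = 0L, n_mismatch = 0L,
                mismatches = m, consistent = FALSE))
  }
  same <- toupper(aa_three(m$residue_type)) == toupper(m$resid)
  list(n_compared = nrow(m),
       n_mismatch = sum(!same),
       mismatches = m[!same, , drop = FALSE],
       consistent = all(same))
}

# one- -> three-letter amino acid code (three-letter input passes through)
aa_three <- function(x) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  x <- as.character(x)
  out <- ifelse(nchar(x) == 1, tab[toupper(x)], toupper(x))
  unname(out)
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file.
#' @param which index or name of the record to return (default first).
#' @return single character string of one-letter residue codes.
#' @export
read_fasta_seq <- function(path, which = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(recs) == 0) stop("no sequences in ", path, call. = FALSE)
  toupper(as.character(recs[[which]]))
}
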