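#' Classify interface residues by mean + n s.d. CSP tiers
#'
#' The classical interface-mapping rule: compute mean and sample s.d.
#' of the endpoint CSPs over all residues with a defined value
#' (responders and non-responders alike, no outlier trimming), then
#' assign each residue the highest tier whose threshold its CSP
#' *strictly* exceeds: `ge1sd` (> mean + 1 s.d.), `ge2sd`, `ge3sd`,
#' else `none`. Ties fall to the lower tier, and tiers are nested by
#' construction.
#'
#' @param csps named numeric vector of endpoint CSPs (ppm), named by
#'   residue number; needs >= 2 defined values (s.d. undefined below
#'   that).
#' @return An `interface_classification` list: `mean_csp`, `sd_csp`,
#'   `thresholds` (named, 1/2/3 s.d.), `tiers` data.frame
#'   (`residue_number`, `csp_ppm`, `tier`), `residues_considered`.
#' @examples
#' classify_by_sd(c(`1` = 0, `2` = 0, `3` = 0.5))
#' @export
classify_by_sd <- function(csps) {
  csps <- csps[is.finite(csps)]
  if (length(csps) < 2) {
    stop("need >= 2 residues with defined endpoint CSPs", call. = FALSE)
  }
  if (is.null(names(csps))) {
    stop("csps must be named by residue number", call. = FALSE)
  }
  m <- mean(csps)
  s <- stats::sd(csps)
  thr <- m + c(ge1sd = 1, ge2sd = 2, ge3sd = 3) * s
  tier <- rep("none", length(csps))
  tier[csps > thr["ge1sd"]] <- "ge1sd"
  tier[csps > thr["ge2sd"]] <- "ge2sd"
  tier[csps > thr["ge3sd"]] <- "ge3sd"
  out <- list(
    mean_csp = m,
    sd_csp = s,
    thresholds = thr,
    tiers = data.frame(residue_number = as.integer(names(csps)),
                       csp_ppm = unname(csps),
                       tier = factor(tier, levels = c("none", "ge1sd",
                                                      "ge2sd", "ge3sd")),
                       stringsAsFactors = FALSE),
    residues_considered = as.integer(names(csps))
  )
  class(out) <- "interface_classification"
  out
}

#' @export
print.interface_classification <- function(x, ...) {
  n <- table(x$tiers$tier)
  cat(sprintf(
    "<interface_classification> %d residues; mean %.4g ppm, sd %.4g ppm\n",
    nrow(x$tiers), x$mean_csp, x$sd_csp))
  cat(sprintf("  tiers: none %d | >1sd %d | >2sd %d | >3sd %d\n",
              n["none"], n["ge1sd"], n["ge2sd"], n["ge3sd"]))
  invisible(x)
}

#' Write an interface classification to CSV
#'
#' @param classification an `interface_classification`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  utils::write.csv(classification$tiers, path, row.names = FALSE)
  invisible(path)
}

#' Map an interface classification onto a structure
#'
#' Writes numeric tier codes (none = 0, >1 s.d. = 1, >2 s.d. = 2,
#' >3 s.d. = 3) into the B-factor column of a PDB model via
#' [write_structure_with_scores()], for surface colouring. Residue
#' types at shared positions are compared first
#' ([check_numbering_consistency()]) so a wrong `offset` fails loudly
#' instead of colouring the wrong patch.
#'
#' @param classification an `interface_classification`.
#' @param pdb bio3d pdb object or PDB path.
#' @param path output PDB path.
#' @param offset model residue = shift residue + offset.
#' @param shift_types optional [shift_table()] (or data.frame with
#'   `residue_number`, `residue_type`) enabling the numbering check;
#'   skipped when NULL.
#' @return output path, invisibly.
#' @export
map_classification_to_structure <- function(classification, pdb, path,
                                            offset = 0L,
                                            shift_types = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  if (!is.null(shift_types)) {
    chk <- check_numbering_consistency(shift_types, pdb, offset = offset)
    if (chk$n_compared > 0 && !chk$consistent) {
      stop("numbering inconsistency at offset ", offset, ": ",
           chk$n_mismatch, "/", chk$n_compared,
           " residue types disagree between shift tables and model",
           call. = FALSE)
    }
  }
  codes <- as.numeric(classification$tiers$tier) - 1
  names(codes) <- classification$tiers$residue_number
  model_res <- unique(pdb$atom$resno)
  mappable <- as.integer(names(codes)) + as.integer(offset)
  if (!any(mappable %in% model_res)) {
    stop("no classified residues map onto the model at offset ", offset,
         call. = FALSE)
  }
  write_structure_with_scores(pdb, codes, path, offset = offset)
}

#' Ungapped pairwise sequence identity
#'
#' Position-by-position identity of two equal-length residue strings:
#' `100 * matches / length`. Reported rounded to the nearest integer
#' percent, with the raw fraction retained. Gapped alignment is out of
#' scope; the comparison this supports (tandem LIM domains) is between
#' equal-length segments.
#'
#' @param seq_a,seq_b residue strings (one-letter codes), equal length.
#' @return list with `percent` (integer-rounded), `fraction`,
#'   `matches`, `length`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 75%
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences differ in length (", length(a), " vs ", length(b),
         "); ungapped comparison requires equal lengths", call. = FALSE)
  }
  if (length(a) == 0) stop("empty sequences", call. = FALSE)
  matches <- sum(a == b)
  frac <- matches / length(a)
  list(percent = as.integer(round(100 * frac)), fraction = frac,
       matches = matches, length = length(a))
}

#' Identity between two segments of one sequence
#'
#' Convenience wrapper for intra-protein domain comparisons such as a
#' tandem LIM pair: extracts `seq[a_range]` and `seq[b_range]` (1-based,
#' inclusive, full-sequence numbering) and calls [pairwise_identity()].
#'
#' @param seq full-length residue string.
#' @param a_range,b_range integer `c(start, end)` pairs; must have equal
#'   widths.
#' @return as [pairwise_identity()].
#' @export
segment_identity <- function(seq, a_range, b_range) {
  stopifnot(length(a_range) == 2, length(b_range) == 2)
  n <- nchar(seq)
  if (a_range[2] > n || b_range[2] > n || a_range[1] < 1 || b_range[1] < 1) {
    stop("segment range outside sequence (length ", n, ")", call. = FALSE)
  }
  pairwise_identity(substr(seq, a_range[1], a_range[2]),
                    substr(seq, b_range[1], b_range[2]))
}
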