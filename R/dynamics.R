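#' Backbone rigidity from heteronuclear NOE ratios
#'
#' The steady-state 15N{1H} NOE ratio (peak intensity with / without
#' proton saturation) reports ps-ns backbone motion: ratios at or above
#' ~0.8 indicate a rigid backbone, smaller values increasing
#' flexibility. The boundary is inclusive — exactly 0.8 is rigid — and
#' configurable. Ratios outside the physically sensible band
#' `[-1.5, 1.2]` trigger a warning (they usually mean an intensity
#' extraction problem) but are still classified.
#'
#' @param residue_number integer residue numbers.
#' @param ratio hetNOE intensity ratios (dimensionless, finite).
#' @param threshold rigidity boundary, default 0.8.
#' @return data.frame with `residue_number`, `ratio`, `label`
#'   (`"rigid"` / `"flexible"`).
#' @examples
#' classify_rigidity(1:3, c(0.85, 0.5, 0.8))
#' @export
classify_rigidity <- function(residue_number, ratio, threshold = 0.8) {
  if (any(!is.finite(ratio))) {
    stop("hetNOE ratios must be finite", call. = FALSE)
  }
  out_of_band <- ratio < -1.5 | ratio > 1.2
  if (any(out_of_band)) {
    warning(sum(out_of_band), " hetNOE ratio(s) outside [-1.5, 1.2]",
            call. = FALSE)
  }
  data.frame(residue_number = as.integer(residue_number),
             ratio = ratio,
             label = ifelse(ratio >= threshold, "rigid", "flexible"),
             stringsAsFactors = FALSE)
}

#' hetNOE ratios from saturated/reference intensities
#'
#' Small helper when only the two intensity columns are at hand; the
#' ratio is `I_sat / I_ref`. Intensity extraction from spectra is out
#' of scope.
#'
#' @param i_sat intensities with 1H saturation.
#' @param i_ref intensities without saturation; must be nonzero.
#' @return numeric ratios.
#' @export
hetnoe_ratio <- function(i_sat, i_ref) {
  if (any(i_ref == 0)) stop("zero reference intensity", call. = FALSE)
  i_sat / i_ref
}

#' Histidine zinc-coordination mode from aromatic carbon shifts
#'
#' In zinc fingers, the difference delta(CE1) - delta(CD2) of a
#' coordinating histidine discriminates the coordination nitrogen: a
#' difference strictly larger than ~17 ppm indicates coordination via
#' N-delta1. The converse case is labelled `"Nepsilon2_or_ambiguous"` —
#' deliberately non-committal, since only the N-delta1 side of the rule
#' is asserted. The difference is reported alongside the label.
#'
#' @param residue_number integer residue numbers.
#' @param delta_CE1,delta_CD2 carbon shifts in ppm (both required).
#' @param threshold_ppm decision boundary, default 17 (strict `>`).
#' @return data.frame with `residue_number`, `delta_CE1`, `delta_CD2`,
#'   `diff_ppm`, `label`.
#' @examples
#' classify_histidine_coordination(403, 139.0, 119.0)  # Ndelta1
#' @export
classify_histidine_coordination <- function(residue_number, delta_CE1,
                                            delta_CD2,
                                            threshold_ppm = 17) {
  if (any(!is.finite(delta_CE1)) || any(!is.finite(delta_CD2))) {
    stop("both CE1 and CD2 shifts are required and must be finite",
         call. = FALSE)
  }
  diff <- delta_CE1 - delta_CD2
  data.frame(residue_number = as.integer(residue_number),
             delta_CE1 = delta_CE1,
             delta_CD2 = delta_CD2,
             diff_ppm = diff,
             label = ifelse(diff > threshold_ppm, "Ndelta1",
                            "Nepsilon2_or_ambiguous"),
             stringsAsFactors = FALSE)
}

#' Histidine coordination from an NMR-STAR shift table
#'
#' Pairs the CD2/CE1 records of a histidine-mode [shift_table()] (see
#' [read_nmrstar_shifts()]) per residue and classifies each.
#'
#' @param st a [shift_table()] containing `CD2` and `CE1` records.
#' @param threshold_ppm see [classify_histidine_coordination()].
#' @return as [classify_histidine_coordination()]; residues missing
#'   either carbon are dropped with a warning.
#' @export
classify_histidines_from_table <- function(st, threshold_ppm = 17) {
  df <- as.data.frame(st)
  ce1 <- df[df$atom == "CE1", c("residue_number", "shift_ppm")]
  cd2 <- df[df$atom == "CD2", c("residue_number", "shift_ppm")]
  m <- merge(ce1, cd2, by = "residue_number",
             suffixes = c("_ce1", "_cd2"))
  n_dropped <- length(union(ce1$residue_number, cd2$residue_number)) -
    nrow(m)
  if (n_dropped > 0) {
    warning(n_dropped, " histidine(s) missing CD2 or CE1, dropped",
            call. = FALSE)
  }
  if (nrow(m) == 0) stop("no complete CD2/CE1 pairs", call. = FALSE)
  classify_histidine_coordination(m$residue_number, m$shift_ppm_ce1,
                                  m$shift_ppm_cd2,
                                  threshold_ppm = threshold_ppm)
}
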