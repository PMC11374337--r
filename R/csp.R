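#' Per-residue amide shift differences between two titration points
#'
#' For every residue carrying both an `H` and an `N` record in both
#' tables, returns the signed differences `point - reference` in ppm.
#' Residues lacking either amide peak in either table are flagged
#' missing: peak absence (proline, exchange broadening) is data, not an
#' error.
#'
#' @param reference the free-state [shift_table()] (the L = 0 point).
#' @param point a later titration point.
#' @return data.frame with columns `residue_number`, `residue_type`,
#'   `d_H`, `d_N` (ppm, `NA` when missing) and logical `valid`. Rows
#'   cover every residue with an amide record in the reference.
#' @export
delta_shifts <- function(reference, point) {
  amide <- function(st) {
    st <- as.data.frame(st)
    st[st$atom %in% c("H", "N"), ]
  }
  ref <- amide(reference)
  pt <- amide(point)
  wide <- function(df) {
    h <- df[df$atom == "H", c("residue_number", "residue_type", "shift_ppm")]
    n <- df[df$atom == "N", c("residue_number", "shift_ppm")]
    names(h)[3] <- "H"
    names(n)[2] <- "N"
    merge(h, n, by = "residue_number", all = TRUE)
  }
  rw <- wide(ref)
  pw <- wide(pt)
  pw$residue_type <- NULL
  m <- merge(rw, pw, by = "residue_number", all.x = TRUE,
             suffixes = c("_ref", "_pt"))
  d_H <- m$H_pt - m$H_ref
  d_N <- m$N_pt - m$N_ref
  valid <- is.finite(d_H) & is.finite(d_N)
  data.frame(residue_number = m$residue_number,
             residue_type = m$residue_type,
             d_H = ifelse(valid, d_H, NA_real_),
             d_N = ifelse(valid, d_N, NA_real_),
             valid = valid,
             stringsAsFactors = FALSE)
}

#' Combined amide chemical shift perturbation
#'
#' Collapses the proton and nitrogen shift changes into one scalar:
#' \deqn{\Delta\delta = s \sqrt{\Delta\delta_H^2 + w\,\Delta\delta_N^2}}
#' with nitrogen weight `w = 0.14` (the usual amide convention, chosen
#' so a nitrogen ppm counts for roughly its spectral-width share) and
#' overall scale `s = 0.5`. The result is in ppm, non-negative, and
#' invariant to the signs of its inputs. Both constants are exposed so
#' alternative conventions are one argument away.
#'
#' @param d_H,d_N amide 1H and 15N shift changes (ppm); vectorised.
#' @param n_weight nitrogen weight, default 0.14.
#' @param scale overall scale, default 0.5.
#' @return combined CSP in ppm.
#' @examples
#' combine_csp(0.10, 0)          # 0.05
#' combine_csp(0.05, 0.50)       # ~0.0968
#' @export
combine_csp <- function(d_H, d_N, n_weight = 0.14, scale = 0.5) {
  if (any(!is.finite(d_H)) || any(!is.finite(d_N))) {
    stop("combine_csp requires finite inputs", call. = FALSE)
  }
  scale * sqrt(d_H^2 + n_weight * d_N^2)
}

#' Combined CSP profiles across a titration series
#'
#' For every residue observed in the free reference, computes the
#' per-point amide shift differences ([delta_shifts()]) and combined
#' CSP ([combine_csp()]). The result is tidy: one row per residue and
#' titration point.
#'
#' @param series a `titration_series` (see [load_titration_series()] /
#'   [titration_series()]); its first point must be the L = 0 reference.
#' @param n_weight,scale passed to [combine_csp()].
#' @return A `csp_profiles` data.frame with columns `residue_number`,
#'   `residue_type`, `point_label`, `P_conc`, `L_conc`, `d_H`, `d_N`,
#'   `csp_ppm`, `valid`. Attribute `dropped_residues` lists residues
#'   never observed with a complete amide pair at any point.
#' @export
build_csp_profiles <- function(series, n_weight = 0.14, scale = 0.5) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$manifest$points
  if (pts$L_conc[1] != 0) {
    stop("first point of the series must be the L = 0 reference",
         call. = FALSE)
  }
  ref <- series$tables[[1]]
  out <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ds <- delta_shifts(ref, series$tables[[i]])
    csp <- rep(NA_real_, nrow(ds))
    csp[ds$valid] <- combine_csp(ds$d_H[ds$valid], ds$d_N[ds$valid],
                                 n_weight = n_weight, scale = scale)
    out[[i]] <- data.frame(residue_number = ds$residue_number,
                           residue_type = ds$residue_type,
                           point_label = pts$point_label[i],
                           P_conc = pts$P_conc[i],
                           L_conc = pts$L_conc[i],
                           d_H = ds$d_H, d_N = ds$d_N,
                           csp_ppm = csp, valid = ds$valid,
                           stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  obs <- tapply(prof$valid, prof$residue_number, any)
  dropped <- as.integer(names(obs)[!obs])
  prof <- prof[order(prof$residue_number, prof$L_conc), ]
  rownames(prof) <- NULL
  attr(prof, "n_weight") <- n_weight
  attr(prof, "scale") <- scale
  attr(prof, "dropped_residues") <- dropped
  class(prof) <- c("csp_profiles", "data.frame")
  prof
}

#' Endpoint CSP per residue
#'
#' The endpoint is the highest-titrant point at which a residue is
#' valid (the convention used for interface classification); the fitted
#' saturation shift is available separately from the global fit for
#' users who prefer it.
#'
#' @param profiles a `csp_profiles` data.frame.
#' @return named numeric vector of endpoint CSPs (ppm), named by
#'   residue number; residues valid only at the reference report 0.
#' @export
endpoint_csp <- function(profiles) {
  stopifnot(inherits(profiles, "csp_profiles") || is.data.frame(profiles))
  sp <- split(profiles, profiles$residue_number)
  vals <- vapply(sp, function(d) {
    d <- d[d$valid, ]
    if (nrow(d) == 0) return(NA_real_)
    d$csp_ppm[which.max(d$L_conc)]
  }, numeric(1))
  vals[!is.na(vals)]
}

#' Number of valid non-reference points per residue
#'
#' @param profiles a `csp_profiles` data.frame.
#' @return named integer vector keyed by residue number.
#' @export
n_valid_points <- function(profiles) {
  nonref <- profiles[profiles$L_conc > 0, ]
  sp <- split(nonref$valid, nonref$residue_number)
  vapply(sp, sum, integer(1))
}

#' Export CSP profiles as tidy CSV
#'
#' @param profiles a `csp_profiles` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_csp_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
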