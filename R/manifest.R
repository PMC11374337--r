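#' Titration manifests and titration series
#'
#' A titration manifest records, for each titration point, the labelled
#' protein concentration `P_conc` and the titrant concentration `L_conc`
#' (both in uM) plus the path of the shift table observed at that point.
#' The first point must be the free reference (`L_conc = 0`), titrant
#' concentrations must be nondecreasing, and `P_conc` must be positive
#' throughout. Concentrations are taken verbatim per point: any dilution
#' correction happens upstream of the manifest.
#'
#' @param labeled_species name of the 15N-labelled species.
#' @param titrant_species name of the unlabelled titrant.
#' @param points data.frame with columns `point_label`, `P_conc`,
#'   `L_conc` and optionally `shift_table_path`.
#' @param temperature_K,pH optional sample conditions.
#' @return A `titration_manifest` object.
#' @export
titration_manifest <- function(labeled_species, titrant_species, points,
                               temperature_K = NULL, pH = NULL) {
  stopifnot(is.data.frame(points))
  need <- c("point_label", "P_conc", "L_conc")
  missing <- setdiff(need, names(points))
  if (length(missing) > 0) {
    stop("manifest points lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(points) < 1) stop("manifest has no points", call. = FALSE)
  if (points$L_conc[1] != 0) {
    stop("first titration point must be the free reference (L_conc = 0)",
         call. = FALSE)
  }
  if (is.unsorted(points$L_conc)) {
    stop("titrant concentrations must be nondecreasing", call. = FALSE)
  }
  if (any(points$P_conc <= 0)) {
    stop("P_conc must be > 0 at every point", call. = FALSE)
  }
  m <- list(labeled_species = labeled_species,
            titrant_species = titrant_species,
            points = points,
            temperature_K = temperature_K, pH = pH)
  class(m) <- "titration_manifest"
  m
}

#' Read a titration manifest from JSON
#'
#' @param path path to a JSON manifest with fields `labeled_species`,
#'   `titrant_species` and `points` (list of objects with `point_label`,
#'   `P_conc`, `L_conc`, `shift_table_path`).
#' @return A [titration_manifest()].
#' @export
read_titration_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("labeled_species", "titrant_species", "points")
  missing <- setdiff(need, names(j))
  if (length(missing) > 0) {
    stop("manifest ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  titration_manifest(j$labeled_species, j$titrant_species,
                     as.data.frame(j$points),
                     temperature_K = j$temperature_K, pH = j$pH)
}

#' Write a titration manifest to JSON
#'
#' @param manifest a [titration_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Assemble a titration series from a manifest
#'
#' Loads every per-point shift table referenced by the manifest. The
#' result bundles the manifest with an ordered list of [shift_table()]s
#' and is the input of [build_csp_profiles()].
#'
#' @param manifest a [titration_manifest()] or path to a manifest JSON.
#' @param base_dir directory against which relative `shift_table_path`s
#'   are resolved; defaults to the manifest's own directory when
#'   `manifest` is a path, else the working directory.
#' @param dialect shift table dialect, see [read_shift_table()].
#' @return A `titration_series`: list with elements `manifest` and
#'   `tables`.
#' @export
load_titration_series <- function(manifest, base_dir = NULL,
                                  dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_titration_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (is.null(manifest$points$shift_table_path)) {
    stop("manifest points carry no shift_table_path", call. = FALSE)
  }
  tables <- lapply(seq_len(nrow(manifest$points)), function(i) {
    p <- manifest$points$shift_table_path[i]
    if (!file.exists(p)) p <- file.path(base_dir, p)
    read_shift_table(p, dialect = dialect,
                     point_label = manifest$points$point_label[i])
  })
  titration_series(manifest, tables)
}

#' Build a titration series from in-memory tables
#'
#' @param manifest a [titration_manifest()].
#' @param tables list of [shift_table()]s, one per manifest point, in
#'   manifest order.
#' @return A `titration_series`.
#' @export
titration_series <- function(manifest, tables) {
  stopifnot(inherits(manifest, "titration_manifest"))
  if (length(tables) != nrow(manifest$points)) {
    stop("need one shift table per manifest point (",
         nrow(manifest$points), "), got ", length(tables), call. = FALSE)
  }
  s <- list(manifest = manifest, tables = tables)
  class(s) <- "titration_series"
  s
}

#' @export
print.titration_series <- function(x, ...) {
  p <- x$manifest$points
  cat(sprintf("<titration_series> %s + %s, %d points, L = %s uM\n",
              x$manifest$labeled_species, x$manifest$titrant_species,
              nrow(p), paste(p$L_conc, collapse = "/")))
  invisible(x)
}
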