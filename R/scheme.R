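#' Synapse subtype classification scheme
#'
#' Encodes the two-level classification used in synaptome maps: three synapse
#' types defined by PSD95/SAP102 channel expression (type 1 PSD95 only,
#' type 2 SAP102 only, type 3 both) and 37 morphological subtypes
#' (type 1 holds subtypes 1-11, type 2 subtypes 12-18, type 3 subtypes 19-37),
#' plus the short-protein-lifetime (SPL) and long-protein-lifetime (LPL)
#' subtype sets used for turnover contrasts. Subtype assignment is
#' nearest-centroid in robust-standardized morphological feature space; the
#' published decision boundaries are not restated in this lineage's papers, so
#' the shipped centroids are a synthetic, versioned stand-in.
#'
#' @param centroids optional data frame of per-subtype feature centroids with
#'   columns `subtype`, `type`, `intensity_psd95`, `intensity_sap102`, and the
#'   morphological features `size`, `circularity`, `aspect`. Defaults to the
#'   packaged synthetic centroids.
#' @return An object of class `subtype_scheme`: a list with elements `version`,
#'   `type_ranges`, `spl`, `lpl`, `centroids`, `morph_features`, and the robust
#'   standardization `center`/`scale` per morphological feature.
#' @export
subtype_scheme <- function(centroids = NULL) {
  type_ranges <- list(`1` = 1:11, `2` = 12:18, `3` = 19:37)
  if (is.null(centroids)) centroids <- default_centroids()
  stopifnot(
    nrow(centroids) == 37L,
    identical(sort(centroids$subtype), 1:37),
    all(c("size", "circularity", "aspect") %in% names(centroids))
  )
  morph <- c("size", "circularity", "aspect")
  center <- vapply(centroids[morph], stats::median, numeric(1))
  scale <- vapply(centroids[morph], stats::mad, numeric(1))
  if (any(scale <= 0)) stop("degenerate centroid feature scale")
  spl <- c(6L, 8L, 11L, 28L, 29L, 31L)
  lpl <- c(2L, 3L, 5L, 30L, 34L)
  stopifnot(length(intersect(spl, lpl)) == 0L,
            all(c(spl, lpl) %in% c(type_ranges$`1`, type_ranges$`3`)))
  structure(
    list(version = "1", type_ranges = type_ranges, spl = spl, lpl = lpl,
         centroids = centroids[order(centroids$subtype), , drop = FALSE],
         morph_features = morph, center = center, scale = scale),
    class = "subtype_scheme"
  )
}

# Synthetic per-subtype centroids: channel intensities separate the 3 types,
# a deterministic lattice of size/circularity/aspect separates subtypes
# within a type. Sizes are unique within each type so nearest-centroid is
# unambiguous.
default_centroids <- function() {
  type_of <- c(rep(1L, 11), rep(2L, 7), rep(3L, 19))
  k <- c(1:11, 1:7, 1:19)  # index within type
  data.frame(
    subtype = 1:37,
    type = type_of,
    intensity_psd95 = ifelse(type_of == 2L, 0, 110 + 6 * k),
    intensity_sap102 = ifelse(type_of == 1L, 0, 95 + 6 * k),
    size = 0.14 + 0.05 * k,
    circularity = 0.45 + 0.25 * ((k - 1) %% 3),
    aspect = 1.0 + 0.3 * ((k - 1) %/% 3)
  )
}

#' Write / read a subtype scheme as versioned JSON
#'
#' @param scheme a `subtype_scheme` object.
#' @param path file path of the JSON scheme.
#' @return `read_subtype_scheme` returns a `subtype_scheme`;
#'   `write_subtype_scheme` returns `path` invisibly.
#' @export
write_subtype_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "subtype_scheme"))
  payload <- list(version = scheme$version,
                  spl = scheme$spl, lpl = scheme$lpl,
                  centroids = scheme$centroids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subtype_scheme
#' @export
read_subtype_scheme <- function(path = system.file("extdata",
                                                   "subtype_scheme_v1.json",
                                                   package = "synwaves")) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- subtype_scheme(centroids = as.data.frame(payload$centroids))
  sch$version <- payload$version
  sch
}

# Map subtypes to their type.
subtype_to_type <- function(subtype, scheme = subtype_scheme()) {
  out <- integer(length(subtype))
  for (tp in names(scheme$type_ranges)) {
    out[subtype %in% scheme$type_ranges[[tp]]] <- as.integer(tp)
  }
  if (any(out == 0L)) stop("subtype outside 1..37")
  out
}

#' PSD95-expressing subtypes (types 1 and 3)
#' @param scheme a `subtype_scheme`.
#' @return Integer vector of the 30 PSD95-expressing subtype labels.
#' @export
psd95_subtypes <- function(scheme = subtype_scheme()) {
  sort(c(scheme$type_ranges$`1`, scheme$type_ranges$`3`))
}
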