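#' Classify puncta into synapse types from channel intensities
#'
#' Type 1 puncta express PSD95 only, type 2 SAP102 only, and type 3 both.
#' A punctum with neither channel above its detection threshold is not a
#' synapse and is rejected.
#'
#' @param intensity_psd95,intensity_sap102 channel intensities (a.u., >= 0);
#'   vectors of equal length.
#' @param thresholds named numeric vector with detection thresholds
#'   `psd95` and `sap102` (a.u.).
#' @return Integer vector of types in `{1, 2, 3}`.
#' @export
classify_type <- function(intensity_psd95, intensity_sap102,
                          thresholds = c(psd95 = 10, sap102 = 10)) {
  stopifnot(length(intensity_psd95) == length(intensity_sap102),
            all(c("psd95", "sap102") %in% names(thresholds)))
  has_p <- intensity_psd95 > thresholds[["psd95"]]
  has_s <- intensity_sap102 > thresholds[["sap102"]]
  if (any(!has_p & !has_s)) {
    stop("punctum with neither channel above threshold: not a synapse")
  }
  ifelse(has_p & has_s, 3L, ifelse(has_p, 1L, 2L))
}

#' Assign synapse subtypes by nearest morphological centroid
#'
#' Within the subtype range of each punctum's (already assigned) type, returns
#' the subtype whose centroid is nearest in robust-standardized morphological
#' feature space (size, circularity, aspect; Euclidean metric). Ties are
#' broken toward the lowest subtype label.
#'
#' @param puncta data frame with the scheme's morphological feature columns.
#' @param type integer vector of types per punctum (from [classify_type()]).
#' @param scheme a [subtype_scheme()].
#' @return Integer vector of subtype labels in 1..37.
#' @export
classify_subtype <- function(puncta, type, scheme = subtype_scheme()) {
  feats <- scheme$morph_features
  stopifnot(all(feats %in% names(puncta)), nrow(puncta) == length(type))
  z <- function(df) {
    sweep(sweep(as.matrix(df[feats]), 2, scheme$center), 2, scheme$scale, "/")
  }
  zp <- z(puncta)
  zc <- z(scheme$centroids)
  out <- integer(nrow(puncta))
  for (tp in unique(type)) {
    range_tp <- scheme$type_ranges[[as.character(tp)]]
    if (is.null(range_tp)) stop("unknown type: ", tp)
    idx <- which(type == tp)
    cen <- zc[scheme$centroids$subtype %in% range_tp, , drop = FALSE]
    labels <- scheme$centroids$subtype[scheme$centroids$subtype %in% range_tp]
    # squared distances puncta x centroids
    d2 <- outer(rowSums(zp[idx, , drop = FALSE]^2), rowSums(cen^2), "+") -
      2 * zp[idx, , drop = FALSE] %*% t(cen)
    # which.max on negated distances returns the first (lowest-label) tie
    out[idx] <- labels[apply(-d2, 1, which.max)]
  }
  out
}

#' Classify a puncta table into types and subtypes
#'
#' @param puncta data frame with channel and morphological feature columns.
#' @param scheme a [subtype_scheme()].
#' @param thresholds detection thresholds passed to [classify_type()].
#' @return The input with `type` and `subtype` columns appended.
#' @export
classify_puncta <- function(puncta, scheme = subtype_scheme(),
                            thresholds = c(psd95 = 10, sap102 = 10)) {
  type <- classify_type(puncta$intensity_psd95, puncta$intensity_sap102,
                        thresholds)
  subtype <- classify_subtype(puncta, type, scheme)
  cbind(puncta, type = type, subtype = subtype)
}

#' Summarize classified puncta into a subregion profile
#'
#' Densities are counts per unit area per subtype (and per type, obtained by
#' summing the type's subtypes); intensity and size summaries are means over
#' the member puncta of each type.
#'
#' @param puncta classified puncta table (columns `subtype`, and optionally
#'   `type`, `intensity_psd95`, `intensity_sap102`, `size`); all rows must
#'   share one subregion.
#' @param area imaged area (same unit as the densities' denominator); > 0.
#' @param scheme a [subtype_scheme()].
#' @return A list of class `subregion_profile`: `subtype_density` (named
#'   length-37 vector), `type_density` (length-3), `type_summaries` (mean
#'   intensity/size per type), `n_puncta`, `area`.
#' @export
summarize_region <- function(puncta, area, scheme = subtype_scheme()) {
  if (area <= 0) stop("area must be positive")
  if (nrow(puncta) > 0 && "subregion" %in% names(puncta) &&
      length(unique(puncta$subregion)) > 1L) {
    stop("all puncta must share one subregion")
  }
  n_sub <- nrow(scheme$centroids)
  counts <- table(factor(puncta$subtype, levels = seq_len(n_sub)))
  subtype_density <- as.numeric(counts) / area
  names(subtype_density) <- seq_len(n_sub)
  type_density <- vapply(names(scheme$type_ranges), function(tp) {
    sum(subtype_density[scheme$type_ranges[[tp]]])
  }, numeric(1))
  summaries <- lapply(names(scheme$type_ranges), function(tp) {
    sel <- puncta$subtype %in% scheme$type_ranges[[tp]]
    cols <- intersect(c("intensity_psd95", "intensity_sap102", "size"),
                      names(puncta))
    if (!any(sel)) {
      stats::setNames(rep(NA_real_, length(cols)), cols)
    } else {
      vapply(cols, function(cl) mean(puncta[[cl]][sel]), numeric(1))
    }
  })
  names(summaries) <- names(scheme$type_ranges)
  structure(list(subtype_density = subtype_density,
                 type_density = type_density,
                 type_summaries = summaries,
                 n_puncta = nrow(puncta), area = area),
            class = "subregion_profile")
}
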