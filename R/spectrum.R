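#' Construct a tandem mass spectrum
#'
#' A `Spectrum` is a centroided fragment-ion peak list together with its
#' precursor metadata. Peaks are stored as two parallel numeric vectors and
#' are sorted by m/z on construction.
#'
#' @param spectrum_id Non-empty string, unique within a run.
#' @param mz Numeric vector of fragment m/z values (Thomson, all > 0).
#' @param intensity Numeric vector of non-negative peak abundances, same
#'   length as `mz`.
#' @param precursor_mz Precursor m/z in Thomson (> 0), or `NA` if unknown.
#' @param precursor_charge Positive integer charge, or `NA` if unknown.
#'   Unknown charges are propagated, never imputed.
#' @param retention_time Retention time in seconds, or `NA`.
#'
#' @return An object of class `Spectrum`.
#' @export
#'
#' @examples
#' s <- spectrum("s1", mz = c(200.1, 100.2), intensity = c(5, 10),
#'               precursor_mz = 500.25, precursor_charge = 2)
#' s$mz  # sorted ascending
spectrum <- function(spectrum_id, mz, intensity,
                     precursor_mz = NA_real_,
                     precursor_charge = NA_integer_,
                     retention_time = NA_real_) {
  if (!is.character(spectrum_id) || length(spectrum_id) != 1L ||
      is.na(spectrum_id) || !nzchar(spectrum_id)) {
    stop("spectrum_id must be a non-empty string", call. = FALSE)
  }
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("all mz values must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.na(precursor_mz) && precursor_mz <= 0) {
    stop("precursor_mz must be > 0 when present", call. = FALSE)
  }
  o <- order(mz)
  structure(
    list(
      spectrum_id = spectrum_id,
      precursor_mz = as.numeric(precursor_mz),
      precursor_charge = as.integer(precursor_charge),
      retention_time = as.numeric(retention_time),
      mz = mz[o],
      intensity = intensity[o]
    ),
    class = "Spectrum"
  )
}

#' Test whether an object is a Spectrum
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_spectrum <- function(x) inherits(x, "Spectrum")

#' @export
print.Spectrum <- function(x, ...) {
  chg <- if (is.na(x$precursor_charge)) "?" else x$precursor_charge
  cat(sprintf("Spectrum '%s': %d peaks, precursor m/z %s, charge %s\n",
              x$spectrum_id, length(x$mz),
              if (is.na(x$precursor_mz)) "?" else
                formatC(x$precursor_mz, format = "f", digits = 4),
              chg))
  invisible(x)
}

#' @export
length.Spectrum <- function(x) length(x$mz)

#' Construct a spectrum cluster
#'
#' A `Cluster` pairs a cluster identifier with the ordered, duplicate-free
#' list of its member spectrum identifiers.
#'
#' @param cluster_id Non-empty string.
#' @param member_ids Character vector of member spectrum identifiers,
#'   length >= 1, no duplicates.
#' @return An object of class `Cluster`.
#' @export
cluster <- function(cluster_id, member_ids) {
  member_ids <- as.character(member_ids)
  if (length(member_ids) < 1L) {
    stop("a cluster must have at least one member", call. = FALSE)
  }
  if (anyDuplicated(member_ids)) {
    stop(sprintf("cluster '%s' has duplicate member ids", cluster_id),
         call. = FALSE)
  }
  structure(list(cluster_id = as.character(cluster_id),
                 member_ids = member_ids),
            class = "Cluster")
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf("Cluster '%s': %d members\n", x$cluster_id,
              length(x$member_ids)))
  invisible(x)
}

#' Build a spectrum store keyed by spectrum identifier
#'
#' @param spectra List of `Spectrum` objects.
#' @return Named list of spectra, keyed by `spectrum_id`.
#' @export
spectrum_store <- function(spectra) {
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate spectrum_id in store: '%s'", dup), call. = FALSE)
  }
  stats::setNames(spectra, ids)
}

# Resolve a cluster's members against a store; errors name the cluster and id.
resolve_members <- function(cl, store) {
  missing <- setdiff(cl$member_ids, names(store))
  if (length(missing)) {
    stop(sprintf("cluster '%s': member spectrum '%s' not found",
                 cl$cluster_id, missing[1]), call. = FALSE)
  }
  store[cl$member_ids]
}
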