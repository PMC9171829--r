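#' Parameters for consensus spectrum generation
#'
#' @param bin_width Bin width in Thomson for the BIN method grid
#'   (default 0.02).
#' @param min_fraction Minimum fraction of cluster members that must
#'   contribute a peak to a bin for it to be kept; bins strictly below the
#'   threshold are discarded (default 0.25).
#' @param merge_tolerance m/z window in Thomson within which the AVERAGE
#'   method merges close peaks (default 0.02).
#' @param similarity_bin_width Bin width in Thomson used to vectorize
#'   spectra for the dot-product similarity of the MOST method
#'   (default 0.02).
#' @param bin_intensity `"peaks"` (default) or `"members"`: whether a BIN
#'   consensus bin's intensity is the mean over the peaks that fell in the
#'   bin, or their sum divided by the total number of cluster members
#'   (down-weighting sparsely occupied bins).
#' @param intensity_transform `"none"` or `"sqrt"`; applied to binned
#'   intensity vectors before normalization in the dot product.
#' @param score_direction `"higher"` or `"lower"`: whether larger
#'   identification scores are better (BEST method).
#' @param tie_break `"first_id"` (deterministic: lexicographically smallest
#'   spectrum identifier) or `"random"` (seeded draw).
#' @param seed Integer seed, used only when `tie_break = "random"`.
#' @return A list of class `ConsensusParams`.
#' @export
consensus_params <- function(bin_width = 0.02,
                             min_fraction = 0.25,
                             merge_tolerance = 0.02,
                             similarity_bin_width = 0.02,
                             bin_intensity = c("peaks", "members"),
                             intensity_transform = c("none", "sqrt"),
                             score_direction = c("higher", "lower"),
                             tie_break = c("first_id", "random"),
                             seed = NULL) {
  bin_intensity <- match.arg(bin_intensity)
  intensity_transform <- match.arg(intensity_transform)
  score_direction <- match.arg(score_direction)
  tie_break <- match.arg(tie_break)
  stopifnot(bin_width > 0, min_fraction > 0, min_fraction <= 1,
            merge_tolerance >= 0, similarity_bin_width > 0)
  if (tie_break == "random" && is.null(seed)) {
    stop("tie_break = 'random' requires an explicit seed", call. = FALSE)
  }
  structure(list(bin_width = bin_width,
                 min_fraction = min_fraction,
                 merge_tolerance = merge_tolerance,
                 similarity_bin_width = similarity_bin_width,
                 bin_intensity = bin_intensity,
                 intensity_transform = intensity_transform,
                 score_direction = score_direction,
                 tie_break = tie_break,
                 seed = seed),
            class = "ConsensusParams")
}

#' Construct a per-cluster consensus record
#'
#' @param cluster_id Cluster identifier.
#' @param method One of `"average"`, `"bin"`, `"most"`, `"best"`.
#' @param spec The consensus `Spectrum`. For MOST/BEST this is the selected
#'   member's spectrum verbatim.
#' @param n_members Number of cluster members the record summarizes.
#' @param source_member_id Selected member's spectrum identifier (MOST and
#'   BEST), `NA` for AVERAGE and BIN.
#' @return An object of class `ConsensusRecord`.
#' @export
consensus_record <- function(cluster_id, method, spec, n_members,
                             source_member_id = NA_character_) {
  method <- match.arg(method, c("average", "bin", "most", "best"))
  stopifnot(is_spectrum(spec), n_members >= 1L)
  structure(list(cluster_id = as.character(cluster_id),
                 method = method,
                 spectrum = spec,
                 source_member_id = as.character(source_member_id),
                 n_members = as.integer(n_members)),
            class = "ConsensusRecord")
}

#' @export
print.ConsensusRecord <- function(x, ...) {
  src <- if (is.na(x$source_member_id)) "" else
    sprintf(" (from member '%s')", x$source_member_id)
  cat(sprintf("ConsensusRecord cluster '%s', method %s, %d members%s: %d peaks\n",
              x$cluster_id, toupper(x$method), x$n_members, src,
              length(x$spectrum$mz)))
  invisible(x)
}

#' Merge peaks with close m/z values
#'
#' Single greedy left-to-right pass over an m/z-sorted peak list: a peak
#' joins the current group when its m/z lies within `tolerance` of the
#' group's running intensity-weighted mean m/z, otherwise it starts a new
#' group. Each group is emitted as one peak with m/z equal to the
#' intensity-weighted mean of its members' m/z and intensity equal to the
#' arithmetic mean of their intensities.
#'
#' @param mz Sorted numeric vector of peak m/z values.
#' @param intensity Numeric vector of peak intensities, same length.
#' @param tolerance Merge window in Thomson (>= 0).
#' @return List with numeric vectors `mz` and `intensity`, sorted by m/z.
#' @export
#'
#' @examples
#' merge_close_peaks(c(100.00, 100.01), c(1, 3), tolerance = 0.02)
#' # one peak at the weighted mean 100.0075 with mean intensity 2
merge_close_peaks <- function(mz, intensity, tolerance) {
  stopifnot(length(mz) == length(intensity), tolerance >= 0)
  if (is.unsorted(mz)) {
    stop("merge_close_peaks requires m/z-sorted input", call. = FALSE)
  }
  n <- length(mz)
  if (n == 0L) return(list(mz = numeric(), intensity = numeric()))
  group <- integer(n)
  g <- 1L
  group[1] <- g
  # running intensity-weighted mean of the open group; unweighted fallback
  # when all intensities in the group are zero
  wsum <- intensity[1]
  wmzsum <- mz[1] * intensity[1]
  count <- 1L
  mzsum <- mz[1]
  for (i in seq_len(n)[-1]) {
    center <- if (wsum > 0) wmzsum / wsum else mzsum / count
    if (mz[i] - center <= tolerance) {
      group[i] <- g
      wsum <- wsum + intensity[i]
      wmzsum <- wmzsum + mz[i] * intensity[i]
      count <- count + 1L
      mzsum <- mzsum + mz[i]
    } else {
      g <- g + 1L
      group[i] <- g
      wsum <- intensity[i]
      wmzsum <- mz[i] * intensity[i]
      count <- 1L
      mzsum <- mz[i]
    }
  }
  wm <- vapply(split(seq_len(n), group), function(idx) {
    if (length(idx) == 1L) return(mz[idx])  # exact for unmerged peaks
    w <- intensity[idx]
    if (sum(w) > 0) sum(mz[idx] * w) / sum(w) else mean(mz[idx])
  }, numeric(1))
  im <- vapply(split(intensity, group), mean, numeric(1))
  o <- order(wm)
  list(mz = unname(wm[o]), intensity = unname(im[o]))
}

#' AVERAGE consensus: intensity-weighted spectrum averaging
#'
#' The representative spectrum is an average of all spectra in the cluster:
#' member peak lists are pooled, sorted by m/z, and peaks with close m/z
#' values are merged into single peaks via [merge_close_peaks()], i.e.
#' merged m/z values are intensity-weighted means and merged intensities
#' are arithmetic means over the contributing peaks. The precursor is set
#' by [consensus_precursor()].
#'
#' @param members Non-empty list of `Spectrum` objects.
#' @param params A [consensus_params()] object.
#' @param spectrum_id Identifier for the output spectrum.
#' @return A `Spectrum`.
#' @export
consensus_average <- function(members, params = consensus_params(),
                              spectrum_id = "consensus") {
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  mz <- unlist(lapply(members, `[[`, "mz"))
  int <- unlist(lapply(members, `[[`, "intensity"))
  o <- order(mz)
  merged <- merge_close_peaks(mz[o], int[o], params$merge_tolerance)
  prec <- consensus_precursor(members)
  spectrum(spectrum_id, mz = merged$mz, intensity = merged$intensity,
           precursor_mz = prec$precursor_mz,
           precursor_charge = prec$precursor_charge)
}

#' BIN consensus: fixed-grid binning with an occupancy filter
#'
#' A consensus vector over half-open bins `[i*w, (i+1)*w)` anchored at m/z 0
#' is populated with every peak of every member. A bin's occupancy is the
#' number of distinct members contributing at least one peak to it; bins
#' whose occupancy fraction is strictly below `min_fraction` are discarded
#' (at the default 0.25, a bin touched by exactly 25% of members is kept).
#' Each surviving bin emits one peak whose m/z and intensity are the
#' unweighted means of all peak m/z and intensity values in the bin; with
#' `params$bin_intensity = "members"` the intensity denominator is the
#' total member count instead, down-weighting sparsely occupied bins.
#'
#' @inheritParams consensus_average
#' @return A `Spectrum`.
#' @export
consensus_bin <- function(members, params = consensus_params(),
                          spectrum_id = "consensus") {
  n_members <- length(members)
  if (n_members == 0L) stop("empty member list", call. = FALSE)
  w <- params$bin_width
  mz <- unlist(lapply(members, `[[`, "mz"))
  int <- unlist(lapply(members, `[[`, "intensity"))
  member <- rep(seq_len(n_members),
                vapply(members, function(s) length(s$mz), integer(1)))
  bin <- floor(mz / w)
  occupancy <- vapply(split(member, bin),
                      function(m) length(unique(m)), integer(1))
  keep_bins <- names(occupancy)[occupancy / n_members >= params$min_fraction]
  sel <- as.character(bin) %in% keep_bins
  if (!any(sel)) {
    prec <- consensus_precursor(members)
    return(spectrum(spectrum_id, numeric(), numeric(),
                    precursor_mz = prec$precursor_mz,
                    precursor_charge = prec$precursor_charge))
  }
  mzm <- vapply(split(mz[sel], bin[sel]), mean, numeric(1))
  intm <- if (params$bin_intensity == "peaks") {
    vapply(split(int[sel], bin[sel]), mean, numeric(1))
  } else {
    vapply(split(int[sel], bin[sel]), sum, numeric(1)) / n_members
  }
  o <- order(mzm)
  prec <- consensus_precursor(members)
  spectrum(spectrum_id, mz = unname(mzm[o]), intensity = unname(intm[o]),
           precursor_mz = prec$precursor_mz,
           precursor_charge = prec$precursor_charge)
}

# Vectorize a spectrum on the similarity grid: named vector of summed
# (optionally sqrt-transformed) intensities, normalized to unit norm.
binned_unit_vector <- function(s, width, transform = "none") {
  bin <- floor(s$mz / width)
  v <- vapply(split(s$intensity, bin), sum, numeric(1))
  if (transform == "sqrt") v <- sqrt(v)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    stop(sprintf("spectrum '%s' has an all-zero intensity vector; dot product undefined",
                 s$spectrum_id), call. = FALSE)
  }
  v / nrm
}

#' Normalized dot-product similarity of two spectra
#'
#' Each spectrum is vectorized onto a fixed grid of half-open bins of width
#' `similarity_bin_width` (intensities within a bin summed), optionally
#' square-root transformed, and normalized to unit Euclidean norm; the
#' similarity is the inner product of the two unit vectors, in \[0, 1\].
#'
#' @param a,b `Spectrum` objects with at least one peak each.
#' @param params A [consensus_params()] object.
#' @return Similarity in \[0, 1\].
#' @export
#'
#' @examples
#' s1 <- spectrum("a", 100.0, 1)
#' s2 <- spectrum("b", c(100.0, 200.0), c(1, 1))
#' spectrum_dot_product(s1, s2)  # 1/sqrt(2)
spectrum_dot_product <- function(a, b, params = consensus_params()) {
  if (length(a$mz) == 0L || length(b$mz) == 0L) {
    stop("dot product requires spectra with at least one peak",
         call. = FALSE)
  }
  va <- binned_unit_vector(a, params$similarity_bin_width,
                           params$intensity_transform)
  vb <- binned_unit_vector(b, params$similarity_bin_width,
                           params$intensity_transform)
  shared <- intersect(names(va), names(vb))
  if (length(shared) == 0L) return(0)
  min(1, sum(va[shared] * vb[shared]))
}

#' MOST consensus: medoid selection by summed pairwise similarity
#'
#' For each member, the [spectrum_dot_product()] against every other member
#' (self-similarity excluded) is summed; the member with the maximal summed
#' similarity — the cluster medoid — is selected and returned verbatim.
#' Ties are broken per `params$tie_break`: `"first_id"` picks the
#' lexicographically smallest spectrum identifier, `"random"` draws among
#' the tied members from the current RNG stream.
#'
#' @inheritParams consensus_average
#' @param cluster_id Identifier recorded in the output.
#' @return A `ConsensusRecord` with `source_member_id` set.
#' @export
consensus_most <- function(members, params = consensus_params(),
                           cluster_id = "cluster") {
  n <- length(members)
  if (n == 0L) stop("empty member list", call. = FALSE)
  if (n == 1L) {
    return(consensus_record(cluster_id, "most", members[[1]], 1L,
                            source_member_id = members[[1]]$spectrum_id))
  }
  vecs <- lapply(members, binned_unit_vector,
                 width = params$similarity_bin_width,
                 transform = params$intensity_transform)
  sums <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- intersect(names(vecs[[i]]), names(vecs[[j]]))
      sim <- if (length(shared)) sum(vecs[[i]][shared] * vecs[[j]][shared])
             else 0
      sums[i] <- sums[i] + sim
      sums[j] <- sums[j] + sim
    }
  }
  pick <- break_ties(which(sums >= max(sums) - 1e-12), members, params)
  consensus_record(cluster_id, "most", members[[pick]], n,
                   source_member_id = members[[pick]]$spectrum_id)
}

break_ties <- function(candidates, members, params) {
  if (length(candidates) == 1L) return(candidates)
  if (params$tie_break == "first_id") {
    ids <- vapply(members[candidates], `[[`, character(1), "spectrum_id")
    candidates[order(ids)[1]]
  } else {
    candidates[sample.int(length(candidates), 1L)]
  }
}

#' BEST consensus: best-identified member selection
#'
#' Selects the member whose peptide-spectrum match score is best per
#' `params$score_direction` and returns its spectrum verbatim. Members
#' without a PSM are not candidates; a cluster in which no member is
#' identified has no valid representative under this method and raises an
#' error.
#'
#' @inheritParams consensus_most
#' @param psms A `psm_table` from [read_psms()] (or compatible data.frame
#'   keyed by `spectrum_id`).
#' @return A `ConsensusRecord` with `source_member_id` set.
#' @export
consensus_best <- function(members, psms, params = consensus_params(),
                           cluster_id = "cluster") {
  n <- length(members)
  if (n == 0L) stop("empty member list", call. = FALSE)
  ids <- vapply(members, `[[`, character(1), "spectrum_id")
  idx <- match(ids, psms$spectrum_id)
  identified <- which(!is.na(idx))
  if (length(identified) == 0L) {
    stop(sprintf("cluster '%s': unidentified cluster (no member has a PSM)",
                 cluster_id), call. = FALSE)
  }
  scores <- psms$score[idx[identified]]
  key <- if (params$score_direction == "higher") scores else -scores
  best <- identified[which(key == max(key))]
  pick <- break_ties(best, members, params)
  consensus_record(cluster_id, "best", members[[pick]], n,
                   source_member_id = members[[pick]]$spectrum_id)
}

#' Consensus precursor m/z and charge
#'
#' The consensus precursor m/z is the median of the member precursor m/z
#' values; the charge is the modal member charge, with ties broken toward
#' the smaller charge. A warning is emitted when members disagree on the
#' charge. Unknown (`NA`) values are excluded; if no member carries a
#' value, the result is `NA`.
#'
#' @param members Non-empty list of `Spectrum` objects.
#' @return List with `precursor_mz` and `precursor_charge`.
#' @export
consensus_precursor <- function(members) {
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  mzs <- vapply(members, `[[`, numeric(1), "precursor_mz")
  chg <- vapply(members, `[[`, integer(1), "precursor_charge")
  mz <- if (all(is.na(mzs))) NA_real_ else stats::median(mzs, na.rm = TRUE)
  chg <- chg[!is.na(chg)]
  if (length(chg) == 0L) {
    z <- NA_integer_
  } else {
    tab <- table(chg)
    if (length(tab) > 1L) {
      warning("cluster members have more than one distinct precursor charge",
              call. = FALSE)
    }
    modal <- as.integer(names(tab)[tab == max(tab)])
    z <- min(modal)  # tie to the smaller charge
  }
  list(precursor_mz = mz, precursor_charge = z)
}

#' Generate consensus spectra for a set of clusters
#'
#' Applies one consensus method to every cluster, resolving member
#' identifiers against a spectrum store. With `method = "best"`, clusters
#' in which no member is identified are skipped and counted, since no valid
#' representative exists for them. The returned list carries a run report
#' in attribute `"report"` with `n_clusters_in`, `n_records_out`, and
#' `n_skipped`.
#'
#' @param clusters List of `Cluster` objects.
#' @param store Named list of spectra from [spectrum_store()].
#' @param method `"average"`, `"bin"`, `"most"`, or `"best"`.
#' @param psms `psm_table`; required when `method = "best"`.
#' @param params A [consensus_params()] object.
#' @return List of `ConsensusRecord`, one per processable cluster, in input
#'   order, with attribute `"report"`.
#' @export
generate_consensus <- function(clusters, store,
                               method = c("average", "bin", "most", "best"),
                               psms = NULL,
                               params = consensus_params()) {
  method <- match.arg(method)
  if (method == "best" && is.null(psms)) {
    stop("method 'best' requires a PSM table", call. = FALSE)
  }
  if (params$tie_break == "random") set.seed(params$seed)
  records <- list()
  n_skipped <- 0L
  for (cl in clusters) {
    members <- resolve_members(cl, store)
    n <- length(members)
    rec <- switch(method,
      average = {
        s <- consensus_average(members, params,
          spectrum_id = sprintf("cluster=%s;method=average;size=%d",
                                cl$cluster_id, n))
        consensus_record(cl$cluster_id, "average", s, n)
      },
      bin = {
        s <- consensus_bin(members, params,
          spectrum_id = sprintf("cluster=%s;method=bin;size=%d",
                                cl$cluster_id, n))
        consensus_record(cl$cluster_id, "bin", s, n)
      },
      most = consensus_most(members, params, cluster_id = cl$cluster_id),
      best = {
        ids <- vapply(members, `[[`, character(1), "spectrum_id")
        if (!any(ids %in% psms$spectrum_id)) {
          n_skipped <- n_skipped + 1L
          NULL
        } else {
          consensus_best(members, psms, params, cluster_id = cl$cluster_id)
        }
      })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  attr(records, "report") <- list(n_clusters_in = length(clusters),
                                  n_records_out = length(records),
                                  n_skipped = n_skipped)
  records
}
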