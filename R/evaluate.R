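#' Canonical peptidoform key
#'
#' A peptidoform is a peptide sequence together with the positions and
#' labels of its modifications. Two peptidoforms are equal iff the sequence
#' and the full, order-independent site list match. Mass deltas are not
#' part of the identity; the site label is.
#'
#' @param peptide Amino-acid sequence.
#' @param modifications Data frame with columns `position` and `label`
#'   (as in the `modifications` list-column of a `psm_table`), or `NULL`.
#' @param sequence_only If `TRUE`, collapse identity to the bare sequence.
#' @return A single string usable as an equality key.
#' @export
peptidoform_key <- function(peptide, modifications = NULL,
                            sequence_only = FALSE) {
  if (sequence_only || is.null(modifications) ||
      nrow(modifications) == 0L) {
    return(peptide)
  }
  o <- order(modifications$position, modifications$label)
  paste0(peptide, "|",
         paste(sprintf("%d:%s", modifications$position[o],
                       modifications$label[o]), collapse = "|"))
}

psm_peptidoform_keys <- function(psms, sequence_only = FALSE) {
  vapply(seq_len(nrow(psms)), function(i) {
    peptidoform_key(psms$peptide[i], psms$modifications[[i]],
                    sequence_only = sequence_only)
  }, character(1))
}

#' Majority peptidoform of a cluster
#'
#' Among the cluster's identified members, finds the modal peptidoform and
#' its fraction of identified member PSMs. Unidentified members are
#' excluded from the denominator. Returns no majority when the modal
#' fraction is not strictly greater than 0.5 or when no member is
#' identified.
#'
#' @param cl A `Cluster`.
#' @param member_psms `psm_table` of member identifications, keyed by
#'   spectrum identifier.
#' @param sequence_only Compare bare sequences instead of full
#'   peptidoforms.
#' @return List with `peptidoform` (key string or `NA`), `fraction` (modal
#'   fraction of identified member PSMs, `NA` when none identified), and
#'   `n_identified`.
#' @export
majority_peptidoform <- function(cl, member_psms, sequence_only = FALSE) {
  idx <- match(cl$member_ids, member_psms$spectrum_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    return(list(peptidoform = NA_character_, fraction = NA_real_,
                n_identified = 0L))
  }
  keys <- psm_peptidoform_keys(member_psms[idx, , drop = FALSE],
                               sequence_only = sequence_only)
  tab <- table(keys)
  frac <- max(tab) / length(keys)
  modal <- names(tab)[tab == max(tab)]
  if (frac > 0.5 && length(modal) == 1L) {
    list(peptidoform = modal, fraction = frac,
         n_identified = length(keys))
  } else {
    list(peptidoform = NA_character_, fraction = frac,
         n_identified = length(keys))
  }
}

#' Filter to multispectral clusters with a majority peptidoform
#'
#' Keeps clusters with at least two members and a single peptidoform
#' carried by strictly more than half of the identified member PSMs;
#' singleton clusters and mixed clusters without such a majority are
#' removed. Order is preserved.
#'
#' @inheritParams majority_peptidoform
#' @param clusters List of `Cluster` objects.
#' @return Filtered list of `Cluster` objects.
#' @export
filter_multispectral <- function(clusters, member_psms,
                                 sequence_only = FALSE) {
  keep <- vapply(clusters, function(cl) {
    length(cl$member_ids) >= 2L &&
      !is.na(majority_peptidoform(cl, member_psms,
                                  sequence_only)$peptidoform)
  }, logical(1))
  clusters[keep]
}

#' Classify a cluster's representative against its members
#'
#' The representative of a filtered multispectral cluster is classified by
#' comparing its identification with those of the cluster members:
#' `"majority"` (high quality) when it matches the majority peptidoform;
#' `"minority"` (low quality) when it matches some member's peptidoform but
#' not the majority; `"novel"` (low quality) when it matches no member's
#' peptidoform — possible for BIN and AVERAGE, which synthesize new
#' spectra; `"unidentified"` when the representative has no PSM.
#'
#' @inheritParams majority_peptidoform
#' @param representative_psm One-row slice of a `psm_table` for the
#'   representative spectrum, or `NULL` when unidentified.
#' @return A list of class `ClusterQuality` with fields `cluster_id`,
#'   `n_members`, `majority_peptidoform`, `majority_fraction`, and
#'   `representative_category`.
#' @export
classify_representative <- function(cl, member_psms,
                                    representative_psm = NULL,
                                    sequence_only = FALSE) {
  maj <- majority_peptidoform(cl, member_psms, sequence_only)
  if (is.null(representative_psm) || nrow(representative_psm) == 0L) {
    category <- "unidentified"
  } else {
    rep_key <- peptidoform_key(representative_psm$peptide[1],
                               representative_psm$modifications[[1]],
                               sequence_only = sequence_only)
    idx <- match(cl$member_ids, member_psms$spectrum_id)
    idx <- idx[!is.na(idx)]
    member_keys <- psm_peptidoform_keys(member_psms[idx, , drop = FALSE],
                                        sequence_only = sequence_only)
    category <- if (!is.na(maj$peptidoform) && rep_key == maj$peptidoform) {
      "majority"
    } else if (rep_key %in% member_keys) {
      "minority"
    } else {
      "novel"
    }
  }
  structure(list(cluster_id = cl$cluster_id,
                 n_members = length(cl$member_ids),
                 majority_peptidoform = maj$peptidoform,
                 majority_fraction = maj$fraction,
                 representative_category = category),
            class = "ClusterQuality")
}

#' High/low-quality representative ratios
#'
#' Fractions of each representative category over the clusters whose
#' representative is identified. The high-quality ratio is the `majority`
#' fraction; the low-quality ratio is `minority` plus `novel`; both are
#' also reported split by category. The `unidentified` count is reported
#' but excluded from every denominator.
#'
#' @param qualities List of `ClusterQuality` from
#'   [classify_representative()].
#' @return Named list: per-category fractions (`majority`, `minority`,
#'   `novel`), `high_quality`, `low_quality`, `n_identified`,
#'   `n_unidentified`. Empty input gives an empty list.
#' @export
quality_ratios <- function(qualities) {
  if (length(qualities) == 0L) return(list())
  cats <- vapply(qualities, `[[`, character(1), "representative_category")
  n_unid <- sum(cats == "unidentified")
  ident <- cats[cats != "unidentified"]
  n <- length(ident)
  if (n == 0L) {
    return(list(majority = NA_real_, minority = NA_real_, novel = NA_real_,
                high_quality = NA_real_, low_quality = NA_real_,
                n_identified = 0L, n_unidentified = n_unid))
  }
  frac <- function(cat) sum(ident == cat) / n
  list(majority = frac("majority"),
       minority = frac("minority"),
       novel = frac("novel"),
       high_quality = frac("majority"),
       low_quality = frac("minority") + frac("novel"),
       n_identified = n,
       n_unidentified = n_unid)
}

#' Mean representative score stratified by cluster size
#'
#' Cluster sizes are stratified into the bins {1}, {2}, {3}, {4}, {5},
#' (5,10], (10,20], and (20, Inf): each size up to five has its own
#' stratum, so a size-5 cluster falls in {5}, not (5,10]. Empty strata are
#' emitted with `n = 0` and an undefined mean.
#'
#' @param clusters List of `Cluster` objects.
#' @param representative_psms Table with the representative identification
#'   per cluster; its `spectrum_id` column carries the cluster identifier.
#' @return `data.frame` with columns `size_bin`, `n`, `mean_score`.
#' @export
score_by_cluster_size <- function(clusters, representative_psms) {
  bins <- c("1", "2", "3", "4", "5", "(5,10]", "(10,20]", "(20,Inf)")
  assign_bin <- function(size) {
    if (size <= 5L) as.character(size)
    else if (size <= 10L) "(5,10]"
    else if (size <= 20L) "(10,20]"
    else "(20,Inf)"
  }
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), integer(1))
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  scores <- representative_psms$score[match(ids,
                                            representative_psms$spectrum_id)]
  bin <- vapply(sizes, assign_bin, character(1))
  out <- data.frame(size_bin = bins, n = 0L, mean_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (b in bins) {
    sc <- scores[bin == b & !is.na(scores)]
    out$n[out$size_bin == b] <- length(sc)
    if (length(sc)) out$mean_score[out$size_bin == b] <- mean(sc)
  }
  out
}

#' Compare representative identifications between two methods
#'
#' Over the identifiers present in both tables, PSM pairs are
#' `corroborative` when the two peptidoforms are fully equal,
#' `divergent_site` when the sequences agree but the modification sites
#' differ, and `divergent_peptide` when the sequences differ. The three
#' counts partition the intersection.
#'
#' @param psms_a,psms_b `psm_table`s keyed by a shared
#'   cluster/representative identifier in their `spectrum_id` column.
#' @return List of class `MethodComparison` with `n_common_spectra`,
#'   `corroborative`, `divergent_site`, `divergent_peptide`.
#' @export
compare_methods <- function(psms_a, psms_b) {
  shared <- intersect(psms_a$spectrum_id, psms_b$spectrum_id)
  ia <- match(shared, psms_a$spectrum_id)
  ib <- match(shared, psms_b$spectrum_id)
  keys_a <- psm_peptidoform_keys(psms_a[ia, , drop = FALSE])
  keys_b <- psm_peptidoform_keys(psms_b[ib, , drop = FALSE])
  seq_a <- psms_a$peptide[ia]
  seq_b <- psms_b$peptide[ib]
  corro <- sum(keys_a == keys_b)
  div_site <- sum(seq_a == seq_b & keys_a != keys_b)
  div_pep <- sum(seq_a != seq_b)
  structure(list(n_common_spectra = length(shared),
                 corroborative = corro,
                 divergent_site = div_site,
                 divergent_peptide = div_pep),
            class = "MethodComparison")
}

#' Count modification sites carrying a label
#'
#' Total number of (PSM, position) pairs carrying the given modification
#' label across a table; a PSM with two sites of the label contributes two.
#'
#' @param psms A `psm_table`.
#' @param label Modification label, e.g. `"Phospho"`.
#' @return Integer count.
#' @export
count_mod_sites <- function(psms, label) {
  sum(vapply(psms$modifications, function(m) {
    if (is.null(m) || nrow(m) == 0L) 0L else sum(m$label == label)
  }, integer(1)))
}

#' Tabulate cluster-quality records
#'
#' @param qualities List of `ClusterQuality`.
#' @return `data.frame` with one row per cluster.
#' @export
quality_table <- function(qualities) {
  data.frame(
    cluster_id = vapply(qualities, `[[`, character(1), "cluster_id"),
    n_members = vapply(qualities, `[[`, integer(1), "n_members"),
    majority_peptidoform = vapply(qualities, `[[`, character(1),
                                  "majority_peptidoform"),
    majority_fraction = vapply(qualities, `[[`, numeric(1),
                               "majority_fraction"),
    representative_category = vapply(qualities, `[[`, character(1),
                                     "representative_category"),
    stringsAsFactors = FALSE
  )
}
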