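#' Simulator configuration
#'
#' Describes clusters of replicate spectra of a shared template, with m/z
#' jitter, multiplicative intensity noise, peak dropout, additive
#' low-intensity noise peaks, and optionally one contaminant member drawn
#' from a different template. Defaults describe well-behaved centroided
#' fragment spectra: jitter (0.005 Th) well inside the 0.02 Th consensus
#' bins, 10% peak dropout, 20% intensity coefficient of variation, and 5
#' noise peaks per replicate.
#'
#' @param n_clusters Number of clusters to generate.
#' @param members_per_cluster Integer, or length-2 integer range from which
#'   each cluster's size is drawn uniformly. The default of 5 is the
#'   smallest size at which a single member's peaks fall strictly below
#'   the default 25% occupancy threshold, so that the occupancy filter —
#'   not intensity — is what removes noise peaks from a BIN consensus.
#' @param n_template_peaks Peaks per template spectrum (default 40).
#' @param mz_range Length-2 numeric, fragment m/z range in Thomson
#'   (default 100-1500).
#' @param intensity_log_mean,intensity_log_sd Log-normal parameters of
#'   template peak intensities (defaults 7 and 1: median ~1100 a.u.).
#' @param mz_jitter_sd Standard deviation of Gaussian m/z jitter per
#'   replicate peak, in Thomson (default 0.005).
#' @param intensity_cv Log-sd of the multiplicative log-normal intensity
#'   noise (default 0.2).
#' @param dropout_p Probability a template peak is missing from a replicate
#'   (default 0.1).
#' @param n_noise_peaks Additive uniform-random noise peaks per replicate,
#'   kept below the template's 25th intensity percentile (default 5).
#' @param contamination_fraction Fraction of clusters containing one member
#'   generated from a different template (default 0).
#' @param seed Mandatory integer seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_clusters = 10L,
                       members_per_cluster = 5L,
                       n_template_peaks = 40L,
                       mz_range = c(100, 1500),
                       intensity_log_mean = 7,
                       intensity_log_sd = 1,
                       mz_jitter_sd = 0.005,
                       intensity_cv = 0.2,
                       dropout_p = 0.1,
                       n_noise_peaks = 5L,
                       contamination_fraction = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("sim_config requires an explicit seed", call. = FALSE)
  }
  stopifnot(n_clusters >= 1L, length(mz_range) == 2L,
            mz_range[1] < mz_range[2],
            dropout_p >= 0, dropout_p <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            intensity_cv >= 0, mz_jitter_sd >= 0, n_noise_peaks >= 0L)
  if (length(members_per_cluster) == 1L) {
    members_per_cluster <- rep(as.integer(members_per_cluster), 2L)
  }
  stopifnot(length(members_per_cluster) == 2L,
            members_per_cluster[1] >= 1L,
            members_per_cluster[1] <= members_per_cluster[2])
  structure(list(n_clusters = as.integer(n_clusters),
                 members_per_cluster = as.integer(members_per_cluster),
                 n_template_peaks = as.integer(n_template_peaks),
                 mz_range = as.numeric(mz_range),
                 intensity_log_mean = intensity_log_mean,
                 intensity_log_sd = intensity_log_sd,
                 mz_jitter_sd = mz_jitter_sd,
                 intensity_cv = intensity_cv,
                 dropout_p = dropout_p,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 contamination_fraction = contamination_fraction,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# minimum template peak spacing: 2x the default consensus bin width, so
# adjacent template peaks can never collide in one 0.02 Th bin
template_min_spacing <- 0.04

#' Generate a template spectrum
#'
#' Draws `n_template_peaks` m/z positions uniformly over `mz_range` subject
#' to a minimum adjacent spacing of 0.04 Th (twice the default consensus
#' bin width), with log-normal intensities, and assigns a synthetic
#' peptidoform label. Draws from the current RNG stream; seed via
#' `set.seed()` or use [make_dataset()].
#'
#' @param config A [sim_config()].
#' @param template_id Identifier (also used to derive the peptidoform
#'   label).
#' @return A `Spectrum` with attribute `"peptidoform"`.
#' @export
make_template <- function(config, template_id = "template_1") {
  n <- config$n_template_peaks
  lo <- config$mz_range[1]
  hi <- config$mz_range[2]
  slack <- (hi - lo) - (n - 1L) * template_min_spacing
  if (slack <= 0) {
    stop(sprintf("cannot place %d peaks with %.2f Th spacing in range [%g, %g]",
                 n, template_min_spacing, lo, hi), call. = FALSE)
  }
  # uniform order statistics plus a fixed spacing offset: exact uniform
  # placement conditional on the minimum-gap constraint
  u <- sort(stats::runif(n, 0, slack))
  mz <- lo + u + (seq_len(n) - 1L) * template_min_spacing
  int <- stats::rlnorm(n, meanlog = config$intensity_log_mean,
                       sdlog = config$intensity_log_sd)
  s <- spectrum(template_id, mz = mz, intensity = int,
                precursor_mz = stats::runif(1, 400, 1200),
                precursor_charge = sample(2:3, 1L))
  attr(s, "peptidoform") <- synthetic_peptide(nchar_len = 12L)
  s
}

synthetic_peptide <- function(nchar_len = 12L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(c(sample(aa, nchar_len - 1L, replace = TRUE), "K"), collapse = "")
}

#' Generate a noisy replicate of a template spectrum
#'
#' Each template peak is kept with probability `1 - dropout_p`; kept peaks
#' receive additive Gaussian m/z jitter (`mz_jitter_sd`) and multiplicative
#' log-normal intensity noise (`intensity_cv` as log-sd). `n_noise_peaks`
#' uniform-random peaks are added at intensities below the template's 25th
#' percentile. Draws from the current RNG stream.
#'
#' @param template A `Spectrum` from [make_template()].
#' @param config A [sim_config()].
#' @param replicate_id Identifier for the replicate.
#' @return A `Spectrum`.
#' @export
make_replicate <- function(template, config, replicate_id = "replicate_1") {
  keep <- stats::runif(length(template$mz)) >= config$dropout_p
  mz <- template$mz[keep]
  int <- template$intensity[keep]
  if (length(mz)) {
    mz <- mz + stats::rnorm(length(mz), 0, config$mz_jitter_sd)
    int <- int * stats::rlnorm(length(int), 0, config$intensity_cv)
  }
  k <- config$n_noise_peaks
  if (k > 0L) {
    q25 <- stats::quantile(template$intensity, 0.25, names = FALSE)
    mz <- c(mz, stats::runif(k, config$mz_range[1], config$mz_range[2]))
    int <- c(int, stats::runif(k, 0, q25))
  }
  spectrum(replicate_id, mz = mz, intensity = int,
           precursor_mz = template$precursor_mz,
           precursor_charge = template$precursor_charge)
}

#' Generate a complete synthetic dataset
#'
#' Simulates clusters of replicate spectra, the cluster-assignment table,
#' and a member PSM table, and optionally writes them as MGF, cluster TSV,
#' and PSM TSV. Member PSM scores increase with the member's dot-product
#' similarity to its own template (`score = 100 * similarity + N(0, 2)`),
#' so better replicates score higher. With contamination, affected
#' clusters contain exactly one member replicated from a separate
#' contaminant template and labeled with that template's peptidoform,
#' producing mixed clusters. The entire draw is reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `spectra.mgf`,
#'   `clusters.tsv`, and `psms.tsv` there.
#' @return List with `spectra` (spectrum store), `clusters`, `psms`,
#'   `ground_truth` (per cluster: template, member table with
#'   `is_contaminant` and `peptidoform`), and `paths` (when written).
#' @export
make_dataset <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  n_contam <- round(config$contamination_fraction * config$n_clusters)
  contam_clusters <- if (n_contam > 0)
    sample(config$n_clusters, n_contam) else integer()
  spectra <- list()
  clusters <- vector("list", config$n_clusters)
  psm_rows <- list()
  ground_truth <- list()
  params <- consensus_params()
  for (k in seq_len(config$n_clusters)) {
    cid <- sprintf("c%03d", k)
    template <- make_template(config, template_id = sprintf("%s_tpl", cid))
    n_members <- if (config$members_per_cluster[1] ==
                     config$members_per_cluster[2]) {
      config$members_per_cluster[1]
    } else {
      sample(config$members_per_cluster[1]:config$members_per_cluster[2], 1L)
    }
    contaminated <- k %in% contam_clusters && n_members >= 2L
    contam_idx <- if (contaminated) sample(n_members, 1L) else 0L
    contam_template <- if (contaminated) {
      make_template(config, template_id = sprintf("%s_contam_tpl", cid))
    } else NULL
    member_ids <- character(n_members)
    gt_members <- data.frame(member_id = character(n_members),
                             is_contaminant = logical(n_members),
                             peptidoform = character(n_members),
                             stringsAsFactors = FALSE)
    for (j in seq_len(n_members)) {
      mid <- sprintf("%s_m%02d", cid, j)
      src <- if (j == contam_idx) contam_template else template
      rep_s <- make_replicate(src, config, replicate_id = mid)
      spectra[[length(spectra) + 1L]] <- rep_s
      member_ids[j] <- mid
      sim <- if (length(rep_s$mz)) spectrum_dot_product(rep_s, src, params)
             else 0
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        spectrum_id = mid,
        peptide = attr(src, "peptidoform"),
        modifications = "",
        score = 100 * sim + stats::rnorm(1, 0, 2),
        stringsAsFactors = FALSE)
      gt_members$member_id[j] <- mid
      gt_members$is_contaminant[j] <- (j == contam_idx)
      gt_members$peptidoform[j] <- attr(src, "peptidoform")
    }
    clusters[[k]] <- cluster(cid, member_ids)
    ground_truth[[cid]] <- list(template = template,
                                contaminant_template = contam_template,
                                members = gt_members)
  }
  psm_tab <- do.call(rbind, psm_rows)
  psm_tab$modifications <- lapply(seq_len(nrow(psm_tab)), function(i) {
    data.frame(position = integer(), label = character(),
               mass_delta = numeric(), stringsAsFactors = FALSE)
  })
  psm_tab$q_value <- NA_real_
  psm_tab$is_decoy <- NA
  attr(psm_tab, "score_direction") <- "higher"
  class(psm_tab) <- c("psm_table", "data.frame")
  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop(sprintf("cannot create output dir '%s'", out_dir),
                    call. = FALSE)
    }
    paths <- list(mgf = file.path(out_dir, "spectra.mgf"),
                  clusters = file.path(out_dir, "clusters.tsv"),
                  psms = file.path(out_dir, "psms.tsv"))
    write_mgf(spectra, paths$mgf)
    write_clusters(clusters, paths$clusters)
    write_psms(psm_tab, paths$psms)
  }
  list(spectra = spectrum_store(spectra),
       clusters = clusters,
       psms = psm_tab,
       ground_truth = ground_truth,
       paths = paths)
}
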