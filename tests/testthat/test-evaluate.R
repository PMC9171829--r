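test_that("majority_peptidoform applies the strict >50% rule", {
  cl <- cluster("c1", c("s1", "s2", "s3", "s4"))
  psms <- mk_psms(paste0("s", 1:4), c("P1", "P1", "P1", "P2"), 1:4)
  maj <- majority_peptidoform(cl, psms)
  expect_equal(maj$peptidoform, "P1")
  expect_equal(maj$fraction, 0.75)

  # 2/4 = 0.5 is not > 0.5
  tied <- mk_psms(paste0("s", 1:4), c("P1", "P1", "P2", "P2"), 1:4)
  expect_true(is.na(majority_peptidoform(cl, tied)$peptidoform))

  # no identified members
  none <- mk_psms("other", "P1", 1)
  m0 <- majority_peptidoform(cl, none)
  expect_true(is.na(m0$peptidoform))
  expect_equal(m0$n_identified, 0L)

  # denominator is identified members only: 2/3 of identified > 0.5
  part <- mk_psms(c("s1", "s2", "s3"), c("P1", "P1", "P2"), 1:3)
  mp <- majority_peptidoform(cl, part)
  expect_equal(mp$peptidoform, "P1")
  expect_equal(mp$fraction, 2 / 3)
})

test_that("modification sites are part of peptidoform identity", {
  cl <- cluster("c1", c("s1", "s2"))
  psms <- mk_psms(c("s1", "s2"), c("PEPTIDEK", "PEPTIDEK"), c(1, 2),
                  modifications = list(mk_mods(3), mk_mods(5)))
  # same sequence, different phosphosite: no majority peptidoform
  expect_true(is.na(majority_peptidoform(cl, psms)$peptidoform))
  # sequence-only comparison collapses them
  expect_equal(majority_peptidoform(cl, psms, sequence_only = TRUE)$peptidoform,
               "PEPTIDEK")
})

test_that("filter_multispectral removes singletons and majority-less clusters", {
  clusters <- list(cluster("single", "s1"),
                   cluster("good", paste0("g", 1:4)),
                   cluster("mixed", c("m1", "m2")))
  psms <- mk_psms(c("s1", paste0("g", 1:4), "m1", "m2"),
                  c("P0", "P1", "P1", "P1", "P2", "P3", "P4"), 1:7)
  kept <- filter_multispectral(clusters, psms)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$cluster_id, "good")
})

test_that("classify_representative distinguishes majority/minority/novel/unidentified", {
  cl <- cluster("c1", paste0("s", 1:4))
  psms <- mk_psms(paste0("s", 1:4), c("P1", "P1", "P1", "P2"), 1:4)
  as_rep <- function(pep) mk_psms("rep", pep, 1)
  expect_equal(classify_representative(cl, psms, as_rep("P1"))$representative_category,
               "majority")
  expect_equal(classify_representative(cl, psms, as_rep("P2"))$representative_category,
               "minority")
  expect_equal(classify_representative(cl, psms, as_rep("P9"))$representative_category,
               "novel")
  q <- classify_representative(cl, psms, NULL)
  expect_equal(q$representative_category, "unidentified")
  expect_equal(q$majority_peptidoform, "P1")
  expect_equal(q$majority_fraction, 0.75)
  expect_equal(q$n_members, 4L)
})

test_that("quality_ratios reports fractions over identified representatives", {
  mk_q <- function(cat) structure(list(cluster_id = "c", n_members = 2L,
                                       majority_peptidoform = "P",
                                       majority_fraction = 1,
                                       representative_category = cat),
                                  class = "ClusterQuality")
  r <- quality_ratios(lapply(c("majority", "majority", "minority"), mk_q))
  expect_equal(r$high_quality, 2 / 3)
  expect_equal(r$low_quality, 1 / 3)

  r_all <- quality_ratios(lapply(rep("majority", 5), mk_q))
  expect_equal(r_all$high_quality, 1.0)
  expect_equal(r_all$low_quality, 0.0)

  # unidentified excluded from the denominator
  r_mix <- quality_ratios(lapply(c("majority", "novel", "unidentified"),
                                 mk_q))
  expect_equal(r_mix$high_quality, 0.5)
  expect_equal(r_mix$low_quality, 0.5)
  expect_equal(r_mix$n_unidentified, 1L)

  expect_length(quality_ratios(list()), 0L)
})

test_that("category fractions partition identified clusters and sum to 1", {
  set.seed(31)
  cats <- c("majority", "minority", "novel", "unidentified")
  for (i in 1:10) {
    draw <- sample(cats, sample(3:40, 1), replace = TRUE)
    qs <- lapply(draw, function(cat) {
      structure(list(cluster_id = "c", n_members = 2L,
                     majority_peptidoform = "P", majority_fraction = 1,
                     representative_category = cat),
                class = "ClusterQuality")
    })
    r <- quality_ratios(qs)
    if (r$n_identified > 0) {
      expect_equal(r$majority + r$minority + r$novel, 1, tolerance = 1e-12)
      expect_equal(r$high_quality + r$low_quality, 1, tolerance = 1e-12)
    }
    expect_equal(r$n_identified + r$n_unidentified, length(draw))
  }
})

test_that("score_by_cluster_size uses the stated strata boundaries", {
  clusters <- list(cluster("a", "s1"), cluster("b", "s2"),
                   cluster("c", c("s3", "s4")))
  reps <- mk_psms(c("a", "b", "c"), rep("P", 3), c(10, 20, 30))
  tab <- score_by_cluster_size(clusters, reps)
  expect_equal(tab$n[tab$size_bin == "1"], 2L)
  expect_equal(tab$mean_score[tab$size_bin == "1"], 15)
  expect_equal(tab$n[tab$size_bin == "2"], 1L)
  expect_equal(tab$mean_score[tab$size_bin == "2"], 30)
  expect_equal(sum(tab$n), 3L)

  # boundary sizes: 5 has its own stratum; 6 and 10 in (5,10]; 21 beyond 20
  big <- list(cluster("p", paste0("p", 1:5)),
              cluster("q", paste0("q", 1:6)),
              cluster("r", paste0("r", 1:10)),
              cluster("t", paste0("t", 1:21)))
  reps2 <- mk_psms(c("p", "q", "r", "t"), rep("P", 4), c(1, 2, 3, 4))
  tab2 <- score_by_cluster_size(big, reps2)
  expect_equal(tab2$n[tab2$size_bin == "5"], 1L)
  expect_equal(tab2$n[tab2$size_bin == "(5,10]"], 2L)
  expect_equal(tab2$n[tab2$size_bin == "(20,Inf)"], 1L)
  # empty strata emitted with n = 0 and undefined mean
  expect_equal(tab2$n[tab2$size_bin == "3"], 0L)
  expect_true(is.na(tab2$mean_score[tab2$size_bin == "3"]))
})

test_that("compare_methods partitions the shared identifiers", {
  ids <- paste0("c", 1:10)
  mods_a <- c(replicate(7, mk_mods(3), simplify = FALSE),
              replicate(2, mk_mods(3), simplify = FALSE),
              list(mk_mods(3)))
  mods_b <- c(replicate(7, mk_mods(3), simplify = FALSE),
              replicate(2, mk_mods(5), simplify = FALSE),
              list(mk_mods(3)))
  peps_a <- c(rep("PEPTIDEK", 9), "AAAAAAAK")
  peps_b <- c(rep("PEPTIDEK", 9), "CCCCCCCK")
  a <- mk_psms(ids, peps_a, 1:10, modifications = mods_a)
  b <- mk_psms(c(ids, "extra"), c(peps_b, "DDDK"), 1:11,
               modifications = c(mods_b, list(mk_mods(integer()))))
  cmp <- compare_methods(a, b)
  expect_equal(cmp$n_common_spectra, 10L)
  expect_equal(cmp$corroborative, 7L)
  expect_equal(cmp$divergent_site, 2L)
  expect_equal(cmp$divergent_peptide, 1L)
  expect_equal(cmp$corroborative + cmp$divergent_site +
                 cmp$divergent_peptide, cmp$n_common_spectra)

  # symmetry: swapping the tables leaves all counts unchanged
  swapped <- compare_methods(b, a)
  expect_equal(swapped$corroborative, cmp$corroborative)
  expect_equal(swapped$divergent_site, cmp$divergent_site)
  expect_equal(swapped$divergent_peptide, cmp$divergent_peptide)

  # same-site different-sequence hand cases
  x <- mk_psms("c1", "PEPTIDEK", 1, modifications = list(mk_mods(3)))
  y <- mk_psms("c1", "PEPTIDEK", 1, modifications = list(mk_mods(5)))
  expect_equal(compare_methods(x, y)$divergent_site, 1L)
  expect_equal(compare_methods(x, x)$corroborative, 1L)
})

test_that("count_mod_sites counts (PSM, position) pairs with the label", {
  psms <- mk_psms(c("s1", "s2", "s3"), rep("PEPTIDEK", 3), 1:3,
                  modifications = list(mk_mods(c(3, 7)),
                                       mk_mods(integer()),
                                       mk_mods(2, label = "Oxidation",
                                               delta = 15.9949)))
  expect_equal(count_mod_sites(psms, "Phospho"), 2L)
  expect_equal(count_mod_sites(psms, "Oxidation"), 1L)
  expect_equal(count_mod_sites(psms, "Acetyl"), 0L)
})

test_that("forced-majority representatives give high-quality ratio 1 for BEST and MOST", {
  # pure clusters: every member carries the template peptidoform, so any
  # selected member is a majority representative
  ds <- make_dataset(sim_config(n_clusters = 12, members_per_cluster = 4,
                                seed = 55))
  filtered <- filter_multispectral(ds$clusters, ds$psms)
  expect_length(filtered, 12L)
  for (method in c("best", "most")) {
    recs <- generate_consensus(ds$clusters, ds$spectra, method,
                               psms = ds$psms)
    qs <- lapply(seq_along(filtered), function(i) {
      rep_id <- recs[[i]]$source_member_id
      rep_row <- ds$psms[match(rep_id, ds$psms$spectrum_id), ,
                         drop = FALSE]
      classify_representative(filtered[[i]], ds$psms, rep_row)
    })
    expect_equal(quality_ratios(qs)$high_quality, 1.0)
  }
})

test_that("selected non-contaminant members are always majority representatives", {
  ds <- make_dataset(sim_config(n_clusters = 20, members_per_cluster = 4,
                                contamination_fraction = 0.25, seed = 12))
  filtered <- filter_multispectral(ds$clusters, ds$psms)
  for (method in c("best", "most")) {
    recs <- generate_consensus(ds$clusters, ds$spectra, method,
                               psms = ds$psms)
    by_id <- stats::setNames(recs,
      vapply(recs, `[[`, character(1), "cluster_id"))
    for (cl in filtered) {
      rec <- by_id[[cl$cluster_id]]
      gt <- ds$ground_truth[[cl$cluster_id]]$members
      contam <- gt$is_contaminant[match(rec$source_member_id,
                                        gt$member_id)]
      rep_row <- ds$psms[match(rec$source_member_id,
                               ds$psms$spectrum_id), , drop = FALSE]
      q <- classify_representative(cl, ds$psms, rep_row)
      if (!contam) {
        expect_equal(q$representative_category, "majority")
      }
    }
  }
})

test_that("raising contamination cannot raise the expected high-quality ratio", {
  ratio_at <- function(contam, seed) {
    ds <- make_dataset(sim_config(n_clusters = 40,
                                  members_per_cluster = 4,
                                  contamination_fraction = contam,
                                  seed = seed))
    filtered <- filter_multispectral(ds$clusters, ds$psms)
    recs <- generate_consensus(ds$clusters, ds$spectra, "best",
                               psms = ds$psms)
    by_id <- stats::setNames(recs,
      vapply(recs, `[[`, character(1), "cluster_id"))
    qs <- lapply(filtered, function(cl) {
      rec <- by_id[[cl$cluster_id]]
      rep_row <- ds$psms[match(rec$source_member_id,
                               ds$psms$spectrum_id), , drop = FALSE]
      classify_representative(cl, ds$psms, rep_row)
    })
    quality_ratios(qs)$high_quality
  }
  seeds <- c(101, 202, 303)
  means <- vapply(c(0, 0.5, 1),
                  function(ct) mean(vapply(seeds, function(s)
                    ratio_at(ct, s), numeric(1))),
                  numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})
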