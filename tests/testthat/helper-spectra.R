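# Small builders and independent oracles shared across test files.

mk_spec <- function(id, mz, int = rep(1, length(mz)),
                    pmz = 500.25, z = 2L) {
  spectrum(id, mz = mz, intensity = int, precursor_mz = pmz,
           precursor_charge = z)
}

# In-memory PSM table compatible with read_psms() output.
mk_psms <- function(spectrum_id, peptide, score,
                    modifications = NULL, direction = "higher") {
  n <- length(spectrum_id)
  if (is.null(modifications)) {
    modifications <- replicate(n, data.frame(
      position = integer(), label = character(),
      mass_delta = numeric(), stringsAsFactors = FALSE),
      simplify = FALSE)
  }
  tab <- data.frame(spectrum_id = spectrum_id, peptide = peptide,
                    score = score, q_value = NA_real_, is_decoy = NA,
                    stringsAsFactors = FALSE)
  tab$modifications <- modifications
  attr(tab, "score_direction") <- direction
  class(tab) <- c("psm_table", "data.frame")
  tab
}

mk_mods <- function(positions, label = "Phospho", delta = 79.9663) {
  data.frame(position = as.integer(positions),
             label = rep(label, length(positions)),
             mass_delta = rep(delta, length(positions)),
             stringsAsFactors = FALSE)
}

# Independent dot-product oracle: explicit dense vectors over the union of
# occupied grid bins, plain loops, no shared code path with the package.
oracle_dot <- function(a, b, width = 0.02) {
  bins <- sort(unique(c(floor(a$mz / width), floor(b$mz / width))))
  va <- vb <- numeric(length(bins))
  ka <- match(floor(a$mz / width), bins)
  kb <- match(floor(b$mz / width), bins)
  for (i in seq_along(ka)) va[ka[i]] <- va[ka[i]] + a$intensity[i]
  for (i in seq_along(kb)) vb[kb[i]] <- vb[kb[i]] + b$intensity[i]
  sum((va / sqrt(sum(va^2))) * (vb / sqrt(sum(vb^2))))
}

# Brute-force medoid: full pairwise similarity matrix, row sums minus the
# diagonal, scan for the maximum (first_id tie-break).
oracle_most_pick <- function(members, width = 0.02) {
  n <- length(members)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- oracle_dot(members[[i]], members[[j]], width)
    }
  }
  sums <- rowSums(S) - diag(S)
  best <- which(sums >= max(sums) - 1e-12)
  ids <- vapply(members[best], `[[`, character(1), "spectrum_id")
  members[[best[order(ids)[1]]]]$spectrum_id
}

# Linear scan-for-extremum oracle for best-identified selection.
oracle_best_pick <- function(members, psms, direction = "higher") {
  best_id <- NA_character_
  best_score <- NA_real_
  for (s in members) {
    i <- match(s$spectrum_id, psms$spectrum_id)
    if (is.na(i)) next
    sc <- psms$score[i]
    better <- is.na(best_score) ||
      (direction == "higher" && sc > best_score) ||
      (direction == "lower" && sc < best_score) ||
      (sc == best_score && s$spectrum_id < best_id)
    if (better) {
      best_id <- s$spectrum_id
      best_score <- sc
    }
  }
  best_id
}

expect_spectrum_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$mz, b$mz, tolerance = tol)
  expect_equal(a$intensity, b$intensity, tolerance = tol)
}
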