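#' Read an MGF peak list
#'
#' Parses a Mascot Generic Format file into a list of [spectrum()] objects.
#' One spectrum is produced per `BEGIN IONS`/`END IONS` block. The spectrum
#' identifier is the `TITLE` value when present, otherwise
#' `"<basename>:index=<k>"` with `k` the 1-based block ordinal. Peaks are
#' sorted by m/z on load; zero-intensity peaks are retained.
#'
#' @param path Path to an MGF file.
#' @return List of `Spectrum` objects, in file order.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  base <- basename(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  ordinal <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      ordinal <- ordinal + 1L
      begin_line <- i
      title <- NULL
      pepmass <- NA_real_
      charge <- NA_integer_
      rt <- NA_real_
      mz <- numeric()
      int <- numeric()
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        l <- trimws(lines[i])
        if (l == "END IONS") {
          closed <- TRUE
          break
        } else if (l == "" || startsWith(l, "#")) {
          # skip
        } else if (grepl("=", l, fixed = TRUE)) {
          key <- toupper(sub("=.*$", "", l))
          val <- sub("^[^=]*=", "", l)
          if (key == "TITLE") {
            title <- val
          } else if (key == "PEPMASS") {
            pepmass <- suppressWarnings(
              as.numeric(strsplit(trimws(val), "[ \t]+")[[1]][1]))
            if (is.na(pepmass)) {
              stop(sprintf("%s: line %d: unparseable PEPMASS '%s'",
                           base, i, val), call. = FALSE)
            }
          } else if (key == "CHARGE") {
            charge <- parse_mgf_charge(val)
          } else if (key == "RTINSECONDS") {
            rt <- suppressWarnings(as.numeric(val))
          }
          # other headers ignored
        } else {
          tok <- strsplit(l, "[ \t]+")[[1]]
          vals <- suppressWarnings(as.numeric(tok[1:2]))
          if (length(tok) < 2L || any(is.na(vals))) {
            stop(sprintf("%s: line %d: malformed peak line '%s'",
                         base, i, l), call. = FALSE)
          }
          mz <- c(mz, vals[1])
          int <- c(int, vals[2])
        }
        i <- i + 1L
      }
      if (!closed) {
        stop(sprintf("%s: line %d: BEGIN IONS without matching END IONS",
                     base, begin_line), call. = FALSE)
      }
      id <- if (!is.null(title) && nzchar(title)) title else
        sprintf("%s:index=%d", base, ordinal)
      spectra[[length(spectra) + 1L]] <-
        spectrum(id, mz = mz, intensity = int, precursor_mz = pepmass,
                 precursor_charge = charge, retention_time = rt)
    } else if (line != "" && !startsWith(line, "#")) {
      stop(sprintf("%s: line %d: content outside BEGIN IONS/END IONS: '%s'",
                   base, i, line), call. = FALSE)
    }
    i <- i + 1L
  }
  spectra
}

parse_mgf_charge <- function(val) {
  v <- trimws(val)
  v <- strsplit(v, "[ \t,]+")[[1]][1]  # first charge if a list
  z <- suppressWarnings(as.integer(sub("[+-]$", "", v)))
  if (is.na(z)) NA_integer_ else abs(z)
}

#' Write spectra or consensus records as MGF
#'
#' m/z values are written with 4 decimal places and intensities with 4
#' significant digits. For [consensus_record()] inputs the `TITLE` line
#' encodes `cluster=<cluster_id>;method=<method>;size=<n_members>`.
#'
#' @param spectra List of `Spectrum` and/or `ConsensusRecord` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    if (inherits(s, "ConsensusRecord")) {
      title <- sprintf("cluster=%s;method=%s;size=%d",
                       s$cluster_id, s$method, s$n_members)
      s <- s$spectrum
    } else {
      title <- s$spectrum_id
    }
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", title), con)
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.4f", s$precursor_mz), con)
    }
    if (!is.na(s$precursor_charge)) {
      writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    }
    if (!is.na(s$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.4f", s$retention_time), con)
    }
    if (length(s$mz)) {
      writeLines(sprintf("%.4f %s", s$mz, format_intensity(s$intensity)),
                 con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

# 4 significant digits, plain decimal notation
format_intensity <- function(x) {
  formatC(signif(x, 4), format = "fg", flag = "#", digits = 4, width = 1)
}

#' Read cluster assignments
#'
#' Two dialects are supported. `"tsv"` is a normalized table with header
#' `cluster_id<TAB>spectrum_id` and one row per member. `"maracluster"` is
#' the blank-line-delimited format of common clustering tools: clusters are
#' separated by blank lines and each member line is `<file><TAB><scan>`;
#' member ids become `"<basename(file)>:scan=<scan>"` and cluster ids
#' `"cluster_<k>"` (1-based file order).
#'
#' @param path Path to the cluster file.
#' @param dialect `"tsv"` or `"maracluster"`.
#' @param id_map Optional path to a two-column TSV (header `from<TAB>to`)
#'   remapping member spectrum identifiers after parsing.
#' @return List of `Cluster` objects in file order; singletons retained.
#' @export
read_clusters <- function(path, dialect = c("tsv", "maracluster"),
                          id_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  clusters <- if (dialect == "tsv") read_clusters_tsv(path)
              else read_clusters_maracluster(path)
  if (!is.null(id_map)) {
    map <- utils::read.delim(id_map, colClasses = "character")
    if (!all(c("from", "to") %in% names(map))) {
      stop("id map must have columns 'from' and 'to'", call. = FALSE)
    }
    lut <- stats::setNames(map$to, map$from)
    clusters <- lapply(clusters, function(cl) {
      hit <- cl$member_ids %in% names(lut)
      cl$member_ids[hit] <- unname(lut[cl$member_ids[hit]])
      cl
    })
  }
  all_ids <- unlist(lapply(clusters, `[[`, "member_ids"))
  if (anyDuplicated(all_ids)) {
    dup <- all_ids[duplicated(all_ids)][1]
    stop(sprintf("spectrum '%s' appears in more than one cluster (a spectrum belongs to exactly one cluster)",
                 dup), call. = FALSE)
  }
  clusters
}

read_clusters_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (nrow(tab) == 0L) return(list())
  if (!all(c("cluster_id", "spectrum_id") %in% names(tab))) {
    stop("cluster TSV must have columns 'cluster_id' and 'spectrum_id'",
         call. = FALSE)
  }
  ids <- unique(tab$cluster_id)  # preserve file order
  lapply(ids, function(cid) {
    cluster(cid, tab$spectrum_id[tab$cluster_id == cid])
  })
}

read_clusters_maracluster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  block <- cumsum(c(TRUE, blank[-length(blank)])) # block index per line
  keep <- !blank
  if (!any(keep)) return(list())
  groups <- split(lines[keep], block[keep])
  clusters <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    members <- vapply(groups[[k]], function(l) {
      tok <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(tok) < 2L) {
        stop(sprintf("malformed cluster member line: '%s'", l),
             call. = FALSE)
      }
      sprintf("%s:scan=%s", basename(tok[1]), trimws(tok[2]))
    }, character(1), USE.NAMES = FALSE)
    clusters[[k]] <- cluster(sprintf("cluster_%d", k), members)
  }
  clusters
}

#' Read a peptide-spectrum match table
#'
#' Reads a TSV with mandatory columns `spectrum_id`, `peptide`, `score` and
#' optional columns `modifications` (semicolon-separated `pos:label:delta`
#' tokens, position 1-based or 0 for the N-terminus), `q_value`, and
#' `is_decoy`. A pragma line `#score_direction=higher|lower` before the
#' header sets the score orientation (default `"higher"`). When a
#' `spectrum_id` is duplicated only the better-scoring row is kept (rank-1
#' semantics), ties broken by first occurrence.
#'
#' @param path Path to the PSM TSV.
#' @return A `data.frame` of class `psm_table` keyed by `spectrum_id`, with
#'   a `modifications` list-column and attribute `score_direction`.
#' @export
read_psms <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  direction <- "higher"
  pragma <- grepl("^#score_direction=", lines)
  if (any(pragma)) {
    direction <- sub("^#score_direction=", "", lines[which(pragma)[1]])
    if (!direction %in% c("higher", "lower")) {
      stop(sprintf("invalid score_direction '%s'", direction), call. = FALSE)
    }
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character")
  needed <- c("spectrum_id", "peptide", "score")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop(sprintf("PSM table missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab$score <- as.numeric(tab$score)
  tab$q_value <- if ("q_value" %in% names(tab))
    as.numeric(tab$q_value) else rep(NA_real_, nrow(tab))
  tab$is_decoy <- if ("is_decoy" %in% names(tab))
    as.logical(tab$is_decoy) else rep(NA, nrow(tab))
  mod_str <- if ("modifications" %in% names(tab)) tab$modifications
             else rep("", nrow(tab))
  tab$modifications <- lapply(seq_len(nrow(tab)), function(i) {
    parse_modifications(mod_str[i], tab$peptide[i])
  })
  # rank-1: keep best row per spectrum_id, first occurrence on ties
  if (nrow(tab) > 1L) {
    key <- if (direction == "higher") -tab$score else tab$score
    o <- order(key)  # order() is stable: ties keep file order
    tab <- tab[o, , drop = FALSE]
    tab <- tab[!duplicated(tab$spectrum_id), , drop = FALSE]
    tab <- tab[order(match(tab$spectrum_id, unique(tab$spectrum_id))), ,
               drop = FALSE]
  }
  rownames(tab) <- NULL
  tab <- tab[, c("spectrum_id", "peptide", "modifications", "score",
                 "q_value", "is_decoy")]
  attr(tab, "score_direction") <- direction
  class(tab) <- c("psm_table", "data.frame")
  tab
}

parse_modifications <- function(s, peptide) {
  empty <- data.frame(position = integer(), label = character(),
                      mass_delta = numeric(), stringsAsFactors = FALSE)
  if (is.na(s) || !nzchar(trimws(s))) return(empty)
  toks <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- lapply(toks, function(tok) {
    f <- strsplit(tok, ":", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(f[1]))
    delta <- suppressWarnings(as.numeric(f[3]))
    if (length(f) != 3L || is.na(pos) || is.na(delta)) {
      stop(sprintf("unparseable modification token '%s'", tok),
           call. = FALSE)
    }
    if (pos < 0L || pos > nchar(peptide)) {
      stop(sprintf("modification position %d outside peptide '%s'",
                   pos, peptide), call. = FALSE)
    }
    data.frame(position = pos, label = f[2], mass_delta = delta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(parts, list(empty)))
}

#' Write a PSM table as TSV
#'
#' Inverse of [read_psms()]: writes the `#score_direction=` pragma, the
#' header, and one row per PSM with modifications serialized as
#' semicolon-separated `pos:label:delta` tokens.
#'
#' @param psms A `psm_table` (or compatible data.frame).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_psms <- function(psms, path) {
  direction <- attr(psms, "score_direction")
  if (is.null(direction)) direction <- "higher"
  mods <- vapply(psms$modifications, function(m) {
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(sprintf("%d:%s:%.4f", m$position, m$label, m$mass_delta),
          collapse = ";")
  }, character(1))
  out <- data.frame(spectrum_id = psms$spectrum_id,
                    peptide = psms$peptide,
                    modifications = mods,
                    score = psms$score,
                    q_value = psms$q_value,
                    is_decoy = psms$is_decoy,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#score_direction=%s", direction), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write cluster assignments as normalized TSV
#'
#' @param clusters List of `Cluster` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, spectrum_id = cl$member_ids,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = character(), spectrum_id = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
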