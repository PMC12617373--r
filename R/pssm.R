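#' Position-specific scoring matrix (PSSM) container
#'
#' A PSSM holds, for every position of a query/reference sequence, the
#' relative frequency of each of the 20 amino acids, the corresponding
#' log-odds scores, and the per-position information content. Downstream
#' statistics use only the frequency matrix; log-odds are kept because the
#' psiblast file dialect carries them and their scale is dialect-dependent.
#'
#' @param query Character vector of query residues (length L).
#' @param freq L x 20 numeric matrix of relative frequencies (columns in
#'   alphabetical one-letter order).
#' @param logodds L x 20 numeric matrix of log-odds scores.
#' @param info Numeric vector of per-position information content, bits.
#' @param n_effective Number of sequences contributing (NA when unknown).
#' @param logodds_units Scale of `logodds` (`"bits"` when computed here,
#'   `"file"` when copied verbatim from a psiblast file).
#' @param source Where the matrices came from.
#' @param percent Optional raw weighted-percentage matrix as read from a
#'   psiblast file (preserved so writing the PSSM back reproduces it exactly).
#' @param weights Optional per-position relative-weight column from the file.
#' @param low_coverage Optional logical vector flagging positions whose
#'   alignment column had a gap fraction above the configured threshold.
#' @return An object of class `fsa_pssm`.
#' @export
new_pssm <- function(query, freq, logodds, info,
                     n_effective = NA_real_,
                     logodds_units = "bits",
                     source = "constructed",
                     percent = NULL,
                     weights = NULL,
                     low_coverage = NULL) {
  L <- length(query)
  stopifnot(
    nrow(freq) == L, ncol(freq) == 20L,
    nrow(logodds) == L, ncol(logodds) == 20L,
    length(info) == L
  )
  dimnames(freq) <- list(seq_len(L), AA_ALPHABET)
  dimnames(logodds) <- list(seq_len(L), AA_ALPHABET)
  if (!is.null(percent)) dimnames(percent) <- list(seq_len(L), AA_ALPHABET)
  structure(
    list(
      query = query,
      position = seq_len(L),
      freq = freq,
      logodds = logodds,
      info = info,
      n_effective = n_effective,
      logodds_units = logodds_units,
      source = source,
      percent = percent,
      weights = weights,
      low_coverage = low_coverage
    ),
    class = "fsa_pssm"
  )
}

#' @export
print.fsa_pssm <- function(x, ...) {
  cat(sprintf(
    "<fsa_pssm> %d positions (source: %s; n_effective: %s; mean info %.2f bits)\n",
    length(x$query), x$source,
    ifelse(is.na(x$n_effective), "unknown", format(x$n_effective)),
    mean(x$info)
  ))
  invisible(x)
}

#' Number of positions in a PSSM
#' @param pssm An [new_pssm()] object.
#' @return Integer length.
#' @export
pssm_length <- function(pssm) length(pssm$query)

#' @export
tidy.fsa_pssm <- function(x, ...) {
  tibble(
    position = rep(x$position, each = 20L),
    query = rep(x$query, each = 20L),
    aa = rep(AA_ALPHABET, times = length(x$query)),
    freq = as.vector(t(x$freq)),
    logodds = as.vector(t(x$logodds)),
    info = rep(x$info, each = 20L)
  )
}

#' @export
glance.fsa_pssm <- function(x, ...) {
  tibble(
    n_positions = length(x$query),
    n_effective = x$n_effective,
    mean_info = mean(x$info),
    logodds_units = x$logodds_units,
    source = x$source
  )
}

#' Build a PSSM from an alignment
#'
#' Alignment columns that are gapped in the reference sequence are dropped so
#' that positions are anchored to the reference, matching the query-anchored
#' convention of psiblast PSSM files. At each remaining column, gaps and
#' unknown residues ('X') in the other rows are excluded from the counts.
#'
#' @param aln An [alignment()].
#' @param pseudocount Non-negative pseudocount mass added via the background
#'   distribution: `p_i(a) = (count_a + pseudocount * background_a) /
#'   (n_i + pseudocount)` with `n_i` the usable characters in the column.
#'   Default 1, which keeps every frequency strictly positive.
#' @param background Length-20 amino-acid background distribution (alphabetical
#'   order), summing to 1. Default uniform.
#' @param gap_threshold Columns whose unusable (gap/X) fraction exceeds this
#'   are flagged `low_coverage` but still computed. Default 0.5.
#' @return An `fsa_pssm` with `logodds = log2(freq / background)` (bits) and
#'   `info` = log2(20) minus the Shannon entropy of the frequency row, bits.
#' @export
#' @examples
#' aln <- alignment(c("r", "s1", "s2"), c("MKV", "MRV", "MKV"))
#' pssm_from_alignment(aln)
pssm_from_alignment <- function(aln, pseudocount = 1,
                                background = rep(1 / 20, 20),
                                gap_threshold = 0.5) {
  if (pseudocount < 0) {
    abort("`pseudocount` must be >= 0.", class = "fsa_parameter_error")
  }
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-6 || any(background < 0)) {
    abort("`background` must be a length-20 non-negative vector summing to 1.",
          class = "fsa_parameter_error")
  }
  background <- as.numeric(background)
  mat <- alignment_matrix(aln)
  ref <- mat[attr(aln, "reference_index"), ]
  keep <- ref != "-"
  if (!any(keep)) {
    abort("Reference sequence is all gaps; no positions remain.",
          class = "fsa_input_error")
  }
  cols <- which(keep)
  L <- length(cols)
  counts <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ALPHABET))
  n_usable <- numeric(L)
  for (k in seq_len(L)) {
    col <- mat[, cols[k]]
    col <- col[col != "-" & col != "X"]
    n_usable[k] <- length(col)
    tab <- table(factor(col, levels = AA_ALPHABET))
    counts[k, ] <- as.numeric(tab)
  }
  if (any(n_usable == 0)) {
    abort(
      sprintf("No usable residues at position(s) %s.",
              paste(which(n_usable == 0), collapse = ", ")),
      class = "fsa_undefined_column_error"
    )
  }
  freq <- (counts + pseudocount * matrix(background, L, 20, byrow = TRUE)) /
    (n_usable + pseudocount)
  logodds <- log2(sweep(freq, 2, background, "/"))
  info <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  gap_frac <- 1 - n_usable / nrow(aln)
  new_pssm(
    query = ref[keep],
    freq = freq,
    logodds = logodds,
    info = info,
    n_effective = nrow(aln),
    logodds_units = "bits",
    source = "alignment",
    percent = freq * 100,
    low_coverage = gap_frac > gap_threshold
  )
}

psiblast_banner <- paste(
  "Last position-specific scoring matrix computed, weighted observed",
  "percentages rounded down, information per position, and relative weight",
  "of gapless real matches to pseudocounts"
)

#' Read an ASCII psiblast-dialect PSSM file
#'
#' Parses the standard psiblast text PSSM: a header row of 40 amino-acid
#' column labels followed by one row per query position holding the 20
#' log-odds scores, the 20 weighted observed percentages, the per-position
#' information content and the relative weight. Frequencies are the
#' percentages divided by 100 (renormalised if the printed row does not sum
#' exactly to 100, as psiblast rounds down).
#'
#' @param path Path to the PSSM file.
#' @return An `fsa_pssm`.
#' @export
read_psiblast_pssm <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fsa_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) == 40L && all(tok %in% AA_ALPHABET)) {
      header_at <- i
      break
    }
    if (length(tok) == 20L && all(tok %in% AA_ALPHABET)) {
      abort(
        sprintf("'%s': header has only one 20-column block; the weighted percentage block is missing.", path),
        class = "fsa_format_error"
      )
    }
  }
  if (is.na(header_at)) {
    abort(sprintf("'%s' is not a psiblast-dialect PSSM: 40-column header not found.", path),
          class = "fsa_format_error")
  }
  rows <- list()
  for (i in seq(header_at + 1L, length.out = max(0L, length(lines) - header_at))) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 2L || is.na(suppressWarnings(as.integer(tok[1L])))) break
    if (length(tok) < 43L) {
      abort(
        sprintf("Line %d of '%s': expected 20 log-odds, 20 percentages and an information column; got %d fields.",
                i, path, length(tok)),
        class = "fsa_format_error"
      )
    }
    num <- suppressWarnings(as.numeric(tok[c(3:43, if (length(tok) >= 44L) 44L)]))
    if (anyNA(num)) {
      abort(sprintf("Line %d of '%s': non-numeric matrix cell '%s'.",
                    i, path, tok[2L + which(is.na(num))[1L]]),
            class = "fsa_parse_error")
    }
    rows[[length(rows) + 1L]] <- list(
      position = as.integer(tok[1L]),
      aa = tok[2L],
      values = num
    )
  }
  if (length(rows) == 0L) {
    abort(sprintf("'%s' is truncated: header present but no matrix rows.", path),
          class = "fsa_format_error")
  }
  L <- length(rows)
  query <- vapply(rows, `[[`, character(1), "aa")
  vals <- do.call(rbind, lapply(rows, `[[`, "values"))
  reorder <- match(AA_ALPHABET, PSIBLAST_ORDER)
  logodds <- vals[, 1:20, drop = FALSE][, reorder, drop = FALSE]
  percent <- vals[, 21:40, drop = FALSE][, reorder, drop = FALSE]
  info <- vals[, 41L]
  weights <- if (ncol(vals) >= 42L) vals[, 42L] else rep(NA_real_, L)
  colnames(logodds) <- AA_ALPHABET
  colnames(percent) <- AA_ALPHABET
  rs <- rowSums(percent)
  freq <- percent / 100
  fix <- rs > 0 & abs(rs - 100) > 1e-9
  if (any(fix)) freq[fix, ] <- percent[fix, , drop = FALSE] / rs[fix]
  if (any(rs == 0)) {
    warn(sprintf("%d position(s) have an all-zero percentage row; their frequencies are undefined and left at 0.",
                 sum(rs == 0)))
  }
  new_pssm(
    query = query,
    freq = freq,
    logodds = logodds,
    info = info,
    n_effective = NA_real_,
    logodds_units = "file",
    source = "psiblast_file",
    percent = percent,
    weights = weights
  )
}

fmt_cell <- function(x, width) {
  if (all(abs(x - round(x)) < 1e-9)) {
    formatC(round(x), width = width, format = "d")
  } else {
    formatC(x, width = width + 4L, format = "f", digits = 4)
  }
}

#' Write a PSSM in the ASCII psiblast dialect
#'
#' Cell values round-trip: reading a file and writing it again reproduces the
#' log-odds, percentage and information cells exactly (integer cells stay
#' integers; the raw percentage block read from a file is reused verbatim).
#'
#' @param pssm An `fsa_pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(pssm, path) {
  reorder <- match(PSIBLAST_ORDER, AA_ALPHABET)
  lo <- pssm$logodds[, reorder, drop = FALSE]
  pct <- (pssm$percent %||% (pssm$freq * 100))[, reorder, drop = FALSE]
  weights <- pssm$weights %||% rep(0, length(pssm$query))
  weights[is.na(weights)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", psiblast_banner), con)
  writeLines(
    paste0(
      "          ",
      paste(formatC(PSIBLAST_ORDER, width = 4), collapse = ""),
      paste(formatC(PSIBLAST_ORDER, width = 4), collapse = "")
    ),
    con
  )
  for (i in seq_along(pssm$query)) {
    writeLines(
      paste0(
        formatC(pssm$position[i], width = 5), " ", pssm$query[i], " ",
        paste(fmt_cell(lo[i, ], 3), collapse = " "),
        "  ",
        paste(fmt_cell(pct[i, ], 3), collapse = " "),
        "  ", formatC(pssm$info[i], width = 5, format = "f", digits = 2),
        " ", formatC(weights[i], width = 8, format = "f", digits = 2)
      ),
      con
    )
  }
  writeLines("", con)
  invisible(path)
}

#' Export a PSSM as TSV
#'
#' One row per position: position, query residue, information content,
#' low-coverage flag (if known), then the 20 frequency and 20 log-odds
#' columns.
#'
#' @param pssm An `fsa_pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_tsv <- function(pssm, path) {
  df <- data.frame(
    position = pssm$position,
    query = pssm$query,
    info = pssm$info,
    low_coverage = pssm$low_coverage %||% NA
  )
  freq <- pssm$freq
  colnames(freq) <- paste0("freq_", AA_ALPHABET)
  lo <- pssm$logodds
  colnames(lo) <- paste0("logodds_", AA_ALPHABET)
  utils::write.table(cbind(df, freq, lo), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
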