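#' Per-position physicochemical class enrichment testing
#'
#' For every position and every class, tests whether the class's amino-acid
#' frequencies at that position are enriched relative to the whole-protein
#' baseline, using the Mann-Whitney U test. With
#' `sample_mode = "member"` (the default) the test sample is the set of
#' per-member frequencies at the position, `A = {p_i(a) : a in class}`, and
#' the baseline is the same members' frequencies at every other position
#' (leave-one-out). With `sample_mode = "class_sum"` a single summed class
#' frequency per position is compared against the other positions' sums.
#'
#' The returned map also carries, per position, the information content
#' `I_i`, the Euclidean norm of the class-frequency difference from the
#' baseline mean (`||d_i||`, see [differential_norms()]), and their product
#' `s_i = I_i * ||d_i||`, the score used by [apply_information_filter()].
#' Before filtering, every position is marked `retained`.
#'
#' @param pssm An `fsa_pssm`.
#' @param scheme An `fsa_scheme` (default [default_scheme()]).
#' @param alpha Per-test significance level (default 0.01).
#' @param sample_mode `"member"` or `"class_sum"`.
#' @param alternative `"greater"` (enrichment, default) or `"two_sided"`.
#' @param p_adjust `"none"` (default; the raw-p rule) or any method accepted
#'   by [stats::p.adjust()] such as `"BH"`.
#' @return A tibble of class `fsa_emap` with one row per position x class:
#'   `position`, `query`, `class`, `U`, `p`, `enriched_raw`, `enriched`,
#'   `info`, `diff_norm`, `filter_score`, `retained`. Run parameters are
#'   stored as attributes (see [emap_params()]).
#' @export
test_enrichment <- function(pssm, scheme = default_scheme(),
                            alpha = 0.01,
                            sample_mode = c("member", "class_sum"),
                            alternative = c("greater", "two_sided"),
                            p_adjust = "none") {
  sample_mode <- match.arg(sample_mode)
  alternative <- match.arg(alternative)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "fsa_parameter_error")
  }
  L <- pssm_length(pssm)
  if (L < 5L) {
    abort("At least 5 positions are required for a meaningful baseline.",
          class = "fsa_parameter_error")
  }
  F_mat <- class_freq_matrix(pssm, scheme)
  classes <- names(scheme$classes)
  n_degenerate <- 0L
  rows <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    members <- scheme$classes[[classes[k]]]
    U <- p <- numeric(L)
    if (sample_mode == "member") {
      V <- pssm$freq[, members, drop = FALSE]
      for (i in seq_len(L)) {
        res <- mann_whitney_u(V[i, ], as.vector(V[-i, , drop = FALSE]),
                              alternative = alternative)
        U[i] <- res$U
        p[i] <- res$p
        if (res$degenerate) n_degenerate <- n_degenerate + 1L
      }
    } else {
      v <- F_mat[, k]
      for (i in seq_len(L)) {
        res <- mann_whitney_u(v[i], v[-i], alternative = alternative)
        U[i] <- res$U
        p[i] <- res$p
        if (res$degenerate) n_degenerate <- n_degenerate + 1L
      }
    }
    rows[[k]] <- tibble(
      position = pssm$position,
      query = pssm$query,
      class = classes[k],
      U = U,
      p = p
    )
  }
  if (n_degenerate > 0L) {
    warn(sprintf(
      "%d position-class test(s) had a fully degenerate sample (all values identical); their p was set to 1.",
      n_degenerate
    ))
  }
  out <- dplyr::bind_rows(rows)
  if (!identical(p_adjust, "none")) {
    out$p <- stats::p.adjust(out$p, method = p_adjust)
  }
  dn <- differential_norm_vector(pssm, scheme)
  per_pos <- tibble(
    position = pssm$position,
    info = pssm$info,
    diff_norm = dn,
    filter_score = pssm$info * dn
  )
  out <- dplyr::left_join(out, per_pos, by = "position")
  out$enriched_raw <- out$p < alpha
  out$enriched <- out$enriched_raw
  out$retained <- TRUE
  out <- dplyr::arrange(out, .data$position, match(.data$class, classes))
  class(out) <- c("fsa_emap", class(out))
  attr(out, "params") <- list(
    alpha = alpha,
    sample_mode = sample_mode,
    alternative = alternative,
    p_adjust = p_adjust,
    keep_fraction = 1,
    scheme = scheme$name,
    classes = classes,
    L = L,
    info_source = pssm$source
  )
  out
}

#' Run parameters stored on an enrichment map
#'
#' @param emap An `fsa_emap`.
#' @return Named list of the parameters the map was computed with.
#' @export
emap_params <- function(emap) attr(emap, "params")

## Internal: per-position Euclidean norm of F_i - colMeans(F).
differential_norm_vector <- function(pssm, scheme) {
  F_mat <- class_freq_matrix(pssm, scheme)
  base <- colMeans(F_mat)
  d <- sweep(F_mat, 2, base)
  sqrt(rowSums(d^2))
}

#' Per-position differential class distributions and their norms
#'
#' The baseline class vector is the mean class-frequency vector over all
#' positions; the differential `d_i` is each position's class vector minus
#' that baseline, and `||d_i||` its Euclidean (Frobenius) norm. Because both
#' vectors lie on the probability simplex, `||d_i|| <= sqrt(2)`.
#'
#' @param pssm An `fsa_pssm`.
#' @param scheme An `fsa_scheme`.
#' @return A tibble with `position`, one `d_<class>` column per class, and
#'   `diff_norm`.
#' @export
differential_norms <- function(pssm, scheme = default_scheme()) {
  F_mat <- class_freq_matrix(pssm, scheme)
  base <- colMeans(F_mat)
  d <- sweep(F_mat, 2, base)
  colnames(d) <- paste0("d_", colnames(d))
  dplyr::bind_cols(
    tibble(position = pssm$position),
    as_tibble(d),
    tibble(diff_norm = sqrt(rowSums(d^2)))
  )
}

#' Information-scaled position filter
#'
#' Ranks positions by `s_i = I_i * ||d_i||` (information content times
#' differential-distribution norm) in descending order, retains the top
#' `ceiling(keep_fraction * L)` and revokes the enrichment flags of the
#' rest. The revocation is recorded, not destructive: `enriched_raw` keeps
#' the pre-filter flags. Ties in `s_i` are broken by ascending position so
#' the retained set is deterministic and nested across `keep_fraction`
#' values.
#'
#' @param emap An `fsa_emap` from [test_enrichment()].
#' @param keep_fraction Fraction of positions to retain, in `[0, 1]`.
#' @return The filtered `fsa_emap`.
#' @export
apply_information_filter <- function(emap, keep_fraction = 0.8) {
  if (!is.numeric(keep_fraction) || is.na(keep_fraction) ||
      keep_fraction < 0 || keep_fraction > 1) {
    abort("`keep_fraction` must be in [0, 1].", class = "fsa_parameter_error")
  }
  params <- emap_params(emap)
  pos <- dplyr::distinct(as_tibble(emap)[c("position", "filter_score")])
  ord <- order(-pos$filter_score, pos$position)
  n_keep <- ceiling(keep_fraction * nrow(pos))
  kept <- pos$position[head(ord, n_keep)]
  emap$retained <- emap$position %in% kept
  emap$enriched <- emap$enriched_raw & emap$retained
  params$keep_fraction <- keep_fraction
  attr(emap, "params") <- params
  emap
}

#' Per-position significance summary of an enrichment map
#'
#' A position is significant when at least one class is enriched after
#' filtering (i.e. `enriched` is TRUE for some class and the position was
#' retained).
#'
#' @param emap An `fsa_emap`.
#' @return A tibble with `position`, `query`, `significant`, and a
#'   `classes` list-column of the enriched class names.
#' @export
position_significance <- function(emap) {
  as_tibble(emap) |>
    dplyr::group_by(.data$position, .data$query) |>
    dplyr::summarise(
      significant = any(.data$enriched),
      classes = list(.data$class[.data$enriched]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$position)
}

#' Export an enrichment map as TSV
#'
#' Columns: position, query, class, U, p, enriched, info, diff_norm,
#' filter_score, retained.
#'
#' @param emap An `fsa_emap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emap_tsv <- function(emap, path) {
  cols <- c("position", "query", "class", "U", "p", "enriched",
            "info", "diff_norm", "filter_score", "retained")
  utils::write.table(as.data.frame(emap)[cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
glance.fsa_emap <- function(x, ...) {
  params <- emap_params(x)
  sig <- position_significance(x)
  tibble(
    n_positions = params$L,
    n_significant = sum(sig$significant),
    n_retained = sum(dplyr::distinct(as_tibble(x)[c("position", "retained")])$retained),
    alpha = params$alpha,
    keep_fraction = params$keep_fraction,
    sample_mode = params$sample_mode,
    alternative = params$alternative,
    scheme = params$scheme
  )
}
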