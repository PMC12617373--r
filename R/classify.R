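#' Classify positions from natural and designed enrichment maps
#'
#' Combines the per-position significance of the natural-homolog map and the
#' designed-sequence map into the four-way annotation: *functional* when only
#' the natural set is significant, *adaptable* when only the designed set is,
#' *structural* when both are, *unlabeled* when neither. With
#' `convergence_mode = "same_class"` the structural call additionally
#' requires at least one enriched class shared by both sets; both-significant
#' positions without a shared class stay unlabeled (which preserves the
#' swap symmetry between the two inputs).
#'
#' Positions whose query residue's own class is not among the natural
#' enriched classes are additionally marked `query_deviates`: the position
#' is flagged because of conservation in the homologs while the query itself
#' carries a rarer residue.
#'
#' @param natural,designed `fsa_emap` objects computed on the same positions
#'   with the same scheme.
#' @param convergence_mode `"any"` (default) or `"same_class"`.
#' @param scheme The `fsa_scheme` used (for the `query_deviates` lookup;
#'   default [default_scheme()]).
#' @return A tibble of class `fsa_track` with columns `position`, `query`,
#'   `label`, `natural_classes`, `designed_classes` (comma-joined),
#'   `query_deviates`; metadata in `attr(, "params")`.
#' @export
classify <- function(natural, designed,
                     convergence_mode = c("any", "same_class"),
                     scheme = default_scheme()) {
  convergence_mode <- match.arg(convergence_mode)
  pn <- emap_params(natural)
  pd <- emap_params(designed)
  if (pn$L != pd$L) {
    abort(sprintf("Enrichment maps are incompatible: %d vs %d positions.", pn$L, pd$L),
          class = "fsa_incompatible_error")
  }
  if (!identical(pn$classes, pd$classes)) {
    abort("Enrichment maps use different class schemes.",
          class = "fsa_incompatible_error")
  }
  sn <- position_significance(natural)
  sd <- position_significance(designed)
  shared <- purrr::map2(sn$classes, sd$classes, intersect)
  nat_sig <- sn$significant
  des_sig <- sd$significant
  label <- dplyr::case_when(
    nat_sig & !des_sig ~ "functional",
    !nat_sig & des_sig ~ "adaptable",
    nat_sig & des_sig ~ "structural",
    .default = "unlabeled"
  )
  if (convergence_mode == "same_class") {
    both <- nat_sig & des_sig
    label[both & lengths(shared) == 0L] <- "unlabeled"
  }
  query_class <- scheme_lookup(scheme, sn$query)
  query_deviates <- nat_sig &
    !purrr::map2_lgl(query_class, sn$classes, ~ .x %in% .y)
  out <- tibble(
    position = sn$position,
    query = sn$query,
    label = factor(label, levels = FSA_LABELS),
    natural_classes = purrr::map_chr(sn$classes, paste, collapse = ","),
    designed_classes = purrr::map_chr(sd$classes, paste, collapse = ","),
    query_deviates = query_deviates
  )
  class(out) <- c("fsa_track", class(out))
  attr(out, "params") <- list(
    convergence_mode = convergence_mode,
    scheme = scheme$name,
    natural = pn,
    designed = pd
  )
  out
}

#' Label fractions of an annotation track
#'
#' @param track An `fsa_track`.
#' @return A tibble with `label`, `n` and `percent` (of all positions; the
#'   percentages sum to 100).
#' @export
summarize_fractions <- function(track) {
  as_tibble(track) |>
    dplyr::count(label = factor(.data$label, levels = FSA_LABELS),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
}

#' Amino-acid composition of each annotation label
#'
#' @param track An `fsa_track`.
#' @return A tibble with `label`, `query` (residue), `n` and `percent` of
#'   that label's total. Labels with no positions are absent.
#' @export
composition_by_class <- function(track) {
  as_tibble(track) |>
    dplyr::count(.data$label, .data$query, name = "n") |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$label, dplyr::desc(.data$n))
}

#' Read a key-residue list
#'
#' A two-column TSV (`position`, `name`), with or without a header line.
#'
#' @param path Path to the TSV.
#' @return A tibble with integer `position` and character `name`.
#' @export
read_key_residues <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^position\\b", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          col.names = c("position", "name"),
                          colClasses = c("integer", "character"))
  as_tibble(df)
}

#' Key-residue capture counts
#'
#' Counts how many positions of a literature-derived key-residue list fall
#' into each annotation label — the benchmarking statistic for the pipeline
#' (a key residue is "captured" when labeled functional or structural).
#'
#' @param track An `fsa_track`.
#' @param keys A tibble with columns `position` and `name`
#'   (see [read_key_residues()]).
#' @return A one-row tibble: `n_keys`, `n_functional`, `n_structural`,
#'   `n_adaptable`, `n_unlabeled`, `n_captured`.
#' @export
capture_stats <- function(track, keys) {
  if (nrow(keys) > 0L) {
    if (anyDuplicated(keys$position)) {
      abort("Key-residue positions must be unique.", class = "fsa_input_error")
    }
    bad <- !(keys$position %in% track$position)
    if (any(bad)) {
      abort(
        sprintf("Key residue(s) outside the annotated range: %s.",
                paste(sprintf("%s (position %d)", keys$name[bad], keys$position[bad]),
                      collapse = ", ")),
        class = "fsa_range_error"
      )
    }
  }
  lab <- as.character(track$label[match(keys$position, track$position)])
  tibble(
    n_keys = nrow(keys),
    n_functional = sum(lab == "functional"),
    n_structural = sum(lab == "structural"),
    n_adaptable = sum(lab == "adaptable"),
    n_unlabeled = sum(lab == "unlabeled"),
    n_captured = sum(lab %in% c("functional", "structural"))
  )
}

#' Export an annotation track as TSV
#'
#' @param track An `fsa_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  df <- as.data.frame(track)
  df$label <- as.character(df$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.fsa_track <- function(x, ...) as_tibble(x)

#' @export
glance.fsa_track <- function(x, ...) {
  fr <- summarize_fractions(x)
  out <- tibble(n_positions = nrow(x))
  for (i in seq_len(nrow(fr))) {
    out[[paste0("pct_", as.character(fr$label[i]))]] <- fr$percent[i]
  }
  out$convergence_mode <- attr(x, "params")$convergence_mode
  out
}
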