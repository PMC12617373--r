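#' Define a physicochemical amino-acid class scheme
#'
#' A scheme is a named partition of the 20 standard amino acids into
#' physicochemical classes. The partition is validated: classes must be
#' pairwise disjoint and jointly cover all 20 residues. Class order is fixed
#' at construction so per-position class vectors are comparable across runs.
#'
#' @param classes Named list; each element a character vector of one-letter
#'   codes (a string like `"DE"` is also accepted).
#' @param name Scheme name recorded in output metadata.
#' @return An object of class `fsa_scheme`.
#' @export
#' @examples
#' chem_scheme(list(charged = "DEKR", other = "ACFGHILMNPQSTVWY"), "two-way")
chem_scheme <- function(classes, name = "custom") {
  if (is.null(names(classes)) || any(names(classes) == "")) {
    abort("Every class must be named.", class = "fsa_scheme_error")
  }
  classes <- lapply(classes, function(x) {
    if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
    toupper(x)
  })
  all_members <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    abort(
      sprintf("Classes overlap: %s assigned more than once.",
              paste(unique(all_members[duplicated(all_members)]), collapse = ", ")),
      class = "fsa_scheme_error"
    )
  }
  missing <- setdiff(AA_ALPHABET, all_members)
  extra <- setdiff(all_members, AA_ALPHABET)
  if (length(missing) || length(extra)) {
    abort(
      sprintf("Classes must partition the 20 amino acids exactly.%s%s",
              if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), ".") else "",
              if (length(extra)) paste0(" Unknown: ", paste(extra, collapse = ", "), ".") else ""),
      class = "fsa_scheme_error"
    )
  }
  structure(list(classes = classes, name = name), class = "fsa_scheme")
}

#' The default six-class physicochemical scheme
#'
#' Acidic \{D, E\}, basic \{K, R\}, hydrophilic \{S, T, N, Q, H, C, Y\},
#' hydrophobic \{A, V, L, I, M, F, W\}, glycine \{G\} and proline \{P\}.
#' Histidine is treated as polar rather than basic; cysteine and tyrosine as
#' polar; tryptophan as hydrophobic. Any one-dimensional grouping is a
#' simplification (especially for histidine and the aromatics), so the scheme
#' is an ordinary configuration object that can be replaced wholesale with
#' [chem_scheme()].
#'
#' @return An `fsa_scheme`.
#' @export
#' @examples
#' default_scheme()
default_scheme <- function() {
  chem_scheme(
    list(
      acidic      = c("D", "E"),
      basic       = c("K", "R"),
      hydrophilic = c("S", "T", "N", "Q", "H", "C", "Y"),
      hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
      glycine     = "G",
      proline     = "P"
    ),
    name = "default6"
  )
}

#' @export
print.fsa_scheme <- function(x, ...) {
  cat(sprintf("<fsa_scheme> '%s' with %d classes\n", x$name, length(x$classes)))
  for (cl in names(x$classes)) {
    cat(sprintf("  %-12s %s\n", cl, paste(x$classes[[cl]], collapse = " ")))
  }
  invisible(x)
}

#' Look up the class of an amino acid
#'
#' @param scheme An `fsa_scheme`.
#' @param aa One-letter amino-acid code(s).
#' @return Character vector of class names.
#' @export
#' @examples
#' scheme_lookup(default_scheme(), c("D", "H"))
scheme_lookup <- function(scheme, aa) {
  map <- rep(names(scheme$classes), lengths(scheme$classes))
  names(map) <- unlist(scheme$classes, use.names = FALSE)
  out <- unname(map[toupper(aa)])
  out
}

## L x K numeric matrix of class frequencies (internal workhorse).
class_freq_matrix <- function(pssm, scheme) {
  K <- length(scheme$classes)
  out <- matrix(0, nrow = pssm_length(pssm), ncol = K,
                dimnames = list(NULL, names(scheme$classes)))
  for (k in seq_len(K)) {
    members <- scheme$classes[[k]]
    out[, k] <- rowSums(pssm$freq[, members, drop = FALSE])
  }
  out
}

#' Per-position class frequencies
#'
#' Sums the PSSM amino-acid frequencies over the members of each
#' physicochemical class: `F_i(c) = sum over a in class c of p_i(a)`. Each
#' row sums to 1 because the classes partition the alphabet.
#'
#' @param pssm An `fsa_pssm`.
#' @param scheme An `fsa_scheme` (default [default_scheme()]).
#' @return A tibble with `position`, `query` and one column per class.
#' @export
class_frequencies <- function(pssm, scheme = default_scheme()) {
  mat <- class_freq_matrix(pssm, scheme)
  dplyr::bind_cols(
    tibble(position = pssm$position, query = pssm$query),
    as_tibble(mat)
  )
}

#' Read a class scheme from a YAML file
#'
#' The file maps class names to residue strings, e.g.
#' `acidic: DE` on one line per class. An optional `name` key names the
#' scheme.
#'
#' @param path Path to the YAML file.
#' @return An `fsa_scheme`.
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  name <- raw$name %||% basename(path)
  raw$name <- NULL
  chem_scheme(raw, name = name)
}
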