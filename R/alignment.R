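#' Construct an alignment object
#'
#' An alignment is a rectangular set of equal-length amino-acid sequences
#' (gaps allowed) anchored to one reference sequence whose non-gap columns
#' define the 1-based position coordinate used throughout the package.
#'
#' @param id Character vector of sequence identifiers.
#' @param seq Character vector of aligned sequences (same length strings over
#'   the 20 amino acids, `-` for gaps and `X` for unknowns; lowercase and `.`
#'   are normalised to uppercase and `-`).
#' @param reference_index Integer; which sequence anchors the position
#'   coordinate (default 1).
#' @return A tibble of class `fsa_alignment` with columns `id` and `seq` and
#'   attributes `width` and `reference_index`.
#' @export
#' @examples
#' alignment(c("a", "b", "c"), c("MKV", "MRV", "MKV"))
alignment <- function(id, seq, reference_index = 1L) {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.", class = "fsa_input_error")
  }
  if (length(seq) < 1L) {
    abort("An alignment needs at least one sequence.", class = "fsa_empty_input_error")
  }
  seq <- unname(toupper(seq))
  seq <- gsub(".", "-", seq, fixed = TRUE)
  id <- unname(as.character(id))
  widths <- nchar(seq)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    abort(
      sprintf(
        "Alignment is ragged: record '%s' has width %d but '%s' has width %d.",
        id[bad], widths[bad], id[1L], widths[1L]
      ),
      class = "fsa_width_error"
    )
  }
  bad_char <- regexpr(sprintf("[^-%sX]", paste(AA_ALPHABET, collapse = "")), seq)
  if (any(bad_char > 0L)) {
    rec <- which(bad_char > 0L)[1L]
    col <- bad_char[rec]
    abort(
      sprintf(
        "Illegal character '%s' in record '%s' at column %d (alphabet: 20 amino acids, '-', 'X').",
        substr(seq[rec], col, col), id[rec], col
      ),
      class = "fsa_alphabet_error"
    )
  }
  reference_index <- as.integer(reference_index)
  if (is.na(reference_index) || reference_index < 1L || reference_index > length(seq)) {
    abort(
      sprintf("`reference_index` must be in [1, %d].", length(seq)),
      class = "fsa_input_error"
    )
  }
  out <- tibble(id = as.character(id), seq = seq)
  class(out) <- c("fsa_alignment", class(out))
  attr(out, "width") <- widths[1L]
  attr(out, "reference_index") <- reference_index
  out
}

#' @export
print.fsa_alignment <- function(x, ...) {
  cat(sprintf(
    "<fsa_alignment> %d sequences x %d columns (reference: '%s')\n",
    nrow(x), alignment_width(x), x$id[attr(x, "reference_index")]
  ))
  NextMethod()
}

#' Alignment accessors
#'
#' @param aln An [alignment()].
#' @return `alignment_width()` the number of columns; `reference_sequence()`
#'   the reference row's aligned sequence as a single string.
#' @export
alignment_width <- function(aln) attr(aln, "width")

#' @rdname alignment_width
#' @export
reference_sequence <- function(aln) aln$seq[attr(aln, "reference_index")]

read_fasta_records <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fsa_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      abort(
        sprintf("No FASTA records could be read from '%s': %s", path, conditionMessage(e)),
        class = "fsa_empty_input_error"
      )
    }
  )
  if (length(set) == 0L) {
    abort(sprintf("No FASTA records in '%s'.", path), class = "fsa_empty_input_error")
  }
  tibble(id = names(set), seq = as.character(set))
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_index Which record anchors the position coordinate
#'   (default: the first).
#' @return An [alignment()].
#' @export
read_msa <- function(path, reference_index = 1L) {
  rec <- read_fasta_records(path)
  alignment(rec$id, rec$seq, reference_index = reference_index)
}

#' Read a ProteinMPNN-dialect FASTA file
#'
#' Sequence-design tools such as ProteinMPNN emit multi-chain records whose
#' chains are joined by a separator character (default `/`) and whose headers
#' carry score metadata after the sample name. This reader flattens such a
#' file into a single-chain alignment.
#'
#' @param path Path to the design FASTA file.
#' @param chain_policy How to handle multi-chain records: `"first_chain"`
#'   keeps only the first chain of each record (the default, appropriate for
#'   homodimer designs whose protomers would otherwise be double-counted),
#'   `"concatenate"` joins the chains end to end, `"pool_all_chains"` turns
#'   every chain into its own alignment row.
#' @param chain_separator Single character separating chains (default `/`).
#' @param drop_header_metadata Keep only the first comma- or space-delimited
#'   token of each header (default `TRUE`).
#' @param reference_index Which resulting row anchors positions (default 1).
#' @return An [alignment()].
#' @export
read_mpnn_fasta <- function(path,
                            chain_policy = c("first_chain", "concatenate", "pool_all_chains"),
                            chain_separator = "/",
                            drop_header_metadata = TRUE,
                            reference_index = 1L) {
  chain_policy <- match.arg(chain_policy)
  rec <- read_fasta_records(path)
  ids <- rec$id
  if (drop_header_metadata) ids <- sub("[,[:space:]].*$", "", ids)
  chains <- strsplit(rec$seq, chain_separator, fixed = TRUE)
  if (chain_policy == "first_chain") {
    seqs <- vapply(chains, `[[`, character(1), 1L)
  } else if (chain_policy == "concatenate") {
    seqs <- vapply(chains, paste0, character(1), collapse = "")
  } else {
    n_chain <- lengths(chains)
    ids <- paste0(rep(ids, n_chain), "|chain", unlist(lapply(n_chain, seq_len)))
    seqs <- unlist(chains)
  }
  alignment(ids, seqs, reference_index = reference_index)
}

#' Write an alignment to FASTA
#'
#' @param aln An [alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

## L x width character matrix of an alignment (rows = sequences).
alignment_matrix <- function(aln) {
  mat <- matrix("", nrow = nrow(aln), ncol = alignment_width(aln))
  for (i in seq_len(nrow(aln))) {
    mat[i, ] <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
  }
  mat
}
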