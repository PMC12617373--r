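#' Run the full annotation analysis on a natural/designed input pair
#'
#' The central entry point: takes the natural-homolog branch and the
#' designed-sequence branch (each either an [alignment()] or an `fsa_pssm`),
#' tests per-position class enrichment in each branch independently against
#' its whole-protein baseline, applies the information-scaled norm filter to
#' each branch, and classifies every position as functional, structural,
#' adaptable or unlabeled.
#'
#' @param natural,designed An [alignment()] or `fsa_pssm` for each branch.
#' @param scheme An `fsa_scheme` (default [default_scheme()]).
#' @param alpha Significance level for the per-class Mann-Whitney tests
#'   (default 0.01).
#' @param keep_fraction Fraction of positions retained by the information
#'   filter in each branch (default 0.8). This is the main tunable: it
#'   should be calibrated per protein family, e.g. against known functional
#'   or structural residues, and mostly moves the adaptable count.
#' @param sample_mode,alternative,p_adjust Passed to [test_enrichment()].
#' @param convergence_mode Passed to [classify()].
#' @param pseudocount,background Passed to [pssm_from_alignment()] when an
#'   input is an alignment.
#' @return An object of class `fsa_result`: a list with `track`
#'   (`fsa_track`), `natural_emap`, `designed_emap`, and `params`.
#' @export
#' @examples
#' sim <- simulate_paired_alignments(default_benchmark_spec(seed = 7, L = 40,
#'   n_natural = 60, n_designed = 60, n_per_label = 3))
#' res <- fsa_annotate(sim$natural, sim$designed)
#' summarize_fractions(res$track)
fsa_annotate <- function(natural, designed,
                         scheme = default_scheme(),
                         alpha = 0.01,
                         keep_fraction = 0.8,
                         sample_mode = "member",
                         alternative = "greater",
                         p_adjust = "none",
                         convergence_mode = "any",
                         pseudocount = 1,
                         background = rep(1 / 20, 20)) {
  as_branch_pssm <- function(x, which) {
    if (inherits(x, "fsa_pssm")) return(x)
    if (inherits(x, "fsa_alignment")) {
      return(pssm_from_alignment(x, pseudocount = pseudocount, background = background))
    }
    abort(sprintf("`%s` must be an alignment or a PSSM.", which),
          class = "fsa_input_error")
  }
  pn <- as_branch_pssm(natural, "natural")
  pd <- as_branch_pssm(designed, "designed")
  if (pssm_length(pn) != pssm_length(pd)) {
    abort(
      sprintf("Branch lengths differ: natural has %d positions, designed has %d.",
              pssm_length(pn), pssm_length(pd)),
      class = "fsa_incompatible_error"
    )
  }
  emap_n <- test_enrichment(pn, scheme, alpha = alpha, sample_mode = sample_mode,
                            alternative = alternative, p_adjust = p_adjust) |>
    apply_information_filter(keep_fraction)
  emap_d <- test_enrichment(pd, scheme, alpha = alpha, sample_mode = sample_mode,
                            alternative = alternative, p_adjust = p_adjust) |>
    apply_information_filter(keep_fraction)
  track <- classify(emap_n, emap_d, convergence_mode = convergence_mode,
                    scheme = scheme)
  structure(
    list(
      track = track,
      natural_emap = emap_n,
      designed_emap = emap_d,
      params = list(
        alpha = alpha, keep_fraction = keep_fraction,
        sample_mode = sample_mode, alternative = alternative,
        p_adjust = p_adjust, convergence_mode = convergence_mode,
        pseudocount = pseudocount, scheme = scheme$name
      )
    ),
    class = "fsa_result"
  )
}

#' @export
print.fsa_result <- function(x, ...) {
  fr <- summarize_fractions(x$track)
  cat(sprintf("<fsa_result> %d positions\n", nrow(x$track)))
  for (i in seq_len(nrow(fr))) {
    cat(sprintf("  %-11s %4d (%5.1f%%)\n", as.character(fr$label[i]), fr$n[i], fr$percent[i]))
  }
  invisible(x)
}

#' @export
tidy.fsa_result <- function(x, ...) as_tibble(x$track)

#' @export
glance.fsa_result <- function(x, ...) glance(x$track)

#' Read a run configuration file
#'
#' A flat YAML key-value file; recognised keys are the arguments of
#' [run_pipeline()]. Command-line style overrides win over file values.
#'
#' @param path Path to the YAML file (optional).
#' @param overrides Named list of values overriding the file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  utils::modifyList(cfg, overrides)
}

#' Run the pipeline from a configuration and write all outputs
#'
#' Reads the two branches (exactly one of MSA or PSSM per branch), runs
#' [fsa_annotate()], and writes the annotation TSV, the two enrichment TSVs,
#' a JSON summary echoing every run parameter, and optionally the annotation
#' heatmap. Deterministic given the configuration.
#'
#' @param config Named list (see [read_run_config()]) with keys:
#'   `natural_msa` or `natural_pssm`; `designed_msa` or `designed_pssm`;
#'   optional `alpha` (default 0.01), `keep_fraction` (0.8), `sample_mode`,
#'   `alternative`, `convergence_mode`, `scheme_file`, `keys`,
#'   `mpnn_dialect` (TRUE to read the designed MSA with [read_mpnn_fasta()]),
#'   `chain_policy`, `pseudocount`, `out_prefix` (default `"fsa"`),
#'   `heatmap` (file extension `"png"`, `"pdf"`, `"svg"`, or `"none"`).
#' @return Invisibly, a list with the `fsa_result` and the written `files`.
#' @export
run_pipeline <- function(config) {
  get <- function(key, default = NULL) config[[key]] %||% default
  read_branch <- function(branch) {
    msa_key <- paste0(branch, "_msa")
    pssm_key <- paste0(branch, "_pssm")
    has_msa <- !is.null(config[[msa_key]])
    has_pssm <- !is.null(config[[pssm_key]])
    if (has_msa == has_pssm) {
      abort(sprintf("Provide exactly one of `%s` or `%s`.", msa_key, pssm_key),
            class = "fsa_config_error")
    }
    if (has_pssm) {
      list(input = read_psiblast_pssm(config[[pssm_key]]), path = config[[pssm_key]])
    } else if (branch == "designed" && isTRUE(get("mpnn_dialect", TRUE))) {
      list(input = read_mpnn_fasta(config[[msa_key]],
                                   chain_policy = get("chain_policy", "first_chain")),
           path = config[[msa_key]])
    } else {
      list(input = read_msa(config[[msa_key]]), path = config[[msa_key]])
    }
  }
  nat <- read_branch("natural")
  des <- read_branch("designed")
  scheme <- if (!is.null(get("scheme_file"))) read_scheme(get("scheme_file")) else default_scheme()
  res <- fsa_annotate(
    nat$input, des$input,
    scheme = scheme,
    alpha = get("alpha", 0.01),
    keep_fraction = get("keep_fraction", 0.8),
    sample_mode = get("sample_mode", "member"),
    alternative = get("alternative", "greater"),
    p_adjust = get("p_adjust", "none"),
    convergence_mode = get("convergence_mode", "any"),
    pseudocount = get("pseudocount", 1)
  )
  prefix <- get("out_prefix", "fsa")
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- c(
    annotation = paste0(prefix, "_annotation.tsv"),
    natural_enrichment = paste0(prefix, "_natural_enrichment.tsv"),
    designed_enrichment = paste0(prefix, "_designed_enrichment.tsv"),
    summary = paste0(prefix, "_summary.json")
  )
  write_track_tsv(res$track, files[["annotation"]])
  write_emap_tsv(res$natural_emap, files[["natural_enrichment"]])
  write_emap_tsv(res$designed_emap, files[["designed_enrichment"]])

  summary <- list(
    parameters = c(
      res$params,
      list(
        seed = get("seed", NA),
        natural_input = nat$path,
        designed_input = des$path,
        input_md5 = as.list(tools::md5sum(c(nat$path, des$path))),
        scheme_classes = lapply(scheme$classes, paste, collapse = "")
      )
    ),
    fractions = summarize_fractions(res$track),
    composition = composition_by_class(res$track)
  )
  keys_path <- get("keys")
  if (!is.null(keys_path)) {
    keys <- read_key_residues(keys_path)
    summary$capture <- as.list(capture_stats(res$track, keys))
  }
  jsonlite::write_json(summary, files[["summary"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  heatmap_fmt <- get("heatmap", "png")
  if (!identical(heatmap_fmt, "none")) {
    files[["heatmap"]] <- paste0(prefix, "_heatmap.", heatmap_fmt)
    render_heatmap(res$track, files[["heatmap"]])
  }
  invisible(list(result = res, files = files))
}
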