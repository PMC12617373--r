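#' Specify a synthetic paired-alignment benchmark
#'
#' Describes a pair of alignments (a "natural" and a "designed" set) with
#' planted, ground-truth-labeled class enrichment. Unplanted columns draw
#' residues independently from the background distribution in both sets. A
#' column planted in a set draws, with probability `strength`, a residue
#' uniformly from the target class's members, and otherwise from the
#' background. Planting in the natural set only yields a ground-truth
#' *functional* position, in the designed set only *adaptable*, in both
#' *structural*.
#'
#' @param L Number of positions.
#' @param n_natural,n_designed Sequences per set (each at least 2).
#' @param background Length-20 amino-acid background (alphabetical order),
#'   summing to 1. Default uniform.
#' @param planted Tibble/data frame with columns `position`, `target_class`,
#'   `planted_set` (`"natural"`, `"designed"` or `"both"`) and `strength`
#'   in (0, 1]. Positions must be unique and within `[1, L]`.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `fsa_synth_spec`.
#' @export
synthetic_spec <- function(L, n_natural, n_designed,
                           background = rep(1 / 20, 20),
                           planted = NULL,
                           seed = 1L) {
  if (n_natural < 2L || n_designed < 2L) {
    abort("Each set needs at least 2 sequences.", class = "fsa_parameter_error")
  }
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be length 20 and sum to 1.", class = "fsa_parameter_error")
  }
  if (is.null(planted)) {
    planted <- tibble(position = integer(), target_class = character(),
                      planted_set = character(), strength = numeric())
  }
  planted <- as_tibble(planted)
  if (nrow(planted) > 0L) {
    stopifnot(all(c("position", "target_class", "planted_set", "strength") %in% names(planted)))
    if (anyDuplicated(planted$position)) {
      abort("Planted positions must be unique.", class = "fsa_parameter_error")
    }
    if (any(planted$position < 1L | planted$position > L)) {
      abort("Planted positions must lie within [1, L].", class = "fsa_parameter_error")
    }
    if (any(planted$strength <= 0 | planted$strength > 1)) {
      abort("Planted `strength` must be in (0, 1].", class = "fsa_parameter_error")
    }
    if (!all(planted$planted_set %in% c("natural", "designed", "both"))) {
      abort("`planted_set` must be 'natural', 'designed' or 'both'.",
            class = "fsa_parameter_error")
    }
  }
  structure(
    list(L = as.integer(L), n_natural = as.integer(n_natural),
         n_designed = as.integer(n_designed), background = background,
         planted = planted, seed = as.integer(seed)),
    class = "fsa_synth_spec"
  )
}

#' Default synthetic benchmark conditions
#'
#' 120 positions, 200 sequences per set, planting strength 0.9, and ten
#' planted positions per ground-truth label (functional, adaptable,
#' structural), with target classes cycling through the four multi-member
#' default classes (acidic, basic, hydrophilic, hydrophobic). These are the
#' conditions used by the package's own recovery benchmark.
#'
#' Singleton classes (glycine, proline) are deliberately not planted: in the
#' leave-one-out rank test a singleton class contributes one observation
#' against `L - 1` baseline values, so its smallest attainable p-value is
#' `rank / L`, and when the same singleton class is planted at several
#' positions only the strict maximum can ever clear `alpha = 0.01`. That
#' granularity bound is a property of the test, not of the data, so
#' singleton plants would measure the bound rather than pipeline recovery
#' (see the methods vignette).
#'
#' @param seed Integer seed.
#' @param strength Planting strength (default 0.9).
#' @param n_per_label Planted positions per label type (default 10).
#' @param L,n_natural,n_designed Dimensions (defaults 120, 200, 200).
#' @param target_classes Classes to cycle plants through (default the four
#'   multi-member classes).
#' @return An `fsa_synth_spec`.
#' @export
default_benchmark_spec <- function(seed = 1L, strength = 0.9, n_per_label = 10L,
                                   L = 120L, n_natural = 200L, n_designed = 200L,
                                   target_classes = c("acidic", "basic",
                                                      "hydrophilic", "hydrophobic")) {
  classes <- target_classes
  sets <- rep(c("natural", "designed", "both"), each = n_per_label)
  n_plant <- length(sets)
  stopifnot(n_plant <= L)
  ## Spread plants evenly over the sequence, deterministically.
  positions <- round(seq(1L, L, length.out = n_plant))
  synthetic_spec(
    L = L, n_natural = n_natural, n_designed = n_designed,
    planted = tibble(
      position = as.integer(positions),
      target_class = rep_len(classes, n_plant),
      planted_set = sets,
      strength = strength
    ),
    seed = seed
  )
}

sample_column <- function(n, background, members = NULL, strength = 0) {
  draws <- sample(AA_ALPHABET, n, replace = TRUE, prob = background)
  if (!is.null(members) && strength > 0) {
    use_plant <- stats::runif(n) < strength
    n_plant <- sum(use_plant)
    if (n_plant > 0L) {
      draws[use_plant] <- sample(members, n_plant, replace = TRUE)
    }
  }
  draws
}

#' Simulate a paired natural/designed alignment benchmark
#'
#' Generation is a pure function of the spec (including its seed): the
#' caller's RNG state is saved and restored. Each alignment gets an extra
#' first row, its per-column modal residue, which serves as the gap-free
#' reference anchoring positions 1..L.
#'
#' @param spec An [synthetic_spec()].
#' @return A list with elements `natural` and `designed` ([alignment()]s of
#'   `n_* + 1` rows, reference first) and `truth`, a tibble with `position`
#'   and the expected `label`.
#' @export
simulate_paired_alignments <- function(spec) {
  stopifnot(inherits(spec, "fsa_synth_spec"))
  scheme <- default_scheme()
  withr::with_seed(spec$seed, {
    make_set <- function(n, set_name) {
      cols <- matrix("", nrow = n, ncol = spec$L)
      for (j in seq_len(spec$L)) {
        hit <- which(spec$planted$position == j &
                       spec$planted$planted_set %in% c(set_name, "both"))
        if (length(hit) == 1L) {
          members <- scheme$classes[[spec$planted$target_class[hit]]]
          cols[, j] <- sample_column(n, spec$background, members,
                                     spec$planted$strength[hit])
        } else {
          cols[, j] <- sample_column(n, spec$background)
        }
      }
      seqs <- apply(cols, 1, paste, collapse = "")
      modal <- apply(cols, 2, function(x) names(which.max(table(x))))
      alignment(
        c("reference", paste0(set_name, "_", seq_len(n))),
        c(paste(modal, collapse = ""), seqs),
        reference_index = 1L
      )
    }
    natural <- make_set(spec$n_natural, "natural")
    designed <- make_set(spec$n_designed, "designed")
    truth_label <- rep("unlabeled", spec$L)
    if (nrow(spec$planted) > 0L) {
      truth_label[spec$planted$position] <- dplyr::recode(
        spec$planted$planted_set,
        natural = "functional", designed = "adaptable", both = "structural"
      )
    }
    list(
      natural = natural,
      designed = designed,
      truth = tibble(position = seq_len(spec$L),
                     label = factor(truth_label, levels = FSA_LABELS))
    )
  })
}

#' Precision/recall of planted-label recovery over a grid of specs
#'
#' Runs the full pipeline on each spec and scores the resulting labels
#' against the planted ground truth, per label type. Precision and recall
#' are reported as `NA` where undefined (no predicted, respectively no true,
#' positions of that label).
#'
#' @param spec_grid A list of [synthetic_spec()] objects.
#' @param ... Passed to [fsa_annotate()] (e.g. `alpha`, `keep_fraction`).
#' @return A tibble with one row per spec x label: spec parameters,
#'   `label`, `n_true`, `n_predicted`, `n_correct`, `precision`, `recall`.
#' @export
sweep_recovery <- function(spec_grid, ...) {
  purrr::map_dfr(seq_along(spec_grid), function(i) {
    spec <- spec_grid[[i]]
    sim <- simulate_paired_alignments(spec)
    fit <- fsa_annotate(sim$natural, sim$designed, ...)
    truth <- as.character(sim$truth$label)
    pred <- as.character(fit$track$label)
    purrr::map_dfr(c("functional", "structural", "adaptable"), function(lb) {
      n_true <- sum(truth == lb)
      n_pred <- sum(pred == lb)
      n_correct <- sum(truth == lb & pred == lb)
      tibble(
        spec_id = i, L = spec$L,
        n_natural = spec$n_natural, n_designed = spec$n_designed,
        n_planted = nrow(spec$planted),
        mean_strength = if (nrow(spec$planted)) mean(spec$planted$strength) else NA_real_,
        seed = spec$seed,
        label = lb, n_true = n_true, n_predicted = n_pred, n_correct = n_correct,
        precision = if (n_pred > 0) n_correct / n_pred else NA_real_,
        recall = if (n_true > 0) n_correct / n_true else NA_real_
      )
    })
  })
}

#' Fraction of planted positions recovering their ground-truth label
#'
#' @param track An `fsa_track`.
#' @param truth Truth tibble from [simulate_paired_alignments()].
#' @return A list with `n_planted`, `n_recovered` and `recovery` (fraction;
#'   NA when nothing was planted).
#' @export
score_recovery <- function(track, truth) {
  planted <- truth[truth$label != "unlabeled", ]
  if (nrow(planted) == 0L) {
    return(list(n_planted = 0L, n_recovered = 0L, recovery = NA_real_))
  }
  pred <- as.character(track$label[match(planted$position, track$position)])
  hit <- pred == as.character(planted$label)
  list(
    n_planted = nrow(planted),
    n_recovered = sum(hit),
    recovery = mean(hit)
  )
}
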