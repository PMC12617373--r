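test_that("exact Mann-Whitney p-values agree with brute-force enumeration", {
  withr::with_seed(11, {
    cases <- list(
      list(x = c(5, 6), y = c(1, 2, 3)),
      list(x = c(0.9, 0.08), y = c(0.1, 0.2, 0.05, 0.3, 0.02, 0.04)),
      list(x = c(1, 1, 2), y = c(1, 2, 2, 3)),        # heavy ties
      list(x = 4, y = c(1, 2, 3, 4, 5))               # singleton with a tie
    )
    for (cs in cases) {
      for (alt in c("greater", "two_sided")) {
        got <- mann_whitney_u(cs$x, cs$y, alternative = alt)
        expect_equal(got$method, "exact")
        expect_equal(got$p, oracle_exact_mw_p(cs$x, cs$y, alt), tolerance = 1e-12)
      }
    }
  })
})

test_that("the normal approximation is sane on large tie-free samples", {
  withr::with_seed(3, {
    x <- rnorm(30, mean = 1)
    y <- rnorm(200)
    got <- mann_whitney_u(x, y, alternative = "greater", exact_limit = 10)
    expect_equal(got$method, "normal")
    ref <- stats::wilcox.test(x, y, alternative = "greater",
                              exact = FALSE, correct = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  })
})

test_that("a position identical to the baseline is never enriched", {
  rows <- rep(list(c(D = 0.3, K = 0.3, A = 0.2, S = 0.2)), 8)
  pssm <- toy_pssm(rows)
  expect_warning(
    emap <- test_enrichment(pssm, alpha = 0.01),
    "degenerate"
  )
  expect_false(any(emap$enriched))
  # fully degenerate classes (no mass anywhere) get p = 1, not an exception
  expect_true(all(emap$p[emap$class %in% c("glycine", "proline")] == 1))
})

test_that("member-mode enrichment matches the permutation oracle on a toy PSSM", {
  # 5 positions; position 1 has concentrated acidic mass
  pssm <- toy_pssm(list(
    c(D = 0.9, E = 0.08),
    c(A = 0.3, L = 0.3),
    c(S = 0.4, T = 0.2),
    c(K = 0.5, R = 0.1),
    c(G = 0.6)
  ))
  emap <- test_enrichment(pssm, alpha = 0.05, sample_mode = "member")
  row <- emap[emap$position == 1 & emap$class == "acidic", ]
  A <- pssm$freq[1, c("D", "E")]
  B <- as.vector(pssm$freq[2:5, c("D", "E")])
  expect_equal(row$p, oracle_exact_mw_p(A, B, "greater"), tolerance = 1e-12)
  expect_true(row$enriched)
})

test_that("class_sum mode compares one summed value per position", {
  pssm <- toy_pssm(list(
    c(H = 0.5, Q = 0.4),
    c(A = 0.3, L = 0.3),
    c(A = 0.25, V = 0.25),
    c(K = 0.3, R = 0.2),
    c(G = 0.5),
    c(D = 0.4, E = 0.3)
  ))
  emap <- test_enrichment(pssm, alpha = 0.2, sample_mode = "class_sum")
  row <- emap[emap$position == 1 & emap$class == "hydrophilic", ]
  # hydrophilic sum at position 1 is the strict maximum of 6 values
  expect_equal(row$p, 1 / 6, tolerance = 1e-12)
  expect_true(row$enriched)
})

test_that("differential norms match hand computation and the simplex bound", {
  # two positions fully concentrated in different classes
  pssm2 <- toy_pssm(list(c(D = 1), c(K = 1)))
  dn <- differential_norms(pssm2)
  expect_equal(dn$diff_norm, c(sqrt(0.5), sqrt(0.5)))
  expect_equal(dn$d_acidic, c(0.5, -0.5))

  # a position equal to the baseline mean has zero norm
  rows <- rep(list(c(A = 0.5, D = 0.5)), 4)
  dn0 <- differential_norms(toy_pssm(rows))
  expect_equal(dn0$diff_norm, rep(0, 4))

  withr::with_seed(5, {
    rows <- lapply(1:10, function(i) {
      p <- runif(20)
      p <- p / sum(p)
      names(p) <- colnames(pssm2$freq)
      p
    })
    dnr <- differential_norms(toy_pssm(rows))
    expect_true(all(dnr$diff_norm <= sqrt(2) + 1e-12))
  })
})

test_that("the information filter ranks by score with position tie-breaks", {
  emap <- emap_from_flags(matrix(TRUE, 5, 6))
  scores <- c(4, 3, 2, 1, 0)
  emap$filter_score <- scores[emap$position]
  f <- apply_information_filter(emap, keep_fraction = 0.4)
  kept <- unique(f$position[f$retained])
  expect_equal(kept, c(1L, 2L))
  expect_true(all(f$enriched[f$position %in% kept]))
  expect_false(any(f$enriched[!f$position %in% kept]))
  expect_true(all(f$enriched_raw))

  # ties broken by ascending position
  emap$filter_score <- rep(1, nrow(emap))
  f2 <- apply_information_filter(emap, keep_fraction = 0.4)
  expect_equal(unique(f2$position[f2$retained]), c(1L, 2L))

  expect_error(apply_information_filter(emap, 1.5), class = "fsa_parameter_error")
  expect_error(apply_information_filter(emap, -0.1), class = "fsa_parameter_error")
})

test_that("retained sets are nested across keep fractions", {
  withr::with_seed(21, {
    aln <- random_alignment(n = 30, L = 25, seed = 21)
    emap <- test_enrichment(pssm_from_alignment(aln), alpha = 0.05)
    fractions <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
    kept <- lapply(fractions, function(f) {
      fe <- apply_information_filter(emap, f)
      unique(fe$position[fe$retained])
    })
    for (i in seq_len(length(fractions) - 1)) {
      expect_true(all(kept[[i]] %in% kept[[i + 1]]))
    }
    expect_length(kept[[1]], 0L)
    expect_length(kept[[length(fractions)]], 25L)
  })
})

test_that("stronger planted enrichment never reduces detection", {
  strengths <- c(0.3, 0.45, 0.6, 0.75, 0.9)
  n_rep <- 20
  detected <- matrix(NA_real_, n_rep, length(strengths))
  for (r in seq_len(n_rep)) {
    for (s in seq_along(strengths)) {
      spec <- synthetic_spec(
        L = 20, n_natural = 80, n_designed = 2,
        planted = tibble::tibble(
          position = c(4L, 11L, 17L),
          target_class = c("acidic", "basic", "hydrophobic"),
          planted_set = "natural",
          strength = strengths[s]
        ),
        seed = 1000 + r
      )
      sim <- simulate_paired_alignments(spec)
      emap <- test_enrichment(pssm_from_alignment(sim$natural), alpha = 0.01)
      planted <- spec$planted
      hit <- vapply(seq_len(nrow(planted)), function(i) {
        any(emap$enriched[emap$position == planted$position[i] &
                            emap$class == planted$target_class[i]])
      }, logical(1))
      detected[r, s] <- mean(hit)
    }
  }
  mean_detect <- colMeans(detected)
  expect_true(all(diff(mean_detect) >= -1e-12))
  expect_gt(mean_detect[length(strengths)], mean_detect[1])
})

test_that("Benjamini-Hochberg adjustment is available and more conservative", {
  pssm <- toy_pssm(list(
    c(D = 0.9, E = 0.08), c(A = 0.3, L = 0.3), c(S = 0.4, T = 0.2),
    c(K = 0.5, R = 0.1), c(G = 0.6), c(H = 0.2, Q = 0.2)
  ))
  raw <- test_enrichment(pssm, alpha = 0.05)
  adj <- test_enrichment(pssm, alpha = 0.05, p_adjust = "BH")
  expect_true(all(adj$p >= raw$p - 1e-12))
  expect_lte(sum(adj$enriched), sum(raw$enriched))
})

test_that("enrichment map export carries the documented columns", {
  pssm <- toy_pssm(list(c(D = 0.9), c(A = 0.4), c(S = 0.4), c(K = 0.4), c(G = 0.5)))
  emap <- apply_information_filter(test_enrichment(pssm, alpha = 0.05), 0.6)
  path <- tempfile(fileext = ".tsv")
  write_emap_tsv(emap, path)
  df <- read.delim(path)
  expect_equal(names(df),
               c("position", "query", "class", "U", "p", "enriched",
                 "info", "diff_norm", "filter_score", "retained"))
  expect_equal(nrow(df), 5L * 6L)
  gl <- glance(emap)
  expect_equal(gl$keep_fraction, 0.6)
  expect_equal(gl$n_retained, 3L)
})
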