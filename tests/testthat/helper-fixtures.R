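# Fixture factories. Everything is generated in code at test time.

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

example_pssm_path <- function() {
  system.file("extdata", "example.pssm", package = "fsannot")
}

# Random gap-containing alignment drawn from the uniform background.
random_alignment <- function(n = 10, L = 20, gap_prob = 0.05, seed = 1) {
  withr::with_seed(seed, {
    alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    ref <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
    others <- vapply(seq_len(n - 1), function(i) {
      chars <- sample(alphabet, L, replace = TRUE)
      chars[runif(L) < gap_prob] <- "-"
      paste(chars, collapse = "")
    }, character(1))
    alignment(c("ref", paste0("s", seq_len(n - 1))), c(ref, others))
  })
}

# A PSSM whose frequency rows are fully specified by the caller
# (list of named vectors; unnamed mass spread uniformly over the rest).
toy_pssm <- function(rows, query = NULL) {
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  L <- length(rows)
  freq <- matrix(0, L, 20, dimnames = list(NULL, alphabet))
  for (i in seq_len(L)) {
    r <- rows[[i]]
    freq[i, names(r)] <- r
    rest <- setdiff(alphabet, names(r))
    freq[i, rest] <- (1 - sum(r)) / length(rest)
  }
  info <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  new_pssm(
    query = query %||% apply(freq, 1, function(p) alphabet[which.max(p)]),
    freq = freq,
    logodds = log2(freq * 20 + 1e-12),
    info = info
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built enrichment map with prescribed per-class significance flags:
# flags is an L x K logical matrix (classes in default-scheme order).
emap_from_flags <- function(flags, query = NULL, alpha = 0.01) {
  classes <- names(default_scheme()$classes)
  L <- nrow(flags)
  stopifnot(ncol(flags) == length(classes))
  query <- query %||% rep("A", L)
  out <- tibble::tibble(
    position = rep(seq_len(L), each = length(classes)),
    query = rep(query, each = length(classes)),
    class = rep(classes, times = L),
    U = 0,
    p = ifelse(as.vector(t(flags)), alpha / 10, 0.5),
    info = rep(1, L * length(classes)),
    diff_norm = rep(1, L * length(classes)),
    filter_score = rep(1, L * length(classes))
  )
  out$enriched_raw <- out$p < alpha
  out$enriched <- out$enriched_raw
  out$retained <- TRUE
  class(out) <- c("fsa_emap", class(out))
  attr(out, "params") <- list(
    alpha = alpha, sample_mode = "member", alternative = "greater",
    p_adjust = "none", keep_fraction = 1, scheme = "default6",
    classes = classes, L = L, info_source = "synthetic"
  )
  out
}
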