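# Small-bundle configuration used across tests: fast but structurally complete.
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_probes = 400, n_mouse_genes = 400,
               n_shared_signal = 20, coexpr_block_size = 8, n_cpg = 40)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Wide expression tibble from a plain matrix (features x samples).
make_expr <- function(m, symbols = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(nrow(m)))
  if (is.null(symbols)) symbols <- sprintf("GENE%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(feature_id = ids, gene_symbol = symbols),
    tibble::as_tibble(m)
  )
}

make_pheno <- function(values, group = NULL, subjects = NULL) {
  n <- length(values)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(n))
  tibble::tibble(subject_id = subjects,
                 group = group %||% rep("PTSD", n),
                 reexperiencing = values,
                 age = seq(25, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, via explicit
# double loop over sorted p-values (independent of stats::p.adjust).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * (m / j))
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive-enumeration hypergeometric upper tail: P(|draw of n from N| has
# >= k of the K marked items), counting all C(N, n) subsets.
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, n)
  hits <- colSums(subs <= K)  # marked items are 1..K
  mean(hits >= k)
}
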