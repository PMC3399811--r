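# Shared fixture builders; everything is generated in code at test time.

mk_map <- function(L, chrom = "chr1", pos = seq_len(L)) {
  marker_map(sprintf("m%04d", seq_len(L)), chrom, pos)
}

mk_ratio <- function(values, chrom = "chr1", pos = NULL) {
  values <- as.matrix(values)
  ratio_matrix(values, mk_map(ncol(values), chrom,
                              pos %||% seq_len(ncol(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A sparse non-negative "call-like" matrix: zeros plus positive aberrations.
rand_call_values <- function(N, L, prob = 0.3, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(0, N, L)
    hit <- matrix(runif(N * L) < prob, N, L)
    v[hit] <- runif(sum(hit), 0.2, 1.5)
    v
  })
}

# Exhaustive-enumeration peel-free p-values for a tiny tag matrix: every
# joint arrangement of independently permuted rows, max column score each.
enumerate_null_maxima <- function(values) {
  A <- abs(values)
  M <- ncol(A)
  perms <- as.matrix(expand.grid(rep(list(seq_len(M)), M)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == seq_len(M))), ,
                 drop = FALSE]
  combos <- expand.grid(rep(list(seq_len(nrow(perms))), nrow(A)))
  apply(combos, 1, function(rowsel) {
    P <- vapply(seq_len(nrow(A)),
                function(n) A[n, perms[rowsel[[n]], ]], numeric(M))
    max(rowSums(P))
  })
}
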