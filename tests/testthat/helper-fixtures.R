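# Builders and independent oracles shared across test files.

# Small three-group expression matrix with given per-group row values.
# `rows` is a named list: gene -> numeric vector of length 3 * n (C, A20, AD
# blocks in order).
make_em <- function(rows, n = 3, groups = c("C", "A20", "AD")) {
  m <- do.call(rbind, rows)
  samples <- unlist(lapply(groups, function(g) paste0(g, "_", seq_len(n))))
  dimnames(m) <- list(names(rows), samples)
  expression_matrix(m, setNames(rep(groups, each = n), samples))
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[ord][i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# All permutations of seq_len(n) (n <= 7), as a matrix with one row each.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact permutation two-sided p-value for a Pearson correlation at tiny n:
# enumerate every reordering of y and count |r_perm| >= |r_obs|.
perm_cor_pvalue <- function(x, y) {
  r_obs <- stats::cor(x, y)
  perms <- all_perms(length(y))
  r_all <- apply(perms, 1, function(idx) stats::cor(x, y[idx]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Independent reimplementation of the trajectory decision rule, written as
# literal case analysis (not shared with the package's vectorized code).
classify_oracle <- function(c1, c2, c3) {
  if (c1 != "ns") {
    if (c2 == "ns") return("transient")
    if (c1 == c2) return("persistent_same_sign")
    return("persistent_reversed")
  }
  if (c2 != "ns") return("deprivation_emergent")
  if (c3 != "ns") return("deprivation_shifted")
  "unchanged"
}

all_triplets <- function() {
  expand.grid(c1 = c("up", "down", "ns"), c2 = c("up", "down", "ns"),
              c3 = c("up", "down", "ns"), stringsAsFactors = FALSE)
}
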