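# Shared fixtures and independent oracles.

hexanone_smi <- function() {
  system.file("extdata", "hexan3one.smi", package = "isetlogp")
}
hexanone_state <- function() {
  system.file("extdata", "hexan3one_state.yaml", package = "isetlogp")
}

# Published reference decomposition for 3-hexanone (4-decimal display).
# Atom order follows the parsed SMILES CCC(=O)CCC.
hexanone_reference <- list(
  mu = 2.6790, d = 1.2342, q_c = 0.224, q_x = -0.288,
  mu_f = 0.6319, a_mu = 1.7193,
  contributions = c(C1 = 0.9891, C2 = 0.5860, C3 = 0.6799, O4 = 1.5416,
                    C5 = 0.5444, C6 = 0.8986, C7 = 0.9535),
  total = 6.1931
)

# Independent evaluator of the index: per-edge accumulation instead of the
# per-atom neighbour sums used by the implementation. Each bonded pair
# (i, j) contributes log10(eff_i) + log10(eff_j); each atom contributes its
# own effective value once.
brute_iset <- function(g, eff) {
  tot <- sum(eff)
  for (k in seq_len(nrow(g$bonds))) {
    tot <- tot + log10(eff[g$bonds$i[k]]) + log10(eff[g$bonds$j[k]])
  }
  tot
}

# From-scratch normal-equation simple linear regression (no lm()).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  res <- y - a - b * x
  sxx_c <- sxx - sx^2 / n
  syy_c <- sum(y^2) - sy^2 / n
  r <- (sxy - sx * sy / n) / sqrt(sxx_c * syy_c)
  list(a = a, b = b, r = r, s = sqrt(sum(res^2) / (n - 2)))
}

# A labelled path graph C1-C2-...-Cn (all carbon).
path_graph <- function(n) {
  mol_graph(rep("C", n),
            if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL)
}

# Relabel the atoms of a graph by a permutation perm (new index of atom i
# is perm[i]), returning the permuted graph.
permute_graph <- function(g, perm) {
  inv <- order(perm)
  mol_graph(g$atoms$element[inv],
            cbind(perm[g$bonds$i], perm[g$bonds$j]),
            orders = g$bonds$order)
}
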