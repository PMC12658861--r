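# Shared fixture builders: every input is generated in code at test time.

# A three-target run loosely shaped like a narcotics mixture injection.
make_demo_targets <- function() {
  list(
    list(mz = 370.1642, rt_apex = 685, height = 1000,
         fragments = data.frame(mz = c(58.00, 193.06, 211.07, 268.13, 328.15,
                                       370.16),
                                intensity = c(1, 47, 108, 193, 182, 1000))),
    list(mz = 286.1430, rt_apex = 146, height = 800,
         fragments = data.frame(mz = c(201.09, 229.09, 268.13, 286.14),
                                intensity = c(104, 72, 24, 800))),
    list(mz = 238.0992, rt_apex = 600, height = 500, fragments = NULL))
}

make_demo_run <- function(noise_sd = 0, seed = 1) {
  synthesize_run(make_demo_targets(), noise_sd = noise_sd,
                 rt_grid = seq(100, 800, by = 5), peak_width = 3,
                 seed = seed)
}

# Small abundance table with known quirks (NA, zeros, constant feature).
make_small_table <- function() {
  v <- rbind(
    F1 = c(1, NA, 0, 4),
    F2 = c(10, 10, 10, 10),
    F3 = c(1, 2, 3, 4))
  colnames(v) <- paste0("S", 1:4)
  feature_table(v)
}

# Two-group table with metadata for association tests.
make_group_table <- function(n_per_group = 10, n_features = 5, delta = 0,
                             seed = 42) {
  lcmstats:::with_seed(seed, {
    n <- 2 * n_per_group
    group <- rep(c("A", "B"), each = n_per_group)
    age <- rnorm(n, 50, 8)
    v <- matrix(rnorm(n_features * n), n_features, n)
    v[1, group == "B"] <- v[1, group == "B"] + delta
    rownames(v) <- paste0("F", seq_len(n_features))
    colnames(v) <- paste0("S", seq_len(n))
    feature_table(v, data.frame(group = group, age = age,
                                row.names = colnames(v)))
  })
}

# A signed two-node chain a -> b used for hand-solved propagation checks.
make_chain_pathway <- function(sign = 1) {
  pathway_graph("chain", "two-node chain",
                nodes = data.frame(id = c("a", "b"),
                                   kind = c("gene", "compound")),
                edges = data.frame(src = "a", dst = "b", sign = sign,
                                   relation = "test"))
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
ora_enumerate <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # label items 1..K as significant
  mean(hits >= k)
}

# Reference Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# KGML snippet: 3 genes, 1 compound, 2 signed relations, 1 unsigned.
write_kgml_fixture <- function(path) {
  writeLines('<?xml version="1.0"?>
<pathway name="path:test01" org="hsa" number="1" title="kgml fixture">
  <entry id="1" name="hsa:10" type="gene"/>
  <entry id="2" name="hsa:20" type="gene"/>
  <entry id="3" name="hsa:30" type="gene"/>
  <entry id="4" name="cpd:C00031" type="compound"/>
  <entry id="5" name="path:hsa00010" type="map"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="4" type="PCrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="1" entry2="3" type="PPrel">
    <subtype name="binding/association" value="---"/>
  </relation>
</pathway>', path)
  path
}
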