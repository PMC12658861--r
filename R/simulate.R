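#' Simulate a two-group abundance matrix with planted effects
#'
#' Emulates the statistical structure of a case/control omics study with
#' age and ancestry covariates: log-scale Gaussian abundances, a subset of
#' planted features shifted between groups by `delta`, additive covariate
#' effects, and NA/zero entries sprinkled at stated rates. Fully
#' deterministic under `seed`. The ground truth (planted feature ids and
#' the generating parameters) is attached as attribute `"truth"`.
#'
#' @param n_per_group Samples per group (default 30).
#' @param n_features Number of features (default 200).
#' @param n_planted Number of features carrying the group effect (default
#'   20).
#' @param delta Between-group shift on the log scale for planted features
#'   (default 1).
#' @param covariate_effects Named vector `c(age = ..., ancestry = ...)` of
#'   per-unit additive effects (default `c(age = 0.01, ancestry = 0.2)`).
#' @param noise_sd Residual standard deviation (default 1).
#' @param missing_rate,zero_rate Fractions of entries set to NA / 0
#'   (defaults 0.02 and 0.01).
#' @param seed Integer seed.
#' @return A [feature_table()] with `group` (A/B), `age`, `ancestry`
#'   metadata.
#' @export
simulate_feature_table <- function(n_per_group = 30, n_features = 200,
                                   n_planted = 20, delta = 1,
                                   covariate_effects = c(age = 0.01,
                                                         ancestry = 0.2),
                                   noise_sd = 1, missing_rate = 0.02,
                                   zero_rate = 0.01, seed = 1) {
  stopifnot(n_per_group >= 1, n_features >= 1, n_planted >= 0,
            n_planted <= n_features, noise_sd > 0)
  with_seed(seed, {
    n <- 2L * n_per_group
    group <- rep(c("A", "B"), each = n_per_group)
    age <- round(rnorm(n, 55, 10), 1)
    ancestry <- rbinom(n, 1, 0.5)
    planted <- if (n_planted) paste0("F", seq_len(n_planted)) else character(0)
    base <- rnorm(n_features, 10, 2)
    v <- matrix(rnorm(n_features * n, 0, noise_sd), n_features, n)
    v <- v + base
    if (n_planted)
      v[seq_len(n_planted), group == "B"] <-
        v[seq_len(n_planted), group == "B"] + delta
    v <- v + outer(rep(1, n_features), covariate_effects[["age"]] * age) +
      outer(rep(1, n_features), covariate_effects[["ancestry"]] * ancestry)
    nmiss <- round(missing_rate * length(v))
    nzero <- round(zero_rate * length(v))
    holes <- sample(length(v), nmiss + nzero)
    v[holes[seq_len(nmiss)]] <- NA
    if (nzero) v[holes[nmiss + seq_len(nzero)]] <- 0
    rownames(v) <- paste0("F", seq_len(n_features))
    colnames(v) <- paste0("S", seq_len(n))
    meta <- data.frame(group = group, age = age, ancestry = ancestry,
                       row.names = colnames(v))
    out <- feature_table(v, meta)
    attr(out, "truth") <- list(planted = planted, delta = delta,
                               covariate_effects = covariate_effects,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Simulate a pathway collection with one enriched pathway
#'
#' Generates random gene+compound pathway graphs over a shared feature
#' universe plus matching per-feature summary statistics. One designated
#' pathway is enriched: its members carry planted effect sizes and small
#' p-values; background features draw null effects and uniform p-values.
#'
#' @param n_pathways Number of pathways (default 10).
#' @param genes_per_pathway,compounds_per_pathway Members per pathway
#'   (defaults 10 and 4).
#' @param n_genes,n_compounds Universe sizes (defaults 300 and 60).
#' @param n_edges Signed edges per pathway (default 12).
#' @param effect Planted absolute effect size for enriched members
#'   (default 1); background effects are N(0, effect/10).
#' @param frac_enriched_sig Fraction of the enriched pathway's members
#'   carrying the planted effect (default 1).
#' @param seed Integer seed.
#' @return List with `pathways` (list of [pathway_graph()]),
#'   `gene_summary`, `compound_summary` (columns `feature_id`, `beta`,
#'   `p`) and `truth` (the enriched pathway id).
#' @export
simulate_pathways <- function(n_pathways = 10, genes_per_pathway = 10,
                              compounds_per_pathway = 4,
                              n_genes = 300, n_compounds = 60,
                              n_edges = 12, effect = 1,
                              frac_enriched_sig = 1, seed = 1) {
  stopifnot(n_pathways >= 1, genes_per_pathway >= 1, effect > 0)
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    compounds <- sprintf("C%04d", seq_len(n_compounds))
    gene_summary <- data.frame(feature_id = genes,
                               beta = rnorm(n_genes, 0, effect / 10),
                               p = runif(n_genes), stringsAsFactors = FALSE)
    compound_summary <- data.frame(feature_id = compounds,
                                   beta = rnorm(n_compounds, 0, effect / 10),
                                   p = runif(n_compounds),
                                   stringsAsFactors = FALSE)
    pathways <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      g <- sample(genes, genes_per_pathway)
      cm <- sample(compounds, compounds_per_pathway)
      nodes <- data.frame(id = c(g, cm),
                          kind = rep(c("gene", "compound"),
                                     c(length(g), length(cm))))
      src <- sample(nodes$id, n_edges, replace = TRUE)
      dst <- sample(nodes$id, n_edges, replace = TRUE)
      keep <- src != dst
      edges <- if (any(keep))
        data.frame(src = src[keep], dst = dst[keep],
                   sign = sample(c(-1, 1), sum(keep), replace = TRUE),
                   relation = "simulated")
      else NULL
      pathways[[i]] <- pathway_graph(sprintf("path%02d", i),
                                     sprintf("simulated pathway %d", i),
                                     nodes, edges,
                                     category = "simulated")
    }
    enriched <- pathways[[1]]$nodes$id
    n_sig <- max(1L, round(frac_enriched_sig * length(enriched)))
    sig_ids <- sample(enriched, n_sig)
    bump <- function(df) {
      hit <- df$feature_id %in% sig_ids
      df$beta[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE) * effect
      df$p[hit] <- runif(sum(hit), 0, 1e-4)
      df
    }
    gene_summary <- bump(gene_summary)
    compound_summary <- bump(compound_summary)
    list(pathways = pathways, gene_summary = gene_summary,
         compound_summary = compound_summary,
         truth = list(enriched = pathways[[1]]$pathway_id,
                      sig_ids = sig_ids))
  })
}
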