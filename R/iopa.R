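#' Construct a pathway graph
#'
#' A typed, signed graph over gene and compound nodes. Edge signs encode
#' activation (+1) and inhibition (-1).
#'
#' @param pathway_id Pathway identifier (e.g. an hsa-style id).
#' @param name Human-readable pathway name.
#' @param nodes Data frame with columns `id` and `kind`
#'   (`"gene"`/`"compound"`).
#' @param edges Data frame with columns `src`, `dst`, `sign` (+1/-1) and
#'   optional `relation` label; may have zero rows.
#' @param category Optional pathway-map category label (used by the
#'   Manhattan table).
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, name = pathway_id,
                          nodes, edges = NULL, category = NA_character_) {
  nodes <- as.data.frame(nodes)
  if (!all(c("id", "kind") %in% names(nodes)))
    stop("nodes needs columns id, kind")
  if (!all(nodes$kind %in% c("gene", "compound")))
    stop("node kind must be gene or compound")
  if (anyDuplicated(paste(nodes$kind, nodes$id)))
    stop("node ids must be unique within their kind")
  if (is.null(edges))
    edges <- data.frame(src = character(0), dst = character(0),
                        sign = numeric(0), relation = character(0))
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    if (!all(c("src", "dst", "sign") %in% names(edges)))
      stop("edges needs columns src, dst, sign")
    if (!"relation" %in% names(edges)) edges$relation <- NA_character_
    bad <- !(edges$src %in% nodes$id) | !(edges$dst %in% nodes$id)
    if (any(bad))
      stop("edge endpoint(s) not in node set: ",
           paste(unique(c(edges$src[bad], edges$dst[bad])), collapse = ", "))
    if (!all(edges$sign %in% c(-1, 1)))
      stop("edge sign must be +1 or -1")
  }
  structure(list(pathway_id = as.character(pathway_id),
                 name = as.character(name), nodes = nodes, edges = edges,
                 category = category),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph %s '%s': %d genes, %d compounds, %d edges>\n",
              x$pathway_id, x$name, sum(x$nodes$kind == "gene"),
              sum(x$nodes$kind == "compound"), nrow(x$edges)))
  invisible(x)
}

relation_sign <- function(label) {
  act <- c("activation", "expression", "+1", "1")
  inh <- c("inhibition", "repression", "-1")
  ifelse(tolower(label) %in% act, 1,
         ifelse(tolower(label) %in% inh, -1, NA_real_))
}

#' Load pathway graphs from TSV or KGML
#'
#' The TSV dialect holds one or more pathways in a single file with columns
#' `pathway_id`, `pathway_name`, `type` (`node`/`edge`), `a`, `b`, `sign`,
#' `relation`, and optional `category`: node rows use `a` = node id,
#' `b` = kind; edge rows use `a` = source, `b` = destination with `sign`
#' either +1/-1 or a relation word (activation/inhibition). KGML (KEGG
#' pathway XML) files are parsed directly; activation/expression map to +1,
#' inhibition/repression to -1 and unsigned relations are dropped (count
#' reported via attribute `"n_dropped_relations"`).
#'
#' @param paths Character vector of file paths (`.tsv`/`.txt` or
#'   `.xml`/`.kgml`).
#' @return List of [pathway_graph()] objects.
#' @export
load_pathways <- function(paths) {
  out <- list(); dropped <- 0L
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.(xml|kgml)$", path, ignore.case = TRUE)) {
      res <- parse_kgml(path)
      dropped <- dropped + attr(res, "n_dropped_relations")
      out <- c(out, list(res))
    } else {
      df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
      need <- c("pathway_id", "type", "a", "b")
      if (!all(need %in% names(df)))
        stop("malformed pathway file ", path, ": needs columns ",
             paste(need, collapse = ", "))
      for (pid in unique(df$pathway_id)) {
        sub <- df[df$pathway_id == pid, , drop = FALSE]
        nm <- if ("pathway_name" %in% names(sub)) sub$pathway_name[1] else pid
        cat_ <- if ("category" %in% names(sub)) sub$category[1] else NA_character_
        nodes <- sub[sub$type == "node", c("a", "b")]
        names(nodes) <- c("id", "kind")
        ed <- sub[sub$type == "edge", , drop = FALSE]
        if (nrow(ed)) {
          sgn <- suppressWarnings(as.numeric(ed$sign))
          word <- relation_sign(as.character(ed$sign))
          sgn[is.na(sgn)] <- word[is.na(sgn)]
          keep <- !is.na(sgn)
          dropped <- dropped + sum(!keep)
          edges <- data.frame(src = ed$a[keep], dst = ed$b[keep],
                              sign = sgn[keep],
                              relation = if ("relation" %in% names(ed))
                                ed$relation[keep] else NA_character_)
        } else edges <- NULL
        g <- tryCatch(pathway_graph(pid, nm, nodes, edges, category = cat_),
                      error = function(e)
                        stop("malformed pathway ", pid, " in ", path, ": ",
                             conditionMessage(e)))
        out <- c(out, list(g))
      }
    }
  }
  attr(out, "n_dropped_relations") <- dropped
  out
}

# Minimal KGML reader: entries of type gene/compound become nodes (KEGG
# name attribute, first token), relations with activation/inhibition-like
# subtypes become signed edges; everything else is dropped.
parse_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  pid <- xml2::xml_attr(doc, "name")
  title <- xml2::xml_attr(doc, "title")
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_ <- vapply(strsplit(xml2::xml_attr(entries, "name"), " "),
                   `[`, character(1), 1)
  keep <- types %in% c("gene", "compound")
  node_map <- setNames(names_[keep], ids[keep])
  kind_map <- setNames(types[keep], ids[keep])
  nodes <- unique(data.frame(id = unname(node_map),
                             kind = unname(kind_map)))
  rels <- xml2::xml_find_all(doc, ".//relation")
  src <- character(0); dst <- character(0); sgn <- numeric(0)
  lab <- character(0); dropped <- 0L
  for (r in rels) {
    e1 <- xml2::xml_attr(r, "entry1"); e2 <- xml2::xml_attr(r, "entry2")
    if (!(e1 %in% names(node_map)) || !(e2 %in% names(node_map))) {
      dropped <- dropped + 1L; next
    }
    subs <- xml2::xml_attr(xml2::xml_find_all(r, ".//subtype"), "name")
    s <- relation_sign(subs)
    s <- s[!is.na(s)]
    if (!length(s)) { dropped <- dropped + 1L; next }
    src <- c(src, node_map[[e1]]); dst <- c(dst, node_map[[e2]])
    sgn <- c(sgn, s[1]); lab <- c(lab, paste(subs, collapse = "/"))
  }
  g <- pathway_graph(if (is.na(pid)) basename(path) else pid,
                     if (is.na(title)) basename(path) else title,
                     nodes,
                     if (length(src)) data.frame(src = src, dst = dst,
                                                 sign = sgn, relation = lab)
                     else NULL)
  attr(g, "n_dropped_relations") <- dropped
  g
}

#' Over-representation analysis for one pathway
#'
#' Hypergeometric upper tail `P(X >= k)` with `N` the universe size of the
#' requested mode, `K` the number of significant features in the universe,
#' `n` the pathway members present in the universe and `k` the significant
#' pathway members.
#'
#' @param pathway A [pathway_graph()].
#' @param universe Data frame with columns `feature_id`, `kind`
#'   (`"gene"`/`"compound"`) and logical `significant`.
#' @param mode `"gene"`, `"compound"` or `"joint"` (genes and compounds
#'   pooled into one universe).
#' @return List with `p`, `N`, `K`, `n`, `k` and `empty` (TRUE with
#'   `p = 1` when no pathway member maps into the universe).
#' @export
ora <- function(pathway, universe, mode = c("joint", "gene", "compound")) {
  mode <- match.arg(mode)
  if (!nrow(universe)) stop("universe is empty")
  u <- if (mode == "joint") universe else universe[universe$kind == mode, ]
  members <- if (mode == "joint") pathway$nodes$id
             else pathway$nodes$id[pathway$nodes$kind == mode]
  N <- nrow(u)
  K <- sum(u$significant)
  inpath <- u$feature_id %in% members
  n <- sum(inpath)
  k <- sum(u$significant & inpath)
  if (n == 0L)
    return(list(p = 1, N = N, K = K, n = 0L, k = 0L, empty = TRUE))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, N = N, K = K, n = n, k = k, empty = FALSE)
}

# Propagation matrix M[v, u] = sign(u -> v) / outdeg(u) and the column
# influence vector c with t_A = c' DeltaE. Damped when (I - M) is singular.
espia_system <- function(pathway) {
  ids <- pathway$nodes$id
  nn <- length(ids)
  M <- matrix(0, nn, nn, dimnames = list(ids, ids))
  ed <- pathway$edges
  if (nrow(ed)) {
    outdeg <- table(factor(ed$src, levels = ids))
    for (j in seq_len(nrow(ed)))
      M[ed$dst[j], ed$src[j]] <- M[ed$dst[j], ed$src[j]] +
        ed$sign[j] / as.numeric(outdeg[[ed$src[j]]])
  }
  A <- diag(nn) - M
  damped <- FALSE
  if (rcond(A) < 1e-10) {
    warning("propagation system near-singular; damping applied")
    A <- diag(nn) - 0.99 * M
    damped <- TRUE
  }
  inv <- solve(A)
  cvec <- colSums(inv) - 1         # per-node accumulated influence
  list(ids = ids, M = M, inv = inv, cvec = cvec, damped = damped)
}

#' Topology-aware perturbation test over a joint gene+compound graph
#'
#' Extends signaling-pathway impact analysis to pathways whose nodes are
#' genes and compounds. Perturbation factors solve
#' `PF(v) = dE(v) + sum_{u->v} sign(u,v) PF(u) / outdeg(u)` by a linear
#' solve; accumulation is `Acc(v) = PF(v) - dE(v)` and the statistic is
#' `t_A = sum_v Acc(v)`. Its null distribution is obtained by reassigning
#' the multiset of observed nonzero perturbations to uniformly random
#' pathway nodes (`n_boot` seeded draws), and the p-value is the
#' median-centered two-sided bootstrap tail.
#'
#' @param pathway A [pathway_graph()].
#' @param delta_e Named numeric vector of observed effects for significant
#'   features (absent/zero for the rest); names are node ids.
#' @param n_boot Number of bootstrap reassignments (>= 100).
#' @param seed Integer seed.
#' @return List with `t_a`, `p`, `n_de`, `t_null` (the bootstrap sample)
#'   and `normalized_score` (`t_a` over the maximum attainable `|t_A|`
#'   under the observed perturbation magnitudes).
#' @export
espia <- function(pathway, delta_e, n_boot = 2000, seed = 1) {
  if (!nrow(pathway$nodes)) stop("pathway has no nodes")
  if (n_boot < 100) stop("n_boot must be at least 100")
  sys <- espia_system(pathway)
  de_full <- setNames(numeric(length(sys$ids)), sys$ids)
  common <- intersect(names(delta_e), sys$ids)
  de_full[common] <- delta_e[common]
  t_a <- sum(sys$cvec * de_full)
  nz <- de_full[de_full != 0]
  if (!length(nz))
    return(list(t_a = 0, p = 1, n_de = 0L, t_null = numeric(0),
                normalized_score = 0))
  t_null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pos <- sample(length(sys$ids), length(nz))
      sum(sys$cvec[pos] * nz)
    }, numeric(1))
  })
  med <- median(t_null)
  p <- (sum(abs(t_null - med) >= abs(t_a - med)) + 1) / (n_boot + 1)
  # largest |t_A| attainable by pairing the biggest |effects| with the most
  # influential nodes, used to normalize scores across pathways
  max_ta <- sum(sort(abs(sys$cvec), decreasing = TRUE)[seq_along(nz)] *
                  sort(abs(nz), decreasing = TRUE))
  list(t_a = t_a, p = p, n_de = length(nz), t_null = t_null,
       normalized_score = if (max_ta > 0) t_a / max_ta else 0)
}

#' Combine two p-values
#'
#' Fisher's method (`X = -2(log p1 + log p2)` against chi-square with 4
#' df, assuming independence) or a Pbine-style dependence-aware
#' combination: the empirical upper tail of Fisher's statistic under a
#' user-supplied joint null sample of `(p1, p2)` pairs. The shipped
#' pbine strategy is an approximation built from permutation nulls, not
#' the original external algorithm.
#'
#' @param p1,p2 P-values in `(0, 1]` (nonpositive values are clamped to
#'   the smallest representable positive number with a warning).
#' @param method `"fisher"` or `"pbine"`.
#' @param null_pairs For `"pbine"`: a 2-column matrix of null `(p1, p2)`
#'   draws.
#' @return Combined p-value.
#' @export
combine_p <- function(p1, p2, method = c("fisher", "pbine"),
                      null_pairs = NULL) {
  method <- match.arg(method)
  clamp <- function(p) {
    if (any(p <= 0)) {
      warning("nonpositive p-value(s) clamped")
      p[p <= 0] <- .Machine$double.xmin
    }
    p
  }
  p1 <- clamp(p1); p2 <- clamp(p2)
  stat <- -2 * (log(p1) + log(p2))
  if (method == "fisher")
    return(pchisq(stat, df = 4, lower.tail = FALSE))
  if (is.null(null_pairs) || ncol(null_pairs) != 2)
    stop("pbine needs a 2-column null_pairs matrix")
  null_stat <- -2 * (log(clamp(null_pairs[, 1])) + log(clamp(null_pairs[, 2])))
  (sum(null_stat >= stat) + 1) / (length(null_stat) + 1)
}

#' Multiple-testing adjustment
#'
#' @param pvec Numeric vector of p-values.
#' @param method `"fdr_bh"` (Benjamini-Hochberg step-up) or
#'   `"bonferroni"` (`min(1, m p)`).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(pvec, method = c("fdr_bh", "bonferroni")) {
  method <- match.arg(method)
  p.adjust(pvec, method = if (method == "fdr_bh") "BH" else "bonferroni")
}

#' Integrative omics pathway analysis
#'
#' Runs joint gene+compound ORA, the topology-aware perturbation test and
#' p-value combination over a pathway collection, with FDR and Bonferroni
#' columns and plot-ready Manhattan/volcano tables.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param gene_summary,compound_summary Data frames with columns
#'   `feature_id`, `beta`, `p` (per-feature summary statistics).
#' @param beta_threshold Features with `|beta| > beta_threshold` are
#'   flagged significant under the default rule (default 0.005).
#' @param sig_rule `"beta"` (effect-size threshold, default) or `"fdr"`
#'   (BH-adjusted `p < 0.05` within each omic).
#' @param combine_method `"fisher"` or `"pbine"` (permutation-based
#'   approximation; see [combine_p()]).
#' @param n_boot Bootstrap draws for the perturbation null (default 2000).
#' @param n_perm Permutations for the pbine joint null (default 1000).
#' @param seed Integer seed covering bootstrap and permutations.
#' @return List with `results` (one row per pathway: counts `G_n`,
#'   `deG_n`, `C_n`, `deC_n`, `P_n`, `deP_n`; `p_ora_gene`,
#'   `p_ora_compound`, `p_ora_joint`; `t_a`, `normalized_espia`,
#'   `p_espia`; `p_combined`, `p_fdr`, `p_bonferroni`, `m_tested`),
#'   `manhattan` and `volcano` tables.
#' @export
iopa_run <- function(pathways, gene_summary, compound_summary,
                     beta_threshold = 0.005,
                     sig_rule = c("beta", "fdr"),
                     combine_method = c("fisher", "pbine"),
                     n_boot = 2000, n_perm = 1000, seed = 1) {
  sig_rule <- match.arg(sig_rule)
  combine_method <- match.arg(combine_method)
  mk_universe <- function(df, kind) {
    sig <- if (sig_rule == "beta") abs(df$beta) > beta_threshold
           else p.adjust(df$p, "BH") < 0.05
    data.frame(feature_id = df$feature_id, kind = kind, beta = df$beta,
               significant = sig, stringsAsFactors = FALSE)
  }
  universe <- rbind(mk_universe(gene_summary, "gene"),
                    mk_universe(compound_summary, "compound"))
  delta_e <- setNames(ifelse(universe$significant, universe$beta, 0),
                      universe$feature_id)
  delta_e <- delta_e[delta_e != 0]

  m <- length(pathways)
  res <- data.frame(
    pathway_id = vapply(pathways, `[[`, character(1), "pathway_id"),
    name = vapply(pathways, `[[`, character(1), "name"),
    category = vapply(pathways, function(g)
      if (is.null(g$category)) NA_character_ else g$category, character(1)),
    G_n = 0L, deG_n = 0L, C_n = 0L, deC_n = 0L, P_n = 0L, deP_n = 0L,
    p_ora_gene = NA_real_, p_ora_compound = NA_real_, p_ora_joint = NA_real_,
    t_a = NA_real_, normalized_espia = NA_real_, p_espia = NA_real_,
    empty = FALSE, stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(2^31 - 2, m + 1))
  sys_list <- vector("list", m)
  for (i in seq_len(m)) {
    g <- pathways[[i]]
    og <- ora(g, universe, "gene"); oc <- ora(g, universe, "compound")
    oj <- ora(g, universe, "joint")
    es <- espia(g, delta_e, n_boot = n_boot, seed = seeds[i])
    res$G_n[i] <- og$n; res$deG_n[i] <- og$k
    res$C_n[i] <- oc$n; res$deC_n[i] <- oc$k
    res$P_n[i] <- oj$n; res$deP_n[i] <- oj$k
    res$p_ora_gene[i] <- og$p; res$p_ora_compound[i] <- oc$p
    res$p_ora_joint[i] <- oj$p
    res$t_a[i] <- es$t_a; res$normalized_espia[i] <- es$normalized_score
    res$p_espia[i] <- es$p
    res$empty[i] <- oj$empty
    sys_list[[i]] <- list(graph = g, t_null = es$t_null)
  }

  if (combine_method == "fisher") {
    res$p_combined <- combine_p(res$p_ora_joint, res$p_espia, "fisher")
  } else {
    res$p_combined <- pbine_combine(pathways, universe, delta_e, res,
                                    sys_list, n_perm, seeds[m + 1])
  }
  res$p_fdr <- adjust_p(res$p_combined, "fdr_bh")
  res$p_bonferroni <- adjust_p(res$p_combined, "bonferroni")
  res$m_tested <- m
  ord <- order(res$p_combined)
  res <- res[ord, ]
  rownames(res) <- NULL
  manhattan <- data.frame(pathway_id = res$pathway_id, name = res$name,
                          category = res$category,
                          neg_log10_p_fdr = -log10(res$p_fdr))
  volcano <- data.frame(pathway_id = res$pathway_id,
                        normalized_espia = res$normalized_espia,
                        neg_log10_p = -log10(res$p_combined))
  list(results = res, manhattan = manhattan, volcano = volcano,
       universe = universe)
}

# Permutation-based joint null for the pbine-style combination: the
# significance labels (and the effect values that ride on them) are
# permuted across the universe; per permutation each pathway yields a
# (p_ORA, p_perturbation) pair, the perturbation p-value being evaluated
# against the pathway's precomputed bootstrap null.
pbine_combine <- function(pathways, universe, delta_e, res, sys_list,
                          n_perm, seed) {
  m <- length(pathways)
  systems <- lapply(pathways, function(g) suppressWarnings(espia_system(g)))
  members <- lapply(pathways, function(g) g$nodes$id)
  N <- nrow(universe); K <- sum(universe$significant)
  betas <- setNames(universe$beta, universe$feature_id)
  obs_stat <- -2 * (log(pmax(res$p_ora_joint, .Machine$double.xmin)) +
                      log(pmax(res$p_espia, .Machine$double.xmin)))
  exceed <- integer(m)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_sig <- universe$feature_id[sample(N, K)]
      de_b <- betas[perm_sig]
      for (i in seq_len(m)) {
        memb <- members[[i]]
        n_i <- res$P_n[i]
        if (n_i == 0L) next
        k_b <- sum(perm_sig %in% memb)
        p_ora_b <- phyper(k_b - 1, K, N - K, n_i, lower.tail = FALSE)
        sysd <- systems[[i]]
        de_full <- setNames(numeric(length(sysd$ids)), sysd$ids)
        common <- intersect(names(de_b), sysd$ids)
        de_full[common] <- de_b[common]
        t_b <- sum(sysd$cvec * de_full)
        t_null <- sys_list[[i]]$t_null
        p_es_b <- if (length(t_null)) {
          med <- median(t_null)
          (sum(abs(t_null - med) >= abs(t_b - med)) + 1) / (length(t_null) + 1)
        } else 1
        stat_b <- -2 * (log(max(p_ora_b, .Machine$double.xmin)) +
                          log(max(p_es_b, .Machine$double.xmin)))
        if (stat_b >= obs_stat[i]) exceed[i] <- exceed[i] + 1L
      }
    }
  })
  (exceed + 1) / (n_perm + 1)
}
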