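#' Feature graph over space x frequency nodes
#'
#' Nodes are all (space, frequency) combinations; node `(s, f)` connects to
#' `(s, f±1)` (consecutive points on the frequency grid) and to `(s2, f)` for
#' every spatially adjacent `s2`. Space is a set of sources/channels with a
#' plain adjacency matrix, or a set of links with the link-neighborhood rule
#' of [link_adjacency()].
#'
#' @param spatial_adj symmetric logical adjacency matrix between spaces.
#' @param n_freq number of frequency grid points.
#' @return list of class `feature_graph`: `n_nodes`, `adj` (neighbor index
#'   list), `space`, `freq` (per-node coordinates).
#' @export
feature_graph <- function(spatial_adj, n_freq) {
  n_space <- nrow(spatial_adj)
  stopifnot(isSymmetric(unname(spatial_adj * 1)), n_freq >= 1)
  n_nodes <- n_space * n_freq
  node <- function(s, f) (s - 1L) * n_freq + f
  adj <- vector("list", n_nodes)
  nb_space <- lapply(seq_len(n_space), function(s) which(spatial_adj[s, ] != 0))
  for (s in seq_len(n_space)) {
    for (f in seq_len(n_freq)) {
      nb <- integer(0)
      if (f > 1L) nb <- c(nb, node(s, f - 1L))
      if (f < n_freq) nb <- c(nb, node(s, f + 1L))
      nb <- c(nb, node(nb_space[[s]], f))
      adj[[node(s, f)]] <- nb
    }
  }
  structure(list(n_nodes = n_nodes, adj = adj,
                 space = rep(seq_len(n_space), each = n_freq),
                 freq = rep(seq_len(n_freq), n_space)),
            class = "feature_graph")
}

#' Link-space adjacency from a ROI partition
#'
#' Two links are neighbors when they share one ROI and their other two ROIs
#' are spatially adjacent; links sharing no ROI are never neighbors.
#'
#' @param part a [make_rois()] result (its `adjacency` is used), or a plain
#'   symmetric ROI adjacency matrix.
#' @return symmetric logical links x links adjacency matrix, with the
#'   [link_table()] row order.
#' @export
link_adjacency <- function(part) {
  roi_adj <- if (inherits(part, "roi_partition")) part$adjacency else part
  n_roi <- nrow(roi_adj)
  links <- link_table(n_roi)
  n_l <- nrow(links)
  out <- matrix(FALSE, n_l, n_l)
  # index links by member ROI
  by_roi <- lapply(seq_len(n_roi), function(r)
    which(links$i == r | links$j == r))
  other <- function(lk, r) ifelse(links$i[lk] == r, links$j[lk], links$i[lk])
  for (r in seq_len(n_roi)) {
    ids <- by_roi[[r]]
    if (length(ids) < 2) next
    oth <- other(ids, r)
    for (a in seq_along(ids)) {
      nb <- ids[roi_adj[oth[a], oth]]
      out[ids[a], nb] <- TRUE
    }
  }
  diag(out) <- FALSE
  out | t(out)
}

#' Clusters of sub-threshold nodes
#'
#' Connected components of the subgraph induced by nodes with `p < alpha`.
#'
#' @param pvals per-node p-values.
#' @param graph a [feature_graph()].
#' @param alpha uncorrected threshold (default 0.05).
#' @return list of integer vectors (node indices), ordered by decreasing
#'   size.
#' @export
form_clusters <- function(pvals, graph, alpha = 0.05) {
  stopifnot(length(pvals) == graph$n_nodes, alpha > 0, alpha < 1)
  active <- !is.na(pvals) & pvals < alpha
  seen <- rep(FALSE, graph$n_nodes)
  clusters <- list()
  for (v in which(active)) {
    if (seen[v]) next
    comp <- integer(0)
    frontier <- v
    seen[v] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
      nxt <- nxt[active[nxt] & !seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters[order(-lengths(clusters))]
}

# internal: fast per-node group tests by whitened OLS with site fixed
# effects. Returns a function of the 0/1 group vector that yields per-node
# p-values; covariate projection is precomputed once.
ols_node_tester <- function(y, tab, stat) {
  n <- nrow(y)
  rank_q <- function(m) {
    dec <- qr(m)
    qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
  }
  xc <- cbind(1, tab$age_s, tab$sex01, tab$iq_s)
  if (nlevels(tab$site) > 1)
    xc <- cbind(xc, stats::model.matrix(~ 0 + site, data = tab)[, -1])
  qc <- rank_q(xc)
  yt <- y - qc %*% crossprod(qc, y)      # covariates + site projected out
  covs <- cbind(tab$age_s, tab$sex01, tab$iq_s)
  p_cov <- ncol(qc)
  function(asd) {
    g <- cbind(asd, asd * covs)
    gt <- g - qc %*% crossprod(qc, g)
    qg <- rank_q(gt)
    df1 <- ncol(qg)
    df2 <- n - p_cov - df1
    proj <- crossprod(qg, yt)
    rss0 <- colSums(yt^2)
    rss1 <- pmax(rss0 - colSums(proj^2), 1e-300)
    if (stat == "mean") {
      fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
      return(stats::pf(fstat, df1, df2, lower.tail = FALSE))
    }
    # variance: Bartlett test on full-model residuals, two groups
    e <- yt - qg %*% proj
    i1 <- asd == 1
    n1 <- sum(i1); n2 <- n - n1
    s1 <- colSums(e[i1, , drop = FALSE]^2) / (n1 - 1)
    s2 <- colSums(e[!i1, , drop = FALSE]^2) / (n2 - 1)
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n - 2)
    lr <- (n - 2) * log(sp) - (n1 - 1) * log(pmax(s1, 1e-300)) -
      (n2 - 1) * log(pmax(s2, 1e-300))
    corr <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (n - 2)) / 3
    stats::pchisq(pmax(lr / corr, 0), df = 1, lower.tail = FALSE)
  }
}

# internal: per-node p-values through the full mixed-model likelihood-ratio
# machinery of group_tests()
lme_node_tester <- function(y, tab, stat) {
  function(asd) {
    tb <- tab
    tb$asd <- asd
    tb$group <- ifelse(asd == 1, "ASD", "NT")
    apply(y, 2, function(col) {
      tb$y <- col
      gt <- group_tests(tb)
      if (stat == "mean") gt$p_mean else gt$p_var
    })
  }
}

#' Cluster-based permutation test over a feature graph
#'
#' Per-node group tests (mean or variance) are thresholded at `alpha` and
#' clustered over the feature graph; the observed cluster sizes are compared
#' with the distribution of the maximal cluster size under `n_perm` random
#' relabelings of the group assignment (covariates stay with their subjects).
#' The corrected p-value of a cluster is the proportion of relabelings whose
#' maximal cluster is strictly larger.
#'
#' @param y subjects x nodes feature matrix.
#' @param meta covariate data.frame (group, age, sex, iq, site).
#' @param graph a [feature_graph()].
#' @param stat "mean" or "variance".
#' @param n_perm number of relabelings (default 2000; below 100 a warning is
#'   given, since the attainable resolution degrades).
#' @param alpha per-node uncorrected threshold (default 0.05).
#' @param engine "ols" (fast whitened least-squares tests with site fixed
#'   effects, used inside the permutation loop) or "lme" (full mixed-model
#'   likelihood-ratio tests per node; slow).
#' @param p_rule "exact" (default) counts the observed labeling among the
#'   randomizations (`+1` in numerator and denominator) and breaks ties
#'   between equal integer cluster sizes by the cluster's summed statistic
#'   mass (sum of `-log` node p-values), so the comparison is effectively
#'   continuous and the p-value calibrated at any problem size; "strict" is
#'   the literal proportion of randomizations with a strictly larger cluster
#'   size (minimum attainable p is then 0, and size ties make it
#'   anticonservative on small feature graphs).
#' @param seed integer seed.
#' @return list of class `cluster_result`: `clusters` (node index sets),
#'   `sizes`, `p` (corrected p per cluster), `null_max_sizes`, `pvals`
#'   (observed per-node p-values).
#' @export
permutation_test <- function(y, meta, graph, stat = c("mean", "variance"),
                             n_perm = 2000, alpha = 0.05,
                             engine = c("ols", "lme"),
                             p_rule = c("exact", "strict"), seed = 1) {
  stat <- match.arg(stat)
  engine <- match.arg(engine)
  p_rule <- match.arg(p_rule)
  y <- as.matrix(y)
  stopifnot(ncol(y) == graph$n_nodes, nrow(y) == nrow(meta))
  if (n_perm < 100) warning("fewer than 100 permutations: p-value resolution is coarse")
  tab <- prepare_feature_table(cbind(meta, y = 0))
  tester <- if (engine == "ols") ols_node_tester(y, tab, stat)
            else lme_node_tester(y, tab, stat)
  asd_obs <- tab$asd
  pvals <- tester(asd_obs)
  clusters <- form_clusters(pvals, graph, alpha)
  sizes <- lengths(clusters)
  masses <- vapply(clusters, function(cl)
    sum(-log(pmax(pvals[cl], 1e-300))), numeric(1))
  # per relabeling, the lexicographically maximal (size, mass) cluster
  best_pair <- function(p_b) {
    cl <- form_clusters(p_b, graph, alpha)
    if (!length(cl)) return(c(0, 0))
    szs <- lengths(cl)
    top <- which(szs == max(szs))
    ms <- vapply(cl[top], function(x)
      sum(-log(pmax(p_b[x], 1e-300))), numeric(1))
    c(max(szs), max(ms))
  }
  set.seed(seed)
  null_best <- vapply(seq_len(n_perm), function(b)
    best_pair(tester(sample(asd_obs))), numeric(2))
  null_max <- null_best[1, ]
  p <- if (p_rule == "strict")
    vapply(sizes, function(sz) mean(null_max > sz), numeric(1))
  else
    vapply(seq_along(sizes), function(k) {
      exceed <- null_max > sizes[k] |
        (null_max == sizes[k] & null_best[2, ] > masses[k])
      (1 + sum(exceed)) / (n_perm + 1)
    }, numeric(1))
  structure(list(clusters = clusters, sizes = sizes, masses = masses, p = p,
                 null_max_sizes = null_max, pvals = pvals, stat = stat,
                 engine = engine, p_rule = p_rule),
            class = "cluster_result")
}
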