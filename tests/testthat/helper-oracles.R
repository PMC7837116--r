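# Brute-force oracles and fixture builders, all in plain loops so they stay
# independent of the package's vectorized implementations.

# --- fixture builders -------------------------------------------------------

make_nodes <- function(skeleton_id, coords, parents,
                       compartments = rep("other", nrow(coords))) {
  data.frame(skeleton_id = skeleton_id, node_id = seq_len(nrow(coords)),
             parent_id = parents, x = coords[, 1], y = coords[, 2],
             z = coords[, 3], compartment = compartments)
}

make_meta <- function(ids, cell_type = "Other", segment = "A1",
                      side = "L", homolog_id = NA, identified = TRUE) {
  data.frame(skeleton_id = ids, cell_type = cell_type, segment = segment,
             side = side, homolog_id = homolog_id, identified = identified)
}

make_links <- function(pre_skel, pre_node, post_skel, post_node,
                       x = 0, y = 0, z = 0) {
  n <- length(pre_skel)
  data.frame(connector_id = seq_len(n), pre_skeleton = pre_skel,
             pre_node = pre_node, post_skeleton = post_skel,
             post_node = post_node,
             x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n))
}

# small random circuit for oracle-equivalence checks: a handful of neurons,
# random tree skeletons, random monadic connectors
random_circuit <- function(seed, n_neurons = 8, nodes_per = 8,
                           n_links = 60) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_neurons))
  nodes <- list()
  for (i in seq_along(ids)) {
    coords <- matrix(stats::runif(nodes_per * 3, 0, 20000), ncol = 3)
    parents <- c(NA, vapply(2:nodes_per,
                            function(k) sample.int(k - 1, 1), integer(1)))
    comp <- sample(c("axon", "dendrite", "other"), nodes_per,
                   replace = TRUE)
    nodes[[i]] <- make_nodes(ids[i], coords, parents, comp)
  }
  nodes <- do.call(rbind, nodes)
  pre_i <- sample.int(nrow(nodes), n_links, replace = TRUE)
  post_i <- sample.int(nrow(nodes), n_links, replace = TRUE)
  ok <- nodes$skeleton_id[pre_i] != nodes$skeleton_id[post_i]
  links <- make_links(nodes$skeleton_id[pre_i][ok], nodes$node_id[pre_i][ok],
                      nodes$skeleton_id[post_i][ok],
                      nodes$node_id[post_i][ok],
                      x = nodes$x[pre_i][ok], y = nodes$y[pre_i][ok],
                      z = nodes$z[pre_i][ok])
  circuit(nodes, links,
          make_meta(ids, cell_type = sample(c("A", "B", "C"), n_neurons,
                                            replace = TRUE)),
          volume_spec(midline_x = 10000, neuropil_width = 20000))
}

# --- oracles ---------------------------------------------------------------

oracle_cable_um <- function(circ, skid, compartment = "all") {
  nd <- circ$nodes[circ$nodes$skeleton_id == skid, ]
  total <- 0
  for (i in seq_len(nrow(nd))) {
    if (is.na(nd$parent_id[i])) next
    if (compartment != "all" && nd$compartment[i] != compartment) next
    p <- which(nd$node_id == nd$parent_id[i])
    total <- total + sqrt(sum((c(nd$x[i], nd$y[i], nd$z[i]) -
                               c(nd$x[p], nd$y[p], nd$z[p]))^2))
  }
  total / 1000
}

oracle_link_count <- function(circ, pre, post, pre_comp = "all",
                              post_comp = "all") {
  cn <- circ$connectors
  comp_of <- function(skel, node) {
    nd <- circ$nodes
    nd$compartment[nd$skeleton_id == skel & nd$node_id == node]
  }
  n <- 0
  for (i in seq_len(nrow(cn))) {
    if (!(cn$pre_skeleton[i] %in% pre)) next
    if (!(cn$post_skeleton[i] %in% post)) next
    if (pre_comp != "all" &&
        comp_of(cn$pre_skeleton[i], cn$pre_node[i]) != pre_comp) next
    if (post_comp != "all" &&
        comp_of(cn$post_skeleton[i], cn$post_node[i]) != post_comp) next
    n <- n + 1
  }
  n
}

oracle_rank <- function(circ, seed_ids, min_synapses = 3,
                        strong_threshold = 15) {
  cn <- circ$connectors
  counts <- list()
  for (i in seq_len(nrow(cn))) {
    if (!(cn$pre_skeleton[i] %in% seed_ids)) next
    if (cn$post_skeleton[i] %in% seed_ids) next
    id <- cn$post_skeleton[i]
    counts[[id]] <- (counts[[id]] %||% 0) + 1
  }
  if (!length(counts))
    return(data.frame(skeleton_id = character(0), synapses = integer(0),
                      rank = integer(0), strength_class = character(0)))
  df <- data.frame(skeleton_id = names(counts),
                   synapses = unlist(counts, use.names = FALSE))
  df <- df[df$synapses >= min_synapses, ]
  df <- df[order(-df$synapses, df$skeleton_id), ]
  df$rank <- seq_len(nrow(df))
  df$strength_class <- ifelse(df$synapses >= strong_threshold,
                              "strong", "weak")
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_profile_counts <- function(x, volume, window_um = 2.5,
                                  grid_step = 0.01) {
  centers <- seq(-0.5, 0.5, by = grid_step)
  half <- window_um * 1000 / 2
  counts <- numeric(length(centers))
  for (i in seq_along(centers)) {
    c_nm <- volume$midline_x + centers[i] * volume$neuropil_width
    for (p in x)
      if (p >= c_nm - half && p <= c_nm + half)
        counts[i] <- counts[i] + 1
  }
  counts
}

oracle_exploration <- function(masks) {
  mature <- masks[[length(masks)]]
  union <- matrix(FALSE, nrow(mature), ncol(mature))
  for (m in masks) union <- union | (m > 0)
  100 * sum(union) / sum(mature > 0)
}

oracle_membrane <- function(vol, thr) {
  d <- dim(vol)
  out <- numeric(d[2])
  for (j in seq_len(d[2])) {
    s <- 0
    for (i in seq_len(d[1]))
      for (k in seq_len(d[3]))
        if (vol[i, j, k] >= thr) s <- s + 1
    out[j] <- s / d[1]
  }
  out
}

# tricube local polynomial regression, independent of stats::loess
oracle_local_regression <- function(x, y, span = 0.1, degree = 2) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    r <- sort(d)[q]
    w <- ifelse(d < r, (1 - (d / r)^3)^3, 0)
    keep <- w > 0
    X <- outer(x[keep] - x0, 0:degree, `^`)
    drop(solve(t(X) %*% (w[keep] * X), t(X) %*% (w[keep] * y[keep])))[1]
  }, numeric(1))
}

# exact one-sided rank-sum p by enumeration of all rank assignments
oracle_wilcoxon_exact <- function(x, y, alternative = "less") {
  m <- length(x); n <- length(y)
  all_ranks <- rank(c(x, y))
  obs <- sum(all_ranks[seq_len(m)])
  combos <- utils::combn(m + n, m)
  sums <- colSums(matrix(sort(all_ranks)[combos], nrow = m))
  switch(alternative,
         less = mean(sums <= obs),
         greater = mean(sums >= obs),
         two_sided = min(1, 2 * min(mean(sums <= obs),
                                    mean(sums >= obs))))
}

oracle_chisq_stat <- function(tab, continuity = FALSE) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (continuity && nrow(tab) == 2)
    pmax(abs(tab - expected) - 0.5, 0) else abs(tab - expected)
  sum(adj^2 / expected)
}
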