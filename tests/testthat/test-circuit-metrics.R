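# A hand-built two-neuron fixture: `seed` with 3 axon nodes, target `tgt`
# with 2 dendrite + 1 axon node, plus a background neuron `bg`.
toy_pair <- function(n_seed_links = 7, seed_from_dendrite = 0,
                     n_bg_links = 0, bg_onto_axon = 0) {
  nodes <- rbind(
    make_nodes("seed", rbind(c(0, 0, 0), c(1000, 0, 0), c(2000, 0, 0)),
               c(NA, 1L, 2L), c("axon", "axon", "dendrite")),
    make_nodes("tgt", rbind(c(0, 5000, 0), c(1000, 5000, 0),
                            c(2000, 5000, 0)),
               c(NA, 1L, 2L), c("dendrite", "dendrite", "axon")),
    make_nodes("bg", rbind(c(0, 9000, 0), c(1000, 9000, 0)),
               c(NA, 1L), c("axon", "axon")))
  pre_node <- c(rep(1L, n_seed_links - seed_from_dendrite),
                rep(3L, seed_from_dendrite))
  links <- make_links(rep("seed", n_seed_links), pre_node,
                      rep("tgt", n_seed_links),
                      rep(c(1L, 2L), length.out = n_seed_links))
  if (n_bg_links > 0) {
    bg <- make_links(rep("bg", n_bg_links), 1L, rep("tgt", n_bg_links),
                     rep(c(2L, 3L), length.out = n_bg_links))
    bg$post_node <- c(rep(2L, n_bg_links - bg_onto_axon),
                      rep(3L, bg_onto_axon))
    bg$connector_id <- bg$connector_id + n_seed_links
    links <- rbind(links, bg)
  }
  circuit(nodes, links,
          make_meta(c("seed", "tgt", "bg"),
                    cell_type = c("Mechanosensory", "Basin", "Other")))
}

test_that("group synapse counts honor hand-placed links and compartments", {
  circ <- toy_pair(n_seed_links = 7)
  expect_equal(group_synapse_count(circ, "seed", "tgt"), 7)

  circ2 <- toy_pair(n_seed_links = 7, seed_from_dendrite = 1)
  expect_equal(group_synapse_count(circ2, "seed", "tgt"), 7)
  expect_equal(group_synapse_count(circ2, "seed", "tgt",
                                   pre_compartment = "axon"), 6)
})

test_that("input fractions: whole, dendritic, and error on no input", {
  circ <- toy_pair(n_seed_links = 30, n_bg_links = 170)
  fr <- input_fraction(circ, "seed", "tgt")
  expect_equal(fr$n_from_pre, 30)
  expect_equal(fr$n_total, 200)
  expect_equal(fr$fraction, 0.15)

  # dendritic mode: denominators count only links onto dendrite nodes
  circ2 <- toy_pair(n_seed_links = 20, n_bg_links = 100, bg_onto_axon = 20)
  fr2 <- input_fraction(circ2, "seed", "tgt", mode = "dendritic")
  expect_equal(fr2$n_total, 100)
  expect_equal(fr2$fraction, 0.20)
  expect_gt(fr2$fraction,
            input_fraction(circ2, "seed", "tgt", mode = "whole")$fraction)

  expect_error(input_fraction(circ, "seed", "bg"), "no input")
})

test_that("subvolume fractions equal whole-mode fractions on the restricted circuit", {
  circ <- random_circuit(21, n_neurons = 10, nodes_per = 8, n_links = 120)
  box <- c(-1e6, 12000, -1e6, 1e6, -1e6, 1e6)
  pre <- "n01"
  posts <- setdiff(skeleton_ids(circ), pre)
  restricted <- restrict_to_subvolume(circ, box)
  for (post in posts[1:4]) {
    direct <- tryCatch(
      input_fraction(circ, pre, post, mode = "subvolume", box = box),
      error = function(e) NULL)
    via <- tryCatch(input_fraction(restricted, pre, post, mode = "whole"),
                    error = function(e) NULL)
    expect_equal(direct, via)
  }
})

test_that("input fractions over a partition of presynaptic groups sum to 1", {
  circ <- random_circuit(22)
  post <- "n01"
  pres <- setdiff(skeleton_ids(circ), post)
  if (group_synapse_count(circ, pres, post) > 0) {
    fractions <- vapply(pres, function(p)
      input_fraction(circ, p, post)$fraction, numeric(1))
    expect_equal(sum(fractions), 1)
  }
})

test_that("input fraction is invariant under rigid motion; density scales inversely", {
  circ <- toy_pair(n_seed_links = 10, n_bg_links = 30)
  moved <- circ
  moved$nodes$x <- moved$nodes$x + 5000
  moved$nodes$y <- moved$nodes$y - 2000
  moved$connectors$x <- moved$connectors$x + 5000
  expect_equal(input_fraction(moved, "seed", "tgt"),
               input_fraction(circ, "seed", "tgt"))

  scaled <- circ
  scaled$nodes$x <- scaled$nodes$x * 2
  scaled$nodes$y <- scaled$nodes$y * 2
  scaled$nodes$z <- scaled$nodes$z * 2
  expect_equal(synapse_density_per_cable(scaled, "seed", "tgt")$density,
               synapse_density_per_cable(circ, "seed", "tgt")$density / 2)
})

test_that("synapse density per cable: hand value and zero-cable error", {
  # 10 links onto a target with exactly 0.5 mm of cable
  nodes <- rbind(
    make_nodes("pre", rbind(c(0, 0, 0)), NA_integer_, "axon"),
    make_nodes("tgt", rbind(c(0, 0, 0), c(500000, 0, 0)), c(NA, 1L),
               c("dendrite", "dendrite")))
  links <- make_links(rep("pre", 10), 1L, rep("tgt", 10),
                      rep(c(1L, 2L), 5))
  circ <- circuit(nodes, links, make_meta(c("pre", "tgt")))
  d <- synapse_density_per_cable(circ, "pre", "tgt")
  expect_equal(d$cable_mm, 0.5)
  expect_equal(d$density, 20)
  expect_error(synapse_density_per_cable(circ, "pre", "pre"), "zero cable")
})

test_that("partner ranking applies inclusion and strength thresholds", {
  # counts A:20, B:16, C:5, D:2
  nodes <- rbind(
    make_nodes("s", rbind(c(0, 0, 0)), NA_integer_, "axon"),
    make_nodes("A", rbind(c(0, 1, 0)), NA_integer_, "dendrite"),
    make_nodes("B", rbind(c(0, 2, 0)), NA_integer_, "dendrite"),
    make_nodes("C", rbind(c(0, 3, 0)), NA_integer_, "dendrite"),
    make_nodes("D", rbind(c(0, 4, 0)), NA_integer_, "dendrite"),
    make_nodes("E", rbind(c(0, 5, 0)), NA_integer_, "dendrite"))
  counts <- c(A = 20, B = 16, C = 5, D = 2, E = 3)
  links <- make_links(rep("s", sum(counts)), 1L,
                      rep(names(counts), counts), 1L)
  circ <- circuit(nodes, links, make_meta(c("s", names(counts))))
  rk <- rank_partners(circ, "s")
  expect_equal(rk$skeleton_id, c("A", "B", "C", "E"))
  expect_equal(rk$strength_class, c("strong", "strong", "weak", "weak"))
  expect_equal(rk$rank, 1:4)
  # boundary inclusivity: exactly 15 is strong, exactly 3 is included
  rk15 <- rank_partners(circ, "s", min_synapses = 16, strong_threshold = 16)
  expect_equal(rk15$skeleton_id, c("A", "B"))
  expect_true("E" %in% rank_partners(circ, "s", min_synapses = 3)$skeleton_id)
  expect_equal(rk$strength_class[rk$synapses == 16], "strong")
})

test_that("count-based operations equal brute-force enumeration", {
  for (s in 1:6) {
    circ <- random_circuit(s)
    types <- unique(circ$metas$cell_type)
    pre <- resolve_group(circ, types[1])
    post <- setdiff(skeleton_ids(circ), pre)
    expect_equal(group_synapse_count(circ, pre, post),
                 oracle_link_count(circ, pre, post))
    expect_equal(group_synapse_count(circ, pre, post, "axon", "dendrite"),
                 oracle_link_count(circ, pre, post, "axon", "dendrite"))
    rk <- rank_partners(circ, pre, min_synapses = 1, strong_threshold = 5)
    ork <- oracle_rank(circ, pre, min_synapses = 1, strong_threshold = 5)
    expect_equal(rk, ork)
  }
})

test_that("homolog conservation: fully conserved toys give p_mean 1", {
  build_side <- function(side, partner_counts) {
    ids <- paste0(names(partner_counts), "_", side)
    nodes <- do.call(rbind, lapply(c(paste0("seed_", side), ids),
                                   function(id)
      make_nodes(id, rbind(c(0, 0, 0), c(1000, 0, 0)), c(NA, 1L),
                 c("axon", "dendrite"))))
    links <- make_links(rep(paste0("seed_", side), sum(partner_counts)), 1L,
                        rep(ids, partner_counts), 2L)
    list(nodes = nodes, links = links, ids = ids)
  }
  counts <- c(A = 20, B = 16)
  L <- build_side("L", counts)
  R <- build_side("R", counts)
  R$links$connector_id <- R$links$connector_id + nrow(L$links)
  metas <- rbind(
    make_meta(c("seed_L", "seed_R"), cell_type = "Mechanosensory",
              side = c("L", "R")),
    make_meta(L$ids, cell_type = "P", side = "L", homolog_id = R$ids),
    make_meta(R$ids, cell_type = "P", side = "R", homolog_id = L$ids))
  circ <- circuit(rbind(L$nodes, R$nodes), rbind(L$links, R$links), metas)
  hc <- homolog_conservation(circ, "seed_L", "seed_R",
                             thresholds = c(1, 15), min_nodes = 1)
  expect_equal(hc$p_mean, c(1, 1))
  expect_equal(hc$n_eligible_left, c(2L, 2L))

  # partners below min_nodes are ineligible; eligible sets shrink with
  # min_nodes and are nested across thresholds
  hc_big <- homolog_conservation(circ, "seed_L", "seed_R",
                                 thresholds = c(1, 15), min_nodes = 500)
  expect_equal(hc_big$n_eligible_left, c(0L, 0L))
  expect_true(is.na(hc_big$p_mean[1]))
  expect_true(all(hc$n_eligible_left[-1] <= hc$n_eligible_left[1]))
})

test_that("fold change arithmetic and zero-denominator handling", {
  expect_equal(fold_change(0.02, 0.02), 1.0)
  expect_equal(fold_change(0.03, 0.02), 1.5)
  expect_error(fold_change(0.1, 0), "zero denominator")
  mfc <- mean_fold_change(c(1.0, 1.2))
  expect_equal(mfc$mean, 1.1)
  expect_equal(mfc$n, 2)
})

test_that("compare_volumes: identity, known fold change, flagged rows", {
  circ <- toy_pair(n_seed_links = 30, n_bg_links = 170)
  pairings <- data.frame(pre_cell_type = "Mechanosensory",
                         pre_segment = "A1", pre_side = "L",
                         post_cell_type = "Basin", post_segment = "A1",
                         post_side = "L", mode = "whole")
  same <- compare_volumes(circ, circ, pairings)
  expect_equal(same$fold_change, 1.0)
  expect_equal(same$chisq, 0, tolerance = 1e-12)

  circ_b <- toy_pair(n_seed_links = 60, n_bg_links = 140)
  cmp <- compare_volumes(circ, circ_b, pairings)
  expect_equal(cmp$fold_change, 2.0)
  tab <- rbind(c(30, 170), c(60, 140))
  ref <- chi_square_proportions(tab)
  expect_equal(cmp$p_value, ref$p_value)

  bad <- pairings
  bad$post_cell_type <- "Unicorn"
  flagged <- compare_volumes(circ, circ_b, bad)
  expect_true(!is.na(flagged$note))
  expect_true(is.na(flagged$p_value))
})

test_that("retention percentages round to the nearest integer percent", {
  ranking <- data.frame(
    skeleton_id = sprintf("p%02d", 1:60),
    synapses = c(rep(20, 23), rep(5, 37)),
    rank = 1:60,
    strength_class = c(rep("strong", 23), rep("weak", 37)))
  # 1 of 23 strong and 9 of 37 weak receive nothing in the experiment
  exp_counts <- stats::setNames(c(rep(10L, 22), 0L,
                                  rep(4L, 28), rep(0L, 9)),
                                ranking$skeleton_id)
  rs <- retention_stats(ranking, exp_counts)
  expect_equal(rs$failure_pct[rs$strength_class == "weak"], 24)
  expect_equal(rs$failure_pct[rs$strength_class == "strong"], 4)

  none <- retention_stats(ranking,
                          stats::setNames(rep(5L, 60), ranking$skeleton_id))
  expect_equal(none$failure_pct, c(0, 0))

  # the alternative failure rule counts sub-threshold partners as failed
  rs2 <- retention_stats(ranking, exp_counts, failure_rule = "below_min")
  expect_true(all(rs2$n_failed >= rs$n_failed))
})

test_that("new partners must be reproducible on both sides and absent from WT", {
  rk <- function(ids, n) data.frame(skeleton_id = ids, synapses = n,
                                    rank = seq_along(ids),
                                    strength_class = "weak")
  left <- rk(c("old1", "newA", "newB"), c(10, 4, 3))
  right <- rk(c("old1", "newA"), c(9, 5))
  got <- new_partners(left, right, wt_partner_ids = "old1")
  expect_equal(got, "newA")   # newB lacks right-side reproducibility
})
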