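#' Default designed input-fraction matrix
#'
#' Rows are presynaptic cell types, columns postsynaptic cell types;
#' entries are the designed fraction of the target's total input coming
#' from that hemisegmental group. Unassigned input is drawn from the
#' `Other` background pool. The defaults emulate the circuit schematic:
#' multisensory excitatory Basins receiving mechanosensory and nociceptive
#' input, inhibitory Ladder/Griddle/Drunken receiving mechanosensory
#' input, and axo-axonic inhibitory input onto the mechanosensory axons
#' themselves.
#'
#' @return numeric matrix (pre x post).
#' @export
default_fraction_matrix <- function() {
  pre <- c("Mechanosensory", "Nociceptive", "Basin", "Ladder", "Griddle",
           "Drunken", "Other")
  post <- c("Basin", "Ladder", "Griddle", "Drunken", "Mechanosensory")
  m <- matrix(0, length(pre), length(post), dimnames = list(pre, post))
  m["Mechanosensory", "Basin"] <- 0.20
  m["Nociceptive", "Basin"] <- 0.10
  m["Ladder", "Basin"] <- 0.10
  m["Mechanosensory", "Ladder"] <- 0.15
  m["Griddle", "Ladder"] <- 0.05
  m["Mechanosensory", "Griddle"] <- 0.12
  m["Mechanosensory", "Drunken"] <- 0.12
  m["Ladder", "Mechanosensory"] <- 0.05
  m["Drunken", "Mechanosensory"] <- 0.03
  m["Other", ] <- 1 - colSums(m[rownames(m) != "Other", ])
  m
}

#' Design for the synthetic circuit generator
#'
#' Defines the study conditions the generator realizes: a bilaterally
#' mirrored hemisegmental roster (8 mechanosensory axons, 4 Basins,
#' 6 bilateral Ladders, 1 Griddle, 1 Drunken, 3 nociceptive axons per
#' hemisegment), designed input-fraction matrices with fixed per-type
#' input totals, strength-binned left-right conservation probabilities,
#' and schematic skeleton geometry around cell-type placement centroids.
#'
#' @param segments segment labels (default `"A1"`).
#' @param roster named per-hemisegment counts for unilateral types.
#' @param bilateral named counts for bilateral types (instantiated once
#'   per segment, side `"bilateral"`).
#' @param n_other background neurons per hemisegment feeding the
#'   unassigned input fraction.
#' @param fraction_matrix pre x post designed fractions (per-post column
#'   sums at most 1; see [default_fraction_matrix()]).
#' @param total_inputs named total input counts per postsynaptic type.
#' @param conservation list with `breaks` (lower strength-bin edges) and
#'   `probs` (per-bin probability that a given side's seed connection
#'   exists; bilateral independence makes this equal to the measured
#'   conditional conservation), plus `count_max` (top of the last bin).
#' @param n_conservation_pairs homolog partner pairs per segment.
#' @param placement named list: cell type to `c(mean, sd)` mediolateral
#'   distance from the midline, nm.
#' @param n_nodes treenodes per skeleton (>= 5).
#' @param node_step_nm random-walk step SD for node placement.
#' @param neuropil_width,midline_x volume geometry, nm.
#' @return list of class `circuit_design`.
#' @export
circuit_design <- function(segments = "A1",
                           roster = c(Mechanosensory = 8, Basin = 4,
                                      Griddle = 1, Drunken = 1,
                                      Nociceptive = 3),
                           bilateral = c(Ladder = 6),
                           n_other = 20,
                           fraction_matrix = default_fraction_matrix(),
                           total_inputs = c(Basin = 400, Ladder = 300,
                                            Griddle = 200, Drunken = 200,
                                            Mechanosensory = 100),
                           conservation = list(
                             breaks = c(1, 5, 10, 15),
                             probs = c(0.75, 0.89, 0.97, 1.00),
                             count_max = 25),
                           n_conservation_pairs = 40,
                           placement = list(
                             Mechanosensory = c(8000, 1500),
                             Nociceptive = c(3000, 1000),
                             Basin = c(6000, 2000),
                             Ladder = c(0, 6000),
                             Griddle = c(5000, 1500),
                             Drunken = c(6000, 1500),
                             Other = c(6000, 4000),
                             Partner = c(6000, 4000)),
                           n_nodes = 30, node_step_nm = 800,
                           neuropil_width = 40000, midline_x = 0) {
  stopifnot(n_nodes >= 5,
            all(colSums(fraction_matrix) <= 1 + 1e-12),
            all(fraction_matrix >= 0),
            all(conservation$probs >= 0 & conservation$probs <= 1),
            length(conservation$breaks) == length(conservation$probs))
  structure(list(segments = segments, roster = roster,
                 bilateral = bilateral, n_other = n_other,
                 fraction_matrix = fraction_matrix,
                 total_inputs = total_inputs,
                 conservation = conservation,
                 n_conservation_pairs = n_conservation_pairs,
                 placement = placement, n_nodes = n_nodes,
                 node_step_nm = node_step_nm,
                 neuropil_width = neuropil_width, midline_x = midline_x),
            class = "circuit_design")
}

SENSORY_TYPES <- c("Mechanosensory", "Nociceptive")

synth_nodes <- function(design, skeleton_id, cell_type, side, seg_index) {
  n <- design$n_nodes
  pl <- design$placement[[cell_type]] %||% c(6000, 3000)
  sgn <- switch(side, L = -1, R = 1, 0)
  cx <- design$midline_x +
    if (sgn == 0) stats::rnorm(1, 0, pl[2]) else
      sgn * abs(stats::rnorm(1, pl[1], pl[2]))
  half <- design$neuropil_width / 2
  cx <- min(max(cx, design$midline_x - half), design$midline_x + half)
  cy <- (seg_index - 1) * 50000 + stats::runif(1, 10000, 40000)
  cz <- stats::rnorm(1, 0, 4000)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- c(cx, cy, cz)
  parent <- c(NA_integer_, integer(n - 1))
  for (i in seq_len(n)[-1]) {
    p <- sample.int(i - 1, 1)
    parent[i] <- p
    pos[i, ] <- pos[p, ] + stats::rnorm(3, 0, design$node_step_nm)
  }
  comp <- if (cell_type %in% SENSORY_TYPES) rep("axon", n) else {
    nd <- ceiling(0.6 * (n - 1))
    c("other", rep("dendrite", nd), rep("axon", n - 1 - nd))
  }
  data.frame(skeleton_id = skeleton_id, node_id = seq_len(n),
             parent_id = parent, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             compartment = comp)
}

post_target_compartment <- function(cell_type) {
  if (cell_type %in% SENSORY_TYPES) "axon"
  else if (cell_type == "Ladder") "any"
  else "dendrite"
}

sample_link_nodes <- function(nodes_by_skel, skels, compartment) {
  vapply(skels, function(sk) {
    nd <- nodes_by_skel[[sk]]
    pool <- if (compartment == "any") nd$node_id else
      nd$node_id[nd$compartment == compartment]
    if (!length(pool)) pool <- nd$node_id
    pool[sample.int(length(pool), 1)]
  }, integer(1))
}

# one block of links: count links from members of a pre group onto one post
synth_link_block <- function(nodes_by_skel, pre_members, post_skel,
                             count, post_compartment) {
  if (count == 0) return(NULL)
  pre <- pre_members[sample.int(length(pre_members), count, replace = TRUE)]
  pre_node <- sample_link_nodes(nodes_by_skel, pre, "axon")
  post_node <- sample_link_nodes(nodes_by_skel, rep(post_skel, count),
                                 post_compartment)
  data.frame(pre_skeleton = pre, pre_node = pre_node,
             post_skeleton = post_skel, post_node = post_node)
}

group_members_for <- function(metas, cell_type, segment, side) {
  sel <- metas$cell_type == cell_type & metas$segment == segment &
    (metas$side == side | metas$side == "bilateral")
  metas$skeleton_id[sel]
}

# realize the designed input fractions for a set of post neurons
synth_inputs <- function(design, metas, nodes_by_skel, post_ids,
                         fraction_matrix = design$fraction_matrix) {
  blocks <- list()
  for (post_skel in post_ids) {
    i <- match(post_skel, metas$skeleton_id)
    ptype <- metas$cell_type[i]
    if (!(ptype %in% colnames(fraction_matrix)) ||
        is.na(design$total_inputs[ptype])) next
    total <- design$total_inputs[[ptype]]
    sides <- if (metas$side[i] == "bilateral") c("L", "R") else metas$side[i]
    tot_side <- if (length(sides) == 2)
      c(floor(total / 2), ceiling(total / 2)) else total
    fr <- fraction_matrix[, ptype]
    fr <- fr[fr > 0]
    for (si in seq_along(sides)) {
      counts <- as.integer(stats::rmultinom(1, tot_side[si], fr))
      names(counts) <- names(fr)
      for (pre_type in names(counts)) {
        members <- group_members_for(metas, pre_type, metas$segment[i],
                                     sides[si])
        members <- setdiff(members, post_skel)  # no autapses
        if (!length(members)) next
        blocks[[length(blocks) + 1]] <-
          synth_link_block(nodes_by_skel, members, post_skel,
                           counts[[pre_type]],
                           post_target_compartment(ptype))
      }
    }
  }
  do.call(rbind, blocks)
}

# assemble flat links into polyadic connectors keyed by presynaptic node
finalize_connectors <- function(links, nodes_by_skel, id_offset = 0) {
  if (is.null(links) || !nrow(links)) return(empty_connectors())
  pre_key <- paste(links$pre_skeleton, links$pre_node)
  links$connector_id <- match(pre_key, unique(pre_key)) + id_offset
  # a (pre, post) pairing may appear at most once per connector:
  # duplicates become their own connectors
  pair <- paste(links$connector_id, links$post_skeleton, links$post_node)
  dup <- duplicated(pair)
  if (any(dup))
    links$connector_id[dup] <- max(links$connector_id) + seq_len(sum(dup))
  xyz <- t(vapply(seq_len(nrow(links)), function(r) {
    nd <- nodes_by_skel[[links$pre_skeleton[r]]]
    j <- match(links$pre_node[r], nd$node_id)
    c(nd$x[j], nd$y[j], nd$z[j])
  }, numeric(3)))
  data.frame(connector_id = links$connector_id,
             pre_skeleton = links$pre_skeleton, pre_node = links$pre_node,
             post_skeleton = links$post_skeleton,
             post_node = links$post_node,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Generate a synthetic circuit with known ground truth
#'
#' Realizes a [circuit_design()]: bilaterally mirrored hemisegments with
#' homolog annotations, schematic random-walk skeletons around cell-type
#' placement centroids, input links drawn multinomially to realize the
#' designed fraction matrix at the designed totals, and homolog partner
#' pairs whose seed connections exist on each side independently with the
#' designed strength-bin probability. Connectors are polyadic, grouped by
#' presynaptic node and placed at it. Pure function of (design, seed).
#'
#' @param design a [circuit_design()].
#' @param seed integer master seed.
#' @return list with `circuit` (a validated [circuit()]) and
#'   `ground_truth` (`design`, designed `fractions`/`totals`, and the
#'   per-pair `conservation` draws).
#' @export
generate_circuit <- function(design = circuit_design(), seed = 1) {
  set.seed(seed)
  metas <- list()
  add_meta <- function(id, type, seg, side, hom = NA_character_,
                       ident = TRUE)
    metas[[length(metas) + 1]] <<- data.frame(
      skeleton_id = id, cell_type = type, segment = seg, side = side,
      homolog_id = hom, identified = ident)
  for (seg in design$segments) {
    for (type in names(design$roster))
      for (k in seq_len(design$roster[[type]])) {
        idL <- paste(seg, "L", type, k, sep = "_")
        idR <- paste(seg, "R", type, k, sep = "_")
        add_meta(idL, type, seg, "L", hom = idR)
        add_meta(idR, type, seg, "R", hom = idL)
      }
    for (type in names(design$bilateral))
      for (k in seq_len(design$bilateral[[type]]))
        add_meta(paste(seg, "bi", type, k, sep = "_"), type, seg,
                 "bilateral")
    for (side in c("L", "R"))
      for (k in seq_len(design$n_other))
        add_meta(paste(seg, side, "Other", k, sep = "_"), "Other", seg,
                 side, ident = FALSE)
    for (k in seq_len(design$n_conservation_pairs)) {
      idL <- paste(seg, "L", "Partner", k, sep = "_")
      idR <- paste(seg, "R", "Partner", k, sep = "_")
      add_meta(idL, "Partner", seg, "L", hom = idR)
      add_meta(idR, "Partner", seg, "R", hom = idL)
    }
  }
  metas <- do.call(rbind, metas)

  nodes_by_skel <- stats::setNames(
    lapply(seq_len(nrow(metas)), function(i)
      synth_nodes(design, metas$skeleton_id[i], metas$cell_type[i],
                  metas$side[i], match(metas$segment[i], design$segments))),
    metas$skeleton_id)

  post_ids <- metas$skeleton_id[metas$cell_type %in%
                                  colnames(design$fraction_matrix)]
  links <- synth_inputs(design, metas, nodes_by_skel, post_ids)

  # homolog conservation pairs: per pair a strength bin, then each side's
  # seed connection exists independently with the bin's probability
  cons <- design$conservation
  lo <- cons$breaks
  hi <- c(cons$breaks[-1], cons$count_max + 1)
  cons_rows <- list()
  cons_links <- list(links)
  draw_count <- function(b) {
    vals <- seq(lo[b], hi[b] - 1)
    vals[sample.int(length(vals), 1)]
  }
  for (seg in design$segments) {
    seedL <- group_members_for(metas, "Mechanosensory", seg, "L")
    seedR <- group_members_for(metas, "Mechanosensory", seg, "R")
    for (k in seq_len(design$n_conservation_pairs)) {
      b <- sample.int(length(lo), 1)
      cL <- if (stats::runif(1) < cons$probs[b]) draw_count(b) else 0L
      cR <- if (stats::runif(1) < cons$probs[b]) draw_count(b) else 0L
      idL <- paste(seg, "L", "Partner", k, sep = "_")
      idR <- paste(seg, "R", "Partner", k, sep = "_")
      if (cL > 0)
        cons_links[[length(cons_links) + 1]] <-
          synth_link_block(nodes_by_skel, seedL, idL, cL, "dendrite")
      if (cR > 0)
        cons_links[[length(cons_links) + 1]] <-
          synth_link_block(nodes_by_skel, seedR, idR, cR, "dendrite")
      cons_rows[[length(cons_rows) + 1]] <-
        data.frame(segment = seg, pair = k, bin = b,
                   left_count = cL, right_count = cR)
    }
  }
  links <- do.call(rbind, cons_links)

  connectors <- finalize_connectors(links, nodes_by_skel)
  circ <- circuit(do.call(rbind, nodes_by_skel), connectors, metas,
                  volume_spec(design$midline_x, design$neuropil_width))
  attr(circ, "design") <- design
  list(circuit = circ,
       ground_truth = list(design = design,
                           fractions = design$fraction_matrix,
                           totals = design$total_inputs,
                           conservation = do.call(rbind, cons_rows)))
}

#' Perturb a synthetic circuit
#'
#' Two perturbation kinds emulate the study's manipulations.
#' `lateral_shift` displaces the target cell type's treenodes and
#' presynaptic connector sites laterally (away from the midline) by a
#' per-axon offset drawn from `N(shift_nm, jitter_nm)`, emulating a
#' guidance-receptor shift. `silencing_rewire` resamples the input links
#' of the affected postsynaptic neurons under gain-multiplied designed
#' fractions (clipped to \[0, 1\], remainder reassigned to the background
#' pool), emulating the connectivity effect of developmental silencing.
#' Annotations are preserved.
#'
#' @param circuit a generated [circuit()] (carries its design).
#' @param spec a list: `kind = "lateral_shift"` with `cell_type`,
#'   `shift_nm`, `jitter_nm`; or `kind = "silencing_rewire"` with `gains`
#'   (data.frame `pre_type`, `post_type`, `gain`).
#' @param seed integer seed.
#' @return the perturbed circuit.
#' @export
apply_perturbation <- function(circuit, spec, seed = 1) {
  set.seed(seed)
  if (spec$kind == "lateral_shift") {
    targets <- circuit$metas$skeleton_id[circuit$metas$cell_type ==
                                           spec$cell_type]
    jitter <- spec$jitter_nm %||% 0
    for (sk in targets) {
      sel <- circuit$nodes$skeleton_id == sk
      dir <- sign(stats::median(circuit$nodes$x[sel]) -
                    circuit$volume$midline_x)
      if (dir == 0) dir <- 1
      offset <- dir * stats::rnorm(1, spec$shift_nm, jitter)
      circuit$nodes$x[sel] <- circuit$nodes$x[sel] + offset
      csel <- circuit$connectors$pre_skeleton == sk
      circuit$connectors$x[csel] <- circuit$connectors$x[csel] + offset
    }
    return(circuit)
  }
  if (spec$kind == "silencing_rewire") {
    design <- attr(circuit, "design")
    if (is.null(design))
      stop("silencing_rewire needs a circuit generated by generate_circuit")
    fm <- design$fraction_matrix
    for (r in seq_len(nrow(spec$gains))) {
      g <- spec$gains[r, ]
      fm[g$pre_type, g$post_type] <-
        min(1, fm[g$pre_type, g$post_type] * g$gain)
    }
    assigned <- colSums(fm[rownames(fm) != "Other", , drop = FALSE])
    if (any(assigned > 1)) stop("gains make fractions sum above 1")
    fm["Other", ] <- 1 - assigned
    posts <- circuit$metas$skeleton_id[circuit$metas$cell_type %in%
                                         unique(spec$gains$post_type)]
    nodes_by_skel <- split(circuit$nodes, circuit$nodes$skeleton_id)
    keep <- !(circuit$connectors$post_skeleton %in% posts)
    new_links <- synth_inputs(design, circuit$metas, nodes_by_skel, posts,
                              fraction_matrix = fm)
    new_conn <- finalize_connectors(new_links, nodes_by_skel,
                                    id_offset =
                                      max(c(0, circuit$connectors$connector_id)))
    circuit$connectors <- rbind(circuit$connectors[keep, ], new_conn)
    rownames(circuit$connectors) <- NULL
    return(circuit)
  }
  stop("unknown perturbation kind: ", spec$kind)
}
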