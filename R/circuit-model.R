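#' @keywords internal
"_PACKAGE"

COMPARTMENTS <- c("axon", "dendrite", "other")

#' Construct a skeletonized circuit
#'
#' A circuit bundles skeletonized neuron reconstructions (rooted trees of
#' treenodes with nm coordinates), polyadic chemical synapses flattened to
#' one row per pre-to-post link, per-neuron annotations, and the geometry of
#' the imaged volume. Coordinates are stored in nm (the convention of
#' CATMAID-style reconstructions); user-facing lengths are reported in um
#' and densities per mm.
#'
#' @param nodes data.frame with columns `skeleton_id`, `node_id`,
#'   `parent_id` (NA at the root), `x`, `y`, `z` (nm), `compartment`
#'   (one of `"axon"`, `"dendrite"`, `"other"`).
#' @param connectors data.frame with one row per pre-to-post link:
#'   `connector_id`, `pre_skeleton`, `pre_node`, `post_skeleton`,
#'   `post_node`, `x`, `y`, `z`. Rows sharing a `connector_id` form one
#'   polyadic connector (one presynaptic site, several postsynaptic links).
#' @param metas data.frame with columns `skeleton_id`, `cell_type`,
#'   `segment`, `side` (`"L"`, `"R"` or `"bilateral"`), `homolog_id`
#'   (NA when unpaired), `identified` (logical).
#' @param volume list with `midline_x` (nm), `neuropil_width` (nm) and
#'   optional `bounds` / `subvolume` boxes (see [box_spec()]).
#' @param validate validate invariants on construction.
#' @return an object of class `circuit`.
#' @seealso [validate_circuit()], [load_circuit()]
#' @export
circuit <- function(nodes, connectors = empty_connectors(), metas,
                    volume = volume_spec(), validate = TRUE) {
  nodes$skeleton_id <- as.character(nodes$skeleton_id)
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$compartment <- as.character(nodes$compartment)
  connectors <- as.data.frame(connectors)
  if (nrow(connectors)) {
    connectors$pre_skeleton <- as.character(connectors$pre_skeleton)
    connectors$post_skeleton <- as.character(connectors$post_skeleton)
  }
  metas$skeleton_id <- as.character(metas$skeleton_id)
  metas$homolog_id <- as.character(metas$homolog_id)
  x <- structure(list(nodes = as.data.frame(nodes),
                      connectors = connectors,
                      metas = as.data.frame(metas),
                      volume = volume),
                 class = "circuit")
  if (validate) validate_circuit(x)
  x
}

empty_connectors <- function() {
  data.frame(connector_id = integer(), pre_skeleton = character(),
             pre_node = integer(), post_skeleton = character(),
             post_node = integer(), x = numeric(), y = numeric(),
             z = numeric())
}

#' Volume geometry
#'
#' @param midline_x mediolateral position of the midline, nm.
#' @param neuropil_width width of the neuropil, nm (> 0). Mediolateral
#'   positions are normalized to this width and centered at the midline.
#' @param bounds,subvolume optional axis-aligned boxes ([box_spec()]);
#'   `subvolume` must be contained in `bounds` when both are given.
#' @export
volume_spec <- function(midline_x = 0, neuropil_width = 40000,
                        bounds = NULL, subvolume = NULL) {
  stopifnot(is.finite(midline_x), neuropil_width > 0)
  if (!is.null(bounds)) bounds <- box_spec(bounds)
  if (!is.null(subvolume)) {
    subvolume <- box_spec(subvolume)
    if (!is.null(bounds) && !all(subvolume[c(1, 3, 5)] >= bounds[c(1, 3, 5)] &
                                 subvolume[c(2, 4, 6)] <= bounds[c(2, 4, 6)]))
      stop("subvolume must be contained in bounds")
  }
  list(midline_x = midline_x, neuropil_width = neuropil_width,
       bounds = bounds, subvolume = subvolume)
}

#' Axis-aligned box in nm
#'
#' @param box numeric of length 6, `c(xmin, xmax, ymin, ymax, zmin, zmax)`,
#'   or a named list with those fields.
#' @export
box_spec <- function(box) {
  if (is.list(box))
    box <- unlist(box[c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")])
  box <- as.numeric(box)
  if (length(box) != 6 || any(!is.finite(box)))
    stop("box must be 6 finite numbers: xmin, xmax, ymin, ymax, zmin, zmax")
  if (box[1] > box[2] || box[3] > box[4] || box[5] > box[6])
    stop("box has min > max on some axis")
  names(box) <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  box
}

#' Validate a circuit's invariants
#'
#' Checks node-id uniqueness, parent references, single-rootedness and
#' acyclicity per skeleton, connector endpoint resolution, non-empty
#' polyadic post lists, uniqueness of (pre, post) pairings within one
#' connector, one meta per skeleton, and symmetry of homolog pairing.
#' Errors name the offending record.
#'
#' @param x a [circuit()].
#' @param forest_ok allow several roots per skeleton (used for circuits
#'   derived by [restrict_to_subvolume()], which can cut a tree into a
#'   forest).
#' @return `x`, invisibly.
#' @export
validate_circuit <- function(x, forest_ok = FALSE) {
  nodes <- x$nodes
  if (!all(c("skeleton_id", "node_id", "parent_id", "x", "y", "z",
             "compartment") %in% names(nodes)))
    stop("nodes table is missing required columns")
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z)))
    stop("non-finite coordinates in nodes for skeleton ",
         nodes$skeleton_id[which(!is.finite(nodes$x * nodes$y * nodes$z))[1]])
  if (!all(nodes$compartment %in% COMPARTMENTS))
    stop("unknown compartment label: ",
         setdiff(nodes$compartment, COMPARTMENTS)[1])
  key <- paste(nodes$skeleton_id, nodes$node_id)
  if (anyDuplicated(key))
    stop("duplicate node_id ", key[anyDuplicated(key)], " within a skeleton")
  for (sk in unique(nodes$skeleton_id)) {
    nd <- nodes[nodes$skeleton_id == sk, ]
    root <- is.na(nd$parent_id)
    if (!any(root)) stop("skeleton ", sk, " has no root")
    if (!forest_ok && sum(root) > 1)
      stop("skeleton ", sk, " has multiple roots")
    if (!all(nd$parent_id[!root] %in% nd$node_id))
      stop("skeleton ", sk, " node ",
           nd$node_id[!root][which(!(nd$parent_id[!root] %in% nd$node_id))[1]],
           " has a dangling parent_id")
    # walk parents; a cycle never reaches a root
    idx <- match(nd$parent_id, nd$node_id)
    depth <- rep(NA_integer_, nrow(nd))
    depth[root] <- 0L
    pending <- which(!root)
    while (length(pending)) {
      ready <- pending[!is.na(depth[idx[pending]])]
      if (!length(ready)) stop("skeleton ", sk, " has cyclic parent links")
      depth[ready] <- depth[idx[ready]] + 1L
      pending <- setdiff(pending, ready)
    }
  }
  cn <- x$connectors
  if (nrow(cn)) {
    pre_ok <- paste(cn$pre_skeleton, cn$pre_node) %in% key
    post_ok <- paste(cn$post_skeleton, cn$post_node) %in% key
    if (!all(pre_ok))
      stop("connector ", cn$connector_id[which(!pre_ok)[1]],
           " references a missing presynaptic node")
    if (!all(post_ok))
      stop("connector ", cn$connector_id[which(!post_ok)[1]],
           " references a missing postsynaptic node")
    pair <- paste(cn$connector_id, cn$post_skeleton, cn$post_node)
    if (anyDuplicated(pair))
      stop("connector ", cn$connector_id[anyDuplicated(pair)],
           " repeats a (pre, post) pairing")
    multi_pre <- tapply(paste(cn$pre_skeleton, cn$pre_node),
                        cn$connector_id, function(v) length(unique(v)))
    if (any(multi_pre > 1))
      stop("connector ", names(multi_pre)[which(multi_pre > 1)[1]],
           " has more than one presynaptic site")
  }
  metas <- x$metas
  sk_ids <- unique(nodes$skeleton_id)
  if (anyDuplicated(metas$skeleton_id))
    stop("duplicate meta for skeleton ",
         metas$skeleton_id[anyDuplicated(metas$skeleton_id)])
  missing_meta <- setdiff(sk_ids, metas$skeleton_id)
  if (length(missing_meta))
    stop("skeleton ", missing_meta[1], " has no meta annotation")
  paired <- metas[!is.na(metas$homolog_id), ]
  if (nrow(paired)) {
    if (any(paired$homolog_id == paired$skeleton_id))
      stop("skeleton ", paired$skeleton_id[paired$homolog_id ==
             paired$skeleton_id][1], " is paired with itself")
    back <- metas$homolog_id[match(paired$homolog_id, metas$skeleton_id)]
    bad <- is.na(back) | back != paired$skeleton_id
    if (any(bad))
      stop("homolog pairing of skeleton ", paired$skeleton_id[which(bad)[1]],
           " is not symmetric")
  }
  invisible(x)
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", length(unique(x$nodes$skeleton_id)), " skeletons, ",
      nrow(x$nodes), " treenodes, ", nrow(x$connectors),
      " synaptic links\n", sep = "")
  invisible(x)
}

skeleton_ids <- function(circuit) unique(circuit$nodes$skeleton_id)

#' Number of treenodes in a skeleton
#'
#' Reconstruction size in nodes; the unit of the "at least 500 nodes"
#' eligibility filter used by [homolog_conservation()].
#'
#' @param circuit a [circuit()].
#' @param skeleton_id one or more skeleton ids.
#' @return named integer vector of node counts.
#' @export
node_count <- function(circuit, skeleton_id = skeleton_ids(circuit)) {
  tab <- table(factor(circuit$nodes$skeleton_id, levels = skeleton_id))
  stats::setNames(as.integer(tab), skeleton_id)
}

#' Cable length of a skeleton
#'
#' Summed Euclidean length of parent-child edges, in um. Each edge is
#' attributed to the child node's compartment, so the per-compartment
#' lengths partition the total.
#'
#' @param circuit a [circuit()].
#' @param skeleton_id skeleton id(s); lengths are summed over them.
#' @param compartment `"all"` or one of `"axon"`, `"dendrite"`, `"other"`.
#' @return length in um (0 for a single-node skeleton).
#' @export
cable_length <- function(circuit, skeleton_id, compartment = "all") {
  nd <- circuit$nodes[circuit$nodes$skeleton_id %in% skeleton_id, ]
  ch <- nd[!is.na(nd$parent_id), ]
  if (compartment != "all") {
    stopifnot(compartment %in% COMPARTMENTS)
    ch <- ch[ch$compartment == compartment, ]
  }
  if (!nrow(ch)) return(0)
  pi <- match(paste(ch$skeleton_id, ch$parent_id),
              paste(nd$skeleton_id, nd$node_id))
  sum(sqrt((ch$x - nd$x[pi])^2 + (ch$y - nd$y[pi])^2 +
           (ch$z - nd$z[pi])^2)) / 1000
}

in_box <- function(x, y, z, box) {
  x >= box[1] & x <= box[2] & y >= box[3] & y <= box[4] &
    z >= box[5] & z <= box[6]
}

#' Restrict a circuit to an axis-aligned subvolume
#'
#' Emulates the coverage correction used when a partially imaged volume is
#' compared with a whole-nervous-system reference: treenodes outside the
#' box are removed, and a synaptic link is kept only when both its
#' presynaptic node and that postsynaptic node remain. Children of removed
#' nodes become roots, so restricted skeletons may be forests. Metas of
#' skeletons left with no nodes are dropped. The operation is idempotent
#' and per-group synapse counts are monotone non-increasing.
#'
#' @param circuit a [circuit()].
#' @param box a [box_spec()] (closed on all faces).
#' @return the restricted circuit (possibly empty).
#' @export
restrict_to_subvolume <- function(circuit, box) {
  box <- box_spec(box)
  nd <- circuit$nodes
  keep <- in_box(nd$x, nd$y, nd$z, box)
  nd <- nd[keep, , drop = FALSE]
  still <- paste(nd$skeleton_id, nd$parent_id) %in%
    paste(nd$skeleton_id, nd$node_id)
  nd$parent_id[!still] <- NA_integer_
  cn <- circuit$connectors
  if (nrow(cn)) {
    key <- paste(nd$skeleton_id, nd$node_id)
    cn <- cn[paste(cn$pre_skeleton, cn$pre_node) %in% key &
             paste(cn$post_skeleton, cn$post_node) %in% key, , drop = FALSE]
  }
  metas <- circuit$metas[circuit$metas$skeleton_id %in% nd$skeleton_id, ,
                         drop = FALSE]
  vol <- circuit$volume
  vol$subvolume <- box
  out <- structure(list(nodes = nd, connectors = cn, metas = metas,
                        volume = vol), class = "circuit")
  validate_circuit(out, forest_ok = TRUE)
  out
}
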