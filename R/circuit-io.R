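SWC_TYPE_TO_COMPARTMENT <- c("2" = "axon", "3" = "dendrite")

compartment_to_swc_type <- function(compartment) {
  unname(c(axon = 2L, dendrite = 3L, other = 0L)[compartment])
}

#' Read one SWC file as a node table
#'
#' Columns are the SWC standard `id type x y z radius parent` (whitespace
#' separated, `#` comments). The type column encodes the compartment:
#' 2 = axon, 3 = dendrite, anything else = other/unlabeled. `parent` is -1
#' at the root. Coordinates are taken to be nm.
#'
#' @param path SWC file; the skeleton id defaults to the file name without
#'   extension.
#' @param skeleton_id override the skeleton id.
#' @return data.frame in the [circuit()] nodes layout.
#' @export
read_swc <- function(path, skeleton_id = sub("\\.swc$", "", basename(path))) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  comp <- SWC_TYPE_TO_COMPARTMENT[as.character(raw$type)]
  comp[is.na(comp)] <- "other"
  data.frame(skeleton_id = skeleton_id,
             node_id = as.integer(raw$id),
             parent_id = ifelse(raw$parent < 0, NA_integer_,
                                as.integer(raw$parent)),
             x = raw$x, y = raw$y, z = raw$z,
             compartment = unname(comp))
}

#' Write one skeleton to SWC
#'
#' @param circuit a [circuit()].
#' @param skeleton_id skeleton to write.
#' @param path output file.
#' @export
write_swc <- function(circuit, skeleton_id, path) {
  nd <- circuit$nodes[circuit$nodes$skeleton_id == skeleton_id, ]
  if (!nrow(nd)) stop("unknown skeleton ", skeleton_id)
  out <- data.frame(id = nd$node_id,
                    type = compartment_to_swc_type(nd$compartment),
                    x = nd$x, y = nd$y, z = nd$z, radius = 0,
                    parent = ifelse(is.na(nd$parent_id), -1L, nd$parent_id))
  utils::write.table(out, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Load a circuit from files
#'
#' Either a set of SWC skeletons plus synapse and annotation CSV tables, or
#' a single JSON circuit document (the dialect written by
#' [write_circuit_json()]).
#'
#' The synapse CSV has one row per pre-to-post link with columns
#' `connector_id, pre_skeleton, pre_node, post_skeleton, post_node, x, y, z`;
#' the annotation CSV has columns
#' `skeleton_id, cell_type, segment, side, homolog_id, identified`.
#'
#' @param json path to a JSON circuit document (exclusive with the rest).
#' @param swc character vector of SWC file paths.
#' @param synapses path to the synapse CSV (optional; no links when absent).
#' @param annotations path to the annotation CSV.
#' @param volume a [volume_spec()].
#' @return a validated [circuit()].
#' @export
load_circuit <- function(json = NULL, swc = NULL, synapses = NULL,
                         annotations = NULL, volume = volume_spec()) {
  if (!is.null(json)) return(read_circuit_json(json))
  if (is.null(swc) || is.null(annotations))
    stop("need either `json` or both `swc` and `annotations`")
  nodes <- do.call(rbind, lapply(swc, read_swc))
  connectors <- if (is.null(synapses)) empty_connectors() else
    required_cols(utils::read.csv(synapses),
                  names(empty_connectors()), "synapse")
  metas <- required_cols(utils::read.csv(annotations),
                         c("skeleton_id", "cell_type", "segment", "side",
                           "homolog_id", "identified"), "annotation")
  metas$identified <- as.logical(metas$identified)
  circuit(nodes, connectors, metas, volume)
}

#' Write / read a circuit as one JSON document
#'
#' The dialect has four members: `skeletons` (a map from skeleton id to an
#' SWC-equivalent node array), `connectors` (one entry per polyadic
#' connector, with its post list), `metas`, and `volume`. Round-trips
#' exactly (up to numeric printing, which is written at full precision).
#'
#' @param circuit a [circuit()].
#' @param path output (input) file.
#' @return `path` (`read_circuit_json`: a validated [circuit()]).
#' @export
write_circuit_json <- function(circuit, path) {
  sk <- split(circuit$nodes[, -1], circuit$nodes$skeleton_id)
  cn <- circuit$connectors
  conn_list <- lapply(split(cn, cn$connector_id), function(g) {
    list(connector_id = g$connector_id[1],
         pre = list(skeleton_id = g$pre_skeleton[1], node_id = g$pre_node[1]),
         posts = data.frame(skeleton_id = g$post_skeleton,
                            node_id = g$post_node),
         x = g$x[1], y = g$y[1], z = g$z[1])
  })
  doc <- list(skeletons = sk, connectors = unname(conn_list),
              metas = circuit$metas, volume = circuit$volume)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_circuit_json
#' @export
read_circuit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- do.call(rbind, lapply(names(doc$skeletons), function(id) {
    nd <- doc$skeletons[[id]]
    nd$parent_id <- as.integer(nd$parent_id)
    cbind(skeleton_id = id, nd)
  }))
  conns <- doc$connectors
  connectors <- if (is.null(conns) || !length(conns)) empty_connectors() else
    do.call(rbind, lapply(seq_len(nrow(conns)), function(i) {
      posts <- conns$posts[[i]]
      data.frame(connector_id = conns$connector_id[i],
                 pre_skeleton = conns$pre$skeleton_id[i],
                 pre_node = conns$pre$node_id[i],
                 post_skeleton = posts$skeleton_id,
                 post_node = posts$node_id,
                 x = conns$x[i], y = conns$y[i], z = conns$z[i])
    }))
  vol <- doc$volume
  circuit(nodes, connectors, doc$metas,
          volume_spec(vol$midline_x, vol$neuropil_width,
                      bounds = vol$bounds, subvolume = vol$subvolume))
}
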