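#' Resolve a hemisegmental cell-type group
#'
#' Individual neurons of the same cell type in one hemisegment are grouped
#' for all connectivity quantifications (e.g. the 8 mechanosensory axons or
#' 4 Basin interneurons of one hemisegment). Bilateral cell types (side
#' annotation `"bilateral"`, e.g. Ladder) are included on both sides.
#'
#' @param circuit a [circuit()].
#' @param cell_type,segment,side annotation filters; `segment`/`side` may
#'   be NULL to match any.
#' @param expected_size when given, error unless exactly this many members
#'   resolve.
#' @return character vector of member skeleton ids.
#' @export
resolve_group <- function(circuit, cell_type, segment = NULL, side = NULL,
                          expected_size = NULL) {
  m <- circuit$metas
  sel <- m$cell_type == cell_type
  if (!is.null(segment)) sel <- sel & m$segment == segment
  if (!is.null(side)) sel <- sel & (m$side == side | m$side == "bilateral")
  members <- m$skeleton_id[sel]
  if (!is.null(expected_size) && length(members) != expected_size)
    stop("group ", cell_type, "/", segment %||% "*", "/", side %||% "*",
         " resolved ", length(members), " members, expected ", expected_size)
  members
}

`%||%` <- function(a, b) if (is.null(a)) b else a

node_compartment <- function(circuit, skeleton, node) {
  nd <- circuit$nodes
  nd$compartment[match(paste(skeleton, node),
                       paste(nd$skeleton_id, nd$node_id))]
}

link_rows <- function(circuit, pre, post,
                      pre_compartment = "all", post_compartment = "all") {
  cn <- circuit$connectors
  sel <- cn$pre_skeleton %in% pre & cn$post_skeleton %in% post
  if (pre_compartment != "all")
    sel <- sel & node_compartment(circuit, cn$pre_skeleton,
                                  cn$pre_node) == pre_compartment
  if (post_compartment != "all")
    sel <- sel & node_compartment(circuit, cn$post_skeleton,
                                  cn$post_node) == post_compartment
  cn[sel, , drop = FALSE]
}

#' Count synapses from one group onto another
#'
#' Each pre-to-post link of a polyadic connector counts once, the
#' convention under which inputs summed over all seed axons are additive.
#'
#' @param circuit a [circuit()].
#' @param pre,post skeleton id vectors (from [resolve_group()] or single
#'   neurons).
#' @param pre_compartment,post_compartment `"all"` or a compartment label;
#'   a link is counted only when its presynaptic node lies in
#'   `pre_compartment` and its postsynaptic node in `post_compartment`.
#' @return integer count.
#' @export
group_synapse_count <- function(circuit, pre, post,
                                pre_compartment = "all",
                                post_compartment = "all") {
  nrow(link_rows(circuit, pre, post, pre_compartment, post_compartment))
}

#' Fraction of synaptic input received from a group
#'
#' Synapses from `pre` onto `post`, divided by the total number of inputs
#' of `post`. Modes: `"whole"` uses all inputs; `"dendritic"` restricts
#' both numerator and denominator to links onto dendrites (used for cell
#' types that receive their seed input mostly on dendrites);
#' `"subvolume"` computes both counts after [restrict_to_subvolume()]
#' (the coverage correction for arbors that leave a partial volume).
#' Groups are resolved against the full circuit before any restriction.
#'
#' @param circuit a [circuit()].
#' @param pre,post skeleton id vectors.
#' @param mode one of `"whole"`, `"dendritic"`, `"subvolume"`.
#' @param box subvolume box, required for `mode = "subvolume"`; defaults
#'   to the volume's stored subvolume.
#' @return list with `n_from_pre`, `n_total`, `fraction`.
#' @export
input_fraction <- function(circuit, pre, post,
                           mode = c("whole", "dendritic", "subvolume"),
                           box = NULL) {
  mode <- match.arg(mode)
  post_comp <- "all"
  if (mode == "subvolume") {
    box <- box %||% circuit$volume$subvolume
    if (is.null(box)) stop("subvolume mode needs a box")
    circuit <- restrict_to_subvolume(circuit, box)
  } else if (mode == "dendritic") {
    post_comp <- "dendrite"
  }
  n_total <- group_synapse_count(circuit, skeleton_ids(circuit), post,
                                 post_compartment = post_comp)
  if (n_total == 0)
    stop("input fraction undefined: target has no input under mode ", mode)
  n_pre <- group_synapse_count(circuit, pre, post,
                               post_compartment = post_comp)
  list(n_from_pre = n_pre, n_total = n_total, fraction = n_pre / n_total)
}

#' Synapse density per mm of cable
#'
#' Synapses from `pre` onto `post` divided by the postsynaptic cable length
#' of the selected compartment, in synapses per mm.
#'
#' @param circuit a [circuit()].
#' @param pre,post skeleton id vectors (`post` typically a single neuron).
#' @param compartment cable (and postsynaptic-node) compartment, or
#'   `"all"`.
#' @return list with `n_synapses`, `cable_mm`, `density`.
#' @export
synapse_density_per_cable <- function(circuit, pre, post,
                                      compartment = "all") {
  cable_mm <- cable_length(circuit, post, compartment) / 1000
  if (cable_mm <= 0) stop("zero cable length for the selected compartment")
  n <- group_synapse_count(circuit, pre, post,
                           post_compartment = compartment)
  list(n_synapses = n, cable_mm = cable_mm, density = n / cable_mm)
}

#' Rank postsynaptic partners of a seed group
#'
#' Sums, per candidate postsynaptic neuron, the links received from all
#' seed members, keeps candidates at or above the significant-connectivity
#' threshold, and classifies them as strongly (>= `strong_threshold`
#' synapses) or weakly connected. Both thresholds are inclusive.
#'
#' @param circuit a [circuit()].
#' @param seed seed skeleton ids (e.g. the 8 mechanosensory axons).
#' @param min_synapses inclusion threshold (default 3).
#' @param strong_threshold strong/weak boundary (default 15; exactly 15 is
#'   strong).
#' @return data.frame with `skeleton_id`, `synapses`, `rank`,
#'   `strength_class`, ordered by descending synapse count (ties broken by
#'   skeleton id for determinism).
#' @export
rank_partners <- function(circuit, seed, min_synapses = 3,
                          strong_threshold = 15) {
  cn <- circuit$connectors
  cn <- cn[cn$pre_skeleton %in% seed & !(cn$post_skeleton %in% seed), ,
           drop = FALSE]
  counts <- table(cn$post_skeleton)
  counts <- counts[counts >= min_synapses]
  ids <- names(counts)[order(-as.integer(counts), names(counts))]
  n <- as.integer(counts)[order(-as.integer(counts), names(counts))]
  data.frame(skeleton_id = ids, synapses = n,
             rank = seq_along(ids),
             strength_class = c("weak", "strong")[(n >= strong_threshold) + 1L])
}

seed_counts <- function(circuit, seed) {
  cn <- circuit$connectors
  cn <- cn[cn$pre_skeleton %in% seed & !(cn$post_skeleton %in% seed), ,
           drop = FALSE]
  tab <- table(cn$post_skeleton)
  stats::setNames(as.integer(tab), names(tab))
}

#' Left-right homolog conservation probability
#'
#' For partners connected to the seed group of one hemisegment with at
#' least `t` synapses, the probability that the bilaterally homologous
#' neuron receives at least one synapse from the opposite hemisegment's
#' seed group. Eligibility requires a homolog annotation, at least
#' `min_nodes` reconstructed nodes and (optionally) identified status.
#' The left and right calculations are averaged (`p_mean`).
#'
#' With `binned = TRUE` the thresholds are instead treated as lower edges
#' of half-open strength bins `[t_i, t_{i+1})` (the last bin unbounded),
#' which is the resolution at which the synthetic generator designs its
#' conservation probabilities.
#'
#' @param circuit a [circuit()].
#' @param seed_L,seed_R seed skeleton ids of the two hemisegments.
#' @param thresholds synapse-count thresholds (default `c(1, 5, 10, 15)`).
#' @param min_nodes minimum reconstruction size in nodes (default 500).
#' @param identified_only restrict to identified partners (default TRUE).
#' @param binned interpret thresholds as bin edges (default FALSE).
#' @return data.frame with one row per threshold/bin: `threshold`,
#'   `n_eligible_left`, `n_eligible_right`, `p_left`, `p_right`, `p_mean`
#'   (NA when no eligible partner on a side).
#' @export
homolog_conservation <- function(circuit, seed_L, seed_R,
                                 thresholds = c(1, 5, 10, 15),
                                 min_nodes = 500, identified_only = TRUE,
                                 binned = FALSE) {
  counts_L <- seed_counts(circuit, seed_L)
  counts_R <- seed_counts(circuit, seed_R)
  m <- circuit$metas
  nn <- node_count(circuit)
  eligible <- function(id) {
    i <- match(id, m$skeleton_id)
    ok <- !is.na(i) & !is.na(m$homolog_id[i]) &
      m$homolog_id[i] %in% m$skeleton_id &
      nn[id] >= min_nodes
    if (identified_only) ok <- ok & m$identified[i]
    ok & !(id %in% c(seed_L, seed_R))
  }
  one_side <- function(counts_here, counts_there, lo, hi) {
    ids <- names(counts_here)[counts_here >= lo & counts_here < hi]
    ids <- ids[eligible(ids)]
    if (!length(ids)) return(c(n = 0L, p = NA_real_))
    hom <- m$homolog_id[match(ids, m$skeleton_id)]
    conserved <- !is.na(counts_there[hom]) & counts_there[hom] >= 1
    c(n = length(ids), p = mean(conserved))
  }
  upper <- if (binned) c(thresholds[-1], Inf) else
    rep(Inf, length(thresholds))
  rows <- lapply(seq_along(thresholds), function(i) {
    L <- one_side(counts_L, counts_R, thresholds[i], upper[i])
    R <- one_side(counts_R, counts_L, thresholds[i], upper[i])
    data.frame(threshold = thresholds[i],
               n_eligible_left = L[["n"]], n_eligible_right = R[["n"]],
               p_left = L[["p"]], p_right = R[["p"]],
               p_mean = mean(c(L[["p"]], R[["p"]])))
  })
  do.call(rbind, rows)
}

#' Fold change between two input fractions
#'
#' The ratio of two fractions; the unit in which connectivity differences
#' between volumes are reported.
#'
#' @param f_a,f_b numerator and denominator fractions (`f_b > 0`).
#' @return `f_a / f_b`.
#' @export
fold_change <- function(f_a, f_b) {
  if (any(f_b <= 0)) stop("fold change undefined for zero denominator")
  f_a / f_b
}

#' @rdname fold_change
#' @param ratios vector of per-connection fold changes.
#' @return `mean_fold_change`: list with `mean`, `sd`, `n`.
#' @export
mean_fold_change <- function(ratios) {
  list(mean = mean(ratios), sd = stats::sd(ratios), n = length(ratios))
}

#' Compare connectivity fractions between two volumes
#'
#' For each pairing, computes the input fraction in both circuits, the
#' fold change of circuit B relative to circuit A, and a chi-square test
#' for proportions on the 2x2 table of (from-seed, other-input) counts.
#' Absolute synapse counts are never compared across volumes (totals grow
#' with development); only fractions. Pairings that fail to resolve or
#' have an undefined fraction in either circuit are flagged (`note`) and
#' left untested.
#'
#' @param circuit_a,circuit_b the two [circuit()]s (A = reference).
#' @param pairings data.frame with columns `pre_cell_type`, `pre_segment`,
#'   `pre_side`, `post_cell_type`, `post_segment`, `post_side`, `mode`
#'   (an [input_fraction()] mode).
#' @param continuity Yates correction for the chi-square test (default
#'   off).
#' @return data.frame with counts, fractions, `fold_change`, `chisq`,
#'   `p_value`, `note`.
#' @export
compare_volumes <- function(circuit_a, circuit_b, pairings,
                            continuity = FALSE) {
  one <- function(pr) {
    res <- lapply(list(circuit_a, circuit_b), function(circ) {
      tryCatch({
        pre <- resolve_group(circ, pr$pre_cell_type, pr$pre_segment,
                             pr$pre_side)
        post <- resolve_group(circ, pr$post_cell_type, pr$post_segment,
                              pr$post_side)
        if (!length(pre) || !length(post)) stop("group resolved empty")
        input_fraction(circ, pre, post, mode = pr$mode)
      }, error = function(e) conditionMessage(e))
    })
    out <- data.frame(n_pre_a = NA_integer_, n_total_a = NA_integer_,
                      fraction_a = NA_real_, n_pre_b = NA_integer_,
                      n_total_b = NA_integer_, fraction_b = NA_real_,
                      fold_change = NA_real_, chisq = NA_real_,
                      p_value = NA_real_, note = NA_character_)
    if (is.character(res[[1]]) || is.character(res[[2]])) {
      out$note <- paste(Filter(is.character, res), collapse = "; ")
      return(out)
    }
    a <- res[[1]]; b <- res[[2]]
    out[1, 1:6] <- c(a$n_from_pre, a$n_total, a$fraction,
                     b$n_from_pre, b$n_total, b$fraction)
    out$fold_change <- if (a$fraction > 0) b$fraction / a$fraction else NA
    tab <- rbind(c(a$n_from_pre, a$n_total - a$n_from_pre),
                 c(b$n_from_pre, b$n_total - b$n_from_pre))
    tst <- tryCatch(chi_square_proportions(tab, continuity = continuity),
                    error = function(e) NULL)
    if (!is.null(tst)) {
      out$chisq <- tst$statistic
      out$p_value <- tst$p_value
    } else out$note <- "chi-square not computable"
    out
  }
  cbind(pairings,
        do.call(rbind, lapply(seq_len(nrow(pairings)),
                              function(i) one(pairings[i, ]))))
}

#' Partner retention and new-partner statistics across volumes
#'
#' Given the wild-type partner ranking of a seed group and the seed-synapse
#' counts measured in an experimental volume (keyed by the experimental
#' candidate each wild-type partner maps to), reports, per strength class,
#' how many wild-type partners failed to receive seed input in the
#' experimental volume, with the failure percentage rounded to the nearest
#' integer percent.
#'
#' @param wt_ranking a [rank_partners()] table from the reference volume.
#' @param exp_counts named integer vector: seed-synapse counts per
#'   experimental neuron id (absent names count as 0).
#' @param matching named character vector mapping wild-type skeleton ids to
#'   experimental ids; defaults to the identity.
#' @param failure_rule `"zero"` (failed = zero seed synapses, default) or
#'   `"below_min"` (failed = fewer than `min_synapses`).
#' @param min_synapses threshold for `"below_min"` and for new partners.
#' @return data.frame with one row per strength class: `n_total`,
#'   `n_failed`, `failure_pct`.
#' @export
retention_stats <- function(wt_ranking, exp_counts, matching = NULL,
                            failure_rule = c("zero", "below_min"),
                            min_synapses = 3) {
  failure_rule <- match.arg(failure_rule)
  ids <- wt_ranking$skeleton_id
  mapped <- if (is.null(matching)) ids else unname(matching[ids])
  got <- exp_counts[mapped]
  got[is.na(got)] <- 0L
  cut <- if (failure_rule == "zero") 1L else min_synapses
  failed <- got < cut
  out <- lapply(c("strong", "weak"), function(cl) {
    sel <- wt_ranking$strength_class == cl
    n <- sum(sel); nf <- sum(failed[sel])
    data.frame(strength_class = cl, n_total = n, n_failed = nf,
               failure_pct = if (n > 0) round(100 * nf / n) else NA_real_)
  })
  do.call(rbind, out)
}

#' New partners acquired in an experimental volume
#'
#' Neurons that receive at least `min_synapses` seed synapses in both the
#' left and right hemisegments of the experimental volume but whose match
#' is absent from the wild-type partner ranking.
#'
#' @param exp_ranking_L,exp_ranking_R [rank_partners()] tables of the two
#'   experimental hemisegments.
#' @param wt_partner_ids wild-type partner ids (after mapping to the
#'   experimental naming).
#' @param homolog_map named character vector pairing left experimental ids
#'   with their right homologs (a left id is reproducible when its homolog
#'   appears in the right ranking); defaults to identity naming.
#' @param min_synapses inclusion threshold (default 3).
#' @return character vector of new-partner ids (left-side naming).
#' @export
new_partners <- function(exp_ranking_L, exp_ranking_R, wt_partner_ids,
                         homolog_map = NULL, min_synapses = 3) {
  left <- exp_ranking_L$skeleton_id[exp_ranking_L$synapses >= min_synapses]
  right <- exp_ranking_R$skeleton_id[exp_ranking_R$synapses >= min_synapses]
  expected_right <- if (is.null(homolog_map)) left else
    unname(homolog_map[left])
  reproducible <- left[!is.na(expected_right) & expected_right %in% right]
  setdiff(reproducible, wt_partner_ids)
}
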