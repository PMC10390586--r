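#' Artificial-stroke (lesion) specification
#'
#' A lesion targets one resting-state network (RSN) of a parcellated
#' connectome and removes connectivity between it and the rest of the
#' network, leaving the internal structure of the RSN untouched. Two
#' variants:
#' * `"node_severity"` — a fixed fraction of the RSN's nodes (a proxy of
#'   stroke severity) is selected uniformly and *all* their connections to
#'   nodes outside the RSN are removed;
#' * `"edge_fraction"` — a fixed fraction of the undirected inter-RSN
#'   connections is selected uniformly and removed (both directions zeroed
#'   together: a tract is one connection).
#'
#' @param target_label RSN label to lesion.
#' @param severity fraction in \[0, 1\].
#' @param variant `"node_severity"` or `"edge_fraction"`.
#' @param n_realizations number of seeded realizations for ensembles
#'   (default 20).
#' @param seed integer master seed.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(target_label, severity,
                        variant = c("node_severity", "edge_fraction"),
                        n_realizations = 20L, seed = 1L) {
  variant <- match.arg(variant)
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (n_realizations < 1L) stop("n_realizations must be at least 1")
  structure(list(target_label = as.character(target_label),
                 severity = severity, variant = variant,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

# round-half-up to nearest integer (R's round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Apply a node-severity lesion
#'
#' Selects `round(severity * |RSN|)` RSN nodes uniformly (round half up) and
#' zeroes all their connections, in both directions, to nodes outside the
#' RSN. Intra-RSN and non-RSN weights are bit-identical to the input and the
#' node count is unchanged.
#'
#' @param net a `weighted_network`.
#' @param parc a `parcellation` of `net`'s nodes.
#' @param spec a `lesion_spec` with `variant = "node_severity"`.
#' @param seed seed for the node selection (defaults to `spec$seed`).
#' @return the lesioned `weighted_network`.
#' @export
apply_node_severity <- function(net, parc, spec, seed = spec$seed) {
  stopifnot_network(net)
  if (length(parc) != net$n_nodes) stop("parcellation length must equal n_nodes")
  rsn <- parcellation_nodes(parc, spec$target_label)
  n_sel <- round_half_up(spec$severity * length(rsn))
  if (n_sel == 0L) return(net)
  sel <- withr::with_seed(as.integer(seed), {
    rsn[sample.int(length(rsn), n_sel)]
  })
  outside <- setdiff(seq_len(net$n_nodes), rsn)
  w <- net$weights
  w[sel, outside] <- 0
  w[outside, sel] <- 0
  weighted_network(Matrix::drop0(w), directed = net$directed,
                   node_ids = net$node_ids)
}

#' Apply an edge-fraction lesion
#'
#' Counts the undirected inter-RSN connections (node pairs with one endpoint
#' in the RSN and `w_ij + w_ji > 0`), selects `round(severity * count)` of
#' them uniformly (round half up) and zeroes both directions. Intra-RSN
#' structure is untouched.
#'
#' @inheritParams apply_node_severity
#' @param spec a `lesion_spec` with `variant = "edge_fraction"`.
#' @export
apply_edge_fraction <- function(net, parc, spec, seed = spec$seed) {
  stopifnot_network(net)
  if (length(parc) != net$n_nodes) stop("parcellation length must equal n_nodes")
  rsn <- parcellation_nodes(parc, spec$target_label)
  in_rsn <- logical(net$n_nodes); in_rsn[rsn] <- TRUE
  supp <- Matrix::summary(support_matrix(net))
  cut_sel <- supp$i < supp$j & (in_rsn[supp$i] != in_rsn[supp$j])
  cut_i <- supp$i[cut_sel]; cut_j <- supp$j[cut_sel]
  n_cut <- length(cut_i)
  n_sel <- round_half_up(spec$severity * n_cut)
  if (n_sel == 0L) return(net)
  pick <- withr::with_seed(as.integer(seed), sample.int(n_cut, n_sel))
  w <- net$weights
  w[cbind(c(cut_i[pick], cut_j[pick]), c(cut_j[pick], cut_i[pick]))] <- 0
  weighted_network(Matrix::drop0(w), directed = net$directed,
                   node_ids = net$node_ids)
}

#' Apply a lesion according to its spec
#'
#' Dispatches on `spec$variant`.
#' @inheritParams apply_node_severity
#' @export
apply_lesion <- function(net, parc, spec, seed = spec$seed) {
  switch(spec$variant,
         node_severity = apply_node_severity(net, parc, spec, seed),
         edge_fraction = apply_edge_fraction(net, parc, spec, seed))
}

#' Seeded ensemble of lesion realizations
#'
#' Draws `spec$n_realizations` independent lesioned networks (sub-seeds
#' derived deterministically from `spec$seed`), runs `downstream` on each,
#' and averages the results. `downstream(lesioned_net, realization_seed)`
#' should return a named numeric vector for averaging; other return types
#' are collected without averaging.
#'
#' @param net a `weighted_network`.
#' @param parc a `parcellation`.
#' @param spec a `lesion_spec`.
#' @param downstream function of `(net, seed)` run per realization.
#' @return list with `realizations` (per-realization results) and `mean`
#'   (element-wise mean, or `NULL` when results are not numeric vectors).
#' @export
lesion_ensemble <- function(net, parc, spec, downstream) {
  results <- lapply(seq_len(spec$n_realizations), function(r) {
    sub <- derive_subseed(spec$seed, r)
    lesioned <- apply_lesion(net, parc, spec, seed = sub)
    tryCatch(downstream(lesioned, sub),
             error = function(e) {
               stop("downstream analysis failed at realization ", r, ": ",
                    conditionMessage(e))
             })
  })
  avg <- NULL
  if (all(vapply(results, is.numeric, logical(1)))) {
    avg <- Reduce(`+`, results) / length(results)
  }
  list(realizations = results, mean = avg)
}
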