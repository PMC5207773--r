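# Thresholded extraction of the cortico-thalamo-basal ganglia circuit graph.
# All cutoffs are strict (edges require a fraction strictly greater than the
# cutoff), matching the ">15%", ">20%", ">50%" rules the thresholds encode.

EDGE_TYPES <- c("corticocortical", "corticostriatal_convergent",
                "thalamostriatal", "thalamocortical", "corticothalamic")

LEGAL_EDGES <- list(
  corticocortical = c("cortical", "cortical"),
  corticostriatal_convergent = c("cortical", "cortical"),
  thalamostriatal = c("thalamic", "striatal_subdivision"),
  thalamocortical = c("thalamic", "cortical"),
  corticothalamic = c("cortical", "thalamic")
)

#' Circuit graph container
#'
#' @param nodes data frame with `name` and `class`
#'   (cortical/thalamic/striatal_subdivision).
#' @param edges data frame with `source`, `target`, `type`, `weight` in
#'   \[0, 1\].
#' @return An object of class `circuit_graph`.
#' @export
circuit_graph <- function(nodes, edges) {
  stopifnot(all(c("name", "class") %in% names(nodes)),
            all(c("source", "target", "type", "weight") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$weight < 0 | edges$weight > 1)) {
      stop("circuit_graph: edge weights must lie in [0, 1]")
    }
    if (!all(edges$type %in% EDGE_TYPES)) {
      stop("circuit_graph: unknown edge type")
    }
    cls <- stats::setNames(nodes$class, nodes$name)
    for (i in seq_len(nrow(edges))) {
      legal <- LEGAL_EDGES[[edges$type[i]]]
      if (!identical(unname(cls[c(edges$source[i], edges$target[i])]),
                     legal)) {
        stop("circuit_graph: edge type '", edges$type[i],
             "' connects illegal node classes")
      }
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "circuit_graph")
}

#' Primary cortical inputs to a striatal subdivision
#'
#' A subregion qualifies as a primary input by route 1 when its dense
#' projection field occupies more than `occupancy_cutoff` (default 20%) of
#' the subdivision's voxels, or by route 2 when more than `within_cutoff`
#' (default 50%) of its dense projections fall inside the subdivision. Both
#' fractions are reported per subregion.
#'
#' @param subdivision nonempty `binary_mask` of the striatal subdivision.
#' @param dense_fields named list of dense-projection `binary_mask` fields.
#' @param occupancy_cutoff,within_cutoff strict cutoffs.
#' @return A data frame: subregion, occupancy, within, route1, route2,
#'   primary.
#' @export
primary_inputs <- function(subdivision, dense_fields,
                           occupancy_cutoff = 0.2, within_cutoff = 0.5) {
  stopifnot(inherits(subdivision, "binary_mask"))
  if (!sum(subdivision$values)) stop("primary_inputs: empty subdivision")
  nm <- names(dense_fields) %||% sprintf("src%02d", seq_along(dense_fields))
  rows <- lapply(seq_along(dense_fields), function(j) {
    f <- dense_fields[[j]]
    check_same_grid(subdivision, f)
    occ <- coverage_fraction(subdivision, f)
    nf <- sum(f$values)
    within <- if (nf == 0) 0 else sum(f$values & subdivision$values) / nf
    data.frame(subregion = nm[j], occupancy = occ, within = within,
               route1 = occ > occupancy_cutoff,
               route2 = within > within_cutoff)
  })
  out <- do.call(rbind, rows)
  out$primary <- out$route1 | out$route2
  out
}

#' Corticocortical edges from a density table
#'
#' Directed edges wherever the projection density in the target area is
#' strictly greater than the cutoff (default 15%).
#'
#' @param density square numeric matrix (source rows, target columns) of
#'   fractions in \[0, 1\] with dimnames.
#' @param cutoff strict density cutoff.
#' @return A data frame of edges: source, target, type, weight.
#' @export
corticocortical_edges <- function(density, cutoff = 0.15) {
  stopifnot(is.matrix(density), nrow(density) == ncol(density))
  idx <- which(density > cutoff & row(density) != col(density),
               arr.ind = TRUE)
  data.frame(
    source = rownames(density)[idx[, 1]],
    target = colnames(density)[idx[, 2]],
    type = rep("corticocortical", nrow(idx)),
    weight = density[idx]
  )
}

#' Primary convergent subregions by tier-averaged convergence
#'
#' Convergence of source subregion s with target subregion t is the mean
#' over density tiers of the fraction of t's tier field covered by s's tier
#' field (dense with dense, moderate with moderate, diffuse with diffuse);
#' a tier with an empty target field is omitted from the mean (and recorded).
#' Sources with convergence strictly greater than the cutoff (default 50%)
#' qualify.
#'
#' @param fields_by_tier list with elements `dense`, `moderate`, `diffuse`,
#'   each a named list of `binary_mask` fields per subregion.
#' @param cutoff strict convergence cutoff.
#' @return A data frame: source, target, convergence, n_tiers, qualifies.
#' @export
primary_convergent <- function(fields_by_tier, cutoff = 0.5) {
  tiers <- c("dense", "moderate", "diffuse")
  stopifnot(all(tiers %in% names(fields_by_tier)))
  nm <- names(fields_by_tier$dense)
  out <- NULL
  for (tgt in nm) {
    for (src in nm) {
      if (src == tgt) next
      fr <- c()
      for (ti in tiers) {
        tf <- fields_by_tier[[ti]][[tgt]]
        sf <- fields_by_tier[[ti]][[src]]
        if (sum(tf$values) == 0) next  # empty target tier: omitted
        fr <- c(fr, coverage_fraction(tf, sf))
      }
      conv <- if (length(fr)) mean(fr) else NA_real_
      out <- rbind(out, data.frame(source = src, target = tgt,
                                   convergence = conv,
                                   n_tiers = length(fr)))
    }
  }
  out$qualifies <- !is.na(out$convergence) & out$convergence > cutoff
  out
}

#' Thalamic edges from nuclear coverage tables
#'
#' Edges for every nucleus whose coverage fraction is strictly greater than
#' the cutoff (default 20%), typed by relation (thalamostriatal,
#' thalamocortical or corticothalamic).
#'
#' @param coverage data frame with `nucleus`, `target` and `fraction`
#'   columns.
#' @param type edge type for the relation.
#' @param cutoff strict coverage cutoff.
#' @return A data frame of edges.
#' @export
thalamic_edges <- function(coverage,
                           type = c("thalamostriatal", "thalamocortical",
                                    "corticothalamic"),
                           cutoff = 0.2) {
  type <- match.arg(type)
  sel <- coverage$fraction > cutoff
  if (type == "corticothalamic") {
    data.frame(source = coverage$target[sel], target = coverage$nucleus[sel],
               type = rep(type, sum(sel)), weight = coverage$fraction[sel])
  } else {
    data.frame(source = coverage$nucleus[sel], target = coverage$target[sel],
               type = rep(type, sum(sel)), weight = coverage$fraction[sel])
  }
}

#' Export / import a circuit graph
#'
#' Lossless round trip through edge-list CSV or GraphML (via igraph).
#'
#' @param graph a `circuit_graph`.
#' @param path output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path` invisibly (export); a `circuit_graph` (import).
#' @export
export_graph <- function(graph, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(graph$edges, path, row.names = FALSE)
    utils::write.csv(graph$nodes, paste0(path, ".nodes.csv"),
                     row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(graph$edges)) graph$edges else
        data.frame(source = character(), target = character()),
      directed = TRUE,
      vertices = data.frame(name = graph$nodes$name,
                            class = graph$nodes$class)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    edges <- utils::read.csv(path)
    nodes <- utils::read.csv(paste0(path, ".nodes.csv"))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(name = igraph::V(g)$name, class = igraph::V(g)$class)
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- if (nrow(ed)) {
      data.frame(source = ed$from, target = ed$to, type = ed$type,
                 weight = as.numeric(ed$weight))
    } else {
      data.frame(source = character(), target = character(),
                 type = character(), weight = numeric())
    }
  }
  circuit_graph(nodes, edges)
}
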