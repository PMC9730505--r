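# Co-expression network profiling of binary TcEMM columns: phi (Pearson)
# correlation, soft-threshold adjacency a = |r|^beta, thresholded graph and
# connected-component profiles.

#' Pairwise correlation of TcEMM columns
#'
#' Exact Pearson correlation (equivalently the phi coefficient) between the
#' binary presence columns of the TcEMM matrix, after dropping columns
#' below the support filter and constant columns (whose correlation is
#' undefined).
#'
#' @param matrix a `tcemm_matrix`.
#' @param min_support minimum pair support for a column to enter the
#'   network (default 1).
#' @return A `tcemm_network` list with `tcemm_ids` and `correlation`
#'   (symmetric matrix, unit diagonal); dropped constant columns are
#'   recorded in attribute `dropped`.
#' @export
tcemm_correlation <- function(matrix, min_support = 1L) {
  n <- length(matrix$pair_ids)
  keep <- matrix$support >= min_support & matrix$support < n &
    matrix$support > 0
  dropped <- matrix$tcemm_ids[matrix$support >= min_support & !keep]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " constant TcEMM column(s)")
  }
  ids <- matrix$tcemm_ids[keep]
  if (length(ids) < 2) {
    stop("fewer than 2 usable TcEMM columns for the network", call. = FALSE)
  }
  X <- as.matrix(matrix$incidence[, keep, drop = FALSE])
  r <- cor(X)
  structure(list(tcemm_ids = ids, correlation = r, dropped = dropped),
            class = "tcemm_network")
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted-network adjacency `a_ij = |r_ij|^beta`. With the
#' default soft power `beta = 4`, an adjacency cutoff of 0.3 corresponds to
#' a correlation cutoff of `0.3^(1/4) = 0.74`.
#'
#' @param network a `tcemm_network` from [tcemm_correlation()].
#' @param beta soft power (> 0), default 4.
#' @return the network with an `adjacency` matrix added.
#' @export
soft_adjacency <- function(network, beta = 4) {
  stopifnot(beta > 0)
  network$adjacency <- abs(network$correlation)^beta
  network$beta <- beta
  network
}

#' Profiles of co-expressed TcEMMs
#'
#' Thresholds the adjacency matrix (edges where `a >= adjacency_threshold`,
#' no self-edges) and takes connected components of the resulting graph.
#' Components with at least two members are profiles; the rest are
#' singletons.
#'
#' @param network a `tcemm_network` with adjacency (see
#'   [soft_adjacency()]).
#' @param adjacency_threshold edge cutoff on adjacency (default 0.3).
#' @return list with `profiles` (list of member character vectors, largest
#'   first), `singletons`, `n_in_profiles`, `fraction_in_profiles`, and
#'   `graph` (the thresholded igraph object with edge attributes `r` and
#'   `adjacency`).
#' @export
build_profiles <- function(network, adjacency_threshold = 0.3) {
  if (is.null(network$adjacency)) network <- soft_adjacency(network)
  A <- network$adjacency
  diag(A) <- 0
  A[A < adjacency_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- network$tcemm_ids
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    igraph::E(g)$adjacency <- igraph::E(g)$weight
    igraph::E(g)$r <- network$correlation[cbind(ends[, 1L], ends[, 2L])]
  }
  comp <- igraph::components(g)
  members <- split(network$tcemm_ids, comp$membership)
  sizes <- vapply(members, length, integer(1))
  profiles <- unname(members[sizes >= 2][order(-sizes[sizes >= 2])])
  singletons <- unlist(members[sizes == 1], use.names = FALSE)
  n_in <- sum(vapply(profiles, length, integer(1)))
  list(profiles = profiles,
       singletons = singletons %||% character(0),
       n_in_profiles = n_in,
       fraction_in_profiles = n_in / length(network$tcemm_ids),
       graph = g)
}

#' Export the co-expression graph
#'
#' Writes the thresholded graph in GraphML (or edge-list TSV), with node
#' attributes carrying screen/selection status flags and edge weights
#' carrying correlation and adjacency.
#'
#' @param network a `tcemm_network` with adjacency.
#' @param profiles result of [build_profiles()].
#' @param annotations optional data frame of per-node flags, with a `tcemm`
#'   column and any of `aft_significant`, `lasso_selected`,
#'   `posi_significant` (other columns are rejected).
#' @param path output path.
#' @param format `"graphml"` or `"tsv"` (edge list: node1, node2, r,
#'   adjacency).
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, profiles, annotations = NULL, path,
                         format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- profiles$graph
  if (!is.null(annotations)) {
    allowed <- c("tcemm", "aft_significant", "lasso_selected",
                 "posi_significant")
    unknown <- setdiff(names(annotations), allowed)
    if (length(unknown) > 0) {
      stop("unknown annotation key: '", unknown[1L], "'", call. = FALSE)
    }
    idx <- match(igraph::V(g)$name, annotations$tcemm)
    for (col in setdiff(names(annotations), "tcemm")) {
      val <- annotations[[col]][idx]
      val[is.na(val)] <- FALSE
      g <- igraph::set_vertex_attr(g, col, value = as.logical(val))
    }
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    if (igraph::ecount(g) > 0) {
      ends <- igraph::ends(g, igraph::E(g))
      df <- data.frame(node1 = ends[, 1L], node2 = ends[, 2L],
                       r = igraph::E(g)$r,
                       adjacency = igraph::E(g)$adjacency)
    } else {
      df <- data.frame(node1 = character(0), node2 = character(0),
                       r = numeric(0), adjacency = numeric(0))
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
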