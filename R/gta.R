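#' Causal density of a directed graph
#'
#' Total amount of causal interactivity: the number of significant directed
#' links, also returned normalized by the n(n-1) possible ordered pairs.
#'
#' @param adjacency logical k x k matrix (no self-edges) or a
#'   [gc_edges()] result.
#' @return List with `count` and `normalized`.
#' @export
causal_density <- function(adjacency) {
  adj <- .as_adjacency(adjacency)
  n <- nrow(adj)
  count <- sum(adj)
  list(count = count, normalized = count / (n * (n - 1)))
}

#' Causal flow and node roles
#'
#' Per node: out-degree minus in-degree. A node with positive flow is a
#' causal "source", negative a causal "sink", zero neutral.
#'
#' @inheritParams causal_density
#' @return A tibble with `node`, `out_degree`, `in_degree`, `flow`, `role`.
#' @export
causal_flow <- function(adjacency) {
  adj <- .as_adjacency(adjacency)
  out_d <- rowSums(adj)
  in_d <- colSums(adj)
  flow <- out_d - in_d
  tibble::tibble(
    node = seq_len(nrow(adj)),
    out_degree = as.integer(out_d),
    in_degree = as.integer(in_d),
    flow = as.integer(flow),
    role = ifelse(flow > 0, "source", ifelse(flow < 0, "sink", "neutral")))
}

#' Combined graph metrics
#'
#' @inheritParams causal_density
#' @return An object of class `graph_metrics` with `density` and `flow`.
#' @export
graph_metrics <- function(adjacency) {
  structure(list(density = causal_density(adjacency),
                 flow = causal_flow(adjacency)),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat("<graph_metrics> ", x$density$count, " link(s), density ",
      signif(x$density$normalized, 3), "\n", sep = "")
  print(x$flow)
  invisible(x)
}

# normalize to adjacency[from, to]; gc_graph stores [to, from]
.as_adjacency <- function(x) {
  if (inherits(x, "gc_graph")) x <- t(x$adjacency)
  adj <- as.matrix(x)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  adj <- adj != 0
  if (any(diag(adj))) stop("self-edges are not allowed")
  adj
}
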