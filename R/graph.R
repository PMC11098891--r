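# Spatial skeleton graph: nodes are upper-body joints, edges follow the
# skeletal structure. The trunk is a star around the neck (shoulders + hips),
# so the two arms are joined only through the neck and cross-arm hop
# distances stay large -- the premise behind squeezing long-range channels.

.edge_template <- function() {
  list(
    c("left_wrist", "left_elbow"),
    c("left_elbow", "left_shoulder"),
    c("left_shoulder", "neck"),
    c("right_wrist", "right_elbow"),
    c("right_elbow", "right_shoulder"),
    c("right_shoulder", "neck"),
    c("neck", "left_hip"),
    c("neck", "right_hip")
  )
}

#' Build the upper-body skeleton graph
#'
#' Constructs the spatial graph over the retained upper-body joints:
#' wrist--elbow--shoulder chains on each arm, shoulders and hips attached to
#' the neck. The adjacency matrix includes self-loops and is row-normalized
#' (each row sums to 1). Temporal structure (the same joint in consecutive
#' frames) is a rule consumed by pooling, not materialized edges.
#'
#' @param joints Character vector of joint names; must span a connected
#'   subgraph of the skeletal edge template. Defaults to the full 9-joint set.
#' @return An object of class `skeleton_graph`: a list with `joints`, an
#'   `edges` tibble, the row-normalized `adjacency` matrix and the all-pairs
#'   `hops` matrix of shortest spatial graph distances.
#' @export
#' @examples
#' g <- skeleton_graph()
#' g$hops["left_wrist", "right_wrist"] # 6 hops across the arms
skeleton_graph <- function(joints = upper_body_joints()) {
  stopifnot(is.character(joints), length(joints) >= 2, !anyDuplicated(joints))
  edges <- purrr::keep(.edge_template(), ~ all(.x %in% joints))
  edges_df <- tibble::tibble(
    from = purrr::map_chr(edges, 1),
    to = purrr::map_chr(edges, 2)
  )
  n <- length(joints)
  A <- matrix(0, n, n, dimnames = list(joints, joints))
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  hops <- .bfs_all_pairs(A)
  if (any(!is.finite(hops))) {
    stop("skeleton graph over {", paste(joints, collapse = ", "),
         "} is disconnected; cannot build a valid spatial graph", call. = FALSE)
  }
  Ahat <- A + diag(n)
  Ahat <- Ahat / rowSums(Ahat)
  structure(
    list(joints = joints, edges = edges_df, adjacency = Ahat, hops = hops),
    class = "skeleton_graph"
  )
}

# breadth-first shortest paths from every node; Inf where unreachable
.bfs_all_pairs <- function(A) {
  n <- nrow(A)
  H <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(is.infinite(dist) & colSums(A[frontier, , drop = FALSE]) > 0)
      dist[nxt] <- d
      frontier <- nxt
    }
    H[s, ] <- dist
  }
  H
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> ", length(x$joints), " joints, ",
      nrow(x$edges), " spatial edges, max hop ", max(x$hops), "\n", sep = "")
  invisible(x)
}

#' All-pairs hop distances on the spatial graph
#'
#' @param graph A [skeleton_graph()].
#' @return Integer matrix of shortest-path lengths between joints.
#' @export
hop_distances <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  graph$hops
}

#' Classify joint pairs by hop distance
#'
#' Node pairs are partitioned by their spatial hop distance: hop 0 is the
#' self-node, hops 1-2 are short-range and hops >= 3 long-range. Long-range
#' pairs (in this topology, mostly cross-arm pairs) are the ones whose
#' channels get squeezed most aggressively.
#'
#' @param hops A hop-distance matrix from [hop_distances()].
#' @return A tibble with one row per ordered pair: `from`, `to`, `hop` and
#'   `range` (factor with levels self/short/long).
#' @export
#' @examples
#' classify_hops(hop_distances(skeleton_graph()))
classify_hops <- function(hops) {
  stopifnot(is.matrix(hops), nrow(hops) == ncol(hops), all(hops >= 0))
  tibble::tibble(
    from = rep(rownames(hops), times = ncol(hops)),
    to = rep(colnames(hops), each = nrow(hops)),
    hop = as.integer(hops),
    range = factor(
      ifelse(hops == 0, "self", ifelse(hops <= 2, "short", "long")),
      levels = c("self", "short", "long")
    )
  )
}
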