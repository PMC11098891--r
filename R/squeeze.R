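# Channel squeezing: the number of feature channels a relevant node
# contributes to a target node shrinks with their hop distance, mirroring the
# exponential decay of information gain with graph distance and the clinical
# observation that Parkinsonian tremor is typically unilateral (so cross-arm
# relevance is small).

.round_half_up <- function(x) floor(x + 0.5)

#' Hop-dependent output channel width
#'
#' The self node keeps all `c_in` channels; short-range nodes (hops 1-2) are
#' squeezed to `round(p * c_in)`; long-range nodes at hop d >= 3 are squeezed
#' to `round(q^d * c_in)`. Widths are rounded half up and floored at one
#' channel. `p` must exceed `q` (short-range neighbors always contribute more
#' than long-range ones).
#'
#' @param hop Non-negative integer hop distance(s); vectorized.
#' @param c_in Input channel count.
#' @param p Squeezing ratio for short-range nodes, in (0, 1].
#' @param q Squeezing ratio base for long-range nodes, in (0, 1); the width
#'   decays as `q^hop`.
#' @return Integer vector of output channel counts.
#' @export
#' @examples
#' squeeze_channels(0:6, c_in = 64)
squeeze_channels <- function(hop, c_in, p = 0.5, q = 0.25) {
  if (!is.numeric(hop) || any(hop < 0) || any(hop != floor(hop))) {
    stop("`hop` must contain non-negative integers", call. = FALSE)
  }
  if (c_in < 1) stop("`c_in` must be a positive channel count", call. = FALSE)
  if (p <= 0 || p > 1 || q <= 0 || q >= 1) {
    stop("squeezing ratios must satisfy 0 < q < 1 and 0 < p <= 1", call. = FALSE)
  }
  if (p <= q) {
    stop("`p` must be (much) greater than `q`: short-range nodes retain more ",
         "channels than long-range ones", call. = FALSE)
  }
  w <- ifelse(hop == 0, c_in,
       ifelse(hop <= 2, .round_half_up(p * c_in), .round_half_up(q^hop * c_in)))
  as.integer(pmax(1, w))
}

#' Squeezing specification for a skeleton graph
#'
#' Tabulates, for every ordered (target, source) joint pair, the hop distance,
#' range class and squeezed channel width used by the pyramidal
#' channel-squeezing-fusion block.
#'
#' @param graph A [skeleton_graph()].
#' @inheritParams squeeze_channels
#' @return A tibble with columns `target`, `source`, `hop`, `range`, `width`,
#'   carrying `c_in`, `p`, `q` as attributes.
#' @export
#' @examples
#' spec <- squeeze_spec(skeleton_graph(), c_in = 64)
#' dplyr::count(spec, width)
squeeze_spec <- function(graph, c_in, p = 0.5, q = 0.25) {
  stopifnot(inherits(graph, "skeleton_graph"))
  spec <- classify_hops(hop_distances(graph))
  names(spec)[names(spec) == "from"] <- "target"
  names(spec)[names(spec) == "to"] <- "source"
  spec$width <- squeeze_channels(spec$hop, c_in, p, q)
  by_hop <- squeeze_channels(0:max(spec$hop), c_in, p, q)
  if (any(diff(by_hop) > 0)) {
    stop("squeezed widths are not non-increasing in hop distance for this ",
         "(c_in, p, q); choose p >= q^3", call. = FALSE)
  }
  attr(spec, "c_in") <- c_in
  attr(spec, "p") <- p
  attr(spec, "q") <- q
  spec
}
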