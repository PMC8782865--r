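# Dual rhythm networks: six nodes (the rhythms), 15 undirected weighted
# edges, one network per polarity (positive / anti), with edge weight
# D+_ij or D-_ij. Zero-weight edges are retained so that state comparisons
# operate on a fixed 15-edge support.

#' Build a rhythm network from degree matrices
#'
#' @param dm A `"degree_matrices"` object.
#' @param polarity `"positive"` (weights from D+) or `"anti"` (from D-).
#' @return An object of class `"rhythm_network"` with an `edges` data.frame
#'   (`source, target, weight` in fixed rhythm order) and tags.
#' @export
build_network <- function(dm, polarity = c("positive", "anti")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(dm, "degree_matrices"))
  D <- if (polarity == "positive") dm$D_plus else dm$D_minus
  if (max(abs(D - t(D))) > 1e-12) stop("degree matrix is not symmetric")
  pr <- rhythm_pairs()
  edges <- data.frame(
    source = .rhythms[pr$i], target = .rhythms[pr$j],
    weight = D[cbind(pr$i, pr$j)],
    polarity = polarity, state = dm$state, channel = dm$channel,
    stringsAsFactors = FALSE
  )
  structure(list(nodes = .rhythms, edges = edges, polarity = polarity,
                 state = dm$state, channel = dm$channel),
            class = "rhythm_network")
}

#' @export
print.rhythm_network <- function(x, ...) {
  cat(sprintf("<rhythm_network> polarity=%s state=%s channel=%s\n",
              x$polarity, x$state, x$channel))
  top <- x$edges[order(-x$edges$weight), ][1:3, ]
  cat("  heaviest edges:",
      paste(sprintf("%s-%s (%.3f)", top$source, top$target, top$weight),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare two rhythm networks
#'
#' Element-wise weight differences over the fixed 15-edge set plus summary
#' statistics (mean absolute difference, Spearman rank correlation of the
#' weight vectors). Both networks must share polarity and node set.
#'
#' @param net_a,net_b `"rhythm_network"` objects of the same polarity.
#' @return A list with `deltas` (per-edge data.frame), `mean_abs_delta`,
#'   `rank_correlation`.
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "rhythm_network"), inherits(net_b, "rhythm_network"))
  if (net_a$polarity != net_b$polarity)
    stop("networks have different polarity")
  if (!identical(net_a$nodes, net_b$nodes)) stop("node sets differ")
  d <- net_a$edges$weight - net_b$edges$weight
  list(
    deltas = data.frame(source = net_a$edges$source,
                        target = net_a$edges$target, delta = d),
    mean_abs_delta = mean(abs(d)),
    rank_correlation = suppressWarnings(
      stats::cor(net_a$edges$weight, net_b$edges$weight, method = "spearman"))
  )
}

#' Hemispheric symmetry of homologous networks
#'
#' Pearson correlation between the 15 homologous edge weights of a left- and
#' a right-hemisphere network of the same polarity and state; NaN (flagged
#' undefined) if either weight vector is constant.
#'
#' @param net_left,net_right `"rhythm_network"` objects.
#' @return Similarity in \[-1, 1\], or NaN when undefined.
#' @export
hemispheric_symmetry <- function(net_left, net_right) {
  stopifnot(inherits(net_left, "rhythm_network"),
            inherits(net_right, "rhythm_network"))
  if (net_left$polarity != net_right$polarity ||
      !identical(net_left$state, net_right$state))
    stop("networks must share polarity and state")
  wl <- net_left$edges$weight
  wr <- net_right$edges$weight
  if (stats::sd(wl) == 0 || stats::sd(wr) == 0) return(NaN)
  stats::cor(wl, wr)
}

#' Export / import a rhythm network as an edge list
#'
#' CSV columns `source,target,weight,polarity,state,channel` with rows in the
#' fixed rhythm order; round-trips losslessly.
#'
#' @param net A `"rhythm_network"`.
#' @param path File path.
#' @export
export_network <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(nodes = .rhythms, edges = e, polarity = e$polarity[1],
                 state = e$state[1], channel = e$channel[1]),
            class = "rhythm_network")
}

# Rebuild a 6x6 symmetric matrix from a network's edge list (inverse of
# build_network; used to assert lossless re-indexing).
network_to_matrix <- function(net) {
  D <- matrix(0, 6, 6, dimnames = list(.rhythms, .rhythms))
  i <- match(net$edges$source, .rhythms)
  j <- match(net$edges$target, .rhythms)
  D[cbind(i, j)] <- net$edges$weight
  D[cbind(j, i)] <- net$edges$weight
  D
}
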