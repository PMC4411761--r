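#' AlphaPore: channels and pores from the alpha complex
#'
#' Represents a molecule as a union of van der Waals balls, builds the
#' regular (weighted Delaunay) triangulation and alpha complex, routes
#' channels through the dual graph of the complement, and ranks pores.
#' See \code{vignette("alphapore-methods")} for the model and the design
#' choices.
#'
#' @useDynLib AlphaPore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new is validObject
#' @keywords internal
"_PACKAGE"

#' One-call pore extraction pipeline
#'
#' Triangulates the structure, builds and prunes the channel network,
#' selects persistence-ranked endpoints, extracts all-pairs important
#' pores and, when a membrane slab is given, scored transmembrane pores.
#'
#' @param s a [WeightedStructure-class].
#' @param k number of boundary representatives (default 10).
#' @param alpha working alpha (A^2), default 0.
#' @param membrane optional [MembraneSlab-class] for transmembrane mode.
#' @param spacing straightness resampling spacing (A).
#' @return list with \code{triangulation}, \code{network},
#'   \code{endpoints}, \code{pores} and (transmembrane mode)
#'   \code{tmPores}.
#' @export
#' @examples
#' tube <- makeTube(length = 30, lumenRadius = 4, constrictionRadius = 2)
#' res <- extractPores(tube, membrane = membraneSlab(8, 22))
#' res$tmPores[[1]]
extractPores <- function(s, k = 10L, alpha = 0, membrane = NULL,
                         spacing = 1) {
  tri <- regularTriangulation(s)
  net <- channelNetwork(tri, alpha = alpha)
  eps <- selectEndpoints(net, k = k)
  pores <- importantPores(net, eps)
  out <- list(triangulation = tri, network = net, endpoints = eps,
              pores = pores)
  if (!is.null(membrane))
    out$tmPores <- transmembranePores(net, eps, membrane, spacing = spacing)
  out
}
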