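#' Filter an edge list by confidence and gene universe
#'
#' Keeps edges with `combined_score >= threshold` (inclusive) whose two
#' endpoints both belong to the gene universe (typically the significant
#' genes of a contrast).
#'
#' @param edges Canonical edge tibble (`gene_a`, `gene_b`,
#'   `combined_score`).
#' @param threshold Confidence cutoff in `(0, 1]` (conventional 0.7).
#' @param universe Optional character vector of allowed genes.
#' @return Filtered edge tibble.
#' @export
filter_edges <- function(edges, threshold = 0.7, universe = NULL) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]",
          class = "immunopanel_validation_error")
  }
  out <- edges |> filter(.data$combined_score >= threshold)
  if (!is.null(universe)) {
    out <- out |>
      filter(.data$gene_a %in% universe, .data$gene_b %in% universe)
  }
  out
}

#' Markov clustering of a weighted gene network
#'
#' Classic MCL on the undirected weighted graph of the edge list:
#' self-loops are added with each node's maximum incident weight, the
#' adjacency matrix is made column-stochastic, and expansion (matrix
#' squaring) alternates with inflation (entrywise power `inflation`,
#' column renormalisation) and pruning of entries below `prune` until
#' the largest entry change drops below `tol` or `max_iter` is reached.
#' Clusters are the connected components of the converged matrix's
#' support; they always refine the input graph's connected components.
#'
#' @param edges Edge tibble (typically from [filter_edges()]).
#' @param inflation Inflation exponent (conventional 1.5).
#' @param max_iter,tol Convergence controls.
#' @param prune Entries below this are zeroed each iteration.
#' @return An `mcl_result`: `membership` tibble (`gene`, `cluster`),
#'   `clusters` (list of gene vectors, largest first), `iterations`,
#'   `converged`, `inflation`.
#' @export
mcl_cluster <- function(edges, inflation = 1.5, max_iter = 200, tol = 1e-6,
                        prune = 1e-8) {
  if (nrow(edges) == 0) {
    abort("empty edge list", class = "immunopanel_validation_error")
  }
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(genes)
  a <- matrix(0, n, n, dimnames = list(genes, genes))
  ia <- match(edges$gene_a, genes)
  ib <- match(edges$gene_b, genes)
  a[cbind(ia, ib)] <- edges$combined_score
  a[cbind(ib, ia)] <- edges$combined_score
  diag(a) <- apply(a, 1, max)
  m <- sweep(a, 2, colSums(a), `/`)

  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    m2 <- m %*% m                 # expansion
    m2 <- m2^inflation            # inflation
    m2[m2 < prune] <- 0
    m2 <- sweep(m2, 2, colSums(m2), `/`)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge in %d iterations", max_iter))
  }
  support <- (m > tol) | (t(m) > tol)
  comp <- components_from_adjacency(support)
  clusters <- split(genes, comp)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, `[[`, "", 1))]
  membership <- tibble(
    gene = unlist(clusters),
    cluster = rep(seq_along(clusters), lengths(clusters))
  )
  structure(list(membership = membership, clusters = unname(clusters),
                 iterations = iter, converged = converged,
                 inflation = inflation),
            class = "mcl_result")
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  current <- 0
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    current <- current + 1
    queue <- start
    comp[start] <- current
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nbr <- which(adj[v, ] & is.na(comp))
      comp[nbr] <- current
      queue <- c(queue, nbr)
    }
  }
  comp
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("<mcl_result> %d clusters over %d genes (inflation %.2f, %s in %d iterations)\n",
              length(x$clusters), nrow(x$membership), x$inflation,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' @export
tidy.mcl_result <- function(x, ...) x$membership

#' @export
glance.mcl_result <- function(x, ...) {
  tibble(n_clusters = length(x$clusters), n_genes = nrow(x$membership),
         largest = max(lengths(x$clusters)), iterations = x$iterations,
         converged = x$converged, inflation = x$inflation)
}
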