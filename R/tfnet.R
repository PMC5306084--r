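#' k-nearest-neighbour mutual information between two vectors
#'
#' Kraskov-Stoegbauer-Grassberger (first) estimator in the max-norm:
#' MI = psi(k) + psi(n) - <psi(nx+1) + psi(ny+1)>, where nx and ny count the
#' neighbours strictly inside the k-th-neighbour max-norm ball projected on
#' each margin. Estimates are in nats and floored at zero. Ties are broken
#' by a tiny uniform jitter drawn from the current RNG state, so seed the
#' RNG for reproducibility.
#'
#' @param x,y Numeric vectors of equal length.
#' @param k Number of neighbours (default 9).
#' @param jitter_sd Amplitude of the tie-breaking jitter relative to each
#'   vector's scale (default 1e-10; 0 disables).
#' @return MI estimate in nats (>= 0). A constant input vector gives 0.
#' @export
knn_mi <- function(x, y, k = 9, jitter_sd = 1e-10) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (k < 1) stop("k must be >= 1")
  if (n < k + 2) stop("need at least k + 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(n, 0, jitter_sd * max(stats::sd(x), 1))
    y <- y + stats::rnorm(n, 0, jitter_sd * max(stats::sd(y), 1))
  }
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dmax <- pmax(dx, dy)
  diag(dmax) <- Inf
  eps <- apply(dmax, 1L, function(r) sort.int(r, partial = k)[k])
  nx <- rowSums(dx < eps) - 1L  # subtract the self (dx[i,i] = 0)
  ny <- rowSums(dy < eps) - 1L
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L))
  max(mi, 0)
}

#' Pairwise k-NN mutual information matrix
#'
#' Applies \code{\link{knn_mi}} to every gene pair of an expression matrix
#' (genes in rows, samples in columns). The k = 9 default follows the
#' network construction this package implements.
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param k Number of neighbours.
#' @param jitter_sd Tie-breaking jitter amplitude (see \code{\link{knn_mi}}).
#' @return Symmetric MI matrix (nats) with zero diagonal and the gene names
#'   as dimnames.
#' @export
knn_mutual_information <- function(matrix, k = 9, jitter_sd = 1e-10) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) stop("matrix of gene rows required")
  g <- nrow(matrix); n <- ncol(matrix)
  if (n < k + 2) stop("need at least k + 2 samples")
  # jitter once so each pair sees consistent values
  jm <- matrix
  if (jitter_sd > 0) {
    sds <- pmax(apply(matrix, 1L, stats::sd), 1)
    jm <- matrix + stats::rnorm(length(matrix), 0, jitter_sd) * sds
  }
  const <- apply(matrix, 1L, stats::sd) == 0
  if (any(const)) {
    message("knn_mutual_information: ", sum(const),
            " constant gene vector(s); their MI set to 0")
  }
  dlist <- lapply(seq_len(g), function(i) abs(outer(jm[i, ], jm[i, ], "-")))
  mi <- matrix(0, g, g, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(g - 1L)) {
    if (const[i]) next
    for (j in (i + 1L):g) {
      if (const[j]) next
      dmax <- pmax(dlist[[i]], dlist[[j]])
      diag(dmax) <- Inf
      eps <- apply(dmax, 1L, function(r) sort.int(r, partial = k)[k])
      nx <- rowSums(dlist[[i]] < eps) - 1L
      ny <- rowSums(dlist[[j]] < eps) - 1L
      v <- digamma(k) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L))
      mi[i, j] <- mi[j, i] <- max(v, 0)
    }
  }
  mi
}

#' Context-likelihood-of-relatedness (CLR) scores from an MI matrix
#'
#' For each gene i, its off-diagonal MI row is z-scored and negative
#' z-values are clipped at zero; the edge score is
#' sqrt(z_i(j)^2 + z_j(i)^2). An MI value that stands out against the
#' backgrounds of both genes scores highly. Rows with zero MI variance
#' contribute zero z-terms.
#'
#' @param mi Square symmetric MI matrix.
#' @return Symmetric score matrix (>= 0), zero diagonal.
#' @export
clr_scores <- function(mi) {
  if (!is.matrix(mi) || nrow(mi) != ncol(mi)) stop("square matrix required")
  if (max(abs(mi - t(mi))) > 1e-8) stop("MI matrix must be symmetric")
  g <- nrow(mi)
  z <- matrix(0, g, g)
  for (i in seq_len(g)) {
    row <- mi[i, -i]
    mu <- mean(row); s <- stats::sd(row)
    if (is.na(s) || s == 0) next
    z[i, -i] <- pmax(0, (mi[i, -i] - mu) / s)
  }
  sc <- sqrt(z^2 + t(z)^2)
  dimnames(sc) <- dimnames(mi)
  sc
}

#' Build a TF co-expression network from CLR scores
#'
#' Restricts the score matrix to the transcription factors present in it and
#' keeps the top \code{edge_quantile} fraction of TF-pair scores as edges:
#' with distinct scores exactly \code{ceiling(edge_quantile * n_pairs)}
#' edges are drawn; pairs tied with the threshold score are all kept.
#' Isolated TFs remain as nodes.
#'
#' @param scores Symmetric CLR score matrix with gene dimnames.
#' @param tf_list Character vector of TF gene symbols (or a single-set list
#'   from \code{\link{read_gmt}}).
#' @param edge_quantile Fraction of TF pairs kept as edges (default 0.001,
#'   the top 0.1%).
#' @return List of class \code{coexpression_network}: \code{nodes},
#'   \code{edges} (data.frame \code{from}, \code{to}, \code{score}),
#'   \code{graph} (igraph object).
#' @export
build_network <- function(scores, tf_list, edge_quantile = 0.001) {
  if (is.list(tf_list)) tf_list <- unique(unlist(tf_list))
  tfs <- intersect(rownames(scores), tf_list)
  if (!length(tfs)) stop("no transcription factor found among the scored genes")
  if (edge_quantile <= 0 || edge_quantile > 1) stop("edge_quantile must be in (0, 1]")
  s <- scores[tfs, tfs, drop = FALSE]
  ut <- which(upper.tri(s), arr.ind = TRUE)
  vals <- s[ut]
  n_pairs <- length(vals)
  n_keep <- min(ceiling(edge_quantile * n_pairs), n_pairs)
  thr <- sort(vals, decreasing = TRUE)[n_keep]
  keep <- vals >= thr
  if (sum(keep) > n_keep) {
    message("build_network: ", sum(keep) - n_keep,
            " extra edge(s) tied at the threshold score kept")
  }
  edges <- data.frame(from = tfs[ut[keep, 1L]], to = tfs[ut[keep, 2L]],
                      score = vals[keep], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$score, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = tfs))
  structure(list(nodes = tfs, edges = edges, graph = gr),
            class = "coexpression_network")
}

#' Fast-greedy community detection on the TF network
#'
#' Greedy modularity maximization; communities are ranked by size and the
#' \code{top_n} largest are retained for downstream enrichment, each flagged
#' if smaller than \code{min_size} genes.
#'
#' @param network \code{coexpression_network} from \code{\link{build_network}}.
#' @param min_size Minimum community size worth analysing (default 6).
#' @param top_n Number of largest communities retained (default 18).
#' @return List with \code{membership} (named integer vector, community ids
#'   1 = largest), \code{sizes}, \code{retained} (ids), \code{small}
#'   (retained ids below min_size), \code{modularity}.
#' @export
detect_communities <- function(network, min_size = 6, top_n = 18) {
  gr <- network$graph
  if (igraph::vcount(gr) == 0L) stop("empty network")
  comm <- igraph::cluster_fast_greedy(igraph::simplify(gr))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  memb <- stats::setNames(unname(relabel[as.character(memb)]), names(memb))
  sizes <- as.integer(sizes)
  retained <- seq_len(min(top_n, length(sizes)))
  list(membership = memb,
       sizes = sizes,
       retained = retained,
       small = retained[sizes[retained] < min_size],
       modularity = igraph::modularity(comm))
}

#' Gene-set enrichment of network communities (one-sided Fisher)
#'
#' For each retained community and each gene set, the one-sided
#' hypergeometric enrichment p-value with all network nodes as background.
#' Terms below \code{alpha} (unadjusted, as in the original community
#' annotation) are reported, sorted by p within community.
#'
#' @param communities Result of \code{\link{detect_communities}}.
#' @param gene_sets Named list of symbol vectors (e.g. GO biological
#'   processes from \code{\link{read_gmt}}).
#' @param alpha Unadjusted p-value cutoff (default 0.05).
#' @return Data.frame with columns \code{community}, \code{term},
#'   \code{overlap}, \code{community_size}, \code{term_size}, \code{p}.
#' @export
enrich_communities <- function(communities, gene_sets, alpha = 0.05) {
  memb <- communities$membership
  background <- names(memb)
  N <- length(background)
  rows <- list()
  for (cid in communities$retained) {
    members <- background[memb == cid]
    if (!length(members)) next
    for (nm in names(gene_sets)) {
      term <- intersect(gene_sets[[nm]], background)
      if (!length(term)) next
      O <- length(intersect(members, term))
      p <- overlap_significance(O, length(members), length(term), N)
      if (p < alpha) {
        rows[[length(rows) + 1L]] <- data.frame(
          community = cid, term = nm, overlap = O,
          community_size = length(members), term_size = length(term), p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(community = integer(), term = character(),
                      overlap = integer(), community_size = integer(),
                      term_size = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$community, out$p, out$term), , drop = FALSE]
}

#' Overlay regulation states on the TF network
#'
#' Marks each TF node up or down when a probe set mapping to it is
#' consistently regulated under the condition; TFs with inconsistently
#' regulated probe sets are removed from the analysis (state "none",
#' flagged). Reports per-community counts of affected TFs and the fraction
#' of all affected TFs falling in each community.
#'
#' @param network \code{coexpression_network}.
#' @param regulation Gene-level regulation table from
#'   \code{\link{collapse_to_genes}}.
#' @param communities Optional result of \code{\link{detect_communities}}
#'   for the per-community summary.
#' @return List with \code{node_state} (named character: up/down/none),
#'   \code{inconsistent} (TF symbols dropped), and, when communities are
#'   given, \code{community_summary} (data.frame \code{community},
#'   \code{n_nodes}, \code{n_affected}, \code{fraction_of_affected}).
#' @export
overlay_regulation <- function(network, regulation, communities = NULL) {
  state <- stats::setNames(rep("none", length(network$nodes)), network$nodes)
  hit <- regulation[regulation$symbol %in% network$nodes, , drop = FALSE]
  inconsistent <- hit$symbol[hit$status == "inconsistent"]
  ok <- hit[hit$status %in% c("up", "down"), , drop = FALSE]
  state[ok$symbol] <- ok$status
  out <- list(node_state = state, inconsistent = inconsistent)
  if (!is.null(communities)) {
    memb <- communities$membership[network$nodes]
    affected <- state != "none"
    total_affected <- sum(affected)
    cids <- sort(unique(memb))
    out$community_summary <- data.frame(
      community = cids,
      n_nodes = vapply(cids, function(c) sum(memb == c), integer(1L)),
      n_affected = vapply(cids, function(c) sum(affected & memb == c), integer(1L)),
      fraction_of_affected = if (total_affected > 0)
        vapply(cids, function(c) sum(affected & memb == c) / total_affected,
               numeric(1L)) else 0,
      stringsAsFactors = FALSE)
  }
  out
}
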