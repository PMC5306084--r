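#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted values (q-values), same order as the input,
#'   clipped at 1.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Signed linear fold change from a log2 difference
#'
#' A log2 difference of +1 maps to +2, of -1 to -2; the magnitude is always
#' \code{2^|log2fc|}, matching the "absolute fold change" convention used
#' for the 1.5-fold gate.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Signed linear fold changes.
#' @export
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Two-group differential expression with fold-change and FDR gates
#'
#' Per-probe pooled-variance two-sample comparison (one-way ANOVA with two
#' levels, so F = t^2), two-sided p, BH adjustment across all probes in the
#' matrix, and a significance flag that is the conjunction of the linear
#' fold-change gate (default |FC| >= 1.5) and the FDR gate (default
#' q <= 0.05). The contrast direction is B minus A: for developmental genes
#' A is the day-0 control and B the differentiated control; for toxicant
#' genes A is the differentiated control and B the treated group.
#'
#' @param matrix Log2 expression matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   length >= 2.
#' @param fc_threshold Linear absolute fold-change gate (>= 1).
#' @param q_threshold FDR gate.
#' @param welch Use Welch's unequal-variance statistic instead of the
#'   classical pooled-variance ANOVA.
#' @return A data.frame (one row per probe, in matrix order) with columns
#'   \code{probe_id}, \code{mean_a}, \code{mean_b}, \code{log2fc},
#'   \code{fold_change}, \code{p}, \code{q}, \code{direction},
#'   \code{significant}.
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    fc_threshold = 1.5, q_threshold = 0.05,
                                    welch = FALSE) {
  validate_expression_matrix(matrix)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  miss <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(miss)) stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")

  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  var_a <- rowSums((a - mean_a)^2) / (na - 1L)
  var_b <- rowSums((b - mean_b)^2) / (nb - 1L)
  delta <- mean_b - mean_a

  if (welch) {
    se2 <- var_a / na + var_b / nb
    df <- se2^2 / ((var_a / na)^2 / (na - 1L) + (var_b / nb)^2 / (nb - 1L))
    tstat <- delta / sqrt(se2)
  } else {
    pooled <- ((na - 1L) * var_a + (nb - 1L) * var_b) / (na + nb - 2L)
    df <- rep.int(na + nb - 2L, nrow(matrix))
    tstat <- delta / sqrt(pooled * (1 / na + 1 / nb))
  }
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  # degenerate probes: zero variance in both groups
  degen <- !is.finite(tstat)
  if (any(degen)) {
    p[degen] <- ifelse(abs(delta[degen]) <= .Machine$double.eps^0.5, 1, 0)
    n_equal <- sum(degen & p == 1)
    if (n_equal) {
      message("differential_expression: ", n_equal,
              " zero-variance probe(s) with equal means set to p = 1")
    }
  }
  q <- bh_fdr(p)
  fc <- signed_fold_change(delta)
  significant <- abs(fc) >= fc_threshold & q <= q_threshold
  direction <- rep("none", nrow(matrix))
  direction[significant & delta > 0] <- "up"
  direction[significant & delta < 0] <- "down"
  data.frame(probe_id = rownames(matrix),
             mean_a = mean_a, mean_b = mean_b,
             log2fc = delta, fold_change = fc,
             p = p, q = q,
             direction = direction, significant = significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regulon sets (up/down significant probes) from a DEG table
#'
#' Splits the significant probes of a contrast into up- and down-regulated
#' sets. With the day0-control vs differentiated-control contrast this
#' yields the developmental (D) genes; with the treated vs
#' differentiated-control contrast the toxicant (T) genes of a compound.
#'
#' @param deg DEG table from \code{\link{differential_expression}}.
#' @param label Free-text label (e.g. "D-genes" or "T-genes VPA 550 uM").
#' @param namespace Identifier namespace of the probes, carried forward so
#'   set operations can check it.
#' @return A list of class \code{regulon_sets} with elements \code{up},
#'   \code{down} (character vectors, disjoint), \code{label},
#'   \code{namespace}.
#' @export
call_regulons <- function(deg, label = "", namespace = "probe") {
  up <- deg$probe_id[deg$significant & deg$log2fc > 0]
  down <- deg$probe_id[deg$significant & deg$log2fc < 0]
  regulon_sets(up, down, label = label, namespace = namespace)
}

#' Construct a regulon-set object
#'
#' @param up,down Character vectors of identifiers; must be disjoint.
#' @param label Free-text label.
#' @param namespace \code{"probe"} or \code{"symbol"}.
#' @return A \code{regulon_sets} list.
#' @export
regulon_sets <- function(up, down, label = "", namespace = "probe") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down))) {
    stop("up and down sets must be disjoint")
  }
  structure(list(up = up, down = down, label = label, namespace = namespace),
            class = "regulon_sets")
}

#' Count regulated probes above linear fold-change tiers
#'
#' @param regulons Regulon sets from \code{\link{call_regulons}}.
#' @param deg The DEG table the regulons were derived from.
#' @param tiers Numeric vector of linear |FC| thresholds (default 2, 5, 10).
#' @return Data.frame with columns \code{tier}, \code{up}, \code{down}.
#' @export
fold_change_tiers <- function(regulons, deg, tiers = c(2, 5, 10)) {
  if (any(tiers < 1)) stop("fold-change tiers must be >= 1")
  fc <- stats::setNames(deg$fold_change, deg$probe_id)
  res <- lapply(tiers, function(tau) {
    data.frame(tier = tau,
               up = sum(abs(fc[regulons$up]) >= tau),
               down = sum(abs(fc[regulons$down]) >= tau))
  })
  do.call(rbind, res)
}

#' Most-regulated probes by FDR-adjusted p-value
#'
#' Returns the k probes with the lowest q among the significant probes,
#' mirroring the "50 most regulated" selection; if fewer than k probes are
#' significant, all of them are returned. Ties on q are broken by ascending
#' raw p, then probe id.
#'
#' @param deg DEG table.
#' @param k Number of probes (default 50).
#' @param significant_only Restrict to significant probes first (default).
#' @return Character vector of probe ids, best first.
#' @export
top_k_by_fdr <- function(deg, k = 50, significant_only = TRUE) {
  if (k < 1) stop("k must be >= 1")
  tab <- if (significant_only) deg[deg$significant, , drop = FALSE] else deg
  ord <- order(tab$q, tab$p, tab$probe_id)
  utils::head(tab$probe_id[ord], k)
}
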