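#' Overlap of developmental and toxicant regulons with directional quadrants
#'
#' O is the number of identifiers deregulated both during differentiation
#' (D) and by the compound (T), irrespective of direction. The four
#' directional quadrants record how the compound acts on developmentally
#' up- and down-regulated genes; the two discordant quadrants
#' (T-up on D-down, T-down on D-up) are the antagonistic ones.
#'
#' @param d,t \code{regulon_sets} in the same identifier namespace.
#' @return List with \code{O} and \code{quadrants} (named counts
#'   \code{t_up_d_up}, \code{t_up_d_down}, \code{t_down_d_up},
#'   \code{t_down_d_down}) and the member sets per quadrant.
#' @export
compute_overlap <- function(d, t) {
  .check_namespace(d, t)
  d_all <- union(d$up, d$down)
  t_all <- union(t$up, t$down)
  q <- list(t_up_d_up = intersect(t$up, d$up),
            t_up_d_down = intersect(t$up, d$down),
            t_down_d_up = intersect(t$down, d$up),
            t_down_d_down = intersect(t$down, d$down))
  list(O = length(intersect(d_all, t_all)),
       quadrants = vapply(q, length, integer(1L)),
       members = q)
}

.check_namespace <- function(d, t) {
  if (!is.null(d$namespace) && !is.null(t$namespace) &&
      !identical(d$namespace, t$namespace)) {
    stop("identifier namespace mismatch: '", d$namespace, "' vs '",
         t$namespace, "'")
  }
}

#' Developmental potency Dp = O/D
#'
#' The fraction of all developmental genes altered by the test compound.
#'
#' @param O Overlap count.
#' @param D Number of developmental genes.
#' @return Dp in [0, 1].
#' @export
compute_dp <- function(O, D) {
  if (D < 1) stop("Dp undefined: no developmental genes (D = 0)")
  if (O < 0 || O > D) stop("O must lie in [0, D]")
  O / D
}

#' Developmental index Di = (O/T) / (D/N)
#'
#' The ratio by which developmental genes are overrepresented among the
#' genes deregulated by the compound, normalized to the total number of
#' developmental genes so that systems with different D can be compared.
#' Di = 1 is the random expectation; Di > 1 means preferential disturbance
#' of development. A compound with no deregulated genes (T = 0) has no
#' defined Di and yields NA (a negative test).
#'
#' @param O Overlap count.
#' @param T_ Number of toxicant-deregulated genes.
#' @param D Number of developmental genes.
#' @param N Total probes measured on the array.
#' @return Di >= 0, or NA if T = 0.
#' @export
compute_di <- function(O, T_, D, N) {
  if (D < 1) stop("Di undefined: no developmental genes (D = 0)")
  if (N < max(D, T_)) stop("N must be at least max(D, T)")
  if (T_ == 0) return(NA_real_)
  (O / T_) / (D / N)
}

#' One-sided overlap significance (Fisher's exact test)
#'
#' Upper-tail hypergeometric probability P(X >= O) for
#' X ~ Hypergeom(N, D, T): the chance of drawing at least O developmental
#' genes when T genes are picked at random from the N on the array. Equal to
#' the one-sided Fisher exact test on the 2x2 overlap table, posed as an
#' enrichment question.
#'
#' @inheritParams compute_di
#' @return p-value in (0, 1].
#' @export
overlap_significance <- function(O, T_, D, N) {
  if (O > min(D, T_)) stop("O cannot exceed min(D, T)")
  if (N < max(D, T_)) stop("N must be at least max(D, T)")
  if (T_ == 0 || D == 0) return(1)
  stats::phyper(O - 1, m = D, n = N - D, k = T_, lower.tail = FALSE)
}

#' Full index computation for one compound/condition
#'
#' Bundles overlap, Dp, Di, Fisher significance, quadrant counts and the
#' antagonistic fraction into one result. \code{o_over_t}, the fraction of
#' the compound's deregulated genes that are developmental, is reported
#' alongside.
#'
#' @param d Developmental regulons.
#' @param t Toxicant regulons for one compound/concentration.
#' @param N Total probes measured (defaults must be supplied by the caller,
#'   typically \code{nrow(matrix)}).
#' @return List of class \code{index_result} with fields \code{D}, \code{T},
#'   \code{O}, \code{N}, \code{Dp}, \code{Di}, \code{o_over_t},
#'   \code{fisher_p}, \code{quadrants}, \code{antagonistic_fraction}.
#' @export
developmental_indices <- function(d, t, N) {
  ov <- compute_overlap(d, t)
  D <- length(union(d$up, d$down))
  T_ <- length(union(t$up, t$down))
  O <- ov$O
  antag <- unname(ov$quadrants["t_up_d_down"] + ov$quadrants["t_down_d_up"])
  structure(list(
    D = D, T = T_, O = O, N = N,
    Dp = compute_dp(O, D),
    Di = compute_di(O, T_, D, N),
    o_over_t = if (T_ > 0) O / T_ else NA_real_,
    fisher_p = overlap_significance(O, T_, D, N),
    quadrants = ov$quadrants,
    antagonistic_fraction = if (O > 0) antag / O else NA_real_
  ), class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("D = %d, T = %d, O = %d, N = %d\n", x$D, x$T, x$O, x$N))
  cat(sprintf("Dp = %.4f  Di = %.3f  Fisher p = %.3g\n", x$Dp, x$Di, x$fisher_p))
  cat("quadrants:", paste(names(x$quadrants), x$quadrants, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Antagonism fractions of developmental genes affected by a compound
#'
#' For each (toxicant direction, developmental direction) pair, the fraction
#' of that developmental direction set hit by the compound in that
#' direction, e.g. \code{t_down_d_up} = |T-down n D-up| / |D-up|. Dominant
#' discordant fractions mean the compound antagonizes spontaneous
#' development.
#'
#' @param d,t \code{regulon_sets} in the same namespace.
#' @return Data.frame with columns \code{t_direction}, \code{d_direction},
#'   \code{count}, \code{d_size}, \code{fraction} (NA when the
#'   developmental direction set is empty).
#' @export
antagonism_fractions <- function(d, t) {
  .check_namespace(d, t)
  grid <- expand.grid(t_direction = c("up", "down"),
                      d_direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(td, dd)
    length(intersect(t[[td]], d[[dd]])), grid$t_direction, grid$d_direction)
  grid$d_size <- vapply(grid$d_direction, function(dd) length(d[[dd]]), integer(1L))
  grid$fraction <- ifelse(grid$d_size > 0, grid$count / grid$d_size, NA_real_)
  grid
}

#' Category-restricted developmental indices
#'
#' Recomputes Dp and Di after restricting the developmental genes (and the
#' overlap) to a biological category, e.g. a GO differentiation process:
#' D_c = |D n c|, O_c = |O n c|, Dp = O_c/D_c, Di = (O_c/T)/(D_c/N). The
#' background N and the compound's T stay global. Categories containing no
#' developmental genes are skipped.
#'
#' @param d,t \code{regulon_sets}.
#' @param categories Named list of identifier vectors (e.g. from
#'   \code{\link{read_gmt}}) in the same namespace as the regulons.
#' @param N Total probes measured.
#' @return Data.frame with one row per retained category: \code{category},
#'   \code{D_c}, \code{O_c}, \code{T}, \code{Dp}, \code{Di},
#'   \code{fisher_p}.
#' @export
category_indices <- function(d, t, categories, N) {
  if (!length(categories)) stop("empty category collection")
  ns <- attr(categories, "namespace")
  if (!is.null(ns) && !is.null(d$namespace) && !identical(ns, d$namespace)) {
    stop("category namespace '", ns, "' does not match regulon namespace '",
         d$namespace, "'")
  }
  d_all <- union(d$up, d$down)
  t_all <- union(t$up, t$down)
  o_all <- intersect(d_all, t_all)
  T_ <- length(t_all)
  rows <- lapply(names(categories), function(nm) {
    cset <- categories[[nm]]
    D_c <- length(intersect(d_all, cset))
    if (D_c == 0L) {
      message("category_indices: skipping '", nm, "' (no developmental genes)")
      return(NULL)
    }
    O_c <- length(intersect(o_all, cset))
    data.frame(category = nm, D_c = D_c, O_c = O_c, T = T_,
               Dp = O_c / D_c,
               Di = if (T_ > 0) (O_c / T_) / (D_c / N) else NA_real_,
               fisher_p = overlap_significance(O_c, T_, D_c, N),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratify regulated probes by baseline expression
#'
#' Classifies each probe as high-baseline if its mean log2 expression
#' exceeds the threshold (strictly) in the undifferentiated (day 0) controls
#' or in the end-stage differentiated controls; low otherwise. The >6 log2
#' default reflects the bimodal frequency distribution of baseline
#' intensities on the array, separating expressed probes from the noise
#' range.
#'
#' @param regulons \code{regulon_sets} of probes to stratify.
#' @param matrix Log2 expression matrix containing the control samples.
#' @param design Sample design with \code{day0_control} and
#'   \code{diff_control} samples.
#' @param threshold_log2 Baseline cutoff (default 6, strict).
#' @return Data.frame with columns \code{probe_id}, \code{direction},
#'   \code{mean_day0}, \code{mean_diff}, \code{baseline}
#'   ("high"/"low").
#' @export
baseline_stratify <- function(regulons, matrix, design, threshold_log2 = 6) {
  design <- validate_sample_design(design, matrix)
  day0 <- design$sample_id[design$role == "day0_control"]
  diff <- design$sample_id[design$role == "diff_control"]
  if (!length(day0) || !length(diff)) {
    stop("design must contain day0_control and diff_control samples")
  }
  probes <- c(regulons$up, regulons$down)
  miss <- setdiff(probes, rownames(matrix))
  if (length(miss)) stop("probe(s) absent from matrix: ", paste(miss, collapse = ", "))
  m0 <- rowMeans(matrix[probes, day0, drop = FALSE])
  m1 <- rowMeans(matrix[probes, diff, drop = FALSE])
  data.frame(probe_id = probes,
             direction = rep(c("up", "down"),
                             c(length(regulons$up), length(regulons$down))),
             mean_day0 = m0, mean_diff = m1,
             baseline = ifelse(m0 > threshold_log2 | m1 > threshold_log2,
                               "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concentration-response profile of the developmental indices
#'
#' Computes one index row per tested concentration against a shared set of
#' developmental genes. Concentrations with no deregulated genes carry
#' Dp = 0 and an undefined Di.
#'
#' @param per_concentration Named list mapping concentration (numeric,
#'   coercible names) to the DEG table of that concentration's treated vs
#'   differentiated-control contrast.
#' @param d Shared developmental \code{regulon_sets}.
#' @param N Total probes measured.
#' @return Data.frame sorted by concentration with columns
#'   \code{concentration}, \code{D}, \code{T}, \code{O}, \code{Dp},
#'   \code{Di}, \code{fisher_p}, \code{antagonistic_fraction}.
#' @export
concentration_profile <- function(per_concentration, d, N) {
  if (!length(per_concentration)) stop("no concentrations supplied")
  conc <- as.numeric(names(per_concentration))
  if (anyNA(conc)) stop("per_concentration must be named by numeric concentrations")
  if (anyDuplicated(conc)) stop("duplicate concentrations")
  ord <- order(conc)
  rows <- lapply(ord, function(i) {
    t <- call_regulons(per_concentration[[i]],
                       label = paste0("T@", conc[i]), namespace = d$namespace)
    T_ <- length(union(t$up, t$down))
    if (T_ == 0L) {
      return(data.frame(concentration = conc[i],
                        D = length(union(d$up, d$down)), T = 0L, O = 0L,
                        Dp = 0, Di = NA_real_, fisher_p = 1,
                        antagonistic_fraction = NA_real_))
    }
    r <- developmental_indices(d, t, N)
    data.frame(concentration = conc[i], D = r$D, T = r$T, O = r$O,
               Dp = r$Dp, Di = r$Di, fisher_p = r$fisher_p,
               antagonistic_fraction = r$antagonistic_fraction)
  })
  do.call(rbind, rows)
}
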