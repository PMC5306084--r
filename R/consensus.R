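#' Collapse probe-level differential expression to gene regulation calls
#'
#' A gene counts as deregulated by a contrast if at least one probe set
#' annotated to it is significant. Genes with significant probes in only one
#' direction get that direction; genes with significant probes in both are
#' flagged inconsistent (and are excluded from downstream consensus counts
#' and network overlays). Unannotated probes are dropped; probes mapping to
#' several genes contribute to each.
#'
#' @param deg DEG table from \code{\link{differential_expression}}.
#' @param annotation Data.frame with columns \code{probe_id}, \code{symbol}
#'   (repeated rows for multi-mapping), as from
#'   \code{\link{read_probe_annotation}}.
#' @return Data.frame, one row per annotated gene: \code{symbol},
#'   \code{status} (up/down/inconsistent/none), \code{n_probes},
#'   \code{n_sig_up}, \code{n_sig_down}, \code{best_fc} (signed FC of the
#'   largest-magnitude significant probe, NA if none).
#' @export
collapse_to_genes <- function(deg, annotation) {
  ann <- unique(annotation[, c("probe_id", "symbol")])
  ann <- ann[ann$probe_id %in% deg$probe_id, , drop = FALSE]
  if (!nrow(ann)) stop("annotation covers no probe in the DEG table")
  idx <- match(ann$probe_id, deg$probe_id)
  per <- data.frame(symbol = ann$symbol,
                    sig = deg$significant[idx],
                    dirn = deg$direction[idx],
                    fc = deg$fold_change[idx],
                    stringsAsFactors = FALSE)
  sp <- split(per, per$symbol)
  rows <- lapply(sp, function(g) {
    n_up <- sum(g$sig & g$dirn == "up")
    n_down <- sum(g$sig & g$dirn == "down")
    status <- if (n_up > 0L && n_down > 0L) "inconsistent"
      else if (n_up > 0L) "up"
      else if (n_down > 0L) "down"
      else "none"
    sig_fc <- g$fc[g$sig]
    data.frame(symbol = g$symbol[1L], status = status,
               n_probes = nrow(g), n_sig_up = n_up, n_sig_down = n_down,
               best_fc = if (length(sig_fc)) sig_fc[which.max(abs(sig_fc))]
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Toxicant-class consensus genes
#'
#' Counts, per gene and direction, how many compounds of a class call it
#' significantly regulated in that direction; a gene is a consensus gene
#' when one direction reaches \code{min_count} compounds. Compounds calling
#' a gene inconsistent contribute to neither direction. The published
#' per-system presets are min_count 3 (UKK mercurials), 4 (UKN1 mercurials,
#' UKK HDAC inhibitors) and 5 (UKN1 HDAC inhibitors).
#'
#' @param per_compound Named list of gene-regulation tables (one per
#'   compound) from \code{\link{collapse_to_genes}}.
#' @param min_count Minimum number of same-direction compounds.
#' @return Data.frame per gene: \code{symbol}, \code{n_up}, \code{n_down},
#'   \code{consensus} (logical), \code{direction} (of the winning count,
#'   "none" if not consensus; ties go to the larger mean |FC|),
#'   \code{mean_fc} (mean signed FC over the compounds calling the winning
#'   direction, NA if none).
#' @export
consensus_genes <- function(per_compound, min_count) {
  if (!length(per_compound)) stop("no compounds supplied")
  if (min_count < 1) stop("min_count must be >= 1")
  if (min_count > length(per_compound)) {
    stop("min_count exceeds the number of compounds (", length(per_compound), ")")
  }
  genes <- sort(unique(unlist(lapply(per_compound, `[[`, "symbol"))))
  n_up <- n_down <- integer(length(genes))
  fc_up <- fc_down <- vector("list", length(genes))
  for (tab in per_compound) {
    i <- match(tab$symbol, genes)
    up <- tab$status == "up"; down <- tab$status == "down"
    n_up[i[up]] <- n_up[i[up]] + 1L
    n_down[i[down]] <- n_down[i[down]] + 1L
    for (j in which(up)) fc_up[[i[j]]] <- c(fc_up[[i[j]]], tab$best_fc[j])
    for (j in which(down)) fc_down[[i[j]]] <- c(fc_down[[i[j]]], tab$best_fc[j])
  }
  consensus <- pmax(n_up, n_down) >= min_count
  direction <- rep("none", length(genes))
  mean_fc <- rep(NA_real_, length(genes))
  for (g in which(consensus)) {
    mu <- if (length(fc_up[[g]])) mean(fc_up[[g]]) else NA_real_
    md <- if (length(fc_down[[g]])) mean(fc_down[[g]]) else NA_real_
    dirn <- if (n_up[g] > n_down[g]) "up"
      else if (n_down[g] > n_up[g]) "down"
      else if (isTRUE(abs(mu) >= abs(md))) "up" else "down"
    direction[g] <- dirn
    mean_fc[g] <- if (dirn == "up") mu else md
  }
  data.frame(symbol = genes, n_up = n_up, n_down = n_down,
             consensus = consensus, direction = direction, mean_fc = mean_fc,
             stringsAsFactors = FALSE)
}

#' Cross-table of genes regulated by exactly 1..n compounds
#'
#' @param per_compound Named list of gene-regulation tables.
#' @return Data.frame with \code{n_compounds} (1..number of compounds) and
#'   counts \code{up}, \code{down} of genes called in that direction by
#'   exactly that many compounds.
#' @export
consensus_crosstable <- function(per_compound) {
  cons <- consensus_genes(per_compound, min_count = 1L)
  n <- length(per_compound)
  data.frame(n_compounds = seq_len(n),
             up = vapply(seq_len(n), function(k) sum(cons$n_up == k), integer(1L)),
             down = vapply(seq_len(n), function(k) sum(cons$n_down == k), integer(1L)))
}

#' Rank diagnostic-gene candidates by the six selection criteria
#'
#' Filters the consensus genes of a toxicant class down to diagnostic
#' candidates: (1) regulated by at least \code{min_count} compounds of the
#' class; (2) preferring large fold changes (the ranking key); (3) a
#' developmental gene; (4) antagonistic to spontaneous development (compound
#' direction opposite to the developmental direction); (5) baseline log2
#' expression above the cutoff at day 0 or at the end of differentiation;
#' (6) optionally restricted to a curated allow-list of genes with
#' understood function (skipped when no list is given, since biological
#' understanding is not computable). Candidates are ranked by number of
#' supporting compounds (descending), then mean |FC| (descending), then
#' gene id.
#'
#' @param consensus Consensus table from \code{\link{consensus_genes}}.
#' @param d_genes Gene-level developmental \code{regulon_sets}.
#' @param baseline Gene-level baseline table with columns \code{symbol} and
#'   \code{baseline} ("high"/"low"); genes absent from the table fail
#'   criterion 5.
#' @param min_count Criterion-1 threshold.
#' @param top_k Maximum number of candidates returned.
#' @param allow_list Optional character vector of gene symbols (criterion 6).
#' @return Ranked data.frame of candidates with per-criterion flags
#'   \code{c1}..\code{c6} (all TRUE for returned rows) and \code{rank}.
#' @export
rank_diagnostic_genes <- function(consensus, d_genes, baseline,
                                  min_count, top_k = 20, allow_list = NULL) {
  if (!nrow(consensus)) return(consensus[0, , drop = FALSE])
  cand <- consensus[consensus$direction %in% c("up", "down"), , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(symbol = character(), direction = character(),
                      n_compounds = integer(), mean_fc = numeric(),
                      c1 = logical(), c2 = logical(), c3 = logical(),
                      c4 = logical(), c5 = logical(), c6 = logical(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  n_support <- ifelse(cand$direction == "up", cand$n_up, cand$n_down)
  c1 <- n_support >= min_count
  c2 <- rep(TRUE, nrow(cand))  # fold change acts through the ranking key
  dev_dir <- rep(NA_character_, nrow(cand))
  dev_dir[cand$symbol %in% d_genes$up] <- "up"
  dev_dir[cand$symbol %in% d_genes$down] <- "down"
  c3 <- !is.na(dev_dir)
  c4 <- c3 & ((dev_dir == "up" & cand$direction == "down") |
                (dev_dir == "down" & cand$direction == "up"))
  hi <- baseline$symbol[baseline$baseline == "high"]
  c5 <- cand$symbol %in% hi
  c6 <- if (is.null(allow_list)) {
    message("rank_diagnostic_genes: no allow-list given; criterion 6 skipped")
    rep(TRUE, nrow(cand))
  } else cand$symbol %in% allow_list
  keep <- c1 & c2 & c3 & c4 & c5 & c6
  out <- data.frame(symbol = cand$symbol, direction = cand$direction,
                    n_compounds = n_support, mean_fc = cand$mean_fc,
                    c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  ord <- order(-out$n_compounds, -abs(out$mean_fc), out$symbol)
  out <- utils::head(out[ord, , drop = FALSE], top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gene-level baseline classification
#'
#' Lifts a probe-level baseline stratification to genes: a gene is
#' high-baseline if any probe mapping to it is.
#'
#' @param baseline Probe-level table from \code{\link{baseline_stratify}}.
#' @param annotation Probe-to-symbol annotation.
#' @return Data.frame with columns \code{symbol}, \code{baseline}.
#' @export
baseline_to_genes <- function(baseline, annotation) {
  ann <- annotation[annotation$probe_id %in% baseline$probe_id, , drop = FALSE]
  b <- stats::setNames(baseline$baseline, baseline$probe_id)
  ann$baseline <- unname(b[ann$probe_id])
  agg <- tapply(ann$baseline, ann$symbol, function(x)
    if (any(x == "high")) "high" else "low")
  data.frame(symbol = names(agg), baseline = unname(agg),
             stringsAsFactors = FALSE)
}
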