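make_deg <- function(probes, sig_up = character(), sig_down = character(),
                     fc_up = 2, fc_down = -2) {
  sig <- probes %in% c(sig_up, sig_down)
  dirn <- ifelse(probes %in% sig_up, "up",
                 ifelse(probes %in% sig_down, "down", "none"))
  data.frame(probe_id = probes,
             log2fc = ifelse(dirn == "up", log2(abs(fc_up)),
                             ifelse(dirn == "down", -log2(abs(fc_down)), 0)),
             fold_change = ifelse(dirn == "up", fc_up,
                                  ifelse(dirn == "down", fc_down, 1)),
             p = ifelse(sig, 1e-5, 0.6), q = ifelse(sig, 1e-3, 0.9),
             direction = dirn, significant = sig,
             stringsAsFactors = FALSE)
}

test_that("probe-to-gene collapse follows the one-significant-probe rule", {
  probes <- paste0("p", 1:6)
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    symbol = c("G1", "G2", "G2", "G3", "G3"))
  deg <- make_deg(probes, sig_up = c("p1", "p4"), sig_down = "p5")
  out <- collapse_to_genes(deg, ann)
  st <- setNames(out$status, out$symbol)
  expect_identical(st[["G1"]], "up")
  expect_identical(st[["G2"]], "none")
  expect_identical(st[["G3"]], "inconsistent")
  # duplicated annotation rows change nothing
  out2 <- collapse_to_genes(deg, rbind(ann, ann))
  expect_identical(out, out2)
  # unannotated probe p6 is dropped
  expect_false(any(grepl("p6", out$symbol)))
})

test_that("gene statuses equal a brute-force per-gene scan on a 50-gene fixture", {
  set.seed(6)
  n <- 150
  probes <- sprintf("p%03d", 1:n)
  ann <- data.frame(probe_id = probes,
                    symbol = sprintf("G%02d", sample(1:50, n, replace = TRUE)))
  sig_up <- sample(probes, 30)
  sig_down <- sample(setdiff(probes, sig_up), 25)
  deg <- make_deg(probes, sig_up, sig_down)
  out <- collapse_to_genes(deg, ann)
  for (g in out$symbol) {
    ps <- ann$probe_id[ann$symbol == g]
    has_up <- any(ps %in% sig_up); has_down <- any(ps %in% sig_down)
    want <- if (has_up && has_down) "inconsistent"
      else if (has_up) "up" else if (has_down) "down" else "none"
    expect_identical(out$status[out$symbol == g], want)
  }
})

test_that("consensus counting matches enumeration and is monotone in min_count", {
  genes <- sprintf("G%02d", 1:20)
  set.seed(12)
  per_compound <- lapply(1:6, function(i) {
    status <- sample(c("up", "down", "none", "inconsistent"), 20,
                     replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
    data.frame(symbol = genes, status = status,
               best_fc = ifelse(status == "up", 2, ifelse(status == "down", -2, NA)),
               stringsAsFactors = FALSE)
  })
  cons <- consensus_genes(per_compound, min_count = 3)
  for (g in seq_along(genes)) {
    n_up <- sum(vapply(per_compound, function(x) x$status[g] == "up", logical(1)))
    n_down <- sum(vapply(per_compound, function(x) x$status[g] == "down", logical(1)))
    expect_equal(cons$n_up[g], n_up)
    expect_equal(cons$n_down[g], n_down)
    expect_equal(cons$consensus[g], max(n_up, n_down) >= 3)
  }
  # inconsistent calls count toward neither direction (checked above via ==)
  ct <- consensus_crosstable(per_compound)
  for (k in 1:6) {
    expect_equal(ct$up[k], sum(cons$n_up == k))
    expect_equal(ct$down[k], sum(cons$n_down == k))
  }
  # raising min_count never adds consensus genes
  prev <- cons$consensus
  for (mc in 4:6) {
    cur <- consensus_genes(per_compound, min_count = mc)$consensus
    expect_true(all(cur <= prev))
    prev <- cur
  }
  expect_error(consensus_genes(per_compound, min_count = 0), ">= 1")
  expect_error(consensus_genes(per_compound, min_count = 7), "exceeds")
})

test_that("diagnostic ranking applies all six criteria and orders candidates", {
  # planted ideal candidate: antagonistic, high baseline, many compounds, big FC
  cons <- data.frame(
    symbol = c("IDEAL", "CODIR", "LOWBASE", "WEAK", "NOND"),
    n_up = c(0, 5, 0, 0, 5),
    n_down = c(6, 0, 6, 3, 0),
    consensus = TRUE,
    direction = c("down", "up", "down", "down", "up"),
    mean_fc = c(-8, 4, -6, -2, 3),
    stringsAsFactors = FALSE)
  d_genes <- regulon_sets(up = c("IDEAL", "CODIR", "LOWBASE", "WEAK"),
                          down = character(), namespace = "symbol")
  baseline <- data.frame(symbol = c("IDEAL", "CODIR", "WEAK", "NOND"),
                         baseline = "high")
  out <- suppressMessages(
    rank_diagnostic_genes(cons, d_genes, baseline, min_count = 4, top_k = 10))
  # CODIR is co-directional with development (c4), LOWBASE fails c5,
  # WEAK fails c1 (3 < 4), NOND is not developmental (c3)
  expect_identical(out$symbol, "IDEAL")
  expect_equal(out$rank, 1L)
  expect_true(all(out$c1 & out$c2 & out$c3 & out$c4 & out$c5 & out$c6))

  # allow-list excludes genes of unknown function
  out2 <- rank_diagnostic_genes(cons, d_genes, baseline, min_count = 4,
                                allow_list = "OTHER")
  expect_equal(nrow(out2), 0)

  # every returned candidate re-passes a direct check of the criteria
  set.seed(3)
  sym <- sprintf("G%02d", 1:40)
  cons2 <- data.frame(symbol = sym,
                      n_up = sample(0:6, 40, TRUE), n_down = sample(0:6, 40, TRUE),
                      consensus = TRUE, stringsAsFactors = FALSE)
  cons2$direction <- ifelse(cons2$n_up >= cons2$n_down, "up", "down")
  cons2$mean_fc <- ifelse(cons2$direction == "up", 1, -1) * runif(40, 1.5, 9)
  dg <- regulon_sets(up = sample(sym[1:20], 15), down = sample(sym[21:40], 5),
                     namespace = "symbol")
  bl <- data.frame(symbol = sym, baseline = sample(c("high", "low"), 40, TRUE))
  res <- suppressMessages(
    rank_diagnostic_genes(cons2, dg, bl, min_count = 3, top_k = 40))
  for (i in seq_len(nrow(res))) {
    g <- res$symbol[i]; dirn <- res$direction[i]
    expect_gte(res$n_compounds[i], 3)
    dev_dir <- if (g %in% dg$up) "up" else if (g %in% dg$down) "down" else NA
    expect_false(is.na(dev_dir))
    expect_true(dev_dir != dirn)
    expect_identical(bl$baseline[bl$symbol == g], "high")
  }
  # ranking keys: n_compounds desc, then |FC| desc
  if (nrow(res) > 1) {
    expect_true(all(diff(res$n_compounds) <= 0))
  }
})
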