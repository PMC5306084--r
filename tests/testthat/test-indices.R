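test_that("overlap and quadrants equal brute-force set algebra", {
  d <- regulon_sets(c("a", "b"), c("x"))
  t0 <- regulon_sets(c("q"), c("r"))
  ov0 <- compute_overlap(d, t0)
  expect_equal(ov0$O, 0)
  expect_true(all(ov0$quadrants == 0))

  t1 <- regulon_sets(character(), c("b", "c"))
  ov1 <- compute_overlap(d, t1)
  expect_equal(ov1$O, 1)
  expect_equal(unname(ov1$quadrants["t_down_d_up"]), 1L)
  expect_identical(ov1$members$t_down_d_up, "b")

  set.seed(2)
  ids <- sprintf("g%04d", 1:1000)
  for (i in 1:20) {
    dset <- sample(ids, 100); tset <- sample(ids, 80)
    du <- sample(dset, 60); dd <- setdiff(dset, du)
    tu <- sample(tset, 30); td <- setdiff(tset, tu)
    d2 <- regulon_sets(du, dd); t2 <- regulon_sets(tu, td)
    ov <- compute_overlap(d2, t2)
    expect_equal(ov$O, length(intersect(dset, tset)))
    expect_equal(unname(ov$quadrants),
                 c(length(intersect(tu, du)), length(intersect(tu, dd)),
                   length(intersect(td, du)), length(intersect(td, dd))))
    # quadrants partition the overlap
    expect_equal(sum(ov$quadrants), ov$O)
  }
  mismatched <- regulon_sets("a", "b", namespace = "symbol")
  expect_error(compute_overlap(d, mismatched), "namespace")
})

test_that("Dp and Di follow their defining formulas", {
  expect_equal(compute_dp(0, 100), 0)
  expect_equal(compute_dp(100, 100), 1)
  expect_equal(compute_dp(500, 4000), 0.125)
  expect_error(compute_dp(1, 0), "D = 0")

  expect_equal(compute_di(50, 100, 1000, 54675), 27.3375)
  expect_equal(compute_di(0, 100, 1000, 54675), 0)
  expect_true(is.na(compute_di(0, 0, 1000, 54675)))
  # O/T equal to D/N is the random expectation
  expect_equal(compute_di(2, 100, 400, 20000), 1)
})

test_that("overlap significance equals the hypergeometric tail oracle", {
  expect_equal(overlap_significance(4, 4, 5, 20), 5 / 4845, tolerance = 1e-12)
  expect_equal(overlap_significance(0, 10, 10, 100), 1)
  expect_equal(overlap_significance(1, 10, 10, 100),
               1 - choose(90, 10) / choose(100, 10), tolerance = 1e-12)
  expect_error(overlap_significance(6, 5, 10, 100), "exceed")

  set.seed(7)
  for (i in 1:50) {
    N <- sample(20:500, 1)
    D <- sample(1:(N - 1), 1)
    T_ <- sample(1:(N - 1), 1)
    O <- sample(0:min(D, T_), 1)
    expect_equal(overlap_significance(O, T_, D, N),
                 hyper_tail_oracle(O, T_, D, N), tolerance = 1e-12)
  }
})

test_that("the Di identity Di = O*N/(T*D) holds on every computed row", {
  set.seed(13)
  ids <- sprintf("g%04d", 1:2000)
  for (i in 1:25) {
    dset <- sample(ids, sample(50:400, 1))
    tset <- sample(ids, sample(10:300, 1))
    du <- sample(dset, length(dset) %/% 2)
    tu <- sample(tset, length(tset) %/% 2)
    r <- developmental_indices(regulon_sets(du, setdiff(dset, du)),
                               regulon_sets(tu, setdiff(tset, tu)),
                               N = 2000)
    expect_equal(r$Di, (r$O * r$N) / (r$T * r$D), tolerance = 1e-12)
    expect_equal(r$Dp, r$O / r$D, tolerance = 1e-12)
    expect_true(r$O <= min(r$D, r$T))
  }
})

test_that("antagonism fractions recover planted structure", {
  d <- regulon_sets(c("a", "b"), c("c", "d"))
  t_empty <- regulon_sets(character(), character())
  fr <- antagonism_fractions(d, t_empty)
  expect_true(all(fr$fraction == 0))

  t_perfect <- regulon_sets(character(), c("a", "b"))
  fr2 <- antagonism_fractions(d, t_perfect)
  expect_equal(fr2$fraction[fr2$t_direction == "down" & fr2$d_direction == "up"], 1)

  # planted antagonism fraction recovered through the full DGE pipeline
  cfg <- synth_config(n_probes = 8000, d_up = 400, d_down = 400,
                      t_total = 400, overlap = 200,
                      antagonism_fraction = 0.7)
  ds <- generate_dataset(cfg, seed = 31)
  m <- quantile_normalize(ds$matrix)
  day0 <- ds$design$sample_id[ds$design$role == "day0_control"]
  diffc <- ds$design$sample_id[ds$design$role == "diff_control"]
  trt <- ds$design$sample_id[ds$design$role == "treated"]
  d_reg <- call_regulons(suppressMessages(
    differential_expression(m, day0, diffc)))
  t_reg <- call_regulons(suppressMessages(
    differential_expression(m, diffc, trt)))
  r <- developmental_indices(d_reg, t_reg, N = nrow(m))
  expect_lt(abs(r$antagonistic_fraction - 0.7), 0.05)
})

test_that("category restriction reproduces global indices and brute force", {
  set.seed(5)
  ids <- sprintf("g%04d", 1:1000)
  dset <- sample(ids, 200); tset <- sample(ids, 100)
  du <- sample(dset, 120); dd <- setdiff(dset, du)
  tu <- sample(tset, 40); td <- setdiff(tset, tu)
  d <- regulon_sets(du, dd); t <- regulon_sets(tu, td)
  full <- list(all_dev = dset)
  ci <- category_indices(d, t, full, N = 1000)
  glob <- developmental_indices(d, t, N = 1000)
  expect_equal(ci$Dp, glob$Dp)
  expect_equal(ci$Di, glob$Di)

  cats <- list(c1 = sample(ids, 300), c2 = sample(ids, 150),
               c3 = sample(ids, 50), empty = setdiff(ids, dset)[1:20])
  out <- suppressMessages(category_indices(d, t, cats, N = 1000))
  for (i in seq_len(nrow(out))) {
    nm <- out$category[i]
    D_c <- length(intersect(dset, cats[[nm]]))
    O_c <- length(intersect(intersect(dset, tset), cats[[nm]]))
    expect_equal(out$D_c[i], D_c)
    expect_equal(out$Dp[i], O_c / D_c)
  }
  expect_false("empty" %in% out$category)
  expect_error(category_indices(d, t, list(), 1000), "empty")
})

test_that("baseline stratification uses a strict >6 rule on either control", {
  m <- rbind(P1 = c(6.5, 6.5, 5.0, 5.0),
             P2 = c(5.9, 5.9, 5.9, 5.9),
             P3 = c(6.0, 6.0, 6.0, 6.0),
             P4 = c(5.0, 5.0, 7.0, 7.0))
  colnames(m) <- paste0("S", 1:4)
  design <- data.frame(sample_id = paste0("S", 1:4),
                       role = rep(c("day0_control", "diff_control"), each = 2),
                       batch = "b1", replicate = c(1, 2, 1, 2))
  reg <- regulon_sets(c("P1", "P2"), c("P3", "P4"))
  out <- baseline_stratify(reg, m, design)
  expect_identical(out$baseline, c("high", "low", "low", "high"))
  expect_error(baseline_stratify(reg, m, design[1:2, ]),
               "diff_control")
})

test_that("concentration profiles track planted dose structure", {
  set.seed(19)
  n <- 3000
  probes <- sprintf("PS%04d", 1:n)
  d <- regulon_sets(probes[1:150], probes[151:300])
  mk_deg <- function(t_idx) {
    sig <- seq_len(n) %in% t_idx
    data.frame(probe_id = probes, log2fc = ifelse(sig, 2, 0),
               fold_change = ifelse(sig, 4, 1), p = ifelse(sig, 1e-6, 0.5),
               q = ifelse(sig, 1e-4, 0.9),
               direction = ifelse(sig, "up", "none"), significant = sig)
  }
  # growing T with a fixed 30% overlap rate -> Dp non-decreasing
  per_conc <- list()
  for (i in 1:4) {
    T_ <- 50 * i
    t_idx <- c(1:(0.3 * T_), 300 + seq_len(0.7 * T_))
    per_conc[[as.character(10^i)]] <- mk_deg(t_idx)
  }
  prof <- concentration_profile(per_conc, d, N = n)
  expect_equal(prof$concentration, 10^(1:4))
  expect_true(all(diff(prof$Dp) >= 0))
  single <- concentration_profile(per_conc[1], d, N = n)
  r1 <- developmental_indices(d, call_regulons(per_conc[[1]]), N = n)
  expect_equal(single$Di, r1$Di)

  # a cytotoxic top dose adding only non-developmental genes lowers Di
  low <- mk_deg(1:60)                      # all developmental
  high <- mk_deg(c(1:60, 500:1400))        # plus 901 cytotoxicity probes
  prof2 <- concentration_profile(list(`1` = low, `100` = high), d, N = n)
  expect_lt(prof2$Di[2], prof2$Di[1])

  expect_error(concentration_profile(list(`1` = low, `1` = high), d, N = n),
               "duplicate")
})

test_that("random T subsets calibrate Di around 1 and p-values are honest", {
  set.seed(23)
  N <- 20000; D <- 1000; T_ <- 100
  draws <- 300
  di <- numeric(draws); pv <- numeric(draws)
  for (i in seq_len(draws)) {
    O <- sum(sample.int(N, T_) <= D)
    di[i] <- compute_di(O, T_, D, N)
    pv[i] <- overlap_significance(O, T_, D, N)
  }
  expect_lt(abs(mean(di) - 1), 0.08)
  expect_lte(mean(pv <= 0.05), 0.06)
})
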