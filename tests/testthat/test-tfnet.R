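test_that("k-NN mutual information behaves like an MI estimator", {
  set.seed(1)
  n <- 1000
  # independence: estimate near zero
  expect_lt(knn_mi(runif(n), runif(n), k = 9), 0.05)
  # functional dependence dominates a mixed matrix
  x <- rnorm(200)
  m <- rbind(a = x, b = x, c = rnorm(200), d = rnorm(200))
  mi <- knn_mutual_information(m, k = 9)
  expect_setequal(unname(which(mi == max(mi), arr.ind = TRUE)[1, ]), c(1, 2))
  # symmetry of the estimator and the matrix
  set.seed(2)
  u <- rnorm(300); v <- u + rnorm(300)
  set.seed(99); m1 <- knn_mi(u, v)
  set.seed(99); m2 <- knn_mi(v, u)
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_true(isSymmetric(mi))
  # constant vector yields zero MI
  m2r <- rbind(k = rep(1, 50), l = rnorm(50))
  expect_true(all(suppressMessages(knn_mutual_information(m2r, k = 3)) == 0))
})

test_that("the estimator matches the bivariate Gaussian closed form", {
  set.seed(7)
  rho <- 0.9; n <- 1000
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  truth <- -0.5 * log(1 - rho^2)
  est <- knn_mi(x, y, k = 9)
  expect_lt(abs(est - truth), 0.1)
  # invariance under monotone rescaling of a margin
  set.seed(8)
  est2 <- knn_mi(exp(x), y, k = 9)
  expect_lt(abs(est2 - est), 0.05)
})

test_that("CLR scores equal the direct formula oracle", {
  g <- 20
  set.seed(10)
  mi <- matrix(0, g, g)
  mi[upper.tri(mi)] <- runif(g * (g - 1) / 2)
  mi <- mi + t(mi)
  sc <- clr_scores(mi)
  expect_equal(sc, clr_oracle(mi), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(sc))

  flat <- matrix(0.4, 5, 5); diag(flat) <- 0
  expect_true(all(clr_scores(flat) == 0))

  spiked <- flat; spiked[1, 2] <- spiked[2, 1] <- 2
  scs <- clr_scores(spiked)
  expect_equal(unname(which(scs == max(scs), arr.ind = TRUE)[1, ]), c(2, 1),
               ignore_attr = TRUE)
})

test_that("edge selection keeps the ceiling of the top quantile", {
  g <- 200
  set.seed(20)
  sc <- matrix(0, g, g, dimnames = list(sprintf("TF%03d", 1:g),
                                        sprintf("TF%03d", 1:g)))
  vals <- sample(seq_len(g * (g - 1) / 2))  # distinct scores
  sc[upper.tri(sc)] <- vals
  sc <- sc + t(sc)
  nw <- build_network(sc, rownames(sc), edge_quantile = 0.001)
  expect_equal(nrow(nw$edges), ceiling(0.001 * g * (g - 1) / 2))  # 20
  expect_equal(length(nw$nodes), g)

  full <- build_network(sc, rownames(sc), edge_quantile = 1)
  expect_equal(nrow(full$edges), g * (g - 1) / 2)
  expect_error(build_network(sc, "NOT_A_TF"), "no transcription factor")
})

test_that("planted co-expression modules are recovered end to end", {
  cx <- generate_coexpression(n_modules = 3, module_size = 10,
                              n_samples = 200, rho = 0.9, seed = 11)
  set.seed(11)
  mi <- knn_mutual_information(cx$matrix, k = 9)
  sc <- clr_scores(mi)
  nw <- build_network(sc, rownames(cx$matrix), edge_quantile = 0.1)
  # kept edges concentrate within planted modules
  same <- cx$modules[nw$edges$from] == cx$modules[nw$edges$to]
  expect_gte(mean(same), 0.8)
  comm <- detect_communities(nw)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(comm$membership[names(cx$modules)],
                                   cx$modules)
  expect_gte(ari, 0.8)
})

test_that("community detection and size filtering follow the fast-greedy rules", {
  # two 8-node cliques joined by one edge
  g <- 8
  blocks <- lapply(c(0, g), function(off) t(combn(off + seq_len(g), 2)))
  edges <- rbind(do.call(rbind, blocks), c(1, g + 1))
  sc <- matrix(0, 2 * g, 2 * g,
               dimnames = list(paste0("TF", 1:(2 * g)), paste0("TF", 1:(2 * g))))
  sc[edges] <- 1; sc <- pmax(sc, t(sc))
  nw <- build_network(sc, rownames(sc),
                      edge_quantile = nrow(edges) / choose(2 * g, 2))
  comm <- detect_communities(nw, min_size = 6, top_n = 18)
  expect_equal(sort(comm$sizes), c(8, 8))
  expect_equal(comm$retained, 1:2)  # fewer than top_n exist -> all retained
  memb <- comm$membership
  expect_length(unique(memb[paste0("TF", 1:g)]), 1)
  expect_length(unique(memb[paste0("TF", (g + 1):(2 * g))]), 1)
  expect_gte(comm$modularity, 0)  # beats the one-community partition
})

test_that("community enrichment uses the shared hypergeometric oracle", {
  memb <- setNames(c(1, 1, 1, 2, 2, 2, 2), paste0("TF", 1:7))
  comm <- list(membership = memb, retained = 1:2)
  sets <- list(exact = c("TF1", "TF2", "TF3"),
               disjoint = c("TF4", "TF5"),
               broad = paste0("TF", 1:6))
  out <- enrich_communities(comm, sets, alpha = 1.01)
  row1 <- out[out$community == 1 & out$term == "exact", ]
  expect_equal(row1$p, hyper_tail_oracle(3, 3, 3, 7), tolerance = 1e-12)
  # the exactly-matching term is the most significant for its community
  expect_equal(out$term[out$community == 1][1], "exact")
  expect_equal(out$p[out$community == 1 & out$term == "disjoint"], 1)
})

test_that("regulation overlay marks consistent TFs and drops inconsistent ones", {
  sc <- matrix(0.5, 4, 4, dimnames = list(paste0("TF", 1:4), paste0("TF", 1:4)))
  diag(sc) <- 0
  nw <- build_network(sc, rownames(sc), edge_quantile = 1)
  reg <- data.frame(symbol = c("TF1", "TF2", "TF3", "OTHER"),
                    status = c("up", "inconsistent", "none", "down"),
                    stringsAsFactors = FALSE)
  ov <- overlay_regulation(nw, reg)
  expect_identical(unname(ov$node_state[c("TF1", "TF2", "TF3", "TF4")]),
                   c("up", "none", "none", "none"))
  expect_identical(ov$inconsistent, "TF2")

  none <- overlay_regulation(nw, reg[reg$status == "none", , drop = FALSE])
  expect_true(all(none$node_state == "none"))

  comm <- list(membership = setNames(c(1, 1, 2, 2), paste0("TF", 1:4)),
               retained = 1:2)
  ov2 <- overlay_regulation(nw, reg, communities = comm)
  cs <- ov2$community_summary
  expect_equal(cs$n_affected[cs$community == 1], 1)
  expect_equal(cs$fraction_of_affected[cs$community == 1], 1)
})
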