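test_that("Pearson networks capture exact linear relations and null independence", {
  x <- sin(seq(0, 20, length.out = 1200))
  m <- rbind(x, 2 * x)
  W <- pearson_network(m)$W
  expect_equal(W[1, 2], 1, tolerance = 1e-12)
  m2 <- rbind(c(1, 2, 3), c(6, 4, 2))
  expect_equal(pearson_network(m2)$W[1, 2], -1, tolerance = 1e-12)
  set.seed(31)
  m3 <- matrix(rnorm(2 * 1200), 2)
  expect_lt(abs(pearson_network(m3)$W[1, 2]), 0.1)
  # zero-variance channel: zeroed row with warning
  m4 <- rbind(rnorm(100), rep(1, 100), rnorm(100))
  expect_warning(W4 <- pearson_network(m4)$W, "zero-variance")
  expect_equal(unname(W4[2, ]), rep(0, 3))
})

test_that("coherence is 1 for identical channels and small for independent noise", {
  set.seed(32)
  x <- rnorm(12000)
  expect_warning(W <- coherence_network(rbind(x, x), 600, c(8, 13))$W, NA)
  expect_equal(W[1, 2], 1, tolerance = 1e-9)
  m <- matrix(rnorm(2 * 12000), 2)
  expect_lt(coherence_network(m, 600, c(8, 13))$W[1, 2], 0.2)
})

test_that("a shared oscillation raises coherence in its own band", {
  set.seed(33)
  t <- seq(1 / 600, 20, by = 1 / 600)
  shared <- sin(2 * pi * 40 * t)
  m <- rbind(shared + rnorm(length(t)), shared + rnorm(length(t)))
  gamma_coh <- coherence_network(m, 600, c(30, 50))$W[1, 2]
  broad <- mean(vapply(list(c(1, 4), c(4, 8), c(8, 13), c(13, 30), c(50, 80)),
                       function(b) coherence_network(m, 600, b)$W[1, 2],
                       numeric(1)))
  expect_gt(gamma_coh, broad)
})

test_that("PLV is 1 under identical or constant-shifted phase and small under independence", {
  t <- seq(1 / 600, 2, by = 1 / 600)
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * t + 1.1)
  expect_equal(plv_network(rbind(x, x), 600, c(8, 13))$W[1, 2], 1, tolerance = 1e-9)
  expect_equal(plv_network(rbind(x, y), 600, c(8, 13))$W[1, 2], 1, tolerance = 1e-6)
  set.seed(34)
  m <- matrix(rnorm(2 * 1200), 2)
  expect_lt(plv_network(m, 600, c(30, 50))$W[1, 2], 0.25)
})

test_that("connectivity matrices are symmetric with zero diagonal and bounded entries", {
  set.seed(35)
  m <- matrix(rnorm(4 * 1200), 4)
  for (W in list(pearson_network(m, 600, c(8, 13)),
                 coherence_network(m, 600, c(8, 13)),
                 plv_network(m, 600, c(8, 13)))) {
    expect_equal(W$W, t(W$W))
    expect_equal(diag(W$W), rep(0, 4), ignore_attr = TRUE)
    if (W$method == "pearson") {
      expect_true(all(W$W >= -1 & W$W <= 1))
    } else {
      expect_true(all(W$W >= 0 & W$W <= 1))
    }
  }
})

test_that("graph properties match closed forms on canonical small graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  gp <- graph_properties(tri)
  expect_equal(gp$cc_mean, 1, tolerance = 1e-12)
  expect_equal(gp$cpl, 1, tolerance = 1e-12)
  expect_equal(gp$ge, 1, tolerance = 1e-12)
  expect_equal(gp$le_mean, 1, tolerance = 1e-12)
  # path A-B-C: distances {1, 1, 2} -> Ge = mean(1, 1, 1/2) = 5/6
  pth <- matrix(0, 3, 3); pth[1, 2] <- pth[2, 1] <- 1; pth[2, 3] <- pth[3, 2] <- 1
  gp2 <- suppressWarnings(graph_properties(pth))
  expect_equal(gp2$ge, 5 / 6, tolerance = 1e-12)
  expect_equal(gp2$cpl, (1 + 1 + 2) / 3, tolerance = 1e-12)
})

test_that("graph properties equal the brute-force oracle on random weighted graphs", {
  set.seed(36)
  for (i in 1:20) {
    W <- matrix(runif(36), 6, 6)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    W[W < 0.3] <- 0  # some absent edges
    if (i %% 3 == 0) W <- W - 0.2  # include negative weights
    gp <- suppressWarnings(graph_properties(W))
    or <- suppressWarnings(oracle_graph(W))
    expect_equal(gp$cc_mean, or$cc_mean, tolerance = 1e-10)
    expect_equal(gp$cpl, or$cpl, tolerance = 1e-10)
    expect_equal(gp$le_mean, or$le_mean, tolerance = 1e-10)
    expect_equal(gp$ge, or$ge, tolerance = 1e-10)
  }
})

test_that("node relabeling leaves the scalar graph properties unchanged", {
  set.seed(37)
  W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2; diag(W) <- 0
  p <- sample(5)
  expect_equal(graph_properties(W), graph_properties(W[p, p]), tolerance = 1e-12)
})

test_that("per-node output is available behind a flag", {
  W <- matrix(1, 4, 4); diag(W) <- 0
  gp <- graph_properties(W, per_node = TRUE)
  expect_length(gp$cc_nodes[[1]], 4)
  expect_length(gp$le_nodes[[1]], 4)
})
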