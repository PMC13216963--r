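triangle <- data.frame(node_a = c("a", "b", "a"), node_b = c("b", "c", "c"),
                       delta = c(1.0, 1.0, 2.1))

test_that("a consistent chain is reproduced exactly with SS = 0", {
  m <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"), delta = c(1, 1))
  fit <- fit_ladder(m, anchor_set(c(a = 0)))
  expect_equal(coef(fit), c(a = 0, b = 1, c = 2), tolerance = 1e-12)
  expect_equal(fit$SS, 0, tolerance = 1e-20)
})

test_that("the inconsistent triangle matches the closed-form normal equations", {
  fit <- fit_ladder(triangle, anchor_set(c(a = 0)))
  expect_equal(unname(coef(fit)[c("b", "c")]), c(3.1 / 3, 6.2 / 3), tolerance = 1e-9)
  expect_equal(fit$n_m, 3L); expect_equal(fit$n_c, 2L)
  expect_equal(consistency_s(fit), sqrt((3 * (0.1 / 3)^2) / 1), tolerance = 1e-9)
  expect_equal(consistency_s(fit), 0.0577, tolerance = 1e-3)
  # normal equations satisfied: residuals orthogonal to each free direction
  m <- fit$measurements
  for (nd in c("b", "c")) {
    g <- sum(m$residual * ((m$node_b == nd) - (m$node_a == nd)))
    expect_lt(abs(g), 1e-9)
  }
})

test_that("shifting the pinned anchor translates values, not residuals", {
  f0 <- fit_ladder(triangle, anchor_set(c(a = 0)))
  f5 <- fit_ladder(triangle, anchor_set(c(a = 5)))
  expect_equal(coef(f5), coef(f0) + 5, tolerance = 1e-10)
  expect_equal(residuals(f5), residuals(f0), tolerance = 1e-12)
  expect_equal(consistency_s(f5), consistency_s(f0), tolerance = 1e-12)
})

test_that("node relabeling leaves residuals and s invariant", {
  relab <- c(a = "z", b = "q", c = "k")
  m2 <- triangle
  m2$node_a <- unname(relab[m2$node_a]); m2$node_b <- unname(relab[m2$node_b])
  f1 <- fit_ladder(triangle, anchor_set(c(a = 0)))
  f2 <- fit_ladder(m2, anchor_set(c(z = 0)))
  expect_equal(sort(abs(residuals(f1))), sort(abs(residuals(f2))), tolerance = 1e-12)
  expect_equal(consistency_s(f1), consistency_s(f2), tolerance = 1e-12)
})

test_that("ladder solve matches a brute-force oracle on random connected graphs", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    m <- random_connected_graph(n, extra = sample(0:3, 1))
    pin <- setNames(rnorm(1), "a")
    fit <- fit_ladder(m, anchor_set(pin))
    oracle <- brute_force_ladder(m, pin)
    expect_equal(coef(fit)[names(oracle)], oracle, tolerance = 1e-6)
  }
})

test_that("a disconnected graph is rejected with its components listed", {
  m <- data.frame(node_a = c("a", "c"), node_b = c("b", "d"), delta = c(1, 1))
  expect_error(fit_ladder(m, anchor_set(c(a = 0))), "disconnected.*[cd]")
})

test_that("degrees of freedom conventions and the undefined case behave", {
  m <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"), delta = c(1, 1.2))
  fit <- fit_ladder(m, anchor_set(c(a = 0)))
  expect_equal(fit$n_m, 2L); expect_equal(fit$n_c, 2L)
  expect_message(s <- consistency_s(fit), "undefined")
  expect_true(is.na(s))
  alt <- fit_ladder(triangle, anchor_set(c(a = 0)), nc_counts_anchors = TRUE)
  expect_equal(alt$n_c, 3L)
  expect_true(is.na(suppressMessages(consistency_s(alt))))
})

test_that("anchoring offset is the mean calc-minus-relative difference", {
  expect_equal(anchor_offset(c(x = 0, y = 1, z = 2), c(x = 10.1, y = 11.0, z = 12.2)),
               mean(c(10.1, 11.0, 12.2) - c(0, 1, 2)))
  expect_equal(anchor_offset(c(x = 0), c(x = 40.8)), 40.8)
  expect_error(anchor_offset(c(x = 0), c(q = 1)), "no overlap")
})

test_that("multi-anchor offset recovers a planted shift from noisy anchors", {
  set.seed(31)
  rel <- setNames(runif(9, 0, 15), paste0("n", 1:9))
  calc <- rel + 40.8 + rnorm(9, 0, 1.5)
  off <- anchor_offset(rel, calc)
  expect_lt(abs(off - 40.8), 3 * 1.5 / sqrt(9))
})

test_that("offset anchoring shifts a fitted ladder onto the reference scale", {
  gl <- gen_ladder(n_nodes = 8, n_edges = 14, noise_sd = 0, seed = 6)
  anchors <- gl$truth[c(1, 4, 7)]
  fit <- fit_ladder(gl$measurements, anchor_set(anchors, mode = "offset_multi"))
  expect_equal(coef(fit)[names(gl$truth)], gl$truth, tolerance = 1e-8)
  expect_equal(fit$n_c, length(gl$truth))   # free nodes (n-1) + offset
})

test_that("a single planted outlier is excluded and the refit is clean", {
  m <- data.frame(node_a = c("a", "b", "a", "c", "b", "a"),
                  node_b = c("b", "c", "c", "d", "d", "d"),
                  delta = c(1, 1, 2, 1, 2, 4.5))   # a->d should be 3
  fit <- exclude_inconsistent(m, anchor_set(c(a = 0)), threshold = 0.75)
  expect_equal(which(fit$measurements$excluded), 6L)
  expect_equal(fit$SS, 0, tolerance = 1e-18)
  expect_equal(unname(coef(fit)["d"]), 3, tolerance = 1e-10)
})

test_that("exclusion is a no-op when all residuals sit under the threshold", {
  f0 <- fit_ladder(triangle, anchor_set(c(a = 0)))
  f1 <- exclude_inconsistent(triangle, anchor_set(c(a = 0)), threshold = 0.75)
  expect_equal(coef(f1), coef(f0), tolerance = 1e-12)
  expect_false(any(f1$measurements$excluded))
})

test_that("planted outliers are caught and no clean edge is ever sacrificed", {
  # a well-connected graph keeps per-edge leverage low enough that a +-1.0
  # outlier leaves a residual near its full size; an outlier landing on a
  # high-leverage edge is statistically invisible, so detection is assessed
  # across replicates while false positives must never occur
  caught <- 0; planted <- 0
  for (k in 1:25) {
    gl <- gen_ladder(n_nodes = 20, n_edges = 120, noise_sd = 0.05,
                     n_outliers = 3, outlier_magnitude = 1.0, seed = 400 + k)
    fit <- exclude_inconsistent(gl$measurements,
                                anchor_set(setNames(gl$truth[1], names(gl$truth)[1])),
                                threshold = 0.75)
    exc <- which(fit$measurements$excluded)
    expect_length(setdiff(exc, gl$outlier_idx), 0)   # no clean edge excluded
    caught <- caught + length(intersect(exc, gl$outlier_idx))
    planted <- planted + length(gl$outlier_idx)
  }
  expect_gt(caught / planted, 0.8)
})

test_that("exclusion always leaves the measurement graph connected", {
  set.seed(61)
  for (rep in 1:10) {
    m <- random_connected_graph(5, extra = 3)
    m$delta <- m$delta + rnorm(nrow(m), 0, 1)   # gross inconsistency everywhere
    fit <- suppressWarnings(
      fit_ladder(m, anchor_set(c(a = 0)), exclude_threshold = 0.05))
    kept <- fit$measurements[!fit$measurements$excluded, ]
    g <- igraph::graph_from_data_frame(
      kept[, c("node_a", "node_b")], directed = FALSE,
      vertices = data.frame(name = sort(unique(c(m$node_a, m$node_b)))))
    expect_equal(igraph::components(g)$no, 1L)
  }
})

test_that("scale report orders nodes, reports the span, and keeps red edges", {
  fit <- fit_ladder(triangle, anchor_set(c(a = 0)))
  rep <- scale_report(fit)
  expect_equal(rep$span, 6.2 / 3, tolerance = 1e-9)
  expect_equal(rep$nodes$node, c("c", "b", "a"))
  single <- fit_ladder(data.frame(node_a = "a", node_b = "b", delta = 0),
                       anchor_set(c(a = 0)))
  expect_equal(scale_report(single)$span, 0)
  expect_true(all(c("measured", "assigned", "residual", "excluded") %in%
                    names(rep$edges)))
})

test_that("predict returns assigned differences for arbitrary node pairs", {
  fit <- fit_ladder(triangle, anchor_set(c(a = 0)))
  p <- predict(fit, data.frame(node_a = "a", node_b = "c"))
  expect_equal(p, 6.2 / 3, tolerance = 1e-9)
  expect_error(predict(fit, data.frame(node_a = "a", node_b = "zz")), "zz")
})

test_that("parameter recovery improves with edge count and s estimates sigma", {
  set.seed(8)
  rmse <- function(n_edges) {
    errs <- vapply(1:6, function(k) {
      gl <- gen_ladder(n_nodes = 20, n_edges = n_edges, noise_sd = 0.1, seed = 100 + k)
      fit <- fit_ladder(gl$measurements,
                        anchor_set(setNames(gl$truth[1], names(gl$truth)[1])))
      sqrt(mean((coef(fit)[names(gl$truth)] - gl$truth)^2))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(rmse(80), rmse(20))
  s_vals <- vapply(1:25, function(k) {
    gl <- gen_ladder(n_nodes = 20, n_edges = 40, noise_sd = 0.1, seed = 200 + k)
    fit <- fit_ladder(gl$measurements,
                      anchor_set(setNames(gl$truth[1], names(gl$truth)[1])))
    consistency_s(fit)
  }, numeric(1))
  expect_true(all(s_vals > 0.05 & s_vals < 0.15))
})

test_that("contradictory duplicate pins are rejected, consistent ones merged", {
  expect_error(anchor_set(c(a = 0, a = 1), mode = "offset_multi"), "contradictory")
  an <- anchor_set(c(a = 1, a = 1, b = 2), mode = "offset_multi")
  expect_equal(length(an$values), 2L)
})
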