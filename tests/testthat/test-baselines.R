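test_that("degree ranking counts incident links once per PPI pair", {
  # star: centre C linked to 4 leaves
  net <- make_net(from = c("C", "L1", "C", "L2", "C", "L3", "C", "L4"),
                  to   = c("L1", "C", "L2", "C", "L3", "C", "L4", "C"),
                  capacity = 1, origin = "ppi")
  rk <- degree_rank(net, c("C", "L1", "L2"))
  expect_identical(rk$candidate[1], "C")
  expect_equal(rk$score[rk$candidate == "C"], 4)
  expect_equal(rk$score[rk$candidate == "L1"], 1)

  # worked-example fixture: G1 has 3 incident links, G5 has 1
  fx <- worked_example_fixture()
  rk2 <- degree_rank(fx$network, c("G1", "G5"))
  expect_equal(rk2$score[rk2$candidate == "G1"], 3)
  expect_equal(rk2$score[rk2$candidate == "G5"], 1)
  expect_lt(which(rk2$candidate == "G1"), which(rk2$candidate == "G5"))

  # permutation invariance and absent candidate
  rk3 <- degree_rank(fx$network, c("G5", "G1"))
  expect_identical(rk2, rk3)
  expect_equal(degree_rank(fx$network, "nope")$score, 0)
})

test_that("neighbourhood entropy is the Shannon entropy of neighbour degrees", {
  # one neighbour -> 0; m equal-degree neighbours -> log2(m)
  star <- make_net(from = c("C", "L1", "C", "L2", "C", "L3"),
                   to   = c("L1", "C", "L2", "C", "L3", "C"),
                   capacity = 1, origin = "ppi")
  rk <- entropy_rank(star, c("C", "L1"))
  expect_equal(rk$score[rk$candidate == "C"], log2(3))
  expect_equal(rk$score[rk$candidate == "L1"], 0)

  # random graph against direct summation
  set.seed(5)
  fi <- random_flow_instance(9, 24, seed = 55)
  net <- targetflow:::new_weighted_network(
    setdiff(fi$nodes, c("S", "T")),
    fi$arcs[fi$arcs$origin != "dummy", ])
  deg <- targetflow:::node_degrees(net)
  links <- targetflow:::network_links(net)
  rk2 <- entropy_rank(net, net$nodes)
  for (v in net$nodes) {
    nb <- unique(c(links$to[links$from == v], links$from[links$to == v]))
    expected <- if (!length(nb)) 0 else {
      p <- deg[nb] / sum(deg[nb])
      -sum(p * log2(p))
    }
    expect_equal(rk2$score[rk2$candidate == v], expected, tolerance = 1e-12)
  }
})

test_that("weighted betweenness matches exhaustive path enumeration", {
  # path graph A - B - C: B is the only interior node
  pth <- make_net(from = c("A", "B", "B", "C"),
                  to   = c("B", "A", "C", "B"),
                  capacity = 1, origin = "ppi")
  rk <- betweenness_rank(pth, c("A", "B", "C"))
  expect_identical(rk$candidate[1], "B")
  expect_gt(rk$score[1], 0)
  expect_equal(rk$score[2:3], c(0, 0))

  # complete graph with equal weights: nobody lies between anyone
  nodes <- c("X", "Y", "Z")
  cmb <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  cmb <- cmb[cmb$from != cmb$to, ]
  cpl <- make_net(cmb$from, cmb$to, capacity = 1, origin = "ppi")
  expect_true(all(betweenness_rank(cpl, nodes)$score == 0))

  # small weighted graph vs brute-force enumeration oracle
  set.seed(8)
  net <- make_net(from = c("A", "A", "B", "C", "D", "B"),
                  to   = c("B", "C", "C", "D", "A", "D"),
                  capacity = c(2, 0.5, 1, 1.5, 0.7, 0.3))
  rk2 <- betweenness_rank(net, net$nodes)
  oracle <- brute_betweenness(net)
  for (v in net$nodes)
    expect_equal(rk2$score[rk2$candidate == v], oracle[[v]],
                 tolerance = 1e-9)
})

test_that("closeness uses reachable-only normalized distances", {
  # directed path centre reaches both sides faster than the endpoint
  pth <- make_net(from = c("A", "B", "B", "C"),
                  to   = c("B", "A", "C", "B"),
                  capacity = 1, origin = "ppi")
  rk <- closeness_rank(pth, c("A", "B"))
  expect_identical(rk$candidate[1], "B")

  # two disconnected cliques: closeness computed within the component
  net2 <- make_net(from = c("A", "B", "C", "D"),
                   to   = c("B", "A", "D", "C"),
                   capacity = 1, origin = "ppi")
  rk2 <- closeness_rank(net2, c("A", "C"))
  expect_equal(rk2$score, c(1, 1))  # one neighbour at distance 1 each

  # small weighted graph against a direct distance-matrix computation
  net3 <- make_net(from = c("A", "A", "B", "C"),
                   to   = c("B", "C", "C", "D"),
                   capacity = c(2, 0.5, 1, 4))
  rk3 <- closeness_rank(net3, net3$nodes)
  d <- igraph::distances(targetflow:::as_igraph_dist(net3), mode = "out")
  for (v in net3$nodes) {
    dv <- d[v, is.finite(d[v, ]) & d[v, ] > 0]
    expected <- if (!length(dv)) 0 else length(dv) / sum(dv)
    expect_equal(rk3$score[rk3$candidate == v], expected, tolerance = 1e-12)
  }

  expect_equal(closeness_rank(net3, "isolated")$score, 0)
})

test_that("random walk with restart matches the two-state closed form", {
  # candidate -> disease single arc; disease node dangles back
  net <- make_net("C", "D", capacity = 1)
  alpha <- 0.3
  rk <- rwr_rank(net, "C", "D", alpha = alpha)
  p_c <- alpha / (1 - (1 - alpha)^2)
  p_d <- (1 - alpha) * p_c
  expect_equal(rk$score, p_d, tolerance = 1e-8)

  # restart mass keeps at least alpha on the candidate itself
  rk2 <- rwr_rank(net, "C", "C", alpha = alpha)
  expect_gte(rk2$score + 1e-12, alpha)

  # stationary vector sums to 1: scoring over all nodes gives total 1
  fi <- random_flow_instance(7, 18, seed = 66)
  net3 <- targetflow:::new_weighted_network(
    setdiff(fi$nodes, c("S", "T")),
    fi$arcs[fi$arcs$origin != "dummy", ])
  rk3 <- rwr_rank(net3, net3$nodes[1], net3$nodes, alpha = 0.3)
  expect_equal(rk3$score, 1, tolerance = 1e-8)
  expect_error(rwr_rank(net, "C", "D", alpha = 1.2), "alpha")
})

test_that("t-test ranking orders candidates by absolute statistic", {
  m <- rbind(flat = rep(1, 6),
             up = c(4, 5, 6, 0, 1, 2),
             down = c(-9, -8, -9, 3, 4, 3))
  colnames(m) <- paste0("s", 1:6)
  em <- expression_matrix(
    m, setNames(rep(c("cancer", "normal"), each = 3), colnames(m)))
  rk <- ttest_rank(em, rownames(m))
  expect_identical(rk$candidate[3], "flat")   # identical groups rank last
  stats <- vapply(rownames(m), function(g) abs(ttest_statistic(em, g)),
                  numeric(1))
  expect_identical(rk$candidate, names(sort(stats, decreasing = TRUE)))
  expect_identical(rk, ttest_rank(em, rev(rownames(m))))
})

test_that("interpolated precision-recall reproduces hand-computed mAP", {
  # all truths first -> mAP 1
  expect_equal(precision_recall(c("a", "b", "c", "d"),
                                c("a", "b"))$map_score, 1)
  # (T, F, T, F): levels 0.5 and 1.0 with interpolated precisions 1, 2/3
  pr <- precision_recall(c("t1", "f1", "t2", "f2"), c("t1", "t2"))
  expect_equal(pr$pr_points$precision, c(1, 2 / 3))
  expect_equal(pr$map_score, 5 / 6)
  # single truth at the bottom of n candidates -> mAP 1/n
  expect_equal(precision_recall(letters[1:10], "j")$map_score, 1 / 10)
  expect_error(precision_recall(letters[1:3], character(0)), "empty truth")
  expect_error(precision_recall(letters[1:3], "z"), "outside")
})

test_that("random rankings have mAP near the truth fraction", {
  set.seed(99)
  n <- 100; truths <- letters_ids <- sprintf("c%03d", 1:n)
  truth <- sample(letters_ids, 10)
  maps <- replicate(60, precision_recall(sample(letters_ids), truth)$map_score)
  # interpolation biases AP upward of the raw truth fraction, but a random
  # ranking stays well below any informative one
  expect_gt(mean(maps), 10 / n / 2)
  expect_lt(mean(maps), 3 * 10 / n)
  expect_lt(sd(maps), 0.1)
})

test_that("top-k windows report counts and average positions", {
  ranking <- sprintf("r%02d", 1:100)
  truth <- c("r01", "r04", "r40")
  tk <- topk_average_position(ranking, truth, fractions = c(0.1, 0.5))
  expect_equal(tk$found, c(2, 3))
  expect_equal(tk$avg_position, c(2.5, 15))
  # no truths inside the window -> count 0, AP undefined
  tk0 <- topk_average_position(ranking, "r99", fractions = 0.05)
  expect_identical(tk0$found, 0L)
  expect_true(is.na(tk0$avg_position))
  # nested windows never lose truths
  tk3 <- topk_average_position(ranking, truth)
  expect_true(all(diff(tk3$found) >= 0))
  expect_error(topk_average_position(ranking, truth, fractions = 0), "\\(0, 1\\]")
})

test_that("direction randomization halves PPI arcs deterministically", {
  fx <- worked_example_fixture()
  expect_identical(randomize_directions(fx$network, 1), fx$network) # no PPIs

  net <- make_net(from = c("A", "B", "B", "C", "X"),
                  to   = c("B", "A", "C", "B", "Y"),
                  capacity = c(2, 2, 3, 3, 1),
                  origin = c("ppi", "ppi", "ppi", "ppi", "regulatory"))
  out <- randomize_directions(net, 42)
  expect_identical(randomize_directions(net, 42), out)     # same seed
  expect_identical(sum(out$arcs$origin == "ppi"), 2L)      # m pairs -> m arcs
  expect_identical(nrow(out$arcs), 3L)
  expect_setequal(out$arcs$capacity[out$arcs$origin == "ppi"], c(2, 3))
  reg <- out$arcs[out$arcs$origin == "regulatory", ]
  expect_identical(reg$from, "X")                          # untouched
})

test_that("log trend fit recovers exact and noisy coefficients", {
  x <- 1:40
  fit <- log_trend_fit(x, -2 * log(x) + 5)
  expect_equal(unname(fit), c(-2, 5), tolerance = 1e-9)

  # noisy synthetic points against the normal-equation oracle
  set.seed(13)
  y <- -2.9 * log(x) + 15 + rnorm(40, 0, 0.3)
  fit2 <- log_trend_fit(x, y)
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit2), c(beta[2], beta[1]), tolerance = 1e-9)

  # constant values: slope 0, intercept the mean
  fit3 <- log_trend_fit(1:10, rep(7, 10))
  expect_equal(unname(fit3), c(0, 7), tolerance = 1e-9)
  expect_error(log_trend_fit(1, 1), "2 points")
  expect_error(log_trend_fit(c(0, 1), c(1, 2)), ">= 1")
})
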