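test_that("sweep on a vertex-transitive graph gives equal losses everywhere", {
  k4 <- matrix(1, 4, 4) - diag(4)
  sw <- single_node_sweep(k4)
  expect_equal(length(unique(round(sw$loss, 12))), 1)
  expect_equal(sw$normalized_loss, rep(0, 4))  # max == min -> all 0
  expect_equal(attr(sw, "spread"), 0)
})

test_that("sweep summary statistics are consistent with the per-node records", {
  set.seed(12)
  a <- random_adjacency(15, 0.3)
  sw <- single_node_sweep(a)
  expect_equal(attr(sw, "mean_loss"), mean(sw$loss), tolerance = 1e-15)
  expect_equal(attr(sw, "max_loss"), max(sw$loss))
  expect_equal(attr(sw, "spread"), max(sw$loss) - min(sw$loss))
  expect_equal(attr(sw, "baseline"), global_efficiency(a), tolerance = 1e-15)
  # mean lesioned efficiency recoverable from losses and baseline
  expect_equal(attr(sw, "mean_lesioned_efficiency"),
               mean((1 - sw$loss) * attr(sw, "baseline")), tolerance = 1e-12)
  expect_equal(sw$normalized_loss,
               (sw$loss - min(sw$loss)) / (max(sw$loss) - min(sw$loss)))
  expect_error(single_node_sweep(matrix(0, 5, 5)), "undefined")
})

test_that("the planted hub attains the maximum sweep loss", {
  hits <- vapply(1:40, function(s) {
    ph <- simulate_planted_hub(50, 0.05, 30, seed = s)
    sw <- single_node_sweep(ph$adjacency)
    which.max(sw$loss) == ph$hub
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("lesion-population counts match exact combinatorics", {
  c1 <- count_lesion_networks(90, 1)
  expect_equal(c1$cumulative, 90)
  expect_equal(c1$single_term, 90)
  c2 <- count_lesion_networks(90, 2)
  expect_equal(c2$single_term, 4005)      # C(90,2)
  expect_equal(c2$cumulative, 4095)       # C(90,1) + C(90,2)
  # cumulative over all k is 2^n - 1
  for (n in c(5, 10, 16)) {
    expect_equal(count_lesion_networks(n, n)$cumulative, 2^n - 1)
  }
  # agreement with base::choose while values are exactly representable
  for (n in c(12, 25, 40)) for (k in c(1, 3, n %/% 2)) {
    expect_equal(count_lesion_networks(n, k)$single_term, choose(n, k))
  }
  expect_error(count_lesion_networks(10, 0), "1..n")
  expect_error(count_lesion_networks(10, 11), "1..n")
})

test_that("counts stay exact far beyond double precision (n = 200)", {
  c200 <- count_lesion_networks(200, 100)
  # frozen independent values (exact integer arithmetic oracle)
  expect_identical(
    c200$single_term_exact,
    "90548514656103281165404177077484163874504589675413336841320")
  expect_identical(
    c200$cumulative_exact,
    "848743279457546778353683134709323383198353791729103086071347")
  expect_true(is.na(c200$single_term))  # > 2^53: no exact double exists
  expect_identical(count_lesion_networks(200, 200)$cumulative_exact,
                   "1606938044258990275541962092341162602522202993782792835301375")
})

test_that("target-network lesion table mirrors set centrality", {
  star5 <- matrix(0, 5, 5)
  star5[1, 2:5] <- star5[2:5, 1] <- 1
  toy <- as_region_table(data.frame(
    index = 1:5, name = paste0("r", 1:5),
    hemisphere = c("left", "right", "left", "right", "left")))
  tab <- lesion_target_networks(
    star5, list(node_set("centre", 1, toy), node_set("leaves", c(2, 3), toy)))
  expect_equal(tab$loss[tab$structure == "centre"], 1)
  expect_equal(tab$loss_pct[tab$structure == "centre"], 100)
  expect_equal(tab$loss[tab$structure == "leaves"],
               set_centrality(star5, c(2, 3))$loss)
  expect_equal(nrow(lesion_target_networks(star5, list())), 0)
})

test_that("disjoint-component targets lose exactly their efficiency share", {
  a <- two_cliques()
  tab <- lesion_target_networks(a, list(
    list(name = "c1", indices = 1:4), list(name = "c2", indices = 5:8)))
  expect_equal(tab$loss, c(0.5, 0.5), tolerance = 1e-12)
  expect_lte(sum(tab$loss), 1 + 1e-12)
})

test_that("edge lesioning between sets matches direct edge accounting", {
  # unconnected sets: removing nothing costs nothing
  a <- two_cliques(bridge = FALSE)
  r0 <- lesion_edges_between(a, 1:4, 5:8)
  expect_equal(r0$loss, 0)
  expect_equal(r0$n_removed, 0)
  # complete K4, a = b = everything: removes every edge, loss 1
  k4 <- matrix(1, 4, 4) - diag(4)
  rall <- lesion_edges_between(k4, 1:4, 1:4)
  expect_equal(rall$loss, 1)
  expect_equal(rall$n_removed, 6)
  # two cliques joined by a single bridge: severing it disconnects them
  ab <- two_cliques(bridge = TRUE)
  base <- oracle_efficiency(ab)
  rb <- lesion_edges_between(ab, 1:4, 5:8)
  expect_equal(rb$n_removed, 1)
  expect_equal(rb$loss, (base - 24 / 56) / base, tolerance = 1e-12)
})

test_that("within-set edge lesion differs from isolation only by external edges", {
  set.seed(14)
  for (rep in 1:20) {
    a <- random_adjacency(14, 0.35)
    if (global_efficiency(a) == 0) next
    s <- sample(14, 5)
    internal <- lesion_edges_between(a, s, s)
    expect_equal(internal$n_removed, sum(a[s, s]) / 2)
    iso <- set_centrality(a, s, mode = "isolate")
    external <- sum(a[s, -s])
    if (external == 0) {
      expect_equal(internal$loss, iso$loss, tolerance = 1e-12)
    } else {
      expect_lte(internal$loss, iso$loss + 1e-12)
    }
  }
})

test_that("hemispheric lesioning is symmetric for exchangeable fixtures", {
  toy16 <- as_region_table(data.frame(
    index = 1:16, name = paste0("r", 1:16),
    hemisphere = rep(c("left", "right"), 8)))
  diff_sym <- vapply(1:30, function(s) {
    g <- simulate_bihemispheric(8, 0.4, 0.2, seed = s)
    h <- lesion_hemisphere(g, toy16)
    h$left$loss - h$right$loss
  }, numeric(1))
  # exchangeable sides: mean difference ~ 0
  expect_lt(abs(mean(diff_sym)), 3 * stats::sd(diff_sym) / sqrt(30))
  # planted asymmetry: denser right side costs more to lesion
  denser_right <- vapply(1:30, function(s) {
    g <- simulate_bihemispheric(8, c(0.15, 0.8), 0.2, seed = s + 500)
    h <- lesion_hemisphere(g, toy16)
    h$right$loss > h$left$loss
  }, logical(1))
  expect_gte(mean(denser_right), 0.9)
})

test_that("with no interhemispheric edges each side's loss is its efficiency share", {
  toy8 <- as_region_table(data.frame(
    index = 1:8, name = paste0("r", 1:8),
    hemisphere = rep(c("left", "right"), 4)))
  g <- simulate_bihemispheric(4, 1, 0, seed = 1)  # two disjoint K4s
  h <- lesion_hemisphere(g, toy8)
  expect_equal(h$left$loss, 0.5, tolerance = 1e-12)
  expect_equal(h$right$loss, 0.5, tolerance = 1e-12)
  expect_equal(h$asymmetry, 0, tolerance = 1e-12)
  # cross-hemisphere efficiency terms are all zero
  d <- shortest_paths(g)
  left <- seq(1, 7, 2)
  expect_true(all(is.infinite(d[left, -left])))
  # edges method: cutting interhemispheric edges of a disconnected pair
  # is a no-op
  he <- lesion_hemisphere(g, toy8, method = "edges")
  expect_equal(he$left$loss, 0)
})

test_that("degree-loss regression matches the normal-equations closed form", {
  x <- c(2, 5, 7, 9, 12)
  y <- c(0.1, 0.25, 0.4, 0.42, 0.9)
  sw <- data.frame(index = 1:5, name = letters[1:5], degree = x,
                   loss = y, normalized_loss = y)
  fit <- degree_loss_regression(sw)
  ref <- oracle_ols(x, y)
  expect_equal(fit$slope, ref$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, ref$r_squared, tolerance = 1e-12)
  # perfectly proportional loss -> R^2 = 1
  sw2 <- sw
  sw2$normalized_loss <- 0.05 * x
  # lm warns about the numerically perfect fit; the property is R^2 = 1
  expect_equal(suppressWarnings(degree_loss_regression(sw2)$r_squared), 1,
               tolerance = 1e-12)
  # constant degree -> undefined slope
  sw3 <- sw
  sw3$degree <- 4
  expect_error(degree_loss_regression(sw3), "constant")
})

test_that("loss permuted against degree gives near-zero R^2 in expectation", {
  set.seed(15)
  r2 <- vapply(1:50, function(i) {
    x <- sample(1:30, 20, replace = TRUE)
    y <- runif(20)
    sw <- data.frame(index = 1:20, name = as.character(1:20), degree = x,
                     loss = y, normalized_loss = y)
    degree_loss_regression(sw)$r_squared
  }, numeric(1))
  expect_lt(mean(r2), 0.15)  # E[R^2] = 1/(n-2) under independence
})
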