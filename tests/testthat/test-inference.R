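# Baseline bootstrap null, empirical p-values, FDR, network inference.

test_that("the bootstrap null of the pooled correlation matches the folded-normal mean on i.i.d. noise", {
  L <- 50; Tn <- 50
  base <- make_iid_baseline(Tn = Tn, N = 4, K = 150, seed = 20)
  null <- bootstrap_null(base, L = L, B_null = 400, mode = "sensor", seed = 21)
  expect_equal(dim(null$samples), c(6, 400))
  expect_true(all(null$samples >= 0 & null$samples <= 1))
  # |corr| of L*T pooled i.i.d. points ~ |N(0, 1/(L*T))|, mean sqrt(2/(pi*L*T))
  expect_equal(mean(null$samples), sqrt(2 / (pi * L * Tn)), tolerance = 0.1)
})

test_that("the bootstrap null is reproducible and flags a degenerate baseline", {
  base <- make_iid_baseline(Tn = 30, N = 3, K = 20, seed = 22)
  a <- bootstrap_null(base, L = 10, B_null = 50, seed = 7)
  b <- bootstrap_null(base, L = 10, B_null = 50, seed = 7)
  expect_identical(a$samples, b$samples)

  base1 <- make_iid_baseline(Tn = 30, N = 3, K = 1, seed = 23)
  expect_warning(n1 <- bootstrap_null(base1, L = 5, B_null = 20, seed = 1),
                 "degenerate")
  expect_true(n1$degenerate)
  expect_equal(apply(n1$samples, 1, sd), rep(0, 3))  # every draw identical
})

test_that("empirical p-values count strictly-above null samples with a 1/B floor", {
  nodes <- c("s1", "s2")
  pairs <- fcnet:::pair_index(2)
  mknull <- function(samples) {
    structure(list(samples = matrix(samples, nrow = 1), nodes = nodes,
                   pairs = pairs, L = 10L, B_null = length(samples),
                   K = 50L, measure = "correlation", mode = "sensor",
                   region_of = NULL, seed = NULL, degenerate = FALSE),
              class = "fc_null")
  }
  mkobs <- function(value) {
    st <- array(NA_real_, dim = c(1, 2, 2))
    st[1, 1, 2] <- st[1, 2, 1] <- value
    structure(list(stat = st, nodes = nodes, pairs = pairs, groups = NULL,
                   measure = "correlation", mode = "sensor",
                   epoch_labels = "e1", n_trials = 10L),
              class = "fc_stats")
  }
  null <- mknull((1:1000) / 1000)
  # observed above all 1000 null samples -> the floor 1/1000
  expect_equal(unname(edge_p_values(mkobs(1.0), null)[1, 1]), 1 / 1000)
  # observed at the empirical median -> 0.5
  expect_equal(unname(edge_p_values(mkobs(0.5), null)[1, 1]), 0.5)
  # observed equal to the null minimum: ties are not "above" (strict >)
  expect_equal(unname(edge_p_values(mkobs(1 / 1000), null)[1, 1]), 999 / 1000)
  # mismatched measures refuse to combine
  bad <- mknull((1:10) / 10); bad$measure <- "canonical"
  expect_error(edge_p_values(mkobs(0.5), bad), "disagree")
})

test_that("FDR selection reproduces the step-up rule", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.300)
  expect_identical(fdr_select(p, 0.05),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(fdr_select(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(fdr_select(0.04, 0.05), TRUE)
  expect_identical(fdr_select(numeric(0)), logical(0))
  expect_error(fdr_select(0.5, q = 1.2), "in \\(0, 1\\)")
})

test_that("FDR selection matches a brute-force scan on random p-value sets", {
  withr::with_seed(30, {
    for (rep in 1:50) {
      n <- sample(1:40, 1)
      p <- round(runif(n)^sample(1:3, 1), 3)
      q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
      expect_identical(fdr_select(p, q), oracle_bh(p, q))
    }
  })
})

test_that("false discovery proportion stays controlled on null-only data", {
  # no coupling anywhere: any detected edge is false
  fdp <- withr::with_seed(31, {
    vapply(1:30, function(r) {
      ep <- make_iid_epochs(E = 1, Tn = 40, N = 6, L = 30, seed = 100 + r)
      base <- make_iid_baseline(Tn = 40, N = 6, K = 80, seed = 200 + r)
      null <- bootstrap_null(base, L = 30, B_null = 500, seed = 300 + r)
      net <- infer_networks(ep, null, q = 0.05)[[1]]
      as.numeric(nrow(net$edges) > 0)  # FDP is 1 when anything is rejected

    }, numeric(1))
  })
  # E[FDP] <= q up to Monte-Carlo error (binomial se ~ 0.04 over 30 runs)
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(length(fdp)) + 0.02)
})

test_that("network inference recovers an injected coupling and reports p-values", {
  # plant one strongly coupled pair in otherwise independent data
  ep <- make_iid_epochs(E = 2, Tn = 40, N = 5, L = 30, seed = 33)
  shared <- withr::with_seed(34, array(rnorm(40 * 30), dim = c(40, 30)))
  for (l in 1:30) {
    ep$data[2, , 1, l] <- zsc(ep$data[2, , 1, l] + 1.5 * shared[, l])
    ep$data[2, , 4, l] <- zsc(ep$data[2, , 4, l] + 1.5 * shared[, l])
  }
  base <- make_iid_baseline(Tn = 40, N = 5, K = 100, seed = 35)
  null <- bootstrap_null(base, L = 30, B_null = 800, seed = 36)
  nets <- infer_networks(ep, null, q = 0.05)
  expect_named(nets, c("before", "after"))
  expect_identical(nets$after$edges, fcnet:::edge_matrix(rbind(c(1L, 4L))))
  expect_equal(nrow(nets$before$edges), 0)
  pos <- fcnet:::pair_position(rbind(c(1L, 4L)), 5)
  expect_equal(nets$after$p[pos], 1 / 800)  # above every null sample
  expect_equal(network_density(nets$after), 1 / 10)
})

test_that("inference warns when the null resolution cannot support the FDR floor", {
  ep <- make_iid_epochs(E = 1, Tn = 30, N = 6, L = 10, seed = 37)
  base <- make_iid_baseline(Tn = 30, N = 6, K = 30, seed = 38)
  null <- bootstrap_null(base, L = 10, B_null = 100, seed = 39)
  # 15 pairs at q = 0.05 need B_null >= 300
  expect_warning(infer_networks(ep, null), "B_null >= 300")
})

test_that("more trials never hurt detection of a true edge, on average", {
  rate <- function(n_trials, seeds) {
    mean(vapply(seeds, function(s) {
      sess <- simulate_session(sim_config(n_trials = n_trials, snr = 0.1,
                                          baseline_duration = 60, seed = s))
      rec <- downsample(bandpass_filter(sess$recording))
      ep <- extract_epochs(rec)
      base <- extract_baseline_intervals(rec, guard = 0.25)
      null <- bootstrap_null(base, L = n_trials, B_null = 500, seed = s)
      nets <- suppressWarnings(infer_networks(ep, null))  # small B_null is fine here
      te <- sess$truth$after_edges
      pos <- fcnet:::pair_position(te, 9)
      est <- fcnet:::pair_position(nets$after$edges, 9)
      mean(pos %in% est)   # true-edge detection rate
    }, numeric(1)))
  }
  seeds <- 401:405
  expect_gte(rate(100, seeds), rate(25, seeds))
})
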