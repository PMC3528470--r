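# Node models, edge scoring and stability selection.

test_that("the top-q cut-off follows the stability-selection bound formula", {
  # independent re-derivation of q(V) = floor(sqrt(V (2 pi - 1) E_total))
  for (p in c(3, 10, 20)) for (V in 1:5) for (pi_thr in c(0.6, 0.75, 0.9)) {
    e_tot <- p * (p - 1) / 2
    expect_identical(stability_q(V, p, pi_thr),
                     as.integer(floor(sqrt(V * (2 * pi_thr - 1) * e_tot))))
  }
  expect_identical(stability_q(5, 20, 0.75), 21L)
})

test_that("symmetrized scores equal the pairwise means of normalized importances", {
  # hand-computed three-node case (weights default to one without skill)
  res <- list(
    structure(list(target = "a",
                   importance = c(b = 0.7, c = 0.3)), class = "node_model_result"),
    structure(list(target = "b",
                   importance = c(a = 0.4, c = 0.6)), class = "node_model_result"),
    structure(list(target = "c",
                   importance = c(a = 0, b = 0)), class = "node_model_result"))
  S <- symmetrize_edge_scores(res)
  expect_equal(S["a", "b"], (0.7 + 0.4) / 2)
  expect_equal(S["a", "c"], (0.3 + 0) / 2)
  expect_equal(S["b", "c"], (0.6 + 0) / 2)
  expect_identical(S, t(S))
  expect_identical(unname(diag(S)), c(0, 0, 0))
  # normalization: un-normalized inputs give the same scores
  res2 <- res
  res2[[1]]$importance <- c(b = 7, c = 3)
  expect_equal(symmetrize_edge_scores(res2), S)
  # skill scales a node's contributions
  res3 <- res
  res3[[1]]$skill <- 0.5
  expect_equal(symmetrize_edge_scores(res3)["a", "b"], (0.5 * 0.7 + 0.4) / 2)
  expect_error(symmetrize_edge_scores(res[c(1, 1)]), "duplicate")
})

test_that("top-q selection matches a brute-force sort with lexicographic ties", {
  set.seed(31)
  for (rep in 1:10) {
    p <- 7
    vars <- paste0("v", sample(10, p))
    S <- matrix(0, p, p, dimnames = list(vars, vars))
    vals <- sample(c(0, 0.1, 0.2, 0.5, 0.9), p * (p - 1) / 2, replace = TRUE)
    S[upper.tri(S)] <- vals
    S <- S + t(S)
    q <- sample(0:15, 1)
    sel <- select_top_q_edges(S, q)
    # oracle: full enumeration and ordering
    ij <- which(upper.tri(S), arr.ind = TRUE)
    df <- data.frame(a = pmin(vars[ij[, 1]], vars[ij[, 2]]),
                     b = pmax(vars[ij[, 1]], vars[ij[, 2]]),
                     s = S[upper.tri(S)])
    df <- df[order(-df$s, df$a, df$b), ]
    df <- df[seq_len(min(q, nrow(df))), , drop = FALSE]
    df <- df[df$s > 0, , drop = FALSE]
    oracle <- as.matrix(df[order(df$a, df$b), c("a", "b")])
    dimnames(oracle) <- list(NULL, c("a", "b"))
    expect_identical(sel, oracle)
  }
  S0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_identical(nrow(select_top_q_edges(S0, 5)), 0L)
})

test_that("node models dispatch on scale and find a planted predictor", {
  tab <- small_table()
  cls <- fit_node_model(tab, "male", seed = 1)
  expect_identical(cls$type, "classification")
  reg <- fit_node_model(tab, "impairment", seed = 1)
  expect_identical(reg$type, "regression")
  expect_length(reg$importance, 19L)
  expect_true(all(reg$importance >= 0))
  expect_true(all(is.finite(reg$importance)))
  expect_error(fit_node_model(tab, "not_a_var"), "unknown target")
  tab2 <- as.data.frame(small_table())
  tab2$age <- 1
  expect_error(fit_node_model(structure(tab2, scales = attr(small_table(), "scales"),
                                        class = class(small_table())),
                              "age"), "degenerate")

  # planted signal: y is a noisy copy of one predictor
  set.seed(11)
  n <- 1500
  d <- as.data.frame(matrix(stats::rnorm(n * 6), n,
                            dimnames = list(NULL, paste0("x", 1:6))))
  d$y <- d$x1 + stats::rnorm(n, sd = 0.5)
  for (s in 1:3) {
    r <- fit_node_model(d, "y", seed = s)
    expect_identical(names(which.max(r$importance)), "x1")
    expect_gt(r$skill, 0.5)
  }
  # null target: no skill, no systematically dominant predictor
  d$z <- stats::rnorm(n)
  r0 <- fit_node_model(d, "z", seed = 4)
  expect_lt(r0$skill, 0.1)
})

test_that("stability selection is deterministic, nested and matches a from-scratch oracle", {
  tab <- small_table()
  vars6 <- c("impairment", "pain", "social_support", "male", "age",
             "perceived_health")
  sub <- structure(as.data.frame(tab)[, vars6],
                   scales = attr(tab, "scales")[vars6],
                   class = c("modeling_table", "data.frame"))
  ctl <- forest_control(num_trees = 50)
  st <- stability_select(sub, scheme = subsample_scheme(8, seed = 5),
                         control = ctl, seed = 5)
  st2 <- stability_select(sub, scheme = subsample_scheme(8, seed = 5),
                          control = ctl, seed = 5)
  expect_identical(st$frequency, st2$frequency)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))

  # nestedness of the selected edge sets across bounds
  keys <- lapply(st$selected, function(e)
    if (nrow(e)) paste(e[, 1], e[, 2], sep = "|") else character(0))
  for (k in seq_len(length(keys) - 1))
    expect_true(all(keys[[k]] %in% keys[[k + 1]]))

  # minimal bound agrees with the first bound whose set contains the edge
  for (key in names(st$minimal_bound)) {
    first <- min(which(vapply(keys, function(x) key %in% x, TRUE)))
    expect_identical(unname(st$minimal_bound[key]), st$bounds[first])
  }

  # from-scratch oracle: re-derive every half-sample with the public
  # operations and the documented seed-splitting scheme, and re-tally
  n <- nrow(sub); h <- floor(n / 2); p <- length(vars6)
  qV <- pmin(as.integer(floor(sqrt(1:5 * 0.5 * p * (p - 1) / 2))),
             p * (p - 1) / 2)
  set.seed(5)
  perms <- lapply(1:8, function(i) sample.int(n))
  counts <- list()
  for (b in 1:8) for (half in 1:2) {
    idx <- if (half == 1) perms[[b]][1:h] else perms[[b]][(h + 1):(2 * h)]
    half_tab <- structure(as.data.frame(sub)[idx, ],
                          scales = attr(sub, "scales"),
                          class = c("modeling_table", "data.frame"))
    res <- lapply(seq_along(vars6), function(j)
      fit_node_model(half_tab, vars6[j], control = ctl,
                     seed = derive_seed_oracle(5, b * 1000 + half * 100 + j)))
    S <- symmetrize_edge_scores(res)
    for (v in 1:5) {
      sel <- select_top_q_edges(S, qV[v])
      if (nrow(sel)) {
        ks <- paste(sel[, 1], sel[, 2], sep = "|")
        for (kk in ks) {
          key <- paste0(v, ":", kk)
          counts[[key]] <- (counts[[key]] %||% 0) + 1
        }
      }
    }
  }
  oracle_sel <- lapply(1:5, function(v) {
    ks <- names(counts)[startsWith(names(counts), paste0(v, ":"))]
    hit <- ks[unlist(counts[ks]) / 16 >= 0.75]
    sort(sub("^[0-9]+:", "", hit))
  })
  for (v in 1:5) expect_identical(sort(keys[[v]]), oracle_sel[[v]])
})

test_that("the estimated graph carries bound labels and isolation flags", {
  runs <- acceptance_recovery_runs()
  g <- runs[[1]]$graph
  expect_s3_class(g, "cig")
  expect_identical(sort(igraph::V(g)$name), sort(variable_roster()$name))
  et <- edge_table(g)
  expect_true(all(et$min_bound %in% 1:5))
  expect_true(all(et$frequency >= 0.75 & et$frequency <= 1))
  expect_identical(igraph::V(g)$isolated, unname(igraph::degree(g) == 0))
})

test_that("stability selection refuses incomplete or tiny tables", {
  tab <- as.data.frame(small_table())
  tab$age[1] <- NA
  expect_error(stability_select(structure(tab, scales = attr(small_table(), "scales"),
                                          class = class(small_table()))),
               "missing values")
  expect_error(stability_select(small_table()[1:60, ]), "subsample too small")
})
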