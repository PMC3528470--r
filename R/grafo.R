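# Graphical random forests: per-node forests, symmetrized permutation
# importance, complementary-pairs stability selection with a bound on the
# expected number of falsely selected edges.

#' Forest settings for the node models
#'
#' Each of the `p` variables is regressed on the remaining `p - 1` with a
#' random forest: classification for binary targets, regression for ordinal,
#' count and continuous targets (treating 5-14-level ordinals as classes
#' would fragment them). Edge scores use permutation importance, which is
#' less biased than impurity importance across mixed predictor scales;
#' negative raw importances are truncated at zero. The forests act as
#' association screeners, not predictors, so they are deliberately shallow
#' with large leaves; both caps are configurable.
#'
#' @param num_trees Trees per node model; default 100.
#' @param mtry Predictors tried per split; default `ceiling(sqrt(p - 1))`.
#' @param max_depth Tree depth cap; default 6.
#' @param min_node_frac Minimum leaf size as a fraction of the fitting
#'   sample; default 0.05 (never below 5 observations).
#' @return An object of class `forest_control`.
#' @export
forest_control <- function(num_trees = 100, mtry = NULL, max_depth = 6,
                           min_node_frac = 0.05) {
  stopifnot(num_trees >= 1, max_depth >= 1,
            min_node_frac > 0, min_node_frac < 1)
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 max_depth = as.integer(max_depth),
                 min_node_frac = min_node_frac),
            class = "forest_control")
}

#' Fit one node model and return predictor importances
#'
#' @param tab A `modeling_table` (or data frame; see [variable_scales()]).
#' @param target Name of the outcome variable.
#' @param control A [forest_control()].
#' @param seed Integer seed for the forest.
#' @return An object of class `node_model_result`: list with `target`,
#'   `importance` (named non-negative vector over the other `p - 1`
#'   variables) and `type` (`"classification"` or `"regression"`).
#' @export
fit_node_model <- function(tab, target, control = forest_control(), seed = 1) {
  vars <- modeling_vars(tab)
  if (!target %in% vars) stop("unknown target variable: ", target, call. = FALSE)
  if (nrow(tab) < 50) stop("need at least 50 rows to fit a node model", call. = FALSE)
  scales <- variable_scales(tab)
  M <- as.matrix(as.data.frame(tab)[, vars])
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("modeling table contains missing values; apply casewise deletion first",
                     call. = FALSE)
  fit_node_model_matrix(M, target, scales, control, seed)
}

# matrix-level worker shared with stability_select (avoids per-call
# data.frame overhead in the subsample loop)
fit_node_model_matrix <- function(M, target, scales, control, seed) {
  y <- M[, target]
  if (length(unique(y)) < 2)
    stop("degenerate (constant) target column: ", target, call. = FALSE)
  x <- M[, colnames(M) != target, drop = FALSE]
  p1 <- ncol(x)
  mtry <- control$mtry %||% ceiling(sqrt(p1))
  min_node <- max(5L, ceiling(control$min_node_frac * nrow(x)))
  classify <- identical(unname(scales[target]), "binary")
  fit <- ranger::ranger(
    x = x, y = if (classify) factor(y) else y,
    num.trees = control$num_trees, mtry = mtry,
    importance = "permutation",
    max.depth = control$max_depth, min.node.size = min_node,
    num.threads = 1, seed = seed)
  imp <- pmax(fit$variable.importance, 0)
  skill <- if (classify) {
    base <- 1 - max(tabulate(factor(y)) / length(y))
    if (base > 0) 1 - fit$prediction.error / base else 0
  } else {
    1 - fit$prediction.error / stats::var(y)
  }
  structure(list(target = target, importance = imp,
                 skill = min(max(skill, 0), 1),
                 type = if (classify) "classification" else "regression"),
            class = "node_model_result")
}

#' Symmetrize directed node-model importances into edge scores
#'
#' Each node's importance vector is normalized to sum to one (so targets on
#' heterogeneous outcome scales contribute comparably) and scaled by the
#' model's out-of-bag skill (one minus the ratio of out-of-bag error to the
#' intercept-only error, clamped to `[0, 1]`); the score of edge
#' \eqn{\{a, b\}} is then the mean of the contribution of `b` for target `a`
#' and of `a` for target `b`. The skill factor extends the all-zero
#' contract — an importance vector that is all zero, or a model that
#' predicts no better than the marginal distribution of its target,
#' contributes (essentially) zero to all of its node's edges — and prevents
#' pure-noise node models, whose few positive importances would otherwise be
#' inflated by the normalization, from masking weak true edges.
#'
#' @param results List of [fit_node_model()] results, one per variable.
#'   Results without a `skill` element get weight one (plain
#'   normalized-mean symmetrization).
#' @return Symmetric `p x p` matrix with zero diagonal, of class
#'   `edge_score_matrix`.
#' @export
symmetrize_edge_scores <- function(results) {
  targets <- vapply(results, `[[`, "", "target")
  if (anyDuplicated(targets)) stop("duplicate node-model targets", call. = FALSE)
  p <- length(targets)
  D <- matrix(0, p, p, dimnames = list(targets, targets))
  for (r in results) {
    imp <- r$importance
    s <- sum(imp)
    w <- r$skill %||% 1
    if (s > 0 && w > 0) D[r$target, names(imp)] <- w * imp / s
  }
  S <- (D + t(D)) / 2
  diag(S) <- 0
  structure(S, class = c("edge_score_matrix", class(S)))
}

#' Select the q highest-scoring edges
#'
#' Zero-score edges are never selected; ties are broken by lexicographic
#' node-pair order so the selection is deterministic.
#'
#' @param scores Symmetric edge-score matrix.
#' @param q Number of edges to keep (`>= 0`).
#' @return Character matrix with columns `a`, `b` (endpoints in alphabetical
#'   order, rows sorted), at most `q` rows.
#' @export
select_top_q_edges <- function(scores, q) {
  stopifnot(q >= 0)
  vars <- rownames(scores)
  ut <- upper.tri(scores)
  ij <- which(ut, arr.ind = TRUE)
  sc <- scores[ut]
  a <- pmin(vars[ij[, 1]], vars[ij[, 2]])
  b <- pmax(vars[ij[, 1]], vars[ij[, 2]])
  ord <- order(-sc, a, b)
  keep <- ord[seq_len(min(q, length(ord)))]
  keep <- keep[sc[keep] > 0]
  out <- cbind(a = a[keep], b = b[keep])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Complementary-pairs subsampling scheme
#'
#' @param n_pairs Number of complementary pairs; default 50 (100
#'   half-samples). Each pair splits the rows into two disjoint halves of
#'   size `floor(n / 2)`.
#' @param seed Integer seed for drawing the pairs.
#' @return Object of class `subsample_scheme`.
#' @export
subsample_scheme <- function(n_pairs = 50, seed = 1) {
  stopifnot(n_pairs >= 1)
  structure(list(n_pairs = as.integer(n_pairs), seed = as.integer(seed)),
            class = "subsample_scheme")
}

#' Top-q cut-off for a bound on the expected number of false positives
#'
#' Under the complementary-pairs stability-selection bound
#' \eqn{E[FP] \le q^2 / ((2\pi_{thr} - 1) E_{total})}, the largest per-subsample
#' selection size honouring `E[FP] <= V` is
#' `q(V) = floor(sqrt(V * (2 * pi_thr - 1) * E_total))`.
#'
#' @param V Bound on the expected number of falsely selected edges.
#' @param p Number of variables (so `E_total = p * (p - 1) / 2`).
#' @param pi_thr Selection-frequency threshold; default 0.75.
#' @return Integer cut-off `q`.
#' @export
stability_q <- function(V, p, pi_thr = 0.75) {
  e_total <- p * (p - 1) / 2
  as.integer(floor(sqrt(V * (2 * pi_thr - 1) * e_total)))
}

#' Stability selection over complementary subsample pairs
#'
#' For each half-sample, fits all `p` node models, symmetrizes importances
#' into edge scores and records the top-`q(V)` edges for every bound `V`.
#' An edge is selected at bound `V` when its selection frequency across the
#' `2 * n_pairs` half-samples reaches `pi_thr`. Because `q(V)` is
#' non-decreasing in `V`, the selected edge sets are nested across bounds.
#'
#' @param tab Complete (post casewise deletion) `modeling_table` or data
#'   frame.
#' @param scheme A [subsample_scheme()]; its seed defaults to `seed`.
#' @param bounds Integer bounds `V`; default `1:5`.
#' @param control A [forest_control()].
#' @param pi_thr Selection-frequency threshold; default 0.75.
#' @param seed Master seed; subsample draws and per-forest seeds are derived
#'   from it.
#' @return Object of class `stability_result`: per-bound selection-frequency
#'   matrices, per-bound selected edge sets, per-edge minimal bound, the
#'   cut-offs `q(V)` and the scheme settings.
#' @export
stability_select <- function(tab, scheme = NULL, bounds = 1:5,
                             control = forest_control(), pi_thr = 0.75,
                             seed = 1) {
  if (is.null(scheme)) scheme <- subsample_scheme(seed = seed)
  stopifnot(inherits(scheme, "subsample_scheme"), all(bounds >= 1),
            pi_thr > 0.5, pi_thr <= 1)
  bounds <- sort(unique(as.integer(bounds)))
  vars <- modeling_vars(tab)
  scales <- variable_scales(tab)
  M <- as.matrix(as.data.frame(tab)[, vars])
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("modeling table contains missing values; apply casewise deletion first",
                     call. = FALSE)
  n <- nrow(M)
  h <- floor(n / 2)
  if (h < 50) stop("subsample too small for forest fitting (need n >= 100)",
                   call. = FALSE)
  p <- length(vars)
  qV <- stats::setNames(pmin(stability_q(bounds, p, pi_thr), p * (p - 1) / 2),
                        paste0("V", bounds))

  set.seed(scheme$seed)
  perms <- lapply(seq_len(scheme$n_pairs), function(i) sample.int(n))

  counts <- array(0L, dim = c(p, p, length(bounds)),
                  dimnames = list(vars, vars, names(qV)))
  for (b in seq_len(scheme$n_pairs)) {
    for (half in 1:2) {
      idx <- if (half == 1) perms[[b]][seq_len(h)] else perms[[b]][(h + 1):(2 * h)]
      Mh <- M[idx, , drop = FALSE]
      results <- lapply(seq_len(p), function(j)
        fit_node_model_matrix(Mh, vars[j], scales, control,
                              seed = derive_seed(seed, b * 1000L + half * 100L + j)))
      S <- symmetrize_edge_scores(results)
      for (k in seq_along(bounds)) {
        sel <- select_top_q_edges(S, qV[k])
        if (nrow(sel))
          counts[, , k][cbind(sel[, 1], sel[, 2])] <-
            counts[, , k][cbind(sel[, 1], sel[, 2])] + 1L
      }
    }
  }
  n_half <- 2 * scheme$n_pairs
  freq <- counts / n_half
  for (k in seq_along(bounds)) {
    fk <- freq[, , k]
    freq[, , k] <- fk + t(fk)      # counts were stored on sorted (upper) pairs
  }
  selected <- lapply(seq_along(bounds), function(k) {
    fk <- freq[, , k]
    ut <- upper.tri(fk)
    ij <- which(fk >= pi_thr & ut, arr.ind = TRUE)
    if (!nrow(ij)) return(matrix(character(0), 0, 2, dimnames = list(NULL, c("a", "b"))))
    out <- cbind(a = pmin(vars[ij[, 1]], vars[ij[, 2]]),
                 b = pmax(vars[ij[, 1]], vars[ij[, 2]]))
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  })
  names(selected) <- names(qV)
  min_bound <- minimal_bounds(selected, bounds)
  structure(list(vars = vars, bounds = bounds, q = qV, pi_thr = pi_thr,
                 n_pairs = scheme$n_pairs, subsample_size = h,
                 frequency = freq, selected = selected,
                 minimal_bound = min_bound, seed = seed),
            class = "stability_result")
}

minimal_bounds <- function(selected, bounds) {
  seen <- character(0)
  out <- list()
  for (k in seq_along(bounds)) {
    keys <- if (nrow(selected[[k]])) paste(selected[[k]][, 1], selected[[k]][, 2], sep = "|")
            else character(0)
    new <- setdiff(keys, seen)
    for (key in new) out[[key]] <- bounds[k]
    seen <- union(seen, keys)
  }
  unlist(out)
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability selection:", length(x$vars), "variables,",
      x$n_pairs, "complementary pairs (half-sample size", x$subsample_size,
      "), pi_thr =", x$pi_thr, "\n")
  for (k in seq_along(x$bounds))
    cat(sprintf("  V=%d (q=%d): %d edges\n", x$bounds[k], x$q[k],
                nrow(x$selected[[k]])))
  invisible(x)
}

#' Estimate the conditional-independence graph
#'
#' End-to-end graphical-random-forest estimate: stability selection at the
#' given bounds, returning the undirected graph at the largest bound with
#' per-edge minimal-bound labels (the smallest `V` at which the edge enters;
#' smaller labels mean more stable edges) and selection frequencies.
#'
#' @inheritParams stability_select
#' @param keep_stability Attach the full `stability_result` as the graph
#'   attribute `stability` (default TRUE).
#' @return An igraph of class `c("cig", "igraph")` whose edges carry
#'   `min_bound` and `frequency` attributes and whose vertices carry an
#'   `isolated` flag.
#' @export
estimate_graph <- function(tab, scheme = NULL, bounds = 1:5,
                           control = forest_control(), pi_thr = 0.75,
                           seed = 1, keep_stability = TRUE) {
  st <- stability_select(tab, scheme = scheme, bounds = bounds,
                         control = control, pi_thr = pi_thr, seed = seed)
  cig_from_stability(st, keep_stability = keep_stability)
}

#' Build a labelled graph from a stability-selection result
#'
#' @param st A `stability_result`.
#' @param keep_stability Attach `st` as a graph attribute.
#' @return A `cig` graph; see [estimate_graph()].
#' @export
cig_from_stability <- function(st, keep_stability = TRUE) {
  kmax <- length(st$bounds)
  edges <- st$selected[[kmax]]
  df <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(df)) {
    keys <- paste(df$a, df$b, sep = "|")
    df$min_bound <- unname(st$minimal_bound[keys])
    df$frequency <- st$frequency[, , kmax][cbind(df$a, df$b)]
  } else {
    df$min_bound <- integer(0)
    df$frequency <- numeric(0)
  }
  g <- igraph::graph_from_data_frame(
    df, directed = FALSE,
    vertices = data.frame(name = st$vars, stringsAsFactors = FALSE))
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  if (keep_stability) g <- igraph::set_graph_attr(g, "stability", st)
  class(g) <- c("cig", class(g))
  g
}

#' @export
print.cig <- function(x, ...) {
  cat("Estimated conditional-independence graph:", igraph::vcount(x),
      "nodes,", igraph::ecount(x), "edges\n")
  iso <- igraph::V(x)$name[igraph::degree(x) == 0]
  if (length(iso)) cat("Isolated:", paste(iso, collapse = ", "), "\n")
  if (igraph::ecount(x)) {
    e <- edge_table(x)
    cat("Edges (min bound, selection frequency):\n")
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %s -- %s  (V>=%d, %.2f)\n", e$a[i], e$b[i],
                  e$min_bound[i], e$frequency[i]))
  }
  invisible(x)
}

#' Edge list of an estimated graph as a data frame
#'
#' @param g A `cig` graph.
#' @return Data frame with columns `a`, `b`, `min_bound`, `frequency`,
#'   sorted by node pair.
#' @export
edge_table <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el))
    return(data.frame(a = character(0), b = character(0),
                      min_bound = integer(0), frequency = numeric(0)))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  out <- data.frame(a = a, b = b,
                    min_bound = igraph::E(g)$min_bound,
                    frequency = igraph::E(g)$frequency)
  out <- out[order(out$a, out$b), ]
  rownames(out) <- NULL
  out
}
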