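# Synthetic-cohort generator: structural simulation along an immorality-free
# orientation of the ground truth, with marginals calibrated by simulation.

#' Default marginal calibration targets
#'
#' Published cohort-description values for the 2007 survey: prevalences for
#' the binary variables, the perceived-health category distribution (median
#' "good", 10%/90% quantiles 1 and 3), and for each count index its
#' prevalence of at least one problem (where published), mean and SD.
#' Continuous variables carry mean/SD and a distribution family (normal for
#' age and education; lognormal for income; zero-inflated lognormal for
#' alcohol, a quarter of respondents being non-drinkers).
#'
#' @return Nested list of targets; see [calibrate_marginals()].
#' @export
default_marginal_targets <- function() {
  list(
    binary = c(male = 0.449, married = 0.509, smoker = 0.272,
               low_physical_activity = 0.255, paid_employment = 0.613,
               migration_background = 0.287, work_restriction = 0.120),
    perceived_health = c(0.25, 0.55, 0.15, 0.04, 0.01),
    counts = list(
      impairment     = list(prevalence = 0.706, mean = 1.4, sd = 1.3, max = 9),
      pain           = list(prevalence = 0.758, mean = 1.6, sd = 1.4, max = 6),
      ap_limitation  = list(prevalence = 0.158, mean = 0.4, sd = 1.4, max = 13),
      social_support = list(prevalence = NA,    mean = 3.3, sd = 0.8, max = 4),
      social_network = list(prevalence = NA,    mean = 3.2, sd = 1.2, max = 5)),
    continuous = list(
      age               = list(dist = "normal", mean = 49.6, sd = 18.5),
      education_years   = list(dist = "normal", mean = 13.0, sd = 3.5),
      income            = list(dist = "lognormal", mean = 4154.1, sd = 3058.6),
      alcohol_g_per_day = list(dist = "zero_lognormal", p0 = 0.25,
                               mean = 9.2, sd = 15.4)),
    macro = list(
      canton_gdp   = list(dist = "lognormal_raw", meanlog = 11.1, sdlog = 0.35),
      canton_gini  = list(dist = "normal", mean = 0.375, sd = 0.05),
      canton_crime = list(dist = "normal", mean = 50, sd = 18)))
}

#' Generator configuration
#'
#' @param n Cohort size; default 18760, the published survey size.
#' @param seed Master seed; all generator randomness (canton sizes, macro
#'   draws, respondent noise, item back-fill, missingness) is derived from it.
#' @param edge_strength Structural coefficient on each standardized parent;
#'   default 0.8, placing standardized node-model signal in the strong
#'   0.5-1.0 band.
#' @param strength_multipliers Optional named numeric vector of per-edge
#'   multipliers keyed `"a|b"` with `a < b` alphabetically. When `NULL`,
#'   built-in multipliers compensate attenuation: edges incident to the rare
#'   A&P-limitation count get 10/7, canton-level macro edges 9/7.
#' @param marginal_targets See [default_marginal_targets()].
#' @param n_cantons Number of cantons; default 26.
#' @param missingness_rate Fraction of cells set missing completely at
#'   random; default 0.0075 (the survey reports under 0.85% missing replies).
#' @param calibration_n Simulation size used to locate the marginal
#'   intercepts; default 50000.
#' @param macro_clustered Keep the macro indicators constant within canton
#'   (default). Note that the shared canton partition links the three macro
#'   columns deterministically within any realized cohort even when the
#'   truth has no macro edges; for null simulations that require twenty
#'   *mutually independent* variables, set this to `FALSE` to draw the macro
#'   columns independently per respondent from their marginals.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 18760, seed = 1, edge_strength = 0.8,
                             strength_multipliers = NULL,
                             marginal_targets = default_marginal_targets(),
                             n_cantons = 26, missingness_rate = 0.0075,
                             calibration_n = 50000, macro_clustered = TRUE) {
  stopifnot(n > 0, n_cantons > 0, calibration_n >= 1000)
  if (missingness_rate < 0 || missingness_rate > 1)
    stop("missingness_rate must lie in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 edge_strength = edge_strength,
                 strength_multipliers = strength_multipliers,
                 marginal_targets = marginal_targets,
                 n_cantons = as.integer(n_cantons),
                 missingness_rate = missingness_rate,
                 calibration_n = as.integer(calibration_n),
                 macro_clustered = isTRUE(macro_clustered)),
            class = "generator_config")
}

# Deterministic seed splitting: one master seed, documented offsets per stage.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

resolve_strengths <- function(truth, config) {
  em <- edge_matrix(truth)
  if (!nrow(em)) return(stats::setNames(numeric(0), character(0)))
  keys <- edge_key(em[, 1], em[, 2])
  mult <- rep(1, nrow(em))
  if (is.null(config$strength_multipliers)) {
    ap <- em[, 1] == "ap_limitation" | em[, 2] == "ap_limitation"
    macro_nodes <- c("canton_gdp", "canton_gini", "canton_crime")
    mac <- em[, 1] %in% macro_nodes & em[, 2] %in% macro_nodes
    mult[ap] <- 10 / 7
    mult[mac] <- 9 / 7
  } else {
    hit <- match(keys, names(config$strength_multipliers))
    mult[!is.na(hit)] <- config$strength_multipliers[hit[!is.na(hit)]]
  }
  stats::setNames(config$edge_strength * mult, keys)
}

# Beta-binomial (or mixture with a point mass at zero) probability vector
# over 0..max, matched to prevalence (P(X >= 1)), mean and SD.
count_pmf <- function(prevalence, mean, sd, max) {
  stopifnot(max >= 1)
  bb <- function(n, a, b) {
    k <- 0:n
    p <- exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
    p / sum(p)
  }
  solve_bb <- function(n, m, v) {
    mu <- min(max(m / n, 1e-6), 1 - 1e-6)
    vb <- n * mu * (1 - mu)
    rho <- if (n > 1 && vb > 0) (v / vb - 1) / (n - 1) else 0
    rho <- min(max(rho, 1e-6), 0.98)
    k <- (1 - rho) / rho
    bb(n, mu * k, (1 - mu) * k)
  }
  if (is.na(prevalence)) return(solve_bb(max, mean, sd^2))
  if (prevalence <= 0 || prevalence > 1)
    stop("infeasible prevalence target: ", prevalence, call. = FALSE)
  if (mean < prevalence || mean > prevalence * max)
    stop("infeasible count target: mean ", mean,
         " incompatible with prevalence ", prevalence, call. = FALSE)
  m_cond <- mean / prevalence - 1               # conditional mean of X - 1
  ex2 <- sd^2 + mean^2
  v_cond <- ex2 / prevalence - (m_cond + 1)^2   # variance of X - 1 given X >= 1
  v_cond <- max(v_cond, 1e-6)
  cond <- solve_bb(max - 1, m_cond, v_cond)
  c(1 - prevalence, prevalence * cond)
}

quantile_grid_probs <- seq(0, 1, length.out = 4001)

# Transform latent scores to observed values using frozen intercepts.
apply_transform <- function(eta, tr) {
  switch(tr$type,
    threshold = as.numeric(eta > tr$cut),
    categories = tr$offset + findInterval(eta, tr$cuts),
    normal = tr$mean + tr$sd * (eta - tr$eta_mean) / tr$eta_sd,
    quantile_map = {
      u <- stats::approx(tr$grid, quantile_grid_probs, xout = eta,
                         rule = 2, ties = "ordered")$y
      u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
      qtarget(u, tr$target)
    },
    stop("unknown transform"))
}

qtarget <- function(u, target) {
  if (target$dist == "lognormal") {
    cv2 <- (target$sd / target$mean)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(target$mean) - sdlog^2 / 2
    stats::qlnorm(u, meanlog, sdlog)
  } else if (target$dist == "lognormal_raw") {
    stats::qlnorm(u, target$meanlog, target$sdlog)
  } else if (target$dist == "zero_lognormal") {
    p0 <- target$p0
    m <- target$mean / (1 - p0)
    ex2 <- (target$sd^2 + target$mean^2) / (1 - p0)
    v <- max(ex2 - m^2, 1e-9)
    sdlog <- sqrt(log1p(v / m^2))
    meanlog <- log(m) - sdlog^2 / 2
    out <- numeric(length(u))
    nz <- u > p0
    out[nz] <- stats::qlnorm((u[nz] - p0) / (1 - p0), meanlog, sdlog)
    out
  } else {
    stats::qnorm(u, target$mean, target$sd)
  }
}

target_transform <- function(var, eta, targets) {
  if (var %in% names(targets$binary)) {
    prev <- targets$binary[[var]]
    if (prev < 0 || prev > 1) stop("infeasible prevalence target for ", var, call. = FALSE)
    list(type = "threshold", cut = unname(stats::quantile(eta, 1 - prev)))
  } else if (var == "perceived_health") {
    p <- targets$perceived_health
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("perceived_health category probabilities must sum to 1", call. = FALSE)
    list(type = "categories", offset = 1,
         cuts = unname(stats::quantile(eta, cumsum(p)[-length(p)])))
  } else if (var %in% names(targets$counts)) {
    tg <- targets$counts[[var]]
    pmf <- count_pmf(tg$prevalence, tg$mean, tg$sd, tg$max)
    list(type = "categories", offset = 0,
         cuts = unname(stats::quantile(eta, cumsum(pmf)[-length(pmf)])))
  } else if (var %in% names(targets$continuous)) {
    tg <- targets$continuous[[var]]
    if (tg$dist == "normal")
      list(type = "normal", mean = tg$mean, sd = tg$sd,
           eta_mean = mean(eta), eta_sd = stats::sd(eta))
    else
      list(type = "quantile_map", target = tg,
           grid = unname(stats::quantile(eta, quantile_grid_probs)))
  } else stop("no marginal target for variable ", var, call. = FALSE)
}

macro_nodes <- function() c("canton_gdp", "canton_gini", "canton_crime")

#' Calibrate generator intercepts against marginal targets
#'
#' Runs a one-off calibration simulation (size `calibration_n`, seed derived
#' from the master seed) along the generation order. For each variable the
#' latent score is the sum of its standardized already-generated parents
#' times the per-edge structural coefficient, plus unit Gaussian noise;
#' intercepts are the empirical quantiles of that score at the target
#' cumulative probabilities (thresholds for binary, cut points for ordinal
#' and count variables, moment/quantile maps for continuous ones). The
#' frozen intercepts make independently generated cohorts match the targets
#' up to Monte-Carlo error.
#'
#' @param truth A `ground_truth` graph.
#' @param config A [generator_config()].
#' @return An object of class `generator_intercepts`.
#' @export
calibrate_marginals <- function(truth = default_ground_truth(),
                                config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  order <- igraph::graph_attr(truth, "generation_order")
  check_truth_order(truth, order)
  strengths <- resolve_strengths(truth, config)
  targets <- config$marginal_targets
  n <- config$calibration_n
  adj <- igraph::as_adjacency_matrix(truth, sparse = FALSE)

  micro <- setdiff(order, macro_nodes())
  set.seed(derive_seed(config$seed, 101))
  vars <- list()
  values <- list()
  for (v in micro) {
    par <- parents_of(v, order, adj)
    eta <- stats::rnorm(n)
    betas <- numeric(0)
    if (length(par)) {
      betas <- stats::setNames(strengths[edge_key(v, par)], par)
      for (p in par) {
        z <- (values[[p]] - vars[[p]]$obs_mean) / vars[[p]]$obs_sd
        eta <- eta + betas[[p]] * z
      }
    }
    tr <- target_transform(v, eta, targets)
    x <- apply_transform(eta, tr)
    vars[[v]] <- list(parents = par, betas = betas, transform = tr,
                      obs_mean = mean(x), obs_sd = max(stats::sd(x), 1e-9))
    values[[v]] <- x
  }

  # Macro chain calibrated over hypothetical cantons (the real cohort draws
  # only n_cantons of them).
  set.seed(derive_seed(config$seed, 102))
  macro <- list()
  mvalues <- list()
  for (v in intersect(order, macro_nodes())) {
    par <- intersect(parents_of(v, order, adj), macro_nodes())
    eta <- stats::rnorm(n)
    betas <- numeric(0)
    if (length(par)) {
      betas <- stats::setNames(strengths[edge_key(v, par)], par)
      for (p in par) {
        z <- (mvalues[[p]] - macro[[p]]$obs_mean) / macro[[p]]$obs_sd
        eta <- eta + betas[[p]] * z
      }
    }
    tg <- targets$macro[[v]]
    tr <- if (tg$dist == "normal")
      list(type = "normal", mean = tg$mean, sd = tg$sd,
           eta_mean = mean(eta), eta_sd = stats::sd(eta))
    else
      list(type = "quantile_map", target = tg,
           grid = unname(stats::quantile(eta, quantile_grid_probs)))
    x <- apply_transform(eta, tr)
    macro[[v]] <- list(parents = par, betas = betas, transform = tr,
                       obs_mean = mean(x), obs_sd = max(stats::sd(x), 1e-9))
    mvalues[[v]] <- x
  }
  structure(list(variables = vars, macro = macro, order = order,
                 micro = micro, seed = config$seed),
            class = "generator_intercepts")
}

parents_of <- function(v, order, adj) {
  nm <- rownames(adj)
  nb <- nm[adj[v, ] == 1]
  nb[match(nb, order) < match(v, order)]
}

check_truth_order <- function(truth, order) {
  nodes <- igraph::V(truth)$name
  if (is.null(order) || !setequal(order, nodes) || length(order) != length(nodes))
    stop("generation_order inconsistent with the graph's node set", call. = FALSE)
  em <- edge_matrix(truth)
  if (nrow(em)) {
    mac <- macro_nodes()
    cross <- xor(em[, 1] %in% mac, em[, 2] %in% mac)
    if (any(cross))
      stop("the generator requires macro and micro nodes to be non-adjacent",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Published specific-problem prevalences (and plausible in-range values where
# unpublished) used as weights when distributing an index value over items.
item_backfill_weights <- function() {
  list(
    impairment = c(vision = 0.12, hearing = 0.09, speaking = 0.015, bmi = 0.12,
                   incontinence = 0.05, defecation = 0.06, energy = 0.42,
                   sleep = 0.25, tachycardia = 0.07),
    pain = c(head = 0.30, chest = 0.09, stomach = 0.14, back = 0.44,
             hands = 0.17, joints = 0.35),
    ap_limitation = c(walking = 0.04, eating = 0.005, getting_up = 0.02,
                      dressing = 0.015, toilet = 0.01, shower = 0.02,
                      meals = 0.02, phone = 0.01, laundry = 0.03,
                      finances = 0.02, transport = 0.03, household = 0.12,
                      shopping = 0.025),
    social_support = c(not_lonely = 0.75, not_missing_someone = 0.80,
                       family_member = 0.95, confidant = 0.90),
    social_network = c(family_visits = 0.60, family_calls = 0.80,
                       friend_visits = 0.55, friend_calls = 0.70,
                       clubs = 0.45))
}

prefix_of <- c(impairment = "imp_", pain = "pain_", ap_limitation = "ap_",
               social_support = "sup_", social_network = "net_")

# Distribute index counts over battery items, weighted sampling without
# replacement, so that re-summing the items reproduces the index exactly.
backfill_items <- function(index_values, weights, prefix) {
  n <- length(index_values)
  m <- length(weights)
  out <- matrix(0L, n, m, dimnames = list(NULL, paste0(prefix, names(weights))))
  k <- as.integer(index_values)
  full <- !is.na(k) & k == m
  out[full, ] <- 1L
  part <- which(!is.na(k) & k > 0 & k < m)
  for (i in part)
    out[i, sample.int(m, k[i], prob = weights)] <- 1L
  out
}

#' Generate a synthetic survey cohort
#'
#' Draws `n` respondents from the structural model oriented along the
#' truth's generation order, using calibrated intercepts. Canton sizes are
#' proportional to a Dirichlet draw; the three macro indicators are drawn
#' once per canton (mutually dependent at the canton level but independent
#' of every individual-level variable) and are constant within canton.
#' Item batteries are back-filled so that the sum indices computed by
#' [assemble_modeling_table()] reproduce the generated index values, and the
#' raw body-mass-index item is emitted on its measurement scale (outside the
#' 16-30 band exactly when the impairment item is positive). Missingness is
#' injected completely at random at the configured rate. Fixed seed implies
#' bit-identical output.
#'
#' @param truth A `ground_truth` graph.
#' @param config A [generator_config()].
#' @param intercepts Optional pre-computed [calibrate_marginals()] result.
#' @return List of class `synthetic_cohort` with elements `respondents`
#'   (item-level table plus `canton_id`) and `cantons` (macro table).
#' @export
generate_cohort <- function(truth = default_ground_truth(),
                            config = generator_config(),
                            intercepts = NULL) {
  stopifnot(inherits(config, "generator_config"))
  order <- igraph::graph_attr(truth, "generation_order")
  check_truth_order(truth, order)
  if (is.null(intercepts)) intercepts <- calibrate_marginals(truth, config)
  n <- config$n

  # canton structure
  set.seed(derive_seed(config$seed, 201))
  sizes <- stats::rgamma(config$n_cantons, shape = 10, rate = 1)
  canton <- sample.int(config$n_cantons, n, replace = TRUE,
                       prob = sizes / sum(sizes))
  macro_tab <- data.frame(canton_id = seq_len(config$n_cantons))
  mvals <- list()
  n_units <- if (config$macro_clustered) config$n_cantons else n
  for (v in intersect(intercepts$order, macro_nodes())) {
    mi <- intercepts$macro[[v]]
    eta <- stats::rnorm(n_units)
    for (p in mi$parents)
      eta <- eta + mi$betas[[p]] *
        (mvals[[p]] - mi_par_mean(intercepts, p)) / mi_par_sd(intercepts, p)
    mvals[[v]] <- apply_transform(eta, mi$transform)
    if (config$macro_clustered) macro_tab[[v]] <- mvals[[v]]
  }

  # micro variables in generation order
  set.seed(derive_seed(config$seed, 202))
  values <- list()
  for (v in intercepts$micro) {
    vi <- intercepts$variables[[v]]
    eta <- stats::rnorm(n)
    for (p in vi$parents) {
      z <- (values[[p]] - intercepts$variables[[p]]$obs_mean) /
        intercepts$variables[[p]]$obs_sd
      eta <- eta + vi$betas[[p]] * z
    }
    values[[v]] <- apply_transform(eta, vi$transform)
  }

  # respondent table: back-filled items + directly measured variables
  set.seed(derive_seed(config$seed, 203))
  wts <- item_backfill_weights()
  resp <- data.frame(row.names = seq_len(n))
  for (idx in names(wts)) {
    items <- backfill_items(values[[idx]], wts[[idx]], prefix_of[[idx]])
    resp <- cbind(resp, as.data.frame(items))
  }
  # raw BMI consistent with its dichotomized impairment item
  bmi_flag <- resp$imp_bmi == 1
  bmi <- stats::runif(n, 17, 29.5)
  high <- bmi_flag & stats::runif(n) < 0.8
  low <- bmi_flag & !high
  bmi[high] <- stats::runif(sum(high), 30.5, 45)
  bmi[low] <- stats::runif(sum(low), 12, 15.5)
  resp$imp_bmi <- bmi
  direct <- setdiff(intercepts$micro,
                    c("impairment", "pain", "ap_limitation",
                      "social_support", "social_network"))
  for (v in direct) resp[[v]] <- values[[v]]
  if (!config$macro_clustered)
    for (v in names(mvals)) resp[[v]] <- mvals[[v]]
  resp$canton_id <- canton

  if (config$missingness_rate > 0)
    resp <- inject_missingness(resp, config$missingness_rate,
                               derive_seed(config$seed, 204))
  structure(list(respondents = resp,
                 cantons = if (config$macro_clustered) macro_tab else NULL),
            class = "synthetic_cohort")
}

mi_par_mean <- function(intercepts, p) intercepts$macro[[p]]$obs_mean
mi_par_sd <- function(intercepts, p) intercepts$macro[[p]]$obs_sd

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$respondents), "respondents,",
      nrow(x$cantons), "cantons,", ncol(x$respondents) - 1, "item-level columns\n")
  invisible(x)
}

#' Inject missingness completely at random
#'
#' @param x Data frame (e.g. the `respondents` element of a cohort); the
#'   `canton_id` column is never blanked.
#' @param rate Per-cell missingness probability in `[0, 1]`.
#' @param seed Integer seed; the injection is deterministic given it.
#' @return The data frame with cells set to `NA`.
#' @export
inject_missingness <- function(x, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  cols <- setdiff(names(x), "canton_id")
  set.seed(seed)
  mask <- matrix(stats::runif(nrow(x) * length(cols)) < rate,
                 nrow(x), length(cols))
  for (j in seq_along(cols)) {
    hit <- mask[, j]
    if (any(hit)) x[[cols[j]]][hit] <- NA
  }
  x
}
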