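# Shared fixtures, generated in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small complete cohort + modeling table used by several unit tests
small_cohort <- function() cached("small_cohort", {
  generate_cohort(default_ground_truth(),
                  generator_config(n = 300, seed = 7, missingness_rate = 0,
                                   calibration_n = 10000))
})

small_table <- function() cached("small_table", {
  co <- small_cohort()
  assemble_modeling_table(co$respondents, co$cantons)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# documented seed-splitting scheme, reimplemented independently for oracles
derive_seed_oracle <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}

truth_edge_keys <- function(g) {
  em <- edge_matrix(g)
  if (!nrow(em)) character(0) else paste(em[, 1], em[, 2], sep = "|")
}

# --- shared simulation runs for the acceptance suite (computed lazily) ----
# Problem sizes are the suite-scale study conditions documented in the
# methods vignette: recovery/sensitivity cohorts n = 1000 (complete),
# 30 subsample pairs; error-control nulls n = 1000 cohorts at default
# missingness with the default 50 pairs.

acceptance_recovery_runs <- function() cached("acc_recovery", {
  truth <- default_ground_truth()
  lapply(1:10, function(s) {
    cfg <- generator_config(n = 1000, seed = 400 + s, missingness_rate = 0,
                            calibration_n = 20000)
    co <- generate_cohort(truth, cfg)
    tab <- assemble_modeling_table(co$respondents, co$cantons)
    g <- estimate_graph(tab, scheme = subsample_scheme(30, seed = 400 + s),
                        seed = 400 + s)
    list(seed = 400 + s, table = tab, graph = g,
         stability = igraph::graph_attr(g, "stability"))
  })
})

acceptance_macro_runs <- function() cached("acc_macro", {
  runs <- acceptance_recovery_runs()
  lapply(runs, function(r) {
    tab <- r$table
    vars <- modeling_vars(tab)
    macro <- c("canton_gdp", "canton_gini", "canton_crime")
    sc <- attr(tab, "scales")
    tab2 <- structure(as.data.frame(tab)[, c(setdiff(vars, macro), "canton_id")],
                      scales = sc[setdiff(vars, macro)],
                      class = c("modeling_table", "data.frame"))
    g2 <- estimate_graph(tab2, scheme = subsample_scheme(30, seed = r$seed),
                         seed = r$seed, keep_stability = FALSE)
    micro_keys <- function(g) {
      k <- truth_edge_keys(g)
      k[!grepl("canton_", k)]
    }
    list(seed = r$seed,
         full_micro = sort(micro_keys(r$graph)),
         reduced_micro = sort(truth_edge_keys(g2)))
  })
})

acceptance_null_runs <- function() cached("acc_null", {
  nt <- null_ground_truth()
  lapply(1:5, function(s) {
    cfg <- generator_config(n = 1000, seed = 600 + s, macro_clustered = FALSE,
                            calibration_n = 20000)
    co <- generate_cohort(nt, cfg)
    tab <- assemble_modeling_table(co$respondents, co$cantons)
    g <- estimate_graph(tab, seed = 600 + s)
    list(seed = 600 + s, graph = g,
         stability = igraph::graph_attr(g, "stability"))
  })
})
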