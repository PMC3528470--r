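# Item dichotomization, sum indices and modeling-table assembly.

test_that("dichotomization rules map responses to problem indicators", {
  bmi <- item_rule("imp_bmi", "outside_interval", lower = 16, upper = 30)
  # strict bounds: 'over 30 or under 16', so the bounds themselves are fine
  expect_identical(dichotomize_item(c(32, 22, 30, 16, 15.9, NA), bmi),
                   c(1L, 0L, 0L, 0L, 1L, NA_integer_))
  above <- item_rule("x", "threshold_above", upper = 3)
  expect_identical(dichotomize_item(c(3, 3.1, NA), above), c(0L, 1L, NA_integer_))
  below <- item_rule("x", "threshold_below", lower = 2)
  expect_identical(dichotomize_item(c(2, 1.9), below), c(0L, 1L))
  neg <- item_rule("x", "negate")
  expect_identical(dichotomize_item(c(0, 1, NA), neg), c(1L, 0L, NA_integer_))
  pass <- item_rule("x", "binary")
  expect_identical(dichotomize_item(c(1, 0), pass), c(1L, 0L))
  expect_error(dichotomize_item(2, pass), "non-binary")
  expect_error(item_rule("x", "no_such_kind"))
  expect_error(item_rule("x", "outside_interval", lower = 16), "both bounds")
})

test_that("sum indices count dichotomized items and propagate missingness", {
  specs <- default_index_specs()
  imp <- specs$impairment
  items <- vapply(imp$rules, `[[`, "", "item")
  all_bad <- as.data.frame(as.list(stats::setNames(rep(1, 9), items)))
  all_bad$imp_bmi <- 35                      # outside the 16-30 band
  expect_identical(build_sum_index(all_bad, imp), 9L)
  none <- as.data.frame(as.list(stats::setNames(rep(0, 9), items)))
  none$imp_bmi <- 22
  expect_identical(build_sum_index(none, imp), 0L)

  pain <- specs$pain
  pat <- data.frame(pain_head = 1, pain_chest = 0, pain_stomach = 1,
                    pain_back = 0, pain_hands = 0, pain_joints = 1)
  expect_identical(build_sum_index(pat, pain), 3L)

  pat$pain_back <- NA
  expect_identical(build_sum_index(pat, pain), NA_integer_)
  expect_error(build_sum_index(pat[, -1], pain), "mismatch")
})

test_that("brute-force enumeration of every response pattern spans the printed ranges", {
  specs <- default_index_specs()
  expected_max <- c(impairment = 9L, pain = 6L, ap_limitation = 13L,
                    social_support = 4L, social_network = 5L)
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    k <- length(spec$rules)
    expect_identical(spec$range_max, k)
    items <- vapply(spec$rules, `[[`, "", "item")
    grid <- as.data.frame(matrix(0, 2^k, k, dimnames = list(NULL, items)))
    for (j in seq_len(k)) grid[[j]] <- rep(rep(0:1, each = 2^(j - 1)), length.out = 2^k)
    if ("imp_bmi" %in% items)   # put the measured item on its raw scale
      grid$imp_bmi <- ifelse(grid$imp_bmi == 1, 33, 24)
    idx <- build_sum_index(grid, spec)
    expect_identical(min(idx), 0L)
    expect_identical(max(idx), expected_max[[nm]])
    expect_true(all(0:expected_max[[nm]] %in% idx))
  }
})

test_that("assembly yields the 20-variable table with casewise deletion", {
  co <- small_cohort()
  tab <- assemble_modeling_table(co$respondents, co$cantons)
  expect_s3_class(tab, "modeling_table")
  expect_identical(sort(modeling_vars(tab)), sort(variable_roster()$name))
  expect_length(modeling_vars(tab), 20L)
  expect_identical(nrow(tab), nrow(co$respondents))  # complete cohort: no loss

  # one missing cell anywhere in a battery or direct variable drops that row
  raw <- co$respondents
  raw$income[5] <- NA
  raw$pain_back[9] <- NA
  tab2 <- assemble_modeling_table(raw, co$cantons)
  expect_identical(nrow(tab2), nrow(raw) - 2L)

  # independent cross-check of the casewise-deletion count
  full <- assemble_modeling_table_keep <- co$respondents
  full$income[5] <- NA; full$pain_back[9] <- NA
  specs <- default_index_specs()
  man <- full
  for (s in specs) man[[s$index_name]] <- build_sum_index(man, s)
  idx <- match(man$canton_id, co$cantons$canton_id)
  for (v in c("canton_gdp", "canton_gini", "canton_crime"))
    man[[v]] <- co$cantons[[v]][idx]
  n_complete <- sum(stats::complete.cases(man[, variable_roster()$name]))
  expect_identical(nrow(tab2), n_complete)

  # idempotence: re-assembling the assembled table changes nothing
  tab3 <- assemble_modeling_table(as.data.frame(tab2))
  expect_identical(as.data.frame(tab3), as.data.frame(tab2))

  # macro values joined by canton
  expect_identical(tab$canton_gdp,
                   co$cantons$canton_gdp[match(tab$canton_id, co$cantons$canton_id)])

  # empty input keeps the schema
  empty <- assemble_modeling_table(co$respondents[0, ], co$cantons)
  expect_identical(nrow(empty), 0L)
  expect_length(modeling_vars(empty), 20L)

  expect_error(assemble_modeling_table(co$respondents[, -1], co$cantons),
               "imp_vision")
  expect_error(assemble_modeling_table(subset(co$respondents, select = -canton_id)),
               "canton_id")
})

test_that("descriptive summary mirrors the cohort-table layout", {
  tab <- small_table()
  s <- summarize_table(tab)
  expect_true(all(c("variable", "stat", "value") %in% names(s)))
  pick <- function(v, st) s$value[s$variable == v & s$stat == st]
  expect_identical(pick("perceived_health", "median"),
                   stats::median(tab$perceived_health))
  # prevalence of index >= 1 equals one minus the fraction of zeros
  for (v in c("pain", "impairment", "ap_limitation"))
    expect_equal(pick(v, "pct_ge1"), 100 * (1 - mean(tab[[v]] == 0)))
  expect_equal(pick("male", "n"), sum(tab$male))
  # a constant column has SD zero
  tab2 <- tab
  tab2$age <- 50
  s2 <- summarize_table(tab2)
  expect_identical(s2$value[s2$variable == "age" & s2$stat == "sd"], 0)
  expect_error(summarize_table(tab[0, ]), "empty")
})

test_that("index specs can be loaded from a config file", {
  cfg <- list(
    pain = list(list(item = "pain_head", kind = "binary"),
                list(item = "pain_score", kind = "threshold_above", upper = 3)))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  specs <- index_specs_from_config(path)
  expect_identical(specs$pain$range_max, 2L)
  expect_identical(
    build_sum_index(data.frame(pain_head = 1, pain_score = 5), specs$pain), 2L)
})
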