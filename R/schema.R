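#' Dichotomization rule for a single survey item
#'
#' Survey items arrive on heterogeneous scales (yes/no, severity grades,
#' measured quantities such as body mass index). Each item is mapped to a
#' 0/1 problem indicator before entering a sum index, with 1 indicating the
#' presence of a problem (or, for the support/network batteries, the presence
#' of a resource).
#'
#' @param item Item (column) name in the raw respondent table.
#' @param kind One of `"binary"` (pass a 0/1 response through unchanged),
#'   `"threshold_above"` (1 if the value is strictly above `upper`),
#'   `"threshold_below"` (1 if strictly below `lower`),
#'   `"outside_interval"` (1 if strictly below `lower` or strictly above
#'   `upper`; the bounds themselves count as unproblematic), or `"negate"`
#'   (flip a 0/1 response).
#' @param lower,upper Numeric bounds, required where the kind uses them.
#' @return An object of class `item_rule`.
#' @examples
#' bmi <- item_rule("imp_bmi", "outside_interval", lower = 16, upper = 30)
#' dichotomize_item(c(32, 22, 30, NA), bmi)
#' @export
item_rule <- function(item, kind = c("binary", "threshold_above",
                                     "threshold_below", "outside_interval",
                                     "negate"),
                      lower = NULL, upper = NULL) {
  kind <- match.arg(kind)
  if (kind == "threshold_above" && is.null(upper))
    stop("rule 'threshold_above' needs an `upper` bound", call. = FALSE)
  if (kind == "threshold_below" && is.null(lower))
    stop("rule 'threshold_below' needs a `lower` bound", call. = FALSE)
  if (kind == "outside_interval" && (is.null(lower) || is.null(upper)))
    stop("rule 'outside_interval' needs both bounds", call. = FALSE)
  structure(list(item = item, kind = kind, lower = lower, upper = upper),
            class = "item_rule")
}

#' Apply a dichotomization rule to item responses
#'
#' @param value Vector of raw item responses.
#' @param rule An [item_rule()].
#' @return Integer vector of 0/1 indicators; missing input stays missing.
#' @export
dichotomize_item <- function(value, rule) {
  if (!inherits(rule, "item_rule")) stop("`rule` must be an item_rule", call. = FALSE)
  out <- switch(rule$kind,
    binary = {
      bad <- !is.na(value) & !value %in% c(0, 1)
      if (any(bad)) stop("non-binary response under a 'binary' rule for item '",
                         rule$item, "'", call. = FALSE)
      as.numeric(value)
    },
    threshold_above = as.numeric(value > rule$upper),
    threshold_below = as.numeric(value < rule$lower),
    outside_interval = as.numeric(value < rule$lower | value > rule$upper),
    negate = {
      bad <- !is.na(value) & !value %in% c(0, 1)
      if (any(bad)) stop("non-binary response under a 'negate' rule for item '",
                         rule$item, "'", call. = FALSE)
      1 - as.numeric(value)
    },
    stop("unknown rule kind", call. = FALSE))
  as.integer(out)
}

#' Specification of a sum index over an item battery
#'
#' A sum index counts dichotomized problem (or resource) indicators across an
#' ordered item battery, so a complete response pattern yields an integer in
#' `[0, range_max]` with `range_max` equal to the number of items.
#'
#' @param index_name One of `"impairment"`, `"pain"`, `"ap_limitation"`,
#'   `"social_support"`, `"social_network"`.
#' @param rules List of [item_rule()] objects, one per battery item.
#' @return An object of class `sum_index_spec` with fields `index_name`,
#'   `rules` and `range_max`.
#' @export
sum_index_spec <- function(index_name, rules) {
  index_name <- match.arg(index_name, c("impairment", "pain", "ap_limitation",
                                        "social_support", "social_network"))
  if (!length(rules) || !all(vapply(rules, inherits, TRUE, "item_rule")))
    stop("`rules` must be a non-empty list of item_rule objects", call. = FALSE)
  structure(list(index_name = index_name, rules = rules,
                 range_max = length(rules)),
            class = "sum_index_spec")
}

#' Default item batteries of the five sum indices
#'
#' Impairment (9 items, including body mass index dichotomized as over 30 or
#' under 16), pain sites (6), limitations in activities and participation
#' (13), perceived social support (4) and social network utilization (5).
#' All items except body mass index default to a pass-through of a 0/1
#' response; thresholds are plain data, so a user of the real survey can
#' swap in item-specific cut-offs without code changes
#' (see [index_specs_from_config()]).
#'
#' @return Named list of five [sum_index_spec()] objects.
#' @export
default_index_specs <- function() {
  bin <- function(items) lapply(items, item_rule, kind = "binary")
  imp_items <- paste0("imp_", c("vision", "hearing", "speaking", "bmi",
                                "incontinence", "defecation", "energy",
                                "sleep", "tachycardia"))
  imp_rules <- bin(imp_items)
  imp_rules[[4]] <- item_rule("imp_bmi", "outside_interval", lower = 16, upper = 30)
  list(
    impairment = sum_index_spec("impairment", imp_rules),
    pain = sum_index_spec("pain", bin(paste0("pain_", c(
      "head", "chest", "stomach", "back", "hands", "joints")))),
    ap_limitation = sum_index_spec("ap_limitation", bin(paste0("ap_", c(
      "walking", "eating", "getting_up", "dressing", "toilet", "shower",
      "meals", "phone", "laundry", "finances", "transport", "household",
      "shopping")))),
    social_support = sum_index_spec("social_support", bin(paste0("sup_", c(
      "not_lonely", "not_missing_someone", "family_member", "confidant")))),
    social_network = sum_index_spec("social_network", bin(paste0("net_", c(
      "family_visits", "family_calls", "friend_visits", "friend_calls",
      "clubs")))))
}

#' Read index specifications from a YAML/JSON-style config list or file
#'
#' The config holds, per index, a list of items with `kind` and optional
#' `lower`/`upper` bounds, mirroring [default_index_specs()].
#'
#' @param config Either a path to a YAML file or an already-parsed list.
#' @return Named list of [sum_index_spec()] objects.
#' @export
index_specs_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- lapply(names(config), function(nm) {
    rules <- lapply(config[[nm]], function(it) {
      item_rule(it$item, it$kind %||% "binary",
                lower = it$lower, upper = it$upper)
    })
    sum_index_spec(nm, rules)
  })
  names(out) <- names(config)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a sum index from an item battery
#'
#' @param responses Data frame (or named list) holding the raw responses for
#'   all items of the battery.
#' @param spec A [sum_index_spec()].
#' @return Integer vector; a respondent with any missing component item gets
#'   a missing index (consistent with casewise deletion downstream).
#' @export
build_sum_index <- function(responses, spec) {
  if (!inherits(spec, "sum_index_spec")) stop("`spec` must be a sum_index_spec", call. = FALSE)
  items <- vapply(spec$rules, `[[`, "", "item")
  missing_cols <- setdiff(items, names(responses))
  if (length(missing_cols))
    stop("battery/spec mismatch for index '", spec$index_name,
         "': missing items ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ind <- do.call(cbind, lapply(seq_along(items), function(i)
    dichotomize_item(responses[[items[i]]], spec$rules[[i]])))
  as.integer(rowSums(ind))
}

#' Roster of the twenty modeling variables
#'
#' The conditional-independence graph is estimated over exactly twenty
#' variables: four functioning variables (perceived health on a 1 = very good
#' to 5 = very poor ordinal scale, and the pain, impairment and
#' activity-and-participation limitation sum indices), personal factors,
#' lifestyle factors, individual socio-economic status, micro-level
#' environmental factors, and three canton-level macro indicators (GDP per
#' capita, Gini coefficient, crime rate) that are constant within canton.
#'
#' @return Data frame with columns `name`, `role` and `scale`.
#' @export
variable_roster <- function() {
  data.frame(
    name = c("perceived_health", "pain", "impairment", "ap_limitation",
             "age", "male", "married",
             "alcohol_g_per_day", "smoker", "low_physical_activity",
             "education_years", "income", "paid_employment",
             "migration_background", "work_restriction",
             "social_support", "social_network",
             "canton_gdp", "canton_gini", "canton_crime"),
    role = c("functioning", "functioning", "functioning", "functioning",
             "personal", "personal", "environment",
             "lifestyle", "lifestyle", "lifestyle",
             "ses", "ses", "ses", "ses", "ses",
             "environment", "environment",
             "macro", "macro", "macro"),
    scale = c("ordinal", "count", "count", "count",
              "continuous", "binary", "binary",
              "continuous", "binary", "binary",
              "continuous", "continuous", "binary", "binary", "binary",
              "count", "count",
              "continuous", "continuous", "continuous"),
    stringsAsFactors = FALSE)
}

#' Assemble the modeling table
#'
#' Builds the five sum indices from their item batteries, joins canton-level
#' macro indicators by canton identifier, restricts to the twenty modeling
#' variables, and applies casewise deletion (any respondent with a missing
#' value in any modeling variable is dropped).
#'
#' @param raw Respondent table: item-level columns plus the directly measured
#'   variables and a `canton_id` column.
#' @param macro Optional canton table with columns `canton_id`, `canton_gdp`,
#'   `canton_gini`, `canton_crime`. May be omitted when `raw` already carries
#'   the macro columns.
#' @param specs Index specifications, default [default_index_specs()].
#' @param roster Variable roster, default [variable_roster()].
#' @return A `modeling_table`: a data frame with the twenty modeling columns
#'   plus `canton_id`, carrying per-variable scale metadata in
#'   `attr(, "scales")`.
#' @export
assemble_modeling_table <- function(raw, macro = NULL,
                                    specs = default_index_specs(),
                                    roster = variable_roster()) {
  raw <- as.data.frame(raw)
  if (!"canton_id" %in% names(raw))
    stop("missing required column: canton_id", call. = FALSE)
  if (!is.null(macro)) {
    need <- c("canton_id", "canton_gdp", "canton_gini", "canton_crime")
    miss <- setdiff(need, names(macro))
    if (length(miss))
      stop("missing required column: ", paste(miss, collapse = ", "), call. = FALSE)
    idx <- match(raw$canton_id, macro$canton_id)
    if (anyNA(idx) && !all(is.na(raw$canton_id[is.na(idx)])))
      stop("canton_id values in `raw` without a macro row", call. = FALSE)
    for (v in c("canton_gdp", "canton_gini", "canton_crime"))
      raw[[v]] <- macro[[v]][idx]
  }
  idx_names <- vapply(specs, `[[`, "", "index_name")
  for (i in seq_along(specs)) {
    nm <- idx_names[i]
    if (!nm %in% names(raw)) raw[[nm]] <- build_sum_index(raw, specs[[i]])
  }
  miss <- setdiff(roster$name, names(raw))
  if (length(miss))
    stop("missing required column: ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- raw[, c(roster$name, "canton_id")]
  keep <- stats::complete.cases(tab[, roster$name])
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  scales <- stats::setNames(roster$scale, roster$name)
  structure(tab, scales = scales, class = c("modeling_table", "data.frame"))
}

#' @export
print.modeling_table <- function(x, ...) {
  scales <- attr(x, "scales")
  cat("Modeling table:", nrow(x), "respondents x", length(scales),
      "variables (+ canton_id)\n")
  tb <- table(scales)
  cat("Scales:", paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                       collapse = ", "), "\n")
  if (nrow(x)) {
    print(utils::head(as.data.frame(x), 4))
    if (nrow(x) > 4) cat("... (", nrow(x) - 4, " more rows)\n", sep = "")
  }
  invisible(x)
}

#' Variable names of a modeling table (excluding canton_id)
#' @param tab A `modeling_table`.
#' @return Character vector of the modeling variable names.
#' @export
modeling_vars <- function(tab) {
  sc <- attr(tab, "scales")
  if (!is.null(sc)) return(names(sc))
  setdiff(names(tab), "canton_id")
}

#' Per-variable scale metadata
#'
#' Returns the declared scales of a modeling table, falling back to a simple
#' inference (two observed values in \{0, 1\} = binary, otherwise numeric) for
#' plain data frames.
#' @param tab A `modeling_table` or data frame.
#' @return Named character vector over the modeling variables.
#' @export
variable_scales <- function(tab) {
  sc <- attr(tab, "scales")
  if (!is.null(sc)) return(sc)
  vars <- setdiff(names(tab), "canton_id")
  vapply(vars, function(v) {
    u <- unique(tab[[v]][!is.na(tab[[v]])])
    if (length(u) <= 2 && all(u %in% c(0, 1))) "binary" else "continuous"
  }, "", USE.NAMES = TRUE)
}

#' Descriptive summary of a modeling table
#'
#' Mirrors the layout of a published cohort-description table: mean and SD
#' for numeric variables, count and percentage for binary variables, median
#' with 10% and 90% quantiles for perceived health, and for the pain,
#' impairment and activity-and-participation indices additionally the
#' prevalence of an index value of at least one.
#'
#' @param tab A `modeling_table`.
#' @return Data frame with columns `variable`, `stat`, `value` in long form.
#' @export
summarize_table <- function(tab) {
  if (!nrow(tab)) stop("empty modeling table", call. = FALSE)
  scales <- variable_scales(tab)
  rows <- list()
  add <- function(variable, stat, value)
    rows[[length(rows) + 1]] <<- data.frame(variable = variable, stat = stat,
                                            value = value)
  for (v in names(scales)) {
    x <- tab[[v]]
    if (v == "perceived_health") {
      add(v, "median", stats::median(x))
      add(v, "q10", unname(stats::quantile(x, 0.10, type = 1)))
      add(v, "q90", unname(stats::quantile(x, 0.90, type = 1)))
    } else if (scales[v] == "binary") {
      add(v, "n", sum(x))
      add(v, "pct", 100 * mean(x))
    } else {
      add(v, "mean", mean(x))
      add(v, "sd", stats::sd(x))
    }
    if (v %in% c("pain", "impairment", "ap_limitation")) {
      add(v, "n_ge1", sum(x >= 1))
      add(v, "pct_ge1", 100 * mean(x >= 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
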