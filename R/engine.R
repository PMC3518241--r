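# The five-step switch algorithm: identity on the formulary, pharmaceutical
# equivalent, pharmaceutical alternative (with regimen recomputation),
# therapeutic equivalent (with conversion-factor dose adjustment), and the
# residual manual-handling category. Steps are tried strictly in order; the
# first success determines the outcome group.

#' Engine configuration
#'
#' Consolidates the tunable thresholds of the switch algorithm.
#'
#' @param rel_tol relative strength tolerance for pharmaceutical
#'   equivalence. The default 0 demands exact strength identity, which is
#'   the strictest reading of "matching strength"; 0.01 additionally
#'   absorbs salt-rounding differences between brands of the same moiety.
#' @param max_dose_deviation maximum tolerated relative deviation of an
#'   achieved from a target daily dose after regimen recomputation
#'   (default 0.10). Infeasible recomputations demote the prescription to
#'   manual handling instead of emitting an out-of-tolerance dose.
#' @param max_combination_components combination products with more active
#'   ingredients than this are never split automatically (default 3).
#' @param allow_split_combinations enable splitting combination products
#'   into single-agent prescriptions when the whole product has no match.
#' @return object of class `engine_config`.
#' @export
engine_config <- function(rel_tol = 0, max_dose_deviation = 0.10,
                          max_combination_components = 3,
                          allow_split_combinations = TRUE) {
  if (rel_tol < 0 || max_dose_deviation < 0)
    stop_rxswitch("tolerances must be non-negative", "rxswitch_invalid")
  max_combination_components <- as.integer(max_combination_components)
  if (max_combination_components < 1L)
    stop_rxswitch("max_combination_components must be >= 1", "rxswitch_invalid")
  structure(list(rel_tol = rel_tol, max_dose_deviation = max_dose_deviation,
                 max_combination_components = max_combination_components,
                 allow_split_combinations = isTRUE(allow_split_combinations)),
            class = "engine_config")
}

warning_note <- function(type, message) list(type = type, message = message)

new_switch_result <- function(group, source, suggestions = list(),
                              warnings = list(), dose_deviation = numeric(),
                              trace = character()) {
  structure(list(group = as.integer(group), source = source,
                 suggestions = suggestions, warnings = warnings,
                 dose_deviation = dose_deviation, trace = trace),
            class = "switch_result")
}

.group_labels <- c("HDF drug", "pharmaceutical equivalent",
                   "pharmaceutical alternative", "therapeutic equivalent",
                   "no automatic switch")

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf("<switch_result> group %d (%s)\n", x$group,
              .group_labels[x$group]))
  cat(sprintf("  source: %s, %s\n",
              if (!is.null(x$source$product)) x$source$product$brand_name
              else x$source$descriptor,
              format_scheme(x$source$regimen)))
  for (s in x$suggestions)
    cat(sprintf("  -> %s (%s), %s\n", s$product$brand_name,
                s$product$product_id, format_scheme(s$regimen)))
  for (w in x$warnings)
    cat(sprintf("  ! %s: %s\n", w$type, w$message))
  invisible(x)
}

salt_warnings <- function(source, candidate) {
  out <- list()
  for (ing in source$ingredients) {
    cand <- parent_strength(candidate, ing$parent)
    if (!is.null(cand) && !identical(cand$salt, ing$salt))
      out[[length(out) + 1L]] <- warning_note(
        "salt-difference",
        sprintf("%s: salt form differs (%s vs %s)", ing$parent,
                if (nzchar(ing$salt)) ing$salt else "none",
                if (nzchar(cand$salt)) cand$salt else "none"))
  }
  out
}

#' Switch one prescription against the formulary
#'
#' Runs the five-step algorithm: (1) the product itself is on the hospital
#' drug formulary — no switch needed; (2) a pharmaceutical equivalent
#' exists — the regimen carries over unchanged; (3) a pharmaceutical
#' alternative exists — the regimen is recomputed to preserve the total
#' daily dose; (4) a therapeutic equivalent exists in an interchange class
#' — the daily dose is multiplied by the class conversion factor and a new
#' regimen computed (single-ingredient oral solids only); (5) no automatic
#' switch — the prescription is flagged for manual handling. Combination
#' products that fail steps 1-3 as a whole may be split into single-agent
#' prescriptions (see [split_combination()]). Unresolved or incomplete
#' prescriptions yield group 5 with an `incomplete` warning rather than an
#' error, so a consultation always produces one result per line.
#'
#' @param p a [prescription()].
#' @param cat a `drug_catalogue`.
#' @param kb an `interchange_kb`.
#' @param cfg an [engine_config()].
#' @return a `switch_result` with the outcome group (1-5), suggested
#'   prescriptions, typed warnings, per-suggestion relative dose deviation
#'   and the trace of steps attempted.
#' @export
switch_prescription <- function(p, cat, kb = default_kb(),
                                cfg = engine_config()) {
  if (!inherits(p, "prescription"))
    stop_rxswitch("p must be a prescription", "rxswitch_invalid")
  trace <- character()
  if (!p$resolved) {
    return(new_switch_result(
      5L, p, warnings = list(warning_note(
        "incomplete", "prescription unresolved or scheme unparseable")),
      trace = "incomplete: demoted to manual handling"))
  }
  src <- p$product

  # step 1: formulary drug
  if (src$on_hdf) {
    return(new_switch_result(
      1L, p, suggestions = list(p), dose_deviation = 0,
      trace = "step 1: product on HDF"))
  }
  trace <- c(trace, "step 1: not on HDF")

  # step 2: pharmaceutical equivalent, regimen unchanged
  eq <- equivalents_query(src, cat, rel_tol = cfg$rel_tol)
  if (length(eq)) {
    best <- eq[[1]]
    warns <- salt_warnings(src, best)
    dev <- strength_deviation(src, best)
    if (dev > 0)
      warns <- c(warns, list(warning_note(
        "dose-deviation",
        sprintf("strength differs by %.2f%% within tolerance", 100 * dev))))
    return(new_switch_result(
      2L, p, suggestions = list(prescription(best, p$regimen)),
      warnings = warns, dose_deviation = dev,
      trace = c(trace, sprintf("step 2: equivalent %s", best$product_id))))
  }
  trace <- c(trace, "step 2: no pharmaceutical equivalent")

  # step 3: pharmaceutical alternative, preserve total daily dose
  res3 <- try_alternatives(p, cat, cfg)
  if (!is.null(res3)) {
    res3$trace <- c(trace, res3$trace)
    return(res3)
  }
  trace <- c(trace, "step 3: no feasible pharmaceutical alternative")

  # combinations: split into single agents via steps 1-3 per component
  if (length(src$ingredients) >= 2L) {
    res_split <- split_combination(p, cat, kb, cfg)
    res_split$trace <- c(trace, res_split$trace)
    return(res_split)
  }

  # step 4: therapeutic equivalent (single-ingredient oral solids only)
  res4 <- try_therapeutic(p, cat, kb, cfg)
  if (!is.null(res4)) {
    res4$trace <- c(trace, res4$trace)
    return(res4)
  }
  trace <- c(trace, "step 4: no feasible therapeutic equivalent")

  new_switch_result(5L, p, trace = c(trace, "step 5: manual handling required"))
}

# Step 3 for a whole product. For combinations a candidate shares the parent
# multiset; the per-parent strength ratios must agree so that one scheme
# preserves every component's daily dose.
try_alternatives <- function(p, cat, cfg) {
  src <- p$product
  alts <- alternatives_query(src, cat, rel_tol = cfg$rel_tol)
  lead <- src$ingredients[[1]]$parent
  target <- total_daily_dose(p, lead)
  ranked <- rank_alternatives(alts, src, lead, target)
  for (cand in ranked) {
    if (length(src$ingredients) > 1L && !ratios_consistent(src, cand)) next
    fit <- redistribute(target, cand, lead,
                        max_dose_deviation = cfg$max_dose_deviation)
    if (!fit$feasible) next
    warns <- salt_warnings(src, cand)
    if (fit$split)
      warns <- c(warns, list(warning_note("tablet-splitting",
                                          "suggested scheme requires splitting dose units")))
    if (fit$deviation > 0)
      warns <- c(warns, list(warning_note(
        "dose-deviation",
        sprintf("achieved daily dose deviates by %.2f%%", 100 * fit$deviation))))
    return(new_switch_result(
      3L, p, suggestions = list(prescription(cand, fit$regimen)),
      warnings = warns, dose_deviation = fit$deviation,
      trace = sprintf("step 3: alternative %s, scheme %s", cand$product_id,
                      format_scheme(fit$regimen))))
  }
  NULL
}

ratios_consistent <- function(src, cand) {
  ratios <- vapply(src$ingredients, function(ing) {
    parent_strength(cand, ing$parent)$amount / ing$amount_norm
  }, numeric(1))
  all(near(ratios, ratios[1], tol = 1e-9))
}

# Candidate order for step 3: smallest relative strength deviation from the
# source, then fewest implied dose units per day at the target dose, then
# product id.
rank_alternatives <- function(alts, src, parent, target_tdd) {
  if (length(alts) == 0L) return(alts)
  src_strength <- parent_strength(src, parent)$amount
  dev <- vapply(alts, function(cand) {
    abs(parent_strength(cand, parent)$amount - src_strength) / src_strength
  }, numeric(1))
  units <- vapply(alts, function(cand)
    target_tdd / parent_strength(cand, parent)$amount, numeric(1))
  ids <- vapply(alts, `[[`, character(1), "product_id")
  alts[order(dev, units, ids)]
}

try_therapeutic <- function(p, cat, kb, cfg) {
  src <- p$product
  if (length(src$ingredients) != 1L) return(NULL)
  cands <- therapeutic_candidates(src, cat, kb)
  if (length(cands) == 0L) return(NULL)
  parent <- src$ingredients[[1]]$parent
  tdd <- total_daily_dose(p, parent)
  fits <- lapply(cands, function(cand) {
    target <- tdd * cand$factor
    fit <- redistribute(target, cand$product,
                        cand$product$ingredients[[1]]$parent,
                        max_dose_deviation = cfg$max_dose_deviation)
    if (!fit$feasible) return(NULL)
    list(cand = cand, fit = fit)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) return(NULL)
  # prefer the candidate achieving the smallest deviation from its
  # equipotent target, then fewer daily units, then product id
  key <- vapply(fits, function(x) x$fit$deviation, numeric(1))
  units <- vapply(fits, function(x) sum(x$fit$regimen$slots), numeric(1))
  ids <- vapply(fits, function(x) x$cand$product$product_id, character(1))
  best <- fits[[order(key, units, ids)[1]]]
  warns <- list()
  for (w in best$cand$warnings)
    warns <- c(warns, list(warning_note(
      "indication-difference",
      "conversion factor differs between labelled indications")))
  if (best$fit$split)
    warns <- c(warns, list(warning_note("tablet-splitting",
                                        "suggested scheme requires splitting dose units")))
  if (best$fit$deviation > 0)
    warns <- c(warns, list(warning_note(
      "dose-deviation",
      sprintf("achieved daily dose deviates by %.2f%% from the equipotent dose",
              100 * best$fit$deviation))))
  new_switch_result(
    4L, p, suggestions = list(prescription(best$cand$product, best$fit$regimen)),
    warnings = warns, dose_deviation = best$fit$deviation,
    trace = sprintf("step 4: therapeutic equivalent %s (factor %.4g, %s), scheme %s",
                    best$cand$product$product_id, best$cand$factor,
                    best$cand$indication, format_scheme(best$fit$regimen)))
}

#' Split a combination product into single-agent prescriptions
#'
#' Invoked when a multi-ingredient product fails steps 1-3 as a whole. Each
#' active ingredient is projected onto a virtual single-agent prescription
#' (component strength, original scheme) and resolved through the
#' equivalent/alternative steps only — combinations are never substituted
#' therapeutically. The split is all-or-nothing: the switch succeeds only
#' if every component resolves, and the recorded group is the worst
#' (highest) component step. Products with more ingredients than
#' `cfg$max_combination_components` are not split.
#'
#' @inheritParams switch_prescription
#' @return a `switch_result` with one suggestion per component, or group 5.
#' @export
split_combination <- function(p, cat, kb = default_kb(), cfg = engine_config()) {
  src <- p$product
  if (length(src$ingredients) < 2L)
    stop_rxswitch("split_combination needs a combination product",
                  "rxswitch_invalid")
  if (length(src$ingredients) > cfg$max_combination_components) {
    return(new_switch_result(
      5L, p, warnings = list(warning_note(
        "combination", sprintf("%d active ingredients exceed the limit of %d for splitting",
                               length(src$ingredients), cfg$max_combination_components))),
      trace = "split: too many components"))
  }
  if (!cfg$allow_split_combinations) {
    return(new_switch_result(5L, p, trace = "split: disabled by configuration"))
  }
  suggestions <- list()
  warnings <- list()
  deviations <- numeric()
  worst <- 1L
  trace <- character()
  for (ing in src$ingredients) {
    virtual <- drug_product(
      product_id = paste0(src$product_id, "::", ing$parent),
      brand_name = sprintf("%s (%s component)", src$brand_name, ing$parent),
      ingredients = list(ing),
      dosage_form = src$dosage_form, release = src$release, route = src$route,
      atc_codes = src$atc_codes, indications = src$indications,
      on_hdf = FALSE, divisibility = src$divisibility)
    vp <- prescription(virtual, p$regimen)
    eq <- equivalents_query(virtual, cat, rel_tol = cfg$rel_tol)
    if (length(eq)) {
      best <- eq[[1]]
      suggestions <- c(suggestions, list(prescription(best, p$regimen)))
      warnings <- c(warnings, salt_warnings(virtual, best))
      deviations <- c(deviations, strength_deviation(virtual, best))
      worst <- max(worst, 2L)
      trace <- c(trace, sprintf("split %s: equivalent %s", ing$parent,
                                best$product_id))
      next
    }
    res3 <- try_alternatives(vp, cat, cfg)
    if (!is.null(res3)) {
      suggestions <- c(suggestions, res3$suggestions)
      warnings <- c(warnings, res3$warnings)
      deviations <- c(deviations, res3$dose_deviation)
      worst <- max(worst, 3L)
      trace <- c(trace, sprintf("split %s: %s", ing$parent, res3$trace))
      next
    }
    # all-or-nothing: one unresolved component fails the whole split
    return(new_switch_result(
      5L, p, warnings = list(warning_note(
        "combination", sprintf("component '%s' has no formulary match", ing$parent))),
      trace = c(trace, sprintf("split %s: unmatched; split abandoned", ing$parent))))
  }
  new_switch_result(worst, p, suggestions = suggestions, warnings = warnings,
                    dose_deviation = deviations,
                    trace = c(trace, sprintf("split: all %d components resolved",
                                             length(src$ingredients))))
}

#' Switch a whole consultation
#'
#' Applies [switch_prescription()] to every line of a medication list,
#' preserving order, and attaches per-group summary counts.
#'
#' @param ps list of [prescription()] objects.
#' @inheritParams switch_prescription
#' @return list of `switch_result` with attribute `summary`, a named
#'   integer vector of counts for groups 1-5.
#' @export
switch_consultation <- function(ps, cat, kb = default_kb(),
                                cfg = engine_config()) {
  results <- lapply(ps, switch_prescription, cat = cat, kb = kb, cfg = cfg)
  groups <- vapply(results, `[[`, integer(1), "group")
  attr(results, "summary") <- vapply(1:5, function(g) sum(groups == g),
                                     integer(1)) |>
    setNames(paste0("group", 1:5))
  results
}
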