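# Dose-scheme representation and regimen arithmetic: parsing the
# morning-noon-evening-night notation, total daily dose, and redistribution
# of a target daily dose onto a candidate product's strength grid.

#' Dose regimen
#'
#' Four administration slots (morning, noon, evening, night) in dose units.
#' A scheme that could not be parsed is carried as free text and flagged,
#' never dropped: downstream the engine routes flagged prescriptions to
#' manual handling.
#'
#' @param slots numeric vector of 4 non-negative slot doses.
#' @param free_text_flag `TRUE` for unparseable schemes.
#' @param text original scheme string, kept for display.
#' @return object of class `regimen`.
#' @export
regimen <- function(slots = c(0, 0, 0, 0), free_text_flag = FALSE, text = NULL) {
  slots <- as.numeric(slots)
  if (length(slots) != 4L || any(is.na(slots)) || any(slots < 0))
    stop_rxswitch("regimen needs 4 non-negative slot doses", "rxswitch_invalid")
  if (!free_text_flag && all(slots == 0))
    stop_rxswitch("a parsed regimen needs at least one non-zero slot",
                  "rxswitch_invalid")
  structure(list(slots = slots, free_text_flag = isTRUE(free_text_flag),
                 text = text %||% format_scheme_slots(slots)),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  if (x$free_text_flag) {
    cat(sprintf("<regimen> free text: \"%s\"\n", x$text))
  } else {
    cat(sprintf("<regimen> %s (%g units/day)\n", format_scheme(x), sum(x$slots)))
  }
  invisible(x)
}

parse_slot <- function(token) {
  token <- trimws(token)
  if (grepl("^[0-9]+/[0-9]+$", token)) {
    parts <- as.numeric(strsplit(token, "/", fixed = TRUE)[[1]])
    if (parts[2] == 0) return(NA_real_)
    return(parts[1] / parts[2])
  }
  if (grepl("^[0-9]+([.][0-9]+)?$", token)) return(as.numeric(token))
  NA_real_
}

#' Parse a dose-scheme string
#'
#' Understands the dash-separated daily notation used on German
#' prescriptions: `"a-b-c"` (morning-noon-evening) and `"a-b-c-d"` (plus
#' night). Slots may be integers, decimals (`0.5`) or fractions (`1/2`,
#' `3/2`). Anything else — free-text instructions, missing schemes —
#' produces a regimen with `free_text_flag = TRUE`.
#'
#' @param text scheme string.
#' @return a [regimen()].
#' @examples
#' parse_scheme("1-0-1")$slots
#' parse_scheme("1/2-0-1/2")$slots
#' parse_scheme("2 Hub morgens")$free_text_flag
#' @export
parse_scheme <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text)))
    return(regimen(free_text_flag = TRUE, text = text %||% ""))
  tokens <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  if (!length(tokens) %in% c(3L, 4L))
    return(regimen(free_text_flag = TRUE, text = text))
  slots <- vapply(tokens, parse_slot, numeric(1))
  if (any(is.na(slots)) || all(slots == 0))
    return(regimen(free_text_flag = TRUE, text = text))
  if (length(slots) == 3L) slots <- c(slots, 0)
  regimen(slots, text = text)
}

format_slot <- function(x) {
  if (near(x, round(x))) return(format(round(x), scientific = FALSE))
  # quarters grid: express as a reduced fraction over 4
  num <- round(x * 4)
  den <- 4
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(num, den)
  sprintf("%d/%d", num %/% d, den %/% d)
}

format_scheme_slots <- function(slots) {
  paste(vapply(slots, format_slot, character(1)), collapse = "-")
}

#' Serialize a regimen back to scheme notation
#'
#' Fractions print as `1/2`, `1/4`, `3/2`, ... on the quarter grid.
#'
#' @param reg a [regimen()].
#' @return scheme string `"a-b-c-d"`; free-text regimens return their
#'   original text.
#' @export
format_scheme <- function(reg) {
  if (reg$free_text_flag) return(reg$text)
  format_scheme_slots(reg$slots)
}

#' Prescription
#'
#' One line of a patient's medication list: a product (resolved against a
#' catalogue, or an unresolved free-text descriptor) plus a dose regimen.
#'
#' @param product a [drug_product()], or `NULL` when unresolved.
#' @param regimen a [regimen()].
#' @param descriptor free-text drug description for unresolved lines.
#' @return object of class `prescription`; `resolved` is `TRUE` when a
#'   product is attached and the regimen parsed.
#' @export
prescription <- function(product = NULL, regimen, descriptor = NULL) {
  if (!is.null(product) && !inherits(product, "drug_product"))
    stop_rxswitch("product must be a drug_product or NULL", "rxswitch_invalid")
  if (!inherits(regimen, "regimen"))
    stop_rxswitch("regimen must be a regimen object", "rxswitch_invalid")
  structure(list(
    product = product,
    regimen = regimen,
    descriptor = descriptor %||% if (!is.null(product)) product$brand_name else "",
    resolved = !is.null(product) && !regimen$free_text_flag
  ), class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("<prescription> %s, %s%s\n",
              if (!is.null(x$product)) x$product$brand_name else x$descriptor,
              format_scheme(x$regimen),
              if (x$resolved) "" else " [unresolved]"))
  invisible(x)
}

#' Total daily dose of one ingredient
#'
#' Sum of slot doses times the product's strength for that ingredient,
#' after unit normalization (mass in mg; IU on the IU scale).
#'
#' @param p a resolved [prescription()].
#' @param parent normalized ingredient name; defaults to the product's
#'   first (or only) ingredient.
#' @return daily dose in mg (or IU for IU-dosed ingredients).
#' @examples
#' simva <- drug_product("p1", "Simva 20", ingredient_strength("simvastatin", 20),
#'                       "tablet", atc_codes = "C10AA01")
#' total_daily_dose(prescription(simva, parse_scheme("1-0-0")))  # 20
#' @export
total_daily_dose <- function(p, parent = NULL) {
  if (!inherits(p, "prescription") || !p$resolved)
    stop_rxswitch("total_daily_dose needs a resolved prescription",
                  "rxswitch_invalid")
  if (is.null(parent)) parent <- p$product$ingredients[[1]]$parent
  ps <- parent_strength(p$product, parent)
  if (is.null(ps))
    stop_rxswitch(sprintf("ingredient '%s' not in product '%s'", parent,
                          p$product$product_id), "rxswitch_invalid")
  sum(p$regimen$slots) * ps$amount
}

# --- redistribution -------------------------------------------------------

# Slots are capped at 4 dose units each; together with quarter divisibility
# this keeps the scheme space small enough for the exhaustive test oracle
# while covering realistic oral regimens.
.max_units_per_slot <- 4

#' Redistribute a target daily dose onto a candidate product
#'
#' Finds the administration scheme on the candidate's strength and
#' divisibility grid whose achieved daily dose is closest to the target.
#' Among schemes with equal (minimal) relative deviation the simplest is
#' preferred: fewest administrations per day, then fewest split (fractional)
#' dose units, then doses placed in earlier slots. A result whose deviation
#' exceeds `max_dose_deviation` is reported infeasible rather than silently
#' approximated, so the engine can demote the switch to manual handling.
#'
#' @param target_tdd positive target daily dose (mg, or IU for IU drugs).
#' @param candidate a `drug_product` carrying `parent`.
#' @param parent ingredient whose dose is being matched; defaults to the
#'   candidate's first ingredient.
#' @param max_dose_deviation maximum tolerated relative deviation of the
#'   achieved from the target daily dose (default 0.10).
#' @return list with `feasible`; when feasible also `regimen`, `achieved`
#'   (daily dose), `deviation` (relative), and `split` (`TRUE` when any
#'   slot is fractional, i.e. tablet splitting is required).
#' @examples
#' prava <- drug_product("p2", "Prava 40", ingredient_strength("pravastatin", 40),
#'                       "tablet", on_hdf = TRUE)
#' redistribute(40, prava)$regimen$slots  # 1 0 0 0
#' @export
redistribute <- function(target_tdd, candidate, parent = NULL,
                         max_dose_deviation = 0.10) {
  if (!is.numeric(target_tdd) || target_tdd <= 0)
    stop_rxswitch("target_tdd must be > 0", "rxswitch_invalid")
  if (is.null(parent)) parent <- candidate$ingredients[[1]]$parent
  ps <- parent_strength(candidate, parent)
  if (is.null(ps))
    stop_rxswitch(sprintf("ingredient '%s' not in candidate '%s'", parent,
                          candidate$product_id), "rxswitch_invalid")
  strength <- ps$amount
  div <- candidate$divisibility
  # achieved dose depends only on the total daily units, a multiple of 1/div
  # in (0, 4 slots x 4 units]; pick the best total, then lay it out.
  step <- 1 / div
  totals <- seq(step, 4 * .max_units_per_slot, by = step)
  devs <- abs(totals * strength - target_tdd) / target_tdd
  best <- min(devs)
  if (best > max_dose_deviation + 1e-12) {
    return(list(feasible = FALSE, best_deviation = best))
  }
  # ties on deviation (under- vs overdose equidistant, or split vs whole):
  # prefer fewest administrations, then no split units, then the smaller
  # total (underdosing over overdosing).
  tying <- totals[near(devs, best)]
  n_admin <- ceiling(tying / .max_units_per_slot - 1e-12)
  has_frac <- !near(tying, round(tying))
  total <- tying[order(n_admin, has_frac, tying)][1]
  slots <- c(0, 0, 0, 0)
  remaining <- total
  for (i in 1:4) {                      # greedy earliest-slot fill
    take <- min(remaining, .max_units_per_slot)
    slots[i] <- take
    remaining <- remaining - take
    if (remaining <= 1e-12) break
  }
  reg <- regimen(slots)
  list(feasible = TRUE, regimen = reg, achieved = total * strength,
       deviation = best, split = any(!near(slots, round(slots))))
}
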