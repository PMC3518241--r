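# Shared builders and independent brute-force oracles for the test suite.

mk <- function(id, parent, amount, on_hdf = FALSE, form = "tablet",
               release = "immediate", route = "oral", atc = "C10AA01",
               ind = "hypercholesterolemia", div = 2, brand = NULL,
               unit = "mg") {
  drug_product(id, brand %||% paste("Brand", id),
               ingredient_strength(parent, amount, unit), form,
               release = release, route = route, atc_codes = atc,
               indications = ind, on_hdf = on_hdf, divisibility = div)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random single- and two-ingredient catalogue for property tests.
random_catalogue <- function(n, seed) {
  set.seed(seed)
  parents <- sprintf("par%02d", 1:6)
  forms <- c("tablet", "capsule", "solution", "injection")
  routes <- c(tablet = "oral", capsule = "oral", solution = "oral",
              injection = "parenteral")
  products <- lapply(seq_len(n), function(i) {
    n_ing <- if (runif(1) < 0.15) 2L else 1L
    pars <- sample(parents, n_ing)
    ings <- lapply(pars, function(p)
      ingredient_strength(p, sample(c(5, 10, 20, 40, 78.09, 77.82), 1)))
    form <- sample(forms, 1)
    drug_product(sprintf("R%03d", i), sprintf("Rand %03d", i), ings, form,
                 release = sample(c("immediate", "modified"), 1),
                 route = unname(routes[form]),
                 atc_codes = sample(c("C10AA01", "C07AB02", "A02BC02"), 1),
                 indications = sample(c("a", "b"), 1),
                 on_hdf = runif(1) < 0.5,
                 divisibility = sample(c(1L, 2L, 4L), 1))
  })
  catalogue(products)
}

# Independent brute-force scan for the pharmaceutical-equivalent predicate.
oracle_equivalents <- function(source, cat, rel_tol = 0) {
  hit <- character()
  src_par <- sort(vapply(source$ingredients, `[[`, character(1), "parent"))
  for (p in cat$products) {
    if (!p$on_hdf || p$product_id == source$product_id) next
    if (p$form_group != source$form_group || p$release != source$release ||
        p$route != source$route) next
    cand_par <- sort(vapply(p$ingredients, `[[`, character(1), "parent"))
    if (!identical(src_par, cand_par)) next
    ok <- TRUE
    for (ing in source$ingredients) {
      match_amt <- NA_real_
      for (c_ing in p$ingredients) {
        if (c_ing$parent == ing$parent && c_ing$is_iu == ing$is_iu)
          match_amt <- c_ing$amount_norm
      }
      if (is.na(match_amt) ||
          abs(match_amt - ing$amount_norm) / ing$amount_norm > rel_tol + 1e-12)
        ok <- FALSE
    }
    if (ok) hit <- c(hit, p$product_id)
  }
  sort(hit)
}

# Independent brute-force scan for the pharmaceutical-alternative predicate.
oracle_alternatives <- function(source, cat, rel_tol = 0) {
  hit <- character()
  src_par <- sort(vapply(source$ingredients, `[[`, character(1), "parent"))
  equivalents <- oracle_equivalents(source, cat, rel_tol)
  for (p in cat$products) {
    if (!p$on_hdf || p$product_id == source$product_id) next
    if (p$form_group != source$form_group || p$release != source$release ||
        p$route != source$route) next
    cand_par <- sort(vapply(p$ingredients, `[[`, character(1), "parent"))
    if (!identical(src_par, cand_par)) next
    units_ok <- all(vapply(source$ingredients, function(ing) {
      any(vapply(p$ingredients, function(c_ing)
        c_ing$parent == ing$parent && c_ing$is_iu == ing$is_iu, logical(1)))
    }, logical(1)))
    if (units_ok && !(p$product_id %in% equivalents))
      hit <- c(hit, p$product_id)
  }
  sort(hit)
}

# Exhaustive-search oracle for dose redistribution: enumerates every scheme
# on the divisibility grid with at most 4 units per slot.
oracle_redistribute <- function(target_tdd, strength, div, max_dev = 0.10) {
  grid <- seq(0, 4, by = 1 / div)
  schemes <- as.matrix(expand.grid(grid, grid, grid, grid))
  totals <- rowSums(schemes)
  keep <- totals > 0
  schemes <- schemes[keep, , drop = FALSE]
  totals <- totals[keep]
  dev <- abs(totals * strength - target_tdd) / target_tdd
  feasible <- dev <= max_dev + 1e-12
  if (!any(feasible)) return(list(feasible = FALSE, best_deviation = min(dev)))
  schemes <- schemes[feasible, , drop = FALSE]
  dev <- dev[feasible]
  n_admin <- rowSums(schemes > 0)
  n_frac <- rowSums(abs(schemes - round(schemes)) > 1e-9)
  # earlier-slot preference: larger doses in earlier slots
  ord <- order(dev, n_admin, n_frac, rowSums(schemes),
               -schemes[, 1], -schemes[, 2], -schemes[, 3], -schemes[, 4])
  best <- schemes[ord[1], ]
  list(feasible = TRUE, slots = unname(best), deviation = dev[ord[1]],
       achieved = sum(best) * strength)
}
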