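# Drug-product data model and indexed queries over the market catalogue and
# its hospital-drug-formulary (HDF) subset.

# Dosage-form -> comparability group. "Comparable dosage forms" is
# operationalized as membership in the same group: the oral solids (plain,
# coated and film-coated tablets, capsules) are mutually comparable; liquids,
# injectables and inhalations each form their own group. Release
# characteristics are carried separately and must match exactly, so a
# modified-release product is never comparable to an immediate-release one.
.default_form_groups <- c(
  "tablet"             = "oral-solid",
  "coated-tablet"      = "oral-solid",
  "film-coated-tablet" = "oral-solid",
  "capsule"            = "oral-solid",
  "solution"           = "oral-liquid",
  "suspension"         = "oral-liquid",
  "injection"          = "injection",
  "infusion"           = "injection",
  "inhalation"         = "inhalation",
  "patch"              = "topical",
  "ointment"           = "topical"
)

#' Default dosage-form comparability mapping
#'
#' @return named character vector mapping dosage-form codes to
#'   comparability groups. Override by passing a modified copy to
#'   [drug_product()] / [load_catalogue()].
#' @export
default_form_groups <- function() .default_form_groups

.release_levels <- c("immediate", "modified")
.route_levels <- c("oral", "parenteral", "inhaled", "topical", "other")
.unit_levels <- c("mg", "microgram", "IU")

#' Ingredient strength record
#'
#' One active ingredient of a product: the normalized moiety (parent), the
#' stripped salt/ester descriptor, and the amount per dose unit.
#'
#' @param name ingredient name as labelled (salt included, any case).
#' @param amount positive numeric amount per dose unit.
#' @param unit one of `"mg"`, `"microgram"`, `"IU"`.
#' @return object of class `ingredient_strength`: list with `parent`,
#'   `salt`, `amount`, `unit`, and `amount_norm` (mg for mass units; IU
#'   amounts are kept on the IU scale and flagged by `is_iu`).
#' @export
ingredient_strength <- function(name, amount, unit = "mg") {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop_rxswitch("ingredient name must be a non-empty string", "rxswitch_invalid")
  amount <- suppressWarnings(as.numeric(amount))
  if (is.na(amount) || amount <= 0)
    stop_rxswitch(sprintf("ingredient '%s': amount must be > 0", name),
                  "rxswitch_invalid")
  unit <- as.character(unit)
  if (!unit %in% .unit_levels)
    stop_rxswitch(sprintf("ingredient '%s': unit must be one of %s", name,
                          paste(.unit_levels, collapse = ", ")),
                  "rxswitch_invalid")
  np <- normalize_parent(name)
  structure(list(
    parent = np$parent, salt = np$salt, amount = amount, unit = unit,
    amount_norm = normalize_amount(amount, unit), is_iu = unit == "IU"
  ), class = "ingredient_strength")
}

#' Drug product record
#'
#' One marketed brand: its active ingredients with strengths, dosage form,
#' release type, route, ATC classification, labelled indications, formulary
#' status and divisibility of one dose unit.
#'
#' @param product_id unique opaque identifier.
#' @param brand_name display string.
#' @param ingredients list of [ingredient_strength()] objects (length >= 1).
#' @param dosage_form controlled form code (see [default_form_groups()]).
#' @param release `"immediate"` or `"modified"`.
#' @param route one of oral, parenteral, inhaled, topical, other.
#' @param atc_codes character vector of ATC codes, levels 4-5.
#' @param indications character vector of controlled indication tokens.
#' @param on_hdf logical: listed on the hospital drug formulary?
#' @param divisibility smallest administrable fraction of a dose unit as its
#'   reciprocal: 1 (indivisible), 2 (halves) or 4 (quarters).
#' @param form_groups mapping used to derive the comparability group.
#' @return object of class `drug_product`.
#' @export
drug_product <- function(product_id, brand_name, ingredients, dosage_form,
                         release = "immediate", route = "oral",
                         atc_codes = character(), indications = character(),
                         on_hdf = FALSE, divisibility = 1,
                         form_groups = default_form_groups()) {
  if (!is.character(product_id) || length(product_id) != 1L || !nzchar(product_id))
    stop_rxswitch("product_id must be a non-empty string", "rxswitch_invalid")
  if (inherits(ingredients, "ingredient_strength")) ingredients <- list(ingredients)
  if (length(ingredients) < 1L)
    stop_rxswitch(sprintf("product '%s': needs at least one ingredient", product_id),
                  "rxswitch_invalid")
  ok <- vapply(ingredients, inherits, logical(1), "ingredient_strength")
  if (!all(ok))
    stop_rxswitch(sprintf("product '%s': ingredients must be ingredient_strength objects",
                          product_id), "rxswitch_invalid")
  if (!release %in% .release_levels)
    stop_rxswitch(sprintf("product '%s': release must be immediate or modified",
                          product_id), "rxswitch_invalid")
  if (!route %in% .route_levels)
    stop_rxswitch(sprintf("product '%s': unknown route '%s'", product_id, route),
                  "rxswitch_invalid")
  atc_codes <- toupper(as.character(atc_codes))
  bad <- atc_codes[!is_valid_atc(atc_codes)]
  if (length(bad))
    stop_rxswitch(sprintf("product '%s': malformed ATC code(s): %s", product_id,
                          paste(bad, collapse = ", ")), "rxswitch_invalid")
  divisibility <- as.integer(divisibility)
  if (!divisibility %in% c(1L, 2L, 4L))
    stop_rxswitch(sprintf("product '%s': divisibility must be 1, 2 or 4", product_id),
                  "rxswitch_invalid")
  if (!dosage_form %in% names(form_groups))
    stop_rxswitch(sprintf("product '%s': unknown dosage form '%s'", product_id,
                          dosage_form), "rxswitch_invalid")
  structure(list(
    product_id = product_id,
    brand_name = as.character(brand_name),
    ingredients = ingredients,
    dosage_form = dosage_form,
    form_group = unname(form_groups[[dosage_form]]),
    release = release,
    route = route,
    atc_codes = atc_codes,
    indications = sort(unique(tolower(as.character(indications)))),
    on_hdf = isTRUE(as.logical(on_hdf)),
    divisibility = divisibility
  ), class = "drug_product")
}

#' @export
print.drug_product <- function(x, ...) {
  ing <- vapply(x$ingredients, function(i)
    sprintf("%s %g %s", i$parent, i$amount, i$unit), character(1))
  cat(sprintf("<drug_product %s> %s [%s; %s %s %s; ATC %s; %s]\n",
              x$product_id, x$brand_name, paste(ing, collapse = " + "),
              x$dosage_form, x$release, x$route,
              paste(x$atc_codes, collapse = ","),
              if (x$on_hdf) "HDF" else "non-HDF"))
  invisible(x)
}

# Canonical key for a product's parent multiset (sorted, "+"-joined).
parent_key <- function(product) {
  paste(sort(vapply(product$ingredients, `[[`, character(1), "parent")),
        collapse = "+")
}

# Strength of `parent` in the product on the normalized scale, with the IU
# flag; NULL if the parent is absent.
parent_strength <- function(product, parent) {
  for (ing in product$ingredients) {
    if (ing$parent == parent)
      return(list(amount = ing$amount_norm, is_iu = ing$is_iu, salt = ing$salt))
  }
  NULL
}

#' Build a catalogue from drug products
#'
#' @param products list of [drug_product()] objects with unique ids.
#' @return object of class `drug_catalogue`: products keyed by id plus a
#'   data-frame index used by the queries.
#' @export
catalogue <- function(products = list()) {
  if (inherits(products, "drug_product")) products <- list(products)
  ids <- vapply(products, `[[`, character(1), "product_id")
  if (anyDuplicated(ids))
    stop_rxswitch(sprintf("duplicate product_id: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                  "rxswitch_invalid")
  names(products) <- ids
  index <- data.frame(
    product_id = ids,
    parent_key = vapply(products, parent_key, character(1)),
    n_ingredients = vapply(products, function(p) length(p$ingredients), integer(1)),
    form_group = vapply(products, `[[`, character(1), "form_group"),
    release = vapply(products, `[[`, character(1), "release"),
    route = vapply(products, `[[`, character(1), "route"),
    on_hdf = vapply(products, `[[`, logical(1), "on_hdf"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(products = products, index = index), class = "drug_catalogue")
}

#' @export
print.drug_catalogue <- function(x, ...) {
  cat(sprintf("<drug_catalogue> %d products (%d on HDF)\n",
              nrow(x$index), sum(x$index$on_hdf)))
  invisible(x)
}

#' @export
length.drug_catalogue <- function(x) nrow(x$index)

#' Number of formulary products in a catalogue
#' @param cat a `drug_catalogue`.
#' @return integer count of products with `on_hdf = TRUE`.
#' @export
hdf_count <- function(cat) sum(cat$index$on_hdf)

#' Look up a product by id
#' @param cat a `drug_catalogue`.
#' @param product_id identifier string.
#' @return the `drug_product`, or `NULL` if absent.
#' @export
get_product <- function(cat, product_id) cat$products[[product_id]]

# --- file i/o -------------------------------------------------------------

# Delimited dialect: UTF-8, semicolon-separated, mandatory header, decimal
# point. Ingredients serialized "parent:amount:unit[:salt]" joined by "+".
.catalogue_columns <- c("product_id", "brand_name", "ingredients", "dosage_form",
                        "release", "route", "atc_codes", "indications",
                        "on_hdf", "divisibility")

parse_ingredient_token <- function(token) {
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3L || length(parts) > 4L)
    stop_rxswitch(sprintf("malformed ingredient token '%s'", token),
                  "rxswitch_parse")
  name <- if (length(parts) == 4L && nzchar(parts[4])) {
    paste(parts[1], parts[4])
  } else {
    parts[1]
  }
  amount <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(amount))
    stop_rxswitch(sprintf("non-numeric amount in ingredient token '%s'", token),
                  "rxswitch_parse")
  ingredient_strength(name, amount, parts[3])
}

row_to_product <- function(row, form_groups) {
  tokens <- strsplit(row[["ingredients"]], "+", fixed = TRUE)[[1]]
  ings <- lapply(trimws(tokens), parse_ingredient_token)
  split_list <- function(x) {
    x <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    x[nzchar(x)]
  }
  drug_product(
    product_id = row[["product_id"]],
    brand_name = row[["brand_name"]],
    ingredients = ings,
    dosage_form = row[["dosage_form"]],
    release = row[["release"]],
    route = row[["route"]],
    atc_codes = split_list(row[["atc_codes"]]),
    indications = split_list(row[["indications"]]),
    on_hdf = row[["on_hdf"]] %in% c("1", "true", "TRUE"),
    divisibility = row[["divisibility"]],
    form_groups = form_groups
  )
}

#' Load a drug catalogue from a file
#'
#' Two dialects are accepted: semicolon-delimited text with a mandatory
#' header (columns `product_id; brand_name; ingredients; dosage_form;
#' release; route; atc_codes; indications; on_hdf; divisibility`, with
#' ingredients as `parent:amount:unit` tokens joined by `+`), or a JSON
#' array of objects with the same field names. JSON Schema documents for
#' both dialects ship under `inst/extdata/`.
#'
#' @param path file path (`.json` extension selects the JSON dialect).
#' @param strict if `TRUE` any invalid row aborts the load; otherwise
#'   invalid rows are skipped, counted and reported via the
#'   `skipped` attribute.
#' @param form_groups dosage-form comparability mapping.
#' @return a `drug_catalogue`; attribute `skipped` holds a character vector
#'   of per-row error messages for rows rejected in non-strict mode.
#' @export
load_catalogue <- function(path, strict = TRUE,
                           form_groups = default_form_groups()) {
  if (!file.exists(path))
    stop_rxswitch(sprintf("catalogue file not found: %s", path), "rxswitch_io")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(recs, function(r) {
      r$ingredients <- if (is.character(r$ingredients)) r$ingredients else
        paste(unlist(r$ingredients), collapse = "+")
      r$atc_codes <- paste(unlist(r$atc_codes), collapse = ",")
      r$indications <- paste(unlist(r$indications), collapse = ",")
      vapply(.catalogue_columns, function(col)
        as.character(r[[col]] %||% ""), character(1))
    })
  } else {
    tab <- read.delim(path, sep = ";", header = TRUE, colClasses = "character",
                      fileEncoding = "UTF-8", strip.white = TRUE)
    missing_cols <- setdiff(.catalogue_columns, names(tab))
    if (length(missing_cols))
      stop_rxswitch(sprintf("catalogue header missing column(s): %s",
                            paste(missing_cols, collapse = ", ")), "rxswitch_parse")
    rows <- lapply(seq_len(nrow(tab)), function(i)
      vapply(.catalogue_columns, function(col) tab[i, col], character(1)))
  }
  products <- list()
  skipped <- character()
  for (i in seq_along(rows)) {
    prod <- tryCatch(row_to_product(as.list(rows[[i]]), form_groups),
                     rxswitch_error = function(e) e)
    if (inherits(prod, "error")) {
      msg <- sprintf("row %d: %s", i, conditionMessage(prod))
      if (strict) stop_rxswitch(msg, "rxswitch_parse")
      skipped <- c(skipped, msg)
    } else {
      if (prod$product_id %in% names(products)) {
        msg <- sprintf("row %d: duplicate product_id '%s'", i, prod$product_id)
        if (strict) stop_rxswitch(msg, "rxswitch_parse")
        skipped <- c(skipped, msg)
      } else {
        products[[prod$product_id]] <- prod
      }
    }
  }
  out <- catalogue(unname(products))
  attr(out, "skipped") <- skipped
  out
}

format_ingredient_token <- function(ing) {
  base <- sprintf("%s:%s:%s", ing$parent, format(ing$amount, scientific = FALSE),
                  ing$unit)
  if (nzchar(ing$salt)) paste0(base, ":", ing$salt) else base
}

#' Write a catalogue to the delimited dialect
#'
#' @param cat a `drug_catalogue`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  rows <- vapply(cat$products, function(p) {
    paste(c(
      p$product_id, p$brand_name,
      paste(vapply(p$ingredients, format_ingredient_token, character(1)),
            collapse = "+"),
      p$dosage_form, p$release, p$route,
      paste(p$atc_codes, collapse = ","),
      paste(p$indications, collapse = ","),
      if (p$on_hdf) "1" else "0",
      as.character(p$divisibility)
    ), collapse = ";")
  }, character(1))
  writeLines(c(paste(.catalogue_columns, collapse = ";"), unname(rows)), path,
             useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- queries --------------------------------------------------------------

# Do two products share the same parent multiset with every per-parent
# strength within relative tolerance? IU strengths compare only to IU.
strengths_match <- function(source, candidate, rel_tol) {
  key_s <- parent_key(source)
  if (key_s != parent_key(candidate)) return(FALSE)
  for (ing in source$ingredients) {
    cand <- parent_strength(candidate, ing$parent)
    if (is.null(cand) || cand$is_iu != ing$is_iu) return(FALSE)
    dev <- abs(cand$amount - ing$amount_norm) / ing$amount_norm
    if (dev > rel_tol + 1e-12) return(FALSE)
  }
  TRUE
}

# Mean relative strength deviation across parents (ranking key).
strength_deviation <- function(source, candidate) {
  devs <- vapply(source$ingredients, function(ing) {
    cand <- parent_strength(candidate, ing$parent)
    if (is.null(cand)) return(NA_real_)
    abs(cand$amount - ing$amount_norm) / ing$amount_norm
  }, numeric(1))
  mean(devs)
}

# Shared predicate: same form group, same release, same route, on HDF,
# not the source itself.
comparable_hdf <- function(source, candidate) {
  candidate$on_hdf &&
    candidate$product_id != source$product_id &&
    candidate$form_group == source$form_group &&
    candidate$release == source$release &&
    candidate$route == source$route
}

#' Pharmaceutical equivalents on the formulary
#'
#' Formulary products with the same active moieties at the same strengths
#' (within `rel_tol` after unit normalization) in a comparable application
#' form: same form group, same release type, same route. The source product
#' itself is never returned. Results are ranked by smallest mean relative
#' strength deviation, then product id, so the order is independent of
#' catalogue row order.
#'
#' @param source a `drug_product`.
#' @param cat a `drug_catalogue`.
#' @param rel_tol non-negative relative strength tolerance. The default 0
#'   requires exact strength identity; 0.01 absorbs salt-rounding
#'   differences such as 78.09 vs 77.82 mg metoprolol.
#' @return list of `drug_product` (possibly empty).
#' @export
equivalents_query <- function(source, cat, rel_tol = 0) {
  if (rel_tol < 0) stop_rxswitch("rel_tol must be >= 0", "rxswitch_invalid")
  hits <- Filter(function(p) {
    comparable_hdf(source, p) && strengths_match(source, p, rel_tol)
  }, cat$products)
  rank_products(source, hits)
}

#' Pharmaceutical alternatives on the formulary
#'
#' Formulary products with the same active moieties in a comparable form
#' (same form group, release, route) but at strengths differing beyond the
#' equivalence tolerance; switching to one requires dose-regimen
#' recomputation. Disjoint from [equivalents_query()] by construction.
#'
#' @inheritParams equivalents_query
#' @return list of `drug_product`, ranked by smallest mean relative
#'   strength deviation then product id.
#' @export
alternatives_query <- function(source, cat, rel_tol = 0) {
  hits <- Filter(function(p) {
    comparable_hdf(source, p) &&
      parent_key(p) == parent_key(source) &&
      all(vapply(source$ingredients, function(ing) {
        cand <- parent_strength(p, ing$parent)
        !is.null(cand) && cand$is_iu == ing$is_iu
      }, logical(1))) &&
      !strengths_match(source, p, rel_tol)
  }, cat$products)
  rank_products(source, hits)
}

rank_products <- function(source, hits) {
  if (length(hits) == 0L) return(list())
  devs <- vapply(hits, function(p) strength_deviation(source, p), numeric(1))
  ids <- vapply(hits, `[[`, character(1), "product_id")
  unname(hits[order(devs, ids)])
}
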