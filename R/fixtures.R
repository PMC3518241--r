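# Deterministic synthetic generator for catalogues, knowledge bases and
# consultations with constructed ground truth. Each generated source drug is
# engineered to have exactly one intended resolution path (on formulary /
# equivalent only / alternative only / therapeutic only / none), so the
# engine's group assignment can be verified against the manifest.

#' Generator specification
#'
#' Defaults emulate the statistical shape of a routine admission-switching
#' service on surgical wards: consultations carry 7.5 +/- 3.9 drugs
#' (truncated at 1), 12.2% of prescriptions are incomplete (missing scheme
#' or unidentifiable brand), and the outcome mix matches a mature formulary
#' service — 31.7% of drugs already on the formulary, 40.7% with a
#' pharmaceutical equivalent, 12.2% with a pharmaceutical alternative, 7.0%
#' with a therapeutic equivalent, 8.4% unswitchable.
#'
#' @param seed integer seed; every artifact is reproducible from it.
#' @param n_products catalogue size.
#' @param hdf_fraction probability that a source drug is itself on the
#'   formulary (the group-1 share). The remaining probability mass is
#'   distributed over the other four outcomes in proportion to
#'   `p_equivalent : p_alternative : p_therapeutic : p_unswitchable`, so
#'   `hdf_fraction = 1` yields an all-formulary catalogue.
#' @param p_equivalent,p_alternative,p_therapeutic,p_unswitchable target
#'   outcome mix for generated source drugs.
#' @param drugs_per_consultation_mean,drugs_per_consultation_sd size
#'   distribution of a consultation (normal, truncated at 1).
#' @param incomplete_rate fraction of prescriptions rendered unresolvable.
#' @param n_consultations number of consultations to generate.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1, n_products = 100,
                           hdf_fraction = 0.317,
                           p_equivalent = 0.407, p_alternative = 0.122,
                           p_therapeutic = 0.070, p_unswitchable = 0.084,
                           drugs_per_consultation_mean = 7.5,
                           drugs_per_consultation_sd = 3.9,
                           incomplete_rate = 0.122,
                           n_consultations = 20) {
  probs <- c(hdf_fraction, p_equivalent, p_alternative, p_therapeutic,
             p_unswitchable)
  if (any(probs < 0) || any(probs > 1))
    stop_rxswitch("probabilities must lie in [0, 1]", "rxswitch_invalid")
  if (sum(probs[-1]) > 1 + 1e-9)
    stop_rxswitch("group mix must sum to at most 1", "rxswitch_invalid")
  if (drugs_per_consultation_sd < 0 || drugs_per_consultation_mean < 1)
    stop_rxswitch("consultation size distribution invalid", "rxswitch_invalid")
  structure(list(
    seed = as.integer(seed), n_products = as.integer(n_products),
    hdf_fraction = hdf_fraction, p_equivalent = p_equivalent,
    p_alternative = p_alternative, p_therapeutic = p_therapeutic,
    p_unswitchable = p_unswitchable,
    drugs_per_consultation_mean = drugs_per_consultation_mean,
    drugs_per_consultation_sd = drugs_per_consultation_sd,
    incomplete_rate = incomplete_rate,
    n_consultations = as.integer(n_consultations)
  ), class = "generator_spec")
}

# Role probabilities: group 1 takes hdf_fraction; the rest of the mass is
# split over groups 2-5 in proportion to the configured mix.
role_probs <- function(spec) {
  rest <- c(spec$p_equivalent, spec$p_alternative, spec$p_therapeutic,
            spec$p_unswitchable)
  if (sum(rest) == 0) {
    c(1, 0, 0, 0, 0)
  } else {
    c(spec$hdf_fraction, rest / sum(rest) * (1 - spec$hdf_fraction))
  }
}

# Synthetic, collision-free ATC level-4 code per drug family. The fixed
# "QA" tail keeps generated codes clear of the excluded prefixes.
family_atc <- function(i) {
  sprintf("%s%02dQA", LETTERS[(i - 1L) %% 26L + 1L], ((i - 1L) %/% 26L) %% 100L)
}

.fixture_strengths <- c(5, 10, 20, 25, 40, 50, 100)
.fixture_schemes <- c("1-0-0", "1-0-1", "1-1-1")

#' Generate a catalogue and knowledge base with ground truth
#'
#' Builds `spec$n_products` synthetic products organised in independent
#' drug families, each engineered for one outcome: a formulary drug, an
#' off-formulary drug with exactly one pharmaceutical equivalent, one with
#' only a different-strength alternative, one with only a therapeutic
#' equivalent (backed by a generated interchange class with known
#' equipotent doses), or a drug with no formulary relative. A share of the
#' equivalent-path families are two-ingredient combination products whose
#' components resolve to single agents; a share of the unswitchable
#' families are four-ingredient combinations. Families never share
#' parents, ATC codes or indications, so resolution paths cannot interfere.
#'
#' @param spec a [generator_spec()].
#' @return list with `catalogue`, `kb`, and `templates` — a data frame of
#'   plannable source prescriptions with their expected group, suggestion
#'   ids and expected daily dose.
#' @export
generate_catalogue <- function(spec) {
  set.seed(spec$seed)
  probs <- role_probs(spec)
  if (spec$p_therapeutic > 0 && probs[4] > 0 && spec$n_products < 2)
    stop_rxswitch("catalogue too small for a therapeutic family",
                  "rxswitch_invalid")
  products <- list()
  classes <- list()
  templates <- list()
  fam <- 0L
  add <- function(p) products[[length(products) + 1L]] <<- p
  while (length(products) < spec$n_products) {
    fam <- fam + 1L
    remaining <- spec$n_products - length(products)
    role <- sample.int(5L, 1L, prob = probs)
    need <- c(1L, 2L, 2L, 2L, 1L)[role]
    if (need > remaining) role <- if (probs[1] > 0) 1L else 5L
    parent <- sprintf("drug%04da", fam)
    atc <- family_atc(fam)
    ind <- sprintf("ind%04d", fam)
    strength <- sample(.fixture_strengths, 1L)
    scheme <- sample(.fixture_schemes, 1L)
    slots_sum <- sum(parse_scheme(scheme)$slots)
    tdd <- slots_sum * strength
    id_src <- sprintf("P%04dS", fam)

    make_src <- function(on_hdf, ingredients = NULL, form = "tablet",
                         route = "oral", atc_codes = atc) {
      drug_product(id_src, sprintf("Brand %04d", fam),
                   ingredients %||% list(ingredient_strength(parent, strength)),
                   form, release = "immediate", route = route,
                   atc_codes = atc_codes, indications = ind,
                   on_hdf = on_hdf, divisibility = 2)
    }

    if (role == 1L) {                   # already on the formulary
      add(make_src(TRUE))
      expected <- list(group = 1L, sugg = id_src, dose = tdd)
    } else if (role == 2L) {            # exact equivalent on the formulary
      combo <- remaining >= 3L && runif(1) < 0.15
      if (combo) {
        parent2 <- sprintf("drug%04db", fam)
        strength2 <- sample(.fixture_strengths, 1L)
        add(make_src(FALSE, ingredients = list(
          ingredient_strength(parent, strength),
          ingredient_strength(parent2, strength2))))
        id_c1 <- sprintf("P%04dE", fam); id_c2 <- sprintf("P%04dF", fam)
        add(drug_product(id_c1, sprintf("Mono %04da", fam),
                         ingredient_strength(parent, strength), "tablet",
                         atc_codes = atc, indications = ind, on_hdf = TRUE,
                         divisibility = 2))
        add(drug_product(id_c2, sprintf("Mono %04db", fam),
                         ingredient_strength(parent2, strength2), "tablet",
                         atc_codes = atc, indications = ind, on_hdf = TRUE,
                         divisibility = 2))
        expected <- list(group = 2L, sugg = paste(id_c1, id_c2, sep = ";"),
                         dose = tdd)
      } else {
        add(make_src(FALSE))
        id_eq <- sprintf("P%04dE", fam)
        add(drug_product(id_eq, sprintf("Generic %04d", fam),
                         ingredient_strength(parent, strength), "tablet",
                         atc_codes = atc, indications = ind, on_hdf = TRUE,
                         divisibility = 2))
        expected <- list(group = 2L, sugg = id_eq, dose = tdd)
      }
    } else if (role == 3L) {            # different-strength alternative only
      add(make_src(FALSE))
      id_alt <- sprintf("P%04dA", fam)
      # double strength: the daily dose is preserved exactly with half the
      # units, so redistribution is always feasible
      add(drug_product(id_alt, sprintf("Alt %04d", fam),
                       ingredient_strength(parent, 2 * strength), "tablet",
                       atc_codes = atc, indications = ind, on_hdf = TRUE,
                       divisibility = 2))
      expected <- list(group = 3L, sugg = id_alt, dose = tdd)
    } else if (role == 4L) {            # therapeutic equivalent only
      add(make_src(FALSE))
      parent_t <- sprintf("drug%04db", fam)
      factor <- sample(c(0.5, 1, 2), 1L)
      id_ther <- sprintf("P%04dT", fam)
      add(drug_product(id_ther, sprintf("Ther %04d", fam),
                       ingredient_strength(parent_t, tdd * factor), "tablet",
                       atc_codes = atc, indications = ind, on_hdf = TRUE,
                       divisibility = 2))
      classes[[length(classes) + 1L]] <- interchange_class(
        sprintf("class%04d", fam), sprintf("Synthetic class %04d", fam), atc,
        list(interchange_member(parent, setNames(list(tdd), ind)),
             interchange_member(parent_t, setNames(list(tdd * factor), ind))))
      expected <- list(group = 4L, sugg = id_ther, dose = tdd * factor)
    } else {                            # no automatic switch
      flavour <- sample(c("no-relative", "excluded-atc", "non-oral",
                          "many-components"), 1L)
      if (flavour == "excluded-atc") {
        add(make_src(FALSE, atc_codes = "A10AB"))
      } else if (flavour == "non-oral") {
        add(make_src(FALSE, form = "injection", route = "parenteral"))
      } else if (flavour == "many-components") {
        ings <- lapply(1:4, function(k)
          ingredient_strength(sprintf("drug%04d%s", fam, letters[k]),
                              sample(.fixture_strengths, 1L)))
        add(make_src(FALSE, ingredients = ings))
      } else {
        add(make_src(FALSE))
      }
      expected <- list(group = 5L, sugg = "", dose = NA_real_)
    }
    templates[[length(templates) + 1L]] <- data.frame(
      template_id = fam, product_id = id_src, parent = parent,
      scheme = scheme, expected_group = expected$group,
      expected_suggestions = expected$sugg, expected_dose = expected$dose,
      stringsAsFactors = FALSE)
  }
  cat_out <- catalogue(products)
  kb_out <- knowledge_base(classes)
  list(catalogue = cat_out, kb = kb_out,
       templates = do.call(rbind, templates))
}

# One consultation size: normal truncated at 1 (a zero-drug consultation is
# meaningless). sd = 0 degenerates to the rounded mean.
draw_consultation_size <- function(mean, sd) {
  if (sd == 0) return(max(1L, as.integer(round(mean))))
  repeat {
    x <- round(rnorm(1, mean, sd))
    if (x >= 1) return(as.integer(x))
  }
}

#' Generate consultations with a ground-truth manifest
#'
#' Draws consultation sizes from the truncated normal size distribution,
#' samples source drugs from the generated templates, and blanks the
#' configured fraction of prescriptions (scheme removed or brand left
#' unresolved — the ways essential information goes missing on handwritten
#' consultation forms). Consultation sampling uses its own RNG stream
#' (`seed + 1`), so generating consultations never perturbs catalogue
#' generation from the same spec.
#'
#' @param spec a [generator_spec()].
#' @param gen result of [generate_catalogue()] run on the same spec.
#' @return list with `consultations` (list of lists of [prescription()])
#'   and `manifest` — a data frame with one row per prescription:
#'   consultation and position, source product, expected group (5 for
#'   incomplete lines), expected suggestion ids, expected daily dose, and
#'   the `incomplete` flag. Attribute `counts` summarises expected groups.
#' @export
generate_consultations <- function(spec, gen) {
  set.seed(spec$seed + 1L)
  templates <- gen$templates
  consultations <- vector("list", spec$n_consultations)
  rows <- list()
  for (ci in seq_len(spec$n_consultations)) {
    size <- draw_consultation_size(spec$drugs_per_consultation_mean,
                                   spec$drugs_per_consultation_sd)
    idx <- sample.int(nrow(templates), size, replace = TRUE)
    ps <- vector("list", size)
    for (k in seq_len(size)) {
      tpl <- templates[idx[k], ]
      product <- get_product(gen$catalogue, tpl$product_id)
      incomplete <- runif(1) < spec$incomplete_rate
      if (incomplete) {
        if (runif(1) < 0.5) {           # scheme missing
          ps[[k]] <- prescription(product, regimen(free_text_flag = TRUE,
                                                   text = ""))
        } else {                        # brand not identifiable
          ps[[k]] <- prescription(NULL, parse_scheme(tpl$scheme),
                                  descriptor = sprintf("%s (illegible)",
                                                       product$brand_name))
        }
      } else {
        ps[[k]] <- prescription(product, parse_scheme(tpl$scheme))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        consultation = ci, position = k, template_id = tpl$template_id,
        product_id = tpl$product_id, scheme = tpl$scheme,
        incomplete = incomplete,
        expected_group = if (incomplete) 5L else tpl$expected_group,
        expected_suggestions = if (incomplete) "" else tpl$expected_suggestions,
        expected_dose = if (incomplete) NA_real_ else tpl$expected_dose,
        stringsAsFactors = FALSE)
    }
    consultations[[ci]] <- ps
  }
  manifest <- do.call(rbind, rows)
  counts <- vapply(1:5, function(g) sum(manifest$expected_group == g),
                   integer(1))
  attr(manifest, "counts") <- setNames(counts, paste0("group", 1:5))
  list(consultations = consultations, manifest = manifest)
}

#' Write a full synthetic fixture set to disk
#'
#' Emits `catalogue.csv` (delimited catalogue dialect), `kb.yaml`,
#' `consultations.csv` (one prescription per line with consultation id and
#' scheme; incomplete lines have a blank scheme or a brand-only
#' descriptor), `manifest.csv`, and `summary.json` with the declared
#' product, formulary and group counts.
#'
#' @param spec a [generator_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list returned by [generate_catalogue()] plus
#'   `manifest` and `consultations`.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_catalogue(spec)
  cons <- generate_consultations(spec, gen)
  write_catalogue(gen$catalogue, file.path(dir, "catalogue.csv"))
  write_kb(gen$kb, file.path(dir, "kb.yaml"))
  man <- cons$manifest
  lines <- c("consultation_id;brand_or_product_id;scheme")
  for (i in seq_len(nrow(man))) {
    p <- cons$consultations[[man$consultation[i]]][[man$position[i]]]
    ref <- if (!is.null(p$product)) p$product$product_id else p$descriptor
    lines <- c(lines, sprintf("%d;%s;%s", man$consultation[i], ref,
                              if (p$regimen$free_text_flag) "" else
                                format_scheme(p$regimen)))
  }
  writeLines(lines, file.path(dir, "consultations.csv"), useBytes = TRUE)
  write.table(man, file.path(dir, "manifest.csv"), sep = ";",
              row.names = FALSE, quote = TRUE)
  jsonlite::write_json(list(
    seed = spec$seed,
    n_products = length(gen$catalogue),
    n_hdf = hdf_count(gen$catalogue),
    n_classes = length(gen$kb$classes),
    n_prescriptions = nrow(man),
    group_counts = as.list(attr(man, "counts"))
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(gen, cons))
}
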