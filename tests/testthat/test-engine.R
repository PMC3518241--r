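make_demo_world <- function() {
  products <- list(
    mk("hdf_bis", "bisoprolol", 5, on_hdf = TRUE, atc = "C07AB07",
       ind = "hypertension"),
    mk("src_simva", "simvastatin", 20, atc = "C10AA01"),
    mk("hdf_prava", "pravastatin", 40, on_hdf = TRUE, atc = "C10AA03"),
    mk("src_ome", "omeprazole", 20, atc = "A02BC01", ind = "reflux"),
    mk("hdf_ome40", "omeprazole", 40, on_hdf = TRUE, atc = "A02BC01",
       ind = "reflux"),
    mk("src_orphan", "orphandrug", 10, atc = "J01CA04", ind = "infection")
  )
  list(cat = catalogue(products), kb = default_kb())
}

test_that("a formulary drug is returned unchanged as group 1", {
  w <- make_demo_world()
  p <- prescription(get_product(w$cat, "hdf_bis"), parse_scheme("1-0-0"))
  res <- switch_prescription(p, w$cat, w$kb)
  expect_equal(res$group, 1L)
  expect_length(res$suggestions, 1L)
  expect_equal(res$suggestions[[1]]$product$product_id, "hdf_bis")
  expect_equal(res$suggestions[[1]]$regimen$slots, p$regimen$slots)
})

test_that("an equivalent carries the regimen over unchanged as group 2", {
  src <- mk("off", "bisoprolol", 5, atc = "C07AB07", ind = "hypertension")
  eq <- mk("on", "bisoprolol", 5, on_hdf = TRUE, atc = "C07AB07",
           ind = "hypertension")
  cat_ <- catalogue(list(src, eq))
  res <- switch_prescription(prescription(src, parse_scheme("1-0-1")), cat_,
                             default_kb())
  expect_equal(res$group, 2L)
  expect_equal(res$suggestions[[1]]$product$product_id, "on")
  expect_equal(res$suggestions[[1]]$regimen$slots, c(1, 0, 1, 0))
})

test_that("an alternative preserves the total daily dose as group 3", {
  w <- make_demo_world()
  p <- prescription(get_product(w$cat, "src_ome"), parse_scheme("1-0-1"))
  res <- switch_prescription(p, w$cat, w$kb)  # 40 mg/day; only 40 mg on HDF
  expect_equal(res$group, 3L)
  expect_equal(res$suggestions[[1]]$product$product_id, "hdf_ome40")
  expect_equal(total_daily_dose(res$suggestions[[1]]), 40)
  expect_equal(res$dose_deviation, 0)
})

test_that("the simvastatin-to-pravastatin switch doubles the daily dose", {
  w <- make_demo_world()
  p <- prescription(get_product(w$cat, "src_simva"), parse_scheme("1-0-0"))
  res <- switch_prescription(p, w$cat, w$kb)
  expect_equal(res$group, 4L)
  sugg <- res$suggestions[[1]]
  expect_equal(sugg$product$product_id, "hdf_prava")
  expect_equal(format_scheme(sugg$regimen), "1-0-0-0")
  expect_equal(total_daily_dose(sugg), 40)
})

test_that("a drug with no formulary relative lands in group 5", {
  w <- make_demo_world()
  p <- prescription(get_product(w$cat, "src_orphan"), parse_scheme("1-0-0"))
  res <- switch_prescription(p, w$cat, w$kb)
  expect_equal(res$group, 5L)
  expect_length(res$suggestions, 0L)
})

test_that("unresolved prescriptions become group 5 with an incomplete warning", {
  w <- make_demo_world()
  free <- prescription(NULL, parse_scheme("irgendwas"), descriptor = "Aspirin?")
  res <- switch_prescription(free, w$cat, w$kb)
  expect_equal(res$group, 5L)
  expect_true("incomplete" %in% vapply(res$warnings, `[[`, character(1), "type"))
  no_scheme <- prescription(get_product(w$cat, "hdf_bis"),
                            parse_scheme("nach Bedarf"))
  res2 <- switch_prescription(no_scheme, w$cat, w$kb)
  expect_equal(res2$group, 5L)
})

test_that("infeasible dose recomputation demotes to group 5", {
  src <- mk("s50", "drugy", 50, atc = "J01CA04", ind = "infection")
  alt <- mk("a40", "drugy", 40, on_hdf = TRUE, div = 1, atc = "J01CA04",
            ind = "infection")
  cat_ <- catalogue(list(src, alt))
  res <- switch_prescription(prescription(src, parse_scheme("1-0-0")), cat_,
                             knowledge_base(list()))
  expect_equal(res$group, 5L)  # 50 mg target unreachable on a 40 mg grid
})

test_that("tablet-splitting and dose-deviation are flagged as typed warnings", {
  src <- mk("s60", "drugz", 60, atc = "J01CA04", ind = "infection")
  alt <- mk("a40", "drugz", 40, on_hdf = TRUE, div = 2, atc = "J01CA04",
            ind = "infection")
  cat_ <- catalogue(list(src, alt))
  res <- switch_prescription(prescription(src, parse_scheme("1-0-0")), cat_,
                             knowledge_base(list()))
  expect_equal(res$group, 3L)
  types <- vapply(res$warnings, `[[`, character(1), "type")
  expect_true("tablet-splitting" %in% types)
  expect_equal(total_daily_dose(res$suggestions[[1]]), 60)
})

test_that("combination products split into single agents, all or nothing", {
  combo <- drug_product("combo", "Duo", list(
    ingredient_strength("lisinopril", 10),
    ingredient_strength("hydrochlorothiazide", 12.5)), "tablet",
    atc_codes = "C09BA03", indications = "hypertension", divisibility = 2)
  lis <- mk("lis", "lisinopril", 10, on_hdf = TRUE, atc = "C09AA03",
            ind = "hypertension")
  hct <- mk("hct", "hydrochlorothiazide", 12.5, on_hdf = TRUE, atc = "C03AA03",
            ind = "hypertension")
  kb <- default_kb()
  res <- switch_prescription(prescription(combo, parse_scheme("1-0-0")),
                             catalogue(list(combo, lis, hct)), kb)
  expect_equal(res$group, 2L)  # worst component step
  expect_setequal(vapply(res$suggestions, function(s) s$product$product_id,
                         character(1)), c("lis", "hct"))
  # one unmatched component discards the whole split
  res2 <- switch_prescription(prescription(combo, parse_scheme("1-0-0")),
                              catalogue(list(combo, lis)), kb)
  expect_equal(res2$group, 5L)
  expect_length(res2$suggestions, 0L)
})

test_that("combination splits record the worst component step", {
  combo <- drug_product("combo", "Duo", list(
    ingredient_strength("lisinopril", 10),
    ingredient_strength("hydrochlorothiazide", 25)), "tablet",
    atc_codes = "C09BA03", indications = "hypertension", divisibility = 2)
  lis <- mk("lis", "lisinopril", 10, on_hdf = TRUE, atc = "C09AA03",
            ind = "hypertension")
  hct_alt <- mk("hct", "hydrochlorothiazide", 12.5, on_hdf = TRUE,
                atc = "C03AA03", ind = "hypertension")
  res <- switch_prescription(prescription(combo, parse_scheme("1-0-0")),
                             catalogue(list(combo, lis, hct_alt)), default_kb())
  expect_equal(res$group, 3L)  # equivalent + alternative -> worst is step 3
  expect_length(res$suggestions, 2L)
})

test_that("combinations with more than three components are never split", {
  ings <- lapply(sprintf("multi%d", 1:4), function(p)
    ingredient_strength(p, 10))
  combo <- drug_product("c4", "Quad", ings, "tablet",
                        atc_codes = "A11AA02", indications = "supplementation",
                        divisibility = 1)
  singles <- lapply(sprintf("multi%d", 1:4), function(p)
    mk(paste0("hdf_", p), p, 10, on_hdf = TRUE, atc = "A11AA02",
       ind = "supplementation"))
  cat_ <- catalogue(c(list(combo), singles))
  res <- switch_prescription(prescription(combo, parse_scheme("1-0-0")), cat_,
                             knowledge_base(list()))
  expect_equal(res$group, 5L)
})

test_that("combinations are never substituted therapeutically", {
  # a combination whose components only have therapeutic relatives fails
  combo <- drug_product("cc", "ComboStatin", list(
    ingredient_strength("simvastatin", 20),
    ingredient_strength("ezetimibe", 10)), "tablet",
    atc_codes = "C10BA02", indications = "hypercholesterolemia",
    divisibility = 2)
  prava <- mk("p", "pravastatin", 40, on_hdf = TRUE, atc = "C10AA03")
  res <- switch_prescription(prescription(combo, parse_scheme("1-0-0")),
                             catalogue(list(combo, prava)), default_kb())
  expect_equal(res$group, 5L)
})

test_that("excluded ATC prefixes and non-oral routes never yield group 4", {
  kb <- default_kb()
  # build sources that would co-class if not excluded
  glib <- mk("g", "glibenclamide", 3.5, atc = "A10AB01", ind = "diabetes-mellitus-2")
  glim <- mk("gl", "glimepiride", 2, on_hdf = TRUE, atc = "A10BB12",
             ind = "diabetes-mellitus-2")
  res <- switch_prescription(prescription(glib, parse_scheme("1-0-0")),
                             catalogue(list(glib, glim)), kb)
  expect_equal(res$group, 5L)
  inhaled <- mk("inh", "salbutamol", 0.1, form = "inhalation", route = "inhaled",
                atc = "R03AC02", ind = "asthma")
  res2 <- switch_prescription(prescription(inhaled, parse_scheme("1-0-1")),
                              catalogue(list(inhaled)), kb)
  expect_equal(res2$group, 5L)
})

test_that("step order is monotone: an earlier match always wins", {
  # product with an exact equivalent AND an alternative AND a therapeutic
  # relative resolves at step 2
  src <- mk("s", "simvastatin", 20, atc = "C10AA01")
  eq <- mk("e", "simvastatin", 20, on_hdf = TRUE, atc = "C10AA01")
  alt <- mk("a", "simvastatin", 40, on_hdf = TRUE, atc = "C10AA01")
  ther <- mk("t", "pravastatin", 40, on_hdf = TRUE, atc = "C10AA03")
  res <- switch_prescription(prescription(src, parse_scheme("1-0-0")),
                             catalogue(list(src, eq, alt, ther)), default_kb())
  expect_equal(res$group, 2L)
  expect_equal(res$suggestions[[1]]$product$product_id, "e")
})

test_that("every result is total, formulary-closed and within dose tolerance", {
  spec <- generator_spec(seed = 13, n_products = 120, n_consultations = 15)
  gen <- generate_catalogue(spec)
  cons <- generate_consultations(spec, gen)
  cfg <- engine_config()
  results <- unlist(lapply(cons$consultations, switch_consultation,
                           cat = gen$catalogue, kb = gen$kb, cfg = cfg),
                    recursive = FALSE)
  for (r in results) {
    expect_true(r$group %in% 1:5)
    if (r$group == 5L) expect_length(r$suggestions, 0L)
    for (s in r$suggestions) expect_true(s$product$on_hdf)
    if (length(r$dose_deviation))
      expect_true(all(r$dose_deviation <= cfg$max_dose_deviation + 1e-9))
    if (r$group == 2L) expect_equal(max(r$dose_deviation), 0)
  }
})

test_that("switching a consultation preserves order and counts groups", {
  w <- make_demo_world()
  expect_length(switch_consultation(list(), w$cat, w$kb), 0L)
  ids <- c("hdf_bis", "src_simva", "src_ome", "src_orphan", "hdf_bis",
           "src_simva", "src_orphan")
  ps <- lapply(ids, function(id)
    prescription(get_product(w$cat, id), parse_scheme("1-0-0")))
  results <- switch_consultation(ps, w$cat, w$kb)
  expect_length(results, 7L)
  expect_equal(vapply(results, function(r) r$source$product$product_id,
                      character(1)), ids)
  counts <- attr(results, "summary")
  expect_equal(unname(counts[c("group1", "group4", "group5")]),
               c(2L, 2L, 2L))
})

test_that("engine output is byte-identical across runs", {
  spec <- generator_spec(seed = 17, n_products = 60, n_consultations = 8)
  run_once <- function() {
    gen <- generate_catalogue(spec)
    cons <- generate_consultations(spec, gen)
    results <- unlist(lapply(cons$consultations, switch_consultation,
                             cat = gen$catalogue, kb = gen$kb),
                      recursive = FALSE)
    jsonlite::toJSON(results_to_records(results), auto_unbox = TRUE, digits = NA)
  }
  expect_identical(as.character(run_once()), as.character(run_once()))
})
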