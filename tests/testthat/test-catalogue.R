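test_that("a valid delimited file loads completely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "product_id;brand_name;ingredients;dosage_form;release;route;atc_codes;indications;on_hdf;divisibility",
    "p1;Simva A;simvastatin:20:mg;tablet;immediate;oral;C10AA01;hypercholesterolemia;1;2",
    "p2;Simva B;simvastatin:40:mg;tablet;immediate;oral;C10AA01;hypercholesterolemia;0;2",
    "p3;Combi;lisinopril:10:mg+hydrochlorothiazide:12.5:mg;tablet;immediate;oral;C09BA03;hypertension;0;1",
    "p4;Drops;metamizole:500:mg;solution;immediate;oral;N02BB02;pain;1;1",
    "p5;Iron;ferrous sulfate:100:mg;coated-tablet;immediate;oral;B03AA07;iron-deficiency;1;1"
  ), path)
  cat_ <- load_catalogue(path)
  expect_length(cat_, 5L)
  expect_length(attr(cat_, "skipped"), 0L)
  expect_equal(hdf_count(cat_), 3L)
  combo <- get_product(cat_, "p3")
  expect_length(combo$ingredients, 2L)
  expect_equal(get_product(cat_, "p5")$ingredients[[1]]$parent, "ferrous sulfate")
})

test_that("invalid rows abort in strict mode and are counted otherwise", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "product_id;brand_name;ingredients;dosage_form;release;route;atc_codes;indications;on_hdf;divisibility",
    "p1;Good;simvastatin:20:mg;tablet;immediate;oral;C10AA01;x;1;2",
    "p2;Bad;simvastatin:-20:mg;tablet;immediate;oral;C10AA01;x;1;2"
  ), path)
  expect_error(load_catalogue(path, strict = TRUE), "row 2.*amount",
               class = "rxswitch_error")
  cat_ <- load_catalogue(path, strict = FALSE)
  expect_length(cat_, 1L)
  expect_match(attr(cat_, "skipped"), "row 2")
})

test_that("duplicate ids and malformed ATC codes are rejected with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "product_id;brand_name;ingredients;dosage_form;release;route;atc_codes;indications;on_hdf;divisibility",
    "p1;A;x:20:mg;tablet;immediate;oral;C10AA01;i;1;2",
    "p1;B;x:20:mg;tablet;immediate;oral;C10AA01;i;1;2",
    "p3;C;x:20:mg;tablet;immediate;oral;NOTANATC;i;1;2"
  ), path)
  expect_error(load_catalogue(path, strict = TRUE), "row 2.*duplicate")
  cat_ <- load_catalogue(path, strict = FALSE)
  expect_length(cat_, 1L)
  expect_length(attr(cat_, "skipped"), 2L)
  expect_match(attr(cat_, "skipped")[2], "ATC")
})

test_that("the JSON dialect loads the same products as the delimited one", {
  json <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(
    product_id = "j1", brand_name = "Json brand",
    ingredients = "bisoprolol:5:mg", dosage_form = "tablet",
    release = "immediate", route = "oral", atc_codes = "C07AB07",
    indications = "hypertension", on_hdf = TRUE, divisibility = 2
  )), auto_unbox = TRUE), json)
  cat_ <- load_catalogue(json)
  expect_length(cat_, 1L)
  p <- get_product(cat_, "j1")
  expect_true(p$on_hdf)
  expect_equal(p$ingredients[[1]]$amount, 5)
})

test_that("write_catalogue / load_catalogue round-trips generator output", {
  dir <- withr::local_tempdir()
  spec <- generator_spec(seed = 42, n_products = 100, n_consultations = 5)
  write_fixtures(spec, dir)
  declared <- jsonlite::read_json(file.path(dir, "summary.json"))
  cat_ <- load_catalogue(file.path(dir, "catalogue.csv"))
  expect_equal(length(cat_), declared$n_products)
  expect_equal(hdf_count(cat_), declared$n_hdf)
})

test_that("an exact copy under another id is a pharmaceutical equivalent", {
  src <- mk("s", "simvastatin", 20, on_hdf = TRUE)
  copy <- mk("c", "simvastatin", 20, on_hdf = TRUE)
  cat_ <- catalogue(list(src, copy))
  hits <- equivalents_query(src, cat_, rel_tol = 0)
  expect_equal(vapply(hits, `[[`, character(1), "product_id"), "c")
})

test_that("strength tolerance governs the near-identical-strength match", {
  # 78.09 vs 77.82 mg metoprolol modified-release: relative difference
  # ~0.0035, missed at exact matching, found with a 1% tolerance
  src <- mk("m1", "metoprolol", 78.09, release = "modified", atc = "C07AB02",
            ind = "hypertension")
  tgt <- mk("m2", "metoprolol", 77.82, on_hdf = TRUE, release = "modified",
            atc = "C07AB02", ind = "hypertension")
  cat_ <- catalogue(list(src, tgt))
  expect_length(equivalents_query(src, cat_, rel_tol = 0), 0L)
  hits <- equivalents_query(src, cat_, rel_tol = 0.01)
  expect_equal(vapply(hits, `[[`, character(1), "product_id"), "m2")
})

test_that("microgram and mg strengths compare on a common scale; IU only to IU", {
  src <- mk("u1", "levothyroxine", 0.1, atc = "H03AA01", ind = "hypothyroidism")
  ug <- mk("u2", "levothyroxine", 100, unit = "microgram", on_hdf = TRUE,
           atc = "H03AA01", ind = "hypothyroidism")
  iu <- mk("u3", "levothyroxine", 100, unit = "IU", on_hdf = TRUE,
           atc = "H03AA01", ind = "hypothyroidism")
  cat_ <- catalogue(list(src, ug, iu))
  hits <- equivalents_query(src, cat_)
  expect_equal(vapply(hits, `[[`, character(1), "product_id"), "u2")
})

test_that("alternatives require a different strength in a comparable form", {
  src <- mk("s20", "simvastatin", 20)
  same <- mk("s20b", "simvastatin", 20, on_hdf = TRUE)
  double <- mk("s40", "simvastatin", 40, on_hdf = TRUE)
  capsule <- mk("s80", "simvastatin", 80, on_hdf = TRUE, form = "capsule")
  retard <- mk("s40r", "simvastatin", 40, on_hdf = TRUE, release = "modified")
  liquid <- mk("s40l", "simvastatin", 40, on_hdf = TRUE, form = "solution")
  cat_ <- catalogue(list(src, same, double, capsule, retard, liquid))
  alt_ids <- vapply(alternatives_query(src, cat_), `[[`, character(1),
                    "product_id")
  # same strength is an equivalent, not an alternative; capsules share the
  # oral-solid group; modified release and liquids are not comparable
  expect_setequal(alt_ids, c("s40", "s80"))
})

test_that("a modified-release source never matches an immediate-release product", {
  src <- mk("r1", "doxazosin", 4, release = "modified", atc = "C02CA04",
            ind = "hypertension")
  ir <- mk("r2", "doxazosin", 4, on_hdf = TRUE, release = "immediate",
           atc = "C02CA04", ind = "hypertension")
  cat_ <- catalogue(list(src, ir))
  expect_length(equivalents_query(src, cat_), 0L)
  expect_length(alternatives_query(src, cat_), 0L)
})

test_that("queries agree with a brute-force scan and stay disjoint and on-HDF", {
  for (seed in 1:5) {
    cat_ <- random_catalogue(50, seed = seed)
    for (tol in c(0, 0.01)) {
      for (src in cat_$products) {
        eq <- vapply(equivalents_query(src, cat_, tol), `[[`, character(1),
                     "product_id")
        alt <- vapply(alternatives_query(src, cat_, tol), `[[`, character(1),
                      "product_id")
        expect_equal(sort(eq), oracle_equivalents(src, cat_, tol))
        expect_equal(sort(alt), oracle_alternatives(src, cat_, tol))
        expect_length(intersect(eq, alt), 0L)
        for (id in c(eq, alt)) expect_true(get_product(cat_, id)$on_hdf)
      }
    }
  }
})

test_that("query results are invariant under catalogue row permutation", {
  cat_ <- random_catalogue(40, seed = 99)
  set.seed(123)
  shuffled <- catalogue(sample(cat_$products))
  for (src in cat_$products) {
    expect_identical(
      vapply(equivalents_query(src, cat_), `[[`, character(1), "product_id"),
      vapply(equivalents_query(src, shuffled), `[[`, character(1), "product_id"))
    expect_identical(
      vapply(alternatives_query(src, cat_), `[[`, character(1), "product_id"),
      vapply(alternatives_query(src, shuffled), `[[`, character(1), "product_id"))
  }
})

test_that("salt descriptors normalize to a shared parent but are retained", {
  tart <- ingredient_strength("Metoprolol tartrate", 100)
  succ <- ingredient_strength("metoprolol succinate", 95)
  expect_equal(tart$parent, "metoprolol")
  expect_equal(succ$parent, "metoprolol")
  expect_equal(tart$salt, "tartrate")
})
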