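# Evaluation bookkeeping: comparison of engine output against reference
# switches, and the per-group performance accounting used to report a
# formulary-switching service's coverage.

suggestion_key <- function(suggestions) {
  if (length(suggestions) == 0L) return(character())
  sort(vapply(suggestions, function(s)
    paste(s$product$product_id, format_scheme(s$regimen), sep = "@"),
    character(1)))
}

#' Compare an engine result with a reference switch
#'
#' The verdict is `identical` exactly when the suggested product multiset
#' and their schemes match the reference; any difference in product or
#' regimen makes it `different`. Finer judgments (equivalent, one side
#' better) come from a blinded expert and are supplied externally via
#' [apply_adjudications()] — they are never inferred.
#'
#' @param engine_result a `switch_result`.
#' @param reference list of [prescription()] objects — the manually
#'   produced switch for the same source prescription.
#' @return object of class `comparison_record`: list with `source_id`,
#'   `verdict`, `engine_key`, `reference_key`, and `NA` placeholders for
#'   `expert_label` / `sub_label`.
#' @export
classify <- function(engine_result, reference) {
  if (inherits(reference, "prescription")) reference <- list(reference)
  ek <- suggestion_key(engine_result$suggestions)
  rk <- suggestion_key(reference)
  structure(list(
    source_id = if (!is.null(engine_result$source$product))
      engine_result$source$product$product_id else engine_result$source$descriptor,
    verdict = if (identical(ek, rk)) "identical" else "different",
    engine_key = ek, reference_key = rk,
    expert_label = NA_character_, sub_label = NA_character_
  ), class = "comparison_record")
}

#' Attach external expert adjudications to comparison records
#'
#' Expert labels apply only to records with verdict `different`; the
#' sub-label (CDSS correct-but-suboptimal vs inadequate) applies only when
#' the reference was judged better.
#'
#' @param records list of `comparison_record`.
#' @param labels data frame with columns `source_id`, `expert_label`
#'   (`equivalent`, `cdss_better`, `reference_better`) and optionally
#'   `sub_label` (`cdss_ok`, `cdss_not_ok`).
#' @return the records with labels attached.
#' @export
apply_adjudications <- function(records, labels) {
  stopifnot(all(c("source_id", "expert_label") %in% names(labels)))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    hit <- which(labels$source_id == rec$source_id)
    if (length(hit) == 0L) next
    if (rec$verdict != "different")
      stop_rxswitch(sprintf(
        "adjudication supplied for '%s' but verdict is identical",
        rec$source_id), "rxswitch_invalid")
    rec$expert_label <- labels$expert_label[hit[1]]
    if (rec$expert_label == "reference_better" && "sub_label" %in% names(labels))
      rec$sub_label <- labels$sub_label[hit[1]]
    records[[i]] <- rec
  }
  records
}

#' Summarise comparison records
#'
#' @param records list of `comparison_record`.
#' @return list with counts and half-up-rounded percentages: total,
#'   identical/different, and the expert-label breakdown of the different
#'   records.
#' @export
comparison_summary <- function(records) {
  verdicts <- vapply(records, `[[`, character(1), "verdict")
  n <- length(records)
  n_id <- sum(verdicts == "identical")
  n_diff <- n - n_id
  labels <- vapply(records, `[[`, character(1), "expert_label")
  subl <- vapply(records, `[[`, character(1), "sub_label")
  pct <- function(k, d) if (d > 0) round_half_up(100 * k / d, 1) else NA_real_
  list(
    n = n, n_identical = n_id, n_different = n_diff,
    pct_identical = pct(n_id, n), pct_different = pct(n_diff, n),
    n_equivalent = sum(labels == "equivalent", na.rm = TRUE),
    n_cdss_better = sum(labels == "cdss_better", na.rm = TRUE),
    n_reference_better = sum(labels == "reference_better", na.rm = TRUE),
    pct_equivalent = pct(sum(labels == "equivalent", na.rm = TRUE), n_diff),
    pct_cdss_better = pct(sum(labels == "cdss_better", na.rm = TRUE), n_diff),
    pct_reference_better = pct(sum(labels == "reference_better", na.rm = TRUE),
                               n_diff),
    n_cdss_ok = sum(subl == "cdss_ok", na.rm = TRUE),
    n_cdss_not_ok = sum(subl == "cdss_not_ok", na.rm = TRUE)
  )
}

#' Per-group performance accounting
#'
#' Tabulates switch results by outcome group over the assessable
#' prescriptions, with percentages rounded half-up to one decimal place —
#' the convention under which a published column may sum to 100.1. The
#' automatic-switch total (groups 1-4) is reported both as the sum of the
#' rounded cells (matching how such tables are printed) and unrounded.
#'
#' @param results list of `switch_result`, or an integer vector of groups.
#' @param n_documented number of documented prescriptions before exclusion.
#' @param n_excluded prescriptions excluded as incomplete/inaccurate;
#'   `n_documented - n_excluded` must equal the number of results.
#' @return object of class `performance_report`.
#' @export
performance_table <- function(results, n_documented = NULL, n_excluded = 0L) {
  groups <- if (is.numeric(results)) as.integer(results)
            else vapply(results, `[[`, integer(1), "group")
  n <- length(groups)
  if (is.null(n_documented)) n_documented <- n + n_excluded
  if (n_documented - n_excluded != n)
    stop_rxswitch(sprintf(
      "inconsistent counts: %d documented - %d excluded != %d results",
      n_documented, n_excluded, n), "rxswitch_invalid")
  counts <- vapply(1:5, function(g) sum(groups == g), integer(1))
  pct <- round_half_up(100 * counts / n, 1)
  structure(list(
    n_documented = n_documented, n_excluded_incomplete = n_excluded,
    n_assessable = n,
    pct_assessable = round_half_up(100 * n / n_documented, 1),
    group_counts = setNames(counts, paste0("group", 1:5)),
    group_pct = setNames(pct, paste0("group", 1:5)),
    cdss_switch_count = sum(counts[1:4]),
    cdss_switch_pct = sum(pct[1:4]),
    cdss_switch_pct_unrounded = 100 * sum(counts[1:4]) / n
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance of the switching engine (n = %d assessable of %d documented, %d excluded as incomplete)\n",
              x$n_assessable, x$n_documented, x$n_excluded_incomplete))
  rows <- c("Group 1: HDF drug", "Group 2: Pharmaceutical equivalent",
            "Group 3: Pharmaceutical alternative",
            "Group 4: Therapeutic equivalent")
  for (g in 1:4)
    cat(sprintf("  %-36s %5d  %5.1f%%\n", rows[g], x$group_counts[g],
                x$group_pct[g]))
  cat(sprintf("  %-36s %5d  %5.1f%%\n", "Sum: automatic switch",
              x$cdss_switch_count, x$cdss_switch_pct))
  cat(sprintf("  %-36s %5d  %5.1f%%\n", "Group 5: No automatic switch",
              x$group_counts[5], x$group_pct[5]))
  invisible(x)
}

# --- medication-list i/o --------------------------------------------------

#' Read a patient medication list
#'
#' Delimited dialect: semicolon-separated with header, columns
#' `brand_or_product_id; scheme` plus optional `consultation_id` (defaults
#' to 1) and `strength_text` (display only). Lines are resolved against the
#' catalogue by product id first, then by exact brand name; unresolved
#' lines become free-text prescriptions that the engine routes to manual
#' handling.
#'
#' @param path input file.
#' @param cat a `drug_catalogue` to resolve against.
#' @return named list of consultations, each a list of [prescription()].
#' @export
read_medication_list <- function(path, cat) {
  if (!file.exists(path))
    stop_rxswitch(sprintf("medication list not found: %s", path), "rxswitch_io")
  tab <- read.delim(path, sep = ";", header = TRUE, colClasses = "character",
                    fileEncoding = "UTF-8", strip.white = TRUE)
  if (!all(c("brand_or_product_id", "scheme") %in% names(tab)))
    stop_rxswitch("medication list needs columns brand_or_product_id and scheme",
                  "rxswitch_parse")
  if (!"consultation_id" %in% names(tab)) tab$consultation_id <- "1"
  brand_index <- setNames(names(cat$products),
                          vapply(cat$products, `[[`, character(1), "brand_name"))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    ref <- tab$brand_or_product_id[i]
    product <- get_product(cat, ref)
    if (is.null(product) && ref %in% names(brand_index))
      product <- get_product(cat, brand_index[[ref]])
    p <- prescription(product, parse_scheme(tab$scheme[i]), descriptor = ref)
    cid <- tab$consultation_id[i]
    out[[cid]] <- c(out[[cid]], list(p))
  }
  out
}

#' Serialize switch results to a plain-data structure
#'
#' @param results list of `switch_result`.
#' @return list of plain lists (group, source, suggestions, warnings,
#'   deviation, trace) ready for JSON output.
#' @export
results_to_records <- function(results) {
  lapply(results, function(r) {
    list(
      source = list(
        descriptor = r$source$descriptor,
        product_id = if (!is.null(r$source$product))
          r$source$product$product_id else NA_character_,
        scheme = format_scheme(r$source$regimen)),
      group = r$group,
      group_label = .group_labels[r$group],
      suggestions = lapply(r$suggestions, function(s) list(
        product_id = s$product$product_id,
        brand_name = s$product$brand_name,
        scheme = format_scheme(s$regimen))),
      warnings = lapply(r$warnings, function(w)
        list(type = w$type, message = w$message)),
      dose_deviation = r$dose_deviation,
      trace = r$trace)
  })
}

#' Render switch results as a human-readable table
#'
#' @param results list of `switch_result`.
#' @return character vector of table lines.
#' @export
results_table <- function(results) {
  header <- sprintf("%-24s %-12s %-5s %-30s %s", "source", "scheme", "group",
                    "suggestion(s)", "warnings")
  rows <- vapply(results, function(r) {
    sugg <- if (length(r$suggestions) == 0L) "-" else
      paste(vapply(r$suggestions, function(s)
        sprintf("%s %s", s$product$product_id, format_scheme(s$regimen)),
        character(1)), collapse = " + ")
    warns <- if (length(r$warnings) == 0L) "" else
      paste(unique(vapply(r$warnings, `[[`, character(1), "type")),
            collapse = ",")
    sprintf("%-24s %-12s %-5d %-30s %s", substr(r$source$descriptor, 1, 24),
            format_scheme(r$source$regimen), r$group, sugg, warns)
  }, character(1))
  c(header, rows)
}
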