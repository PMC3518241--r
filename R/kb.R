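# Therapeutic-interchange knowledge base: ATC-scoped drug classes with
# per-member equipotent daily doses, indication constraints, and exclusion
# rules. Conversion factors are never stored pairwise: a factor is always
# the ratio of two equipotent daily doses, which makes reciprocity and
# transitivity within a class hold by construction.

#' Default exclusion rules
#'
#' Drug classes barred from automatic therapeutic substitution: insulins
#' (A10A, substitution must be personalised with tailored blood-glucose
#' monitoring), alpha-adrenoceptor blockers (C02CA, switches can require a
#' release-form change), hyperkalemia/hyperphosphatemia agents (V03AE,
#' heterogeneous mechanisms), and other antianemics (B03XA, biosimilars
#' needing expert handling). Therapeutic substitution is additionally
#' restricted to oral solid dosage forms.
#'
#' @param atc_prefixes ATC prefixes barred from automatic substitution.
#' @param oral_only restrict therapeutic substitution to the oral route.
#' @return object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(atc_prefixes = c("A10A", "C02CA", "V03AE", "B03XA"),
                            oral_only = TRUE) {
  atc_prefixes <- toupper(as.character(atc_prefixes))
  bad <- atc_prefixes[!grepl("^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$",
                             atc_prefixes)]
  if (length(bad))
    stop_rxswitch(sprintf("invalid ATC prefix(es): %s", paste(bad, collapse = ", ")),
                  "rxswitch_invalid")
  structure(list(atc_prefixes = atc_prefixes, oral_only = isTRUE(oral_only)),
            class = "exclusion_rules")
}

#' Interchange-class member
#'
#' One drug parent within an interchange class, with its equipotent daily
#' dose per labelled indication. Equipotent doses are the exchange
#' currency: the conversion factor from drug a to drug b for indication i
#' is `dose(b, i) / dose(a, i)`.
#'
#' @param parent ingredient name (normalized to the active moiety).
#' @param equipotent_daily_dose named numeric vector or list: indication
#'   token -> positive daily dose (mg/day or IU/day).
#' @param notes free-text curator notes.
#' @return object of class `interchange_member`.
#' @export
interchange_member <- function(parent, equipotent_daily_dose, notes = "") {
  parent <- normalize_parent(parent)$parent
  edd <- unlist(equipotent_daily_dose)
  if (length(edd) < 1L || is.null(names(edd)) || any(!nzchar(names(edd))))
    stop_rxswitch(sprintf("member '%s': needs at least one named indication dose",
                          parent), "rxswitch_invalid")
  edd <- setNames(as.numeric(edd), tolower(names(edd)))
  if (any(is.na(edd)) || any(edd <= 0))
    stop_rxswitch(sprintf("member '%s': equipotent doses must be > 0", parent),
                  "rxswitch_invalid")
  structure(list(parent = parent, equipotent_daily_dose = edd,
                 notes = as.character(notes)),
            class = "interchange_member")
}

#' Interchange class
#'
#' An ATC-scoped set of mutually exchangeable drug parents.
#'
#' @param class_id unique identifier.
#' @param name display name, e.g. "HMG-CoA reductase inhibitors".
#' @param atc_codes level-4 ATC codes covered by the class.
#' @param members list of [interchange_member()] with unique parents.
#' @param oral_solid_only restrict substitution within this class to oral
#'   solid forms (the default and the only supported mode).
#' @return object of class `interchange_class`.
#' @export
interchange_class <- function(class_id, name, atc_codes, members,
                              oral_solid_only = TRUE) {
  atc_codes <- toupper(as.character(atc_codes))
  if (length(atc_codes) == 0L)
    stop_rxswitch(sprintf("class '%s': atc_codes must be non-empty", class_id),
                  "rxswitch_invalid")
  bad <- atc_codes[!is_valid_atc(atc_codes)]
  if (length(bad))
    stop_rxswitch(sprintf("class '%s': malformed ATC code(s): %s", class_id,
                          paste(bad, collapse = ", ")), "rxswitch_invalid")
  ok <- vapply(members, inherits, logical(1), "interchange_member")
  if (!all(ok))
    stop_rxswitch(sprintf("class '%s': members must be interchange_member objects",
                          class_id), "rxswitch_invalid")
  parents <- vapply(members, `[[`, character(1), "parent")
  if (anyDuplicated(parents))
    stop_rxswitch(sprintf("class '%s': duplicate member parent(s): %s", class_id,
                          paste(unique(parents[duplicated(parents)]), collapse = ", ")),
                  "rxswitch_invalid")
  names(members) <- parents
  structure(list(class_id = as.character(class_id), name = as.character(name),
                 atc_codes = atc_codes, members = members,
                 oral_solid_only = isTRUE(oral_solid_only)),
            class = "interchange_class")
}

#' Assemble a knowledge base
#'
#' @param classes list of [interchange_class()] objects.
#' @param exclusions an [exclusion_rules()] object.
#' @return object of class `interchange_kb`.
#' @export
knowledge_base <- function(classes = list(), exclusions = exclusion_rules()) {
  ids <- vapply(classes, `[[`, character(1), "class_id")
  if (anyDuplicated(ids))
    stop_rxswitch(sprintf("duplicate class_id: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                  "rxswitch_invalid")
  for (cl in classes) {
    if (atc_under_prefix(cl$atc_codes, exclusions$atc_prefixes))
      stop_rxswitch(sprintf(
        "class '%s' carries an ATC code under an excluded prefix", cl$class_id),
        "rxswitch_invalid")
  }
  names(classes) <- ids
  structure(list(classes = classes, exclusions = exclusions),
            class = "interchange_kb")
}

#' @export
print.interchange_kb <- function(x, ...) {
  cat(sprintf("<interchange_kb> %d classes, %d members; excluded prefixes: %s\n",
              length(x$classes),
              sum(vapply(x$classes, function(cl) length(cl$members), integer(1))),
              paste(x$exclusions$atc_prefixes, collapse = ", ")))
  invisible(x)
}

#' Load a knowledge base from a YAML file
#'
#' The file has a top-level `classes` list (each with `class_id`, `name`,
#' `atc_codes`, `members`; members carry `parent` and an
#' `equipotent_daily_dose` mapping indication -> mg/day) and an optional
#' `exclusions` block (`atc_prefixes`, `oral_only`). A JSON Schema for the
#' format ships under `inst/extdata/`. The packaged default KB
#' (`default_kb()`) holds the 21 interchange classes supported for
#' automatic substitution.
#'
#' @param path YAML file path.
#' @return an `interchange_kb`.
#' @export
load_kb <- function(path) {
  if (!file.exists(path))
    stop_rxswitch(sprintf("knowledge base file not found: %s", path), "rxswitch_io")
  doc <- yaml::read_yaml(path)
  if (is.null(doc$classes))
    stop_rxswitch("knowledge base file lacks a 'classes' list", "rxswitch_parse")
  excl <- if (!is.null(doc$exclusions)) {
    exclusion_rules(
      atc_prefixes = unlist(doc$exclusions$atc_prefixes %||%
                              c("A10A", "C02CA", "V03AE", "B03XA")),
      oral_only = doc$exclusions$oral_only %||% TRUE
    )
  } else {
    exclusion_rules()
  }
  classes <- lapply(doc$classes, function(cl) {
    members <- lapply(cl$members %||% list(), function(m)
      interchange_member(m$parent, m$equipotent_daily_dose, m$notes %||% ""))
    interchange_class(cl$class_id, cl$name %||% cl$class_id,
                      unlist(cl$atc_codes), members,
                      oral_solid_only = cl$oral_solid_only %||% TRUE)
  })
  knowledge_base(classes, excl)
}

#' The packaged default knowledge base
#'
#' Twenty-one drug classes supported for automatic therapeutic
#' substitution, from antacids through benzodiazepine-related hypnotics.
#' The equipotent daily doses shipped with the package are curator-editable
#' placeholders taken from approved maintenance doses (the fallback source
#' when no head-to-head comparison is published); sites deploying the
#' system are expected to review and adapt them.
#'
#' @return an `interchange_kb` with 21 classes.
#' @export
default_kb <- function() {
  load_kb(system.file("extdata", "default_kb.yaml", package = "rxswitch",
                      mustWork = TRUE))
}

#' Write a knowledge base to YAML
#'
#' @param kb an `interchange_kb`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  doc <- list(
    exclusions = list(atc_prefixes = as.list(kb$exclusions$atc_prefixes),
                      oral_only = kb$exclusions$oral_only),
    classes = lapply(unname(kb$classes), function(cl) {
      list(class_id = cl$class_id, name = cl$name,
           atc_codes = as.list(cl$atc_codes),
           oral_solid_only = cl$oral_solid_only,
           members = lapply(unname(cl$members), function(m) {
             list(parent = m$parent,
                  equipotent_daily_dose = as.list(m$equipotent_daily_dose),
                  notes = m$notes)
           }))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Validate a third-party knowledge-base file
#'
#' Lints structure and invariants (unique ids, positive doses, ATC syntax,
#' no class under an excluded prefix) and reports every problem found.
#'
#' @param path YAML file path.
#' @return character vector of problems; empty when the file is valid.
#' @export
lint_kb <- function(path) {
  res <- tryCatch(load_kb(path), rxswitch_error = function(e) e)
  if (inherits(res, "error")) conditionMessage(res) else character()
}

# --- lookups --------------------------------------------------------------

# All classes in which `parent` is a member.
classes_of <- function(parent, kb) {
  Filter(function(cl) parent %in% names(cl$members), kb$classes)
}

#' Conversion factor between two co-classed drugs
#'
#' The factor multiplying the source's daily dose to obtain the equipotent
#' daily dose of the target: `equipotent(tgt, i) / equipotent(src, i)` for
#' the matched indication `i`. When no indication is given and the shared
#' indications imply different factors, the lexicographically first shared
#' indication is used and a `differing-indications` warning is attached —
#' mirroring the rule that a multi-indication drug with indication-dependent
#' factors must be flagged to the prescriber.
#'
#' @param src,tgt source and target parent names (distinct).
#' @param kb an `interchange_kb`.
#' @param indication optional indication token; must be shared by both
#'   members when given.
#' @return list with `factor` (> 0), `indication` (the one used), and
#'   `warnings` (character vector of warning type tokens).
#' @examples
#' kb <- default_kb()
#' conversion_factor("simvastatin", "pravastatin", kb)$factor  # 2
#' @export
conversion_factor <- function(src, tgt, kb, indication = NULL) {
  src <- normalize_parent(src)$parent
  tgt <- normalize_parent(tgt)$parent
  if (identical(src, tgt))
    stop_rxswitch("source and target parent must differ", "rxswitch_invalid")
  common <- Filter(function(cl) all(c(src, tgt) %in% names(cl$members)),
                   kb$classes)
  if (length(common) == 0L)
    stop_rxswitch(sprintf("'%s' and '%s' share no interchange class", src, tgt),
                  "rxswitch_no_class")
  cl <- common[[1]]
  dose_s <- cl$members[[src]]$equipotent_daily_dose
  dose_t <- cl$members[[tgt]]$equipotent_daily_dose
  shared <- sort(intersect(names(dose_s), names(dose_t)))
  if (length(shared) == 0L)
    stop_rxswitch(sprintf("'%s' and '%s' share no indication", src, tgt),
                  "rxswitch_no_indication")
  warnings <- character()
  if (!is.null(indication)) {
    indication <- tolower(indication)
    if (!indication %in% shared)
      stop_rxswitch(sprintf("indication '%s' not shared by '%s' and '%s'",
                            indication, src, tgt), "rxswitch_no_indication")
    used <- indication
  } else {
    factors <- dose_t[shared] / dose_s[shared]
    if (length(unique(round(factors, 9))) > 1L)
      warnings <- c(warnings, "differing-indications")
    used <- shared[1]
  }
  list(factor = unname(dose_t[[used]] / dose_s[[used]]), indication = used,
       warnings = warnings)
}

#' Therapeutic-equivalent candidates for a product
#'
#' Formulary products whose active moiety shares an interchange class with
#' the source's, carrying the dose-conversion factor for each. Candidates
#' are only produced for single-ingredient oral solid sources whose ATC
#' codes do not fall under an excluded prefix; substitutions are further
#' restricted to candidates whose labelled indications intersect the
#' source's (a calcium-channel blocker for hypertension is never replaced
#' by one labelled only for cerebral-vasospasm prevention).
#'
#' @param source a single-ingredient `drug_product`.
#' @param cat a `drug_catalogue`.
#' @param kb an `interchange_kb`.
#' @return list of candidates, each `list(product, factor, indication,
#'   warnings)`, ordered by product id; empty when the source is excluded
#'   or unmatched.
#' @export
therapeutic_candidates <- function(source, cat, kb) {
  if (length(source$ingredients) != 1L)
    stop_rxswitch("therapeutic_candidates requires a single-ingredient product",
                  "rxswitch_invalid")
  excl <- kb$exclusions
  if (atc_under_prefix(source$atc_codes, excl$atc_prefixes)) return(list())
  if (excl$oral_only && (source$route != "oral" || source$form_group != "oral-solid"))
    return(list())
  src_parent <- source$ingredients[[1]]$parent
  src_classes <- classes_of(src_parent, kb)
  if (length(src_classes) == 0L) return(list())
  out <- list()
  for (p in cat$products) {
    if (!p$on_hdf || length(p$ingredients) != 1L) next
    if (excl$oral_only && (p$route != "oral" || p$form_group != "oral-solid")) next
    if (atc_under_prefix(p$atc_codes, excl$atc_prefixes)) next
    tgt_parent <- p$ingredients[[1]]$parent
    if (tgt_parent == src_parent) next
    co <- Filter(function(cl) tgt_parent %in% names(cl$members), src_classes)
    if (length(co) == 0L) next
    cl <- co[[1]]
    dose_s <- cl$members[[src_parent]]$equipotent_daily_dose
    dose_t <- cl$members[[tgt_parent]]$equipotent_daily_dose
    usable <- intersect(names(dose_s), names(dose_t))
    # indication constraint: labelled indications of the two products must
    # intersect (when both carry labels), and the matched indication must
    # have an equipotent dose on both sides
    if (length(source$indications) && length(p$indications)) {
      labelled <- intersect(source$indications, p$indications)
      if (length(labelled) == 0L) next
      usable <- intersect(usable, labelled)
    }
    if (length(usable) == 0L) next
    usable <- sort(usable)
    factors <- dose_t[usable] / dose_s[usable]
    warnings <- if (length(unique(round(factors, 9))) > 1L)
      "differing-indications" else character()
    out[[length(out) + 1L]] <- list(product = p, factor = unname(factors[[1]]),
                                    indication = usable[1],
                                    warnings = warnings)
  }
  if (length(out))
    out <- out[order(vapply(out, function(x) x$product$product_id, character(1)))]
  out
}
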