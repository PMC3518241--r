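# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published performance tables in
#' this domain are conventionally rounded half-up, so percentages recompute
#' exactly from counts.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)   # 1, not 0
#' round_half_up(68.65, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Salt/ester descriptors stripped when normalizing an ingredient name to its
# active moiety ("drug parent"). Conservative, suffix-only: a trailing match
# is removed, anything else is left untouched.
.salt_tokens <- c(
  "hydrochloride", "dihydrochloride", "hydrobromide", "sodium", "disodium",
  "potassium", "calcium", "magnesium", "tartrate", "bitartrate", "succinate",
  "fumarate", "hemifumarate", "maleate", "mesilate", "mesylate", "besilate",
  "besylate", "tosylate", "citrate", "sulfate", "sulphate", "acetate",
  "phosphate", "hydrogen", "nitrate", "oxalate", "lactate", "gluconate",
  "embonate", "pamoate", "hemihydrate", "monohydrate", "dihydrate",
  "trihydrate", "anhydrous"
)

#' Normalize an active-ingredient name to its drug parent
#'
#' Case-folds, collapses whitespace, and strips trailing salt/ester/hydrate
#' descriptors so that, e.g., "Metoprolol tartrate" and "metoprolol
#' succinate" share the parent "metoprolol". The stripped descriptor is
#' retained separately by [ingredient_strength()] for warning purposes.
#'
#' @param name character vector of ingredient names.
#' @return list with components `parent` (normalized moiety) and `salt`
#'   (stripped descriptor, `""` if none).
#' @examples
#' normalize_parent("Metoprolol tartrate")
#' normalize_parent("ferrous sulfate")  # mineral compound kept whole
#' @export
normalize_parent <- function(name) {
  x <- tolower(trimws(name))
  x <- gsub("\\s+", " ", x)
  salt <- character(length(x))
  for (i in seq_along(x)) {
    words <- strsplit(x[i], " ", fixed = TRUE)[[1]]
    # mineral compounds ("ferrous sulfate", "calcium carbonate"): the anion
    # is part of the active moiety, never a salt descriptor
    if (words[1] %in% .mineral_cations) next
    repeat {
      words <- strsplit(x[i], " ", fixed = TRUE)[[1]]
      if (length(words) < 2L || !(words[length(words)] %in% .salt_tokens)) break
      salt[i] <- trimws(paste(words[length(words)], salt[i]))
      x[i] <- paste(words[-length(words)], collapse = " ")
    }
  }
  list(parent = x, salt = salt)
}

.mineral_cations <- c("ferrous", "ferric", "iron", "calcium", "magnesium",
                      "potassium", "sodium", "aluminium", "aluminum", "zinc",
                      "lithium")

#' Validate ATC codes (levels 4 and 5)
#'
#' Accepts the chemical-subgroup (level 4, e.g. `C10AA`) and substance
#' (level 5, e.g. `C10AA01`) patterns of the Anatomic Therapeutic Chemical
#' classification.
#'
#' @param codes character vector.
#' @return logical vector, `TRUE` where syntactically valid.
#' @export
is_valid_atc <- function(codes) {
  grepl("^[A-Z][0-9]{2}[A-Z]{2}([0-9]{2})?$", codes)
}

# TRUE where any of `codes` falls under any of `prefixes` (ATC prefix match).
atc_under_prefix <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) return(FALSE)
  any(vapply(codes, function(code) {
    any(startsWith(code, prefixes))
  }, logical(1)))
}

# Amount in the comparison unit: mg for mass units, IU kept as-is but tagged.
# IU never compares to mass; the tag travels with the value.
normalize_amount <- function(amount, unit) {
  switch(unit,
    mg = amount,
    microgram = amount / 1000,
    IU = amount,
    stop("unknown unit: ", unit)
  )
}

stop_rxswitch <- function(msg, class) {
  stop(structure(
    class = c(class, "rxswitch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Near-equality for dose arithmetic on rationals stored as doubles.
near <- function(x, y, tol = 1e-9) abs(x - y) <= tol
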